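test_that("G4 effect truth table: same strands promote, mixed suppress", {
  expect_equal(g4_effect("+", "+"), "promotes")
  expect_equal(g4_effect("-", "-"), "promotes")
  expect_equal(g4_effect("+", "-"), "suppresses")
  expect_equal(g4_effect("-", "+"), "suppresses")
  # invariance under simultaneous strand inversion
  flip <- function(s) ifelse(s == "+", "-", "+")
  for (a in c("+", "-")) for (b in c("+", "-")) {
    expect_equal(g4_effect(a, b), g4_effect(flip(a), flip(b)))
  }
})

test_that("Z matches suppress regardless of bound strand; class guard enforced", {
  zf <- data.frame(chrom = "c1", start = 0, end = 20, flipon_class = "Z",
                   motif_strand = ".", id = "z1", strand = ".", stringsAsFactors = FALSE)
  for (s in c("+", "-")) {
    m <- data.frame(family = "famA", genome_strand = s, site_class = "MJ",
                    relative_strand = "coding", stringsAsFactors = FALSE)
    call <- z_effect(zf, m)
    expect_equal(call$effect, "suppresses")
    expect_equal(call$site_class, "MJ")   # junction-mediated suppression reportable
  }
  gf <- zf; gf$flipon_class <- "G"
  expect_error(z_effect(gf, m), "requires a Z flipon")
})

test_that("call_conformations emits G4/Z calls and skips S and H flipons", {
  flipons <- data.frame(chrom = "c1", start = c(0, 50, 100, 150),
                        end = c(20, 70, 120, 170),
                        flipon_class = c("G", "Z", "S", "H"),
                        motif_strand = c("+", ".", ".", "-"),
                        id = paste0("f", 1:4), strand = ".", stringsAsFactors = FALSE)
  matches <- data.frame(
    chrom = "c1", start = c(5, 55, 105, 155), end = c(12, 62, 112, 162),
    family = "famA", genome_strand = c("+", "-", "+", "+"),
    flipon_id = paste0("f", 1:4), flipon_class = c("G", "Z", "S", "H"),
    motif_strand = c("+", ".", ".", "-"), site_class = "M", overlap_bases = 7L,
    relative_strand = NA_character_, stringsAsFactors = FALSE)
  calls <- call_conformations(matches, flipons)
  expect_equal(nrow(calls), 2L)
  g4 <- calls[calls$structure == "G4", ]
  expect_equal(g4$effect, "promotes")
  expect_equal(g4$structure_strand, "+")
  expect_equal(calls$effect[calls$structure == "Z"], "suppresses")
})

test_that("hairpin folding finds designed stems and respects the loop minimum", {
  f <- fold_hairpin("GCGCGCTTTGCGCGC", allow_wobble = FALSE)
  expect_equal(f$stem_len, 6L)
  expect_equal(f$loop_len, 3L)
  expect_true(f$feasible)
  expect_true(f$z_compatible)

  # (GT)6: no canonical stem at all, a pure-wobble stem when allowed
  f0 <- fold_hairpin("GTGTGTGTGTGT", allow_wobble = FALSE)
  expect_equal(f0$stem_len, 0L)
  expect_false(f0$feasible)
  f1 <- fold_hairpin("GTGTGTGTGTGT", allow_wobble = TRUE)
  expect_gte(f1$stem_len, 4L)
  expect_true(f1$feasible)
  expect_equal(f1$pairs_used, "G:T")

  # A4T4 cannot reach a 4 bp stem once the loop takes 3 bases
  f2 <- fold_hairpin("AAAATTTT", allow_wobble = FALSE)
  expect_lte(f2$stem_len, 2L)
  expect_false(f2$feasible)

  expect_error(fold_hairpin("ACGT"), "too short")
})

test_that("wobble never shortens the best stem", {
  set.seed(99)
  for (i in 1:40) {
    s <- random_dna(sample(11:16, 1))
    f0 <- fold_hairpin(s, allow_wobble = FALSE)
    f1 <- fold_hairpin(s, allow_wobble = TRUE)
    expect_gte(f1$stem_len, f0$stem_len)
  }
})

test_that("hairpin search agrees with an independent brute-force enumerator", {
  set.seed(402)
  seqs <- c(vapply(1:60, function(i) random_dna(sample(11:14, 1)), character(1)),
            vapply(1:40, function(i) paste(sample(c("G", "T"), 12, replace = TRUE),
                                           collapse = ""), character(1)))
  for (s in seqs) {
    for (w in c(FALSE, TRUE)) {
      expect_equal(fold_hairpin(s, allow_wobble = w)$stem_len,
                   brute_force_best_stem(s, allow_wobble = w),
                   info = paste(s, w))
    }
  }
})

test_that("Z-quadruplex flag requires an alternating GT run longer than 11 bases", {
  expect_true(zq_candidate("GTGTGTGTGTGT"))        # 12 bases
  expect_false(zq_candidate("GTGTGTGTGT"))          # 10 bases
  expect_false(zq_candidate("GTGTGAGTGTGT"))        # run broken by A
  expect_false(zq_candidate("GTGTGGTGTGTG"))        # GG breaks alternation
  expect_true(zq_candidate(paste0("CCC", "TGTGTGTGTGTGT", "AAA")))
})
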