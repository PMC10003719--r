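test_that("promoters are strand-aware and clamped at chromosome edges", {
  mkgene <- function(strand, tss, start, end) {
    gene_set(data.frame(gene_id = "g", chrom = "c1", strand = strand,
                        tss = tss, start = start, end = end,
                        biotype = "coding", stringsAsFactors = FALSE))
  }
  sizes <- c(c1 = 100000)
  expect_equal(unlist(build_promoters(mkgene("+", 5000, 5000, 9000), sizes)[, c("start", "end")]),
               c(start = 4000, end = 6000))
  expect_equal(unlist(build_promoters(mkgene("-", 5000, 1000, 5001), sizes)[, c("start", "end")]),
               c(start = 4001, end = 6001))
  expect_equal(unlist(build_promoters(mkgene("+", 300, 300, 5000), sizes)[, c("start", "end")]),
               c(start = 0, end = 1300))
})

test_that("window profile counts a flipon once per window touched", {
  gs <- gene_set(data.frame(gene_id = "g", chrom = "c1", strand = "+",
                            tss = 5000, start = 5000, end = 9000,
                            biotype = "coding", stringsAsFactors = FALSE))
  prom <- build_promoters(gs, c(c1 = 100000))
  no_matches <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                           family = character(0), genome_strand = character(0),
                           flipon_id = character(0), site_class = character(0))
  fl <- data.frame(chrom = "c1", start = 4950, end = 5060, flipon_class = "Z",
                   motif_strand = ".", id = "f1", strand = ".", stringsAsFactors = FALSE)
  wp <- window_profile(fl, no_matches, prom)
  z <- wp[wp$flipon_class == "Z", ]
  expect_equal(z$flipon_count[z$window == -100], 1L)
  expect_equal(z$flipon_count[z$window == 0], 1L)
  expect_equal(sum(z$flipon_count), 2L)   # counted in both touched windows

  fl2 <- data.frame(chrom = "c1", start = 4990, end = 4995, flipon_class = "Z",
                    motif_strand = ".", id = "f1", strand = ".", stringsAsFactors = FALSE)
  wp2 <- window_profile(fl2, no_matches, prom)
  expect_equal(sum(wp2$flipon_count), 1L)
  expect_equal(wp2$flipon_count[wp2$window == -100 & wp2$flipon_class == "Z"], 1L)
})

test_that("window profile total equals the sum of windows touched per flipon", {
  b <- shared_bundle()
  ds <- shared_dataset()
  wp <- b$window_profile
  per_flipon_windows <- 0L
  prom <- b$promoters
  for (p in seq_len(nrow(prom))) {
    for (lab in seq(-1000, 900, by = 100)) {
      span <- if (prom$strand[p] == "+") c(prom$tss[p] + lab, prom$tss[p] + lab + 100) else
        c(prom$tss[p] - lab - 100 + 1, prom$tss[p] - lab + 1)
      per_flipon_windows <- per_flipon_windows +
        sum(ds$flipons$chrom == prom$chrom[p] &
              ds$flipons$start < span[2] & ds$flipons$end > span[1])
    }
  }
  expect_equal(sum(wp$flipon_count), per_flipon_windows)
})

test_that("coding/noncoding fractions are direct percentages of all flipons", {
  gs <- tiny_genes()
  sizes <- c(c1 = 1e5, chr1 = 1e5)
  fl <- data.frame(chrom = "chr1",
                   start = c(4500, 4600, 26300, 50000, 50500, 51000, 51500, 52000, 52500, 53000),
                   end = c(4520, 4620, 26320, rep(NA, 7)), stringsAsFactors = FALSE)
  fl$end[is.na(fl$end)] <- fl$start[is.na(fl$end)] + 20
  fl$flipon_class <- "Z"; fl$motif_strand <- "."; fl$id <- sprintf("f%02d", 1:10)
  fr <- coding_noncoding_fractions(fl, gs, sizes, scope = "PP")
  expect_equal(fr$pct[fr$biotype == "coding"], 20)      # 2 of 10 in coding PP
  expect_equal(fr$pct[fr$biotype == "noncoding"], 10)   # 1 of 10 in noncoding PP
  empty <- gene_set(gs$genes[0, ])
  fr0 <- coding_noncoding_fractions(fl, empty, sizes, scope = "PP")
  expect_equal(fr0$pct, c(0, 0))
  expect_true(all(fr$pct <= 100))
})

test_that("heptamer census slides one window at a time and counts overlaps", {
  genome <- c(c1 = paste0("TGTGTGTG", strrep("C", 50)))
  prom <- data.frame(gene_id = "g", chrom = "c1", start = 0, end = 8,
                     strand = "+", tss = 0, biotype = "coding", stringsAsFactors = FALSE)
  none <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  cen <- heptamer_census(prom, genome, none)
  expect_equal(cen$pp_counts[["TGTGTGT"]], 1L)
  expect_equal(cen$pp_counts[["GTGTGTG"]], 1L)
  expect_equal(sum(cen$pp_counts), 8 - 6)

  genome <- c(c1 = paste0("AAAAAAAA", strrep("C", 50)))
  cen <- heptamer_census(prom, genome, none)
  expect_equal(cen$pp_counts[["AAAAAAA"]], 2L)
})

test_that("a flipon with multiple copies of a heptamer maps to it once", {
  genome <- c(c1 = paste0(strrep("C", 10), "TGTGTGTGTGT", strrep("C", 10)))
  fl <- data.frame(chrom = "c1", start = 10, end = 21, flipon_class = "Z",
                   motif_strand = ".", id = "f1", strand = ".", stringsAsFactors = FALSE)
  prom <- data.frame(gene_id = "g", chrom = "c1", start = 0, end = 31,
                     strand = "+", tss = 0, biotype = "coding", stringsAsFactors = FALSE)
  cen <- heptamer_census(prom, genome, fl)
  # the repeat holds 3 sliding copies of TGTGTGT but the flipon counts once
  expect_equal(cen$pp_counts[["TGTGTGT"]], 3L)
  expect_equal(cen$flipon_counts[["TGTGTGT"]], 1L)
})

test_that("census total equals sum of promoter lengths minus 6 on clean promoters", {
  ds <- shared_dataset()
  b <- shared_bundle()
  cen <- b$heptamer_census
  merged <- ds$genome   # promoters are disjoint by construction
  expect_equal(sum(cen$pp_counts), sum(b$promoters$end - b$promoters$start - 6))
})
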