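mk_mirs <- function(identity7) {
  data.frame(name = paste0("fam", seq_along(identity7)),
             mature_seq = NA_character_,
             seed7 = chartr("T", "U", identity7),
             mrs_identity = identity7,
             mrs_target = revcomp(identity7),
             conserved = TRUE, stringsAsFactors = FALSE)
}

test_that("scan finds identity matches on plus and minus strands, N blocks", {
  genome <- c(c1 = "AACTACCTCAA")
  region <- genome_interval("c1", 0, 11)
  m <- scan_mrs_matches(genome, region, mk_mirs("CTACCTC"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 2)   # AACTACCTCAA: CTACCTC starts at index 2
  expect_equal(m$end, 9)
  expect_equal(m$genome_strand, "+")

  m <- scan_mrs_matches(genome, region, mk_mirs("GAGGTAG"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 2)   # revcomp(GAGGTAG) = CTACCTC found on plus
  expect_equal(m$genome_strand, "-")

  m <- scan_mrs_matches(c(c1 = "AANTACCTCAA"), region, mk_mirs("CTACCTC"))
  expect_equal(nrow(m), 0L)

  expect_error(scan_mrs_matches(genome, genome_interval("c1", 0, 50), mk_mirs("CTACCTC")),
               "bounds")
})

test_that("overlapping occurrences are all reported and junction margin is scanned", {
  genome <- c(c1 = paste0(strrep("C", 10), "AAAAAAAAA", strrep("C", 10)))
  m <- scan_mrs_matches(genome, genome_interval("c1", 10, 19), mk_mirs("AAAAAAA"))
  expect_equal(m$start, c(10, 11, 12))   # three overlapping placements

  # junction placement: the 7-mer overlaps the region by one base and is
  # only visible because of the 6 bp scan margin
  genome <- c(c1 = paste0("CC", "GATTACA", strrep("C", 20)))
  m <- scan_mrs_matches(genome, genome_interval("c1", 8, 28), mk_mirs("GATTACA"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 2)
})

test_that("scan agrees with a naive substring oracle on random sequence", {
  set.seed(301)
  mirs <- mk_mirs(vapply(1:8, function(i) random_dna(7), character(1)))
  for (rep in 1:5) {
    L <- 2000
    genome <- c(c1 = random_dna(L))
    m <- scan_mrs_matches(genome, genome_interval("c1", 0, L), mirs)
    kmers <- substring(genome[["c1"]], 1:(L - 6), 7:L)
    oracle <- do.call(rbind, lapply(seq_len(nrow(mirs)), function(j) {
      sp <- which(kmers == mirs$mrs_identity[j]) - 1
      sm <- which(kmers == revcomp(mirs$mrs_identity[j])) - 1
      rbind(
        data.frame(start = sp, family = rep(mirs$name[j], length(sp)),
                   genome_strand = rep("+", length(sp))),
        data.frame(start = sm, family = rep(mirs$name[j], length(sm)),
                   genome_strand = rep("-", length(sm))))
    }))
    oracle <- oracle[order(oracle$start, oracle$family, oracle$genome_strand), ]
    got <- m[order(m$start, m$family, m$genome_strand), c("start", "family", "genome_strand")]
    rownames(oracle) <- rownames(got) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("classify_site follows the overlap-count rule at the spec anchors", {
  fl <- genome_interval("chr1", 100, 150)
  expect_equal(classify_site(genome_interval("chr1", 110, 117), fl),
               list(site_class = "M", overlap_bases = 7L))
  # 5'-end minus 6 bp: single-base junction overlap
  expect_equal(classify_site(genome_interval("chr1", 94, 101), fl),
               list(site_class = "J", overlap_bases = 1L))
  expect_equal(classify_site(genome_interval("chr1", 146, 153), fl),
               list(site_class = "MJ", overlap_bases = 4L))
  expect_equal(classify_site(genome_interval("chr1", 0, 7), fl)$site_class, "none")
})

test_that("sliding a 7-mer across a flipon visits J, MJx5, M..., MJx5, J", {
  for (flen in c(7, 12, 30)) {
    fl <- genome_interval("chr1", 1000, 1000 + flen)
    classes <- vapply(seq(1000 - 7, 1000 + flen), function(s) {
      classify_site(genome_interval("chr1", s, s + 7), fl)$site_class
    }, character(1))
    expect_equal(classes[1], "none")
    inner <- classes[-c(1, length(classes))]
    expect_equal(classes[length(classes)], "none")
    expect_equal(inner, c("J", rep("MJ", 5), rep("M", flen - 6), rep("MJ", 5), "J"))
  }
  # sub-7 bp flipons can never host an M site
  fl <- genome_interval("chr1", 1000, 1004)
  classes <- vapply(seq(1000 - 7, 1004), function(s) {
    classify_site(genome_interval("chr1", s, s + 7), fl)$site_class
  }, character(1))
  expect_false("M" %in% classes)
  expect_true(all(classes %in% c("none", "J", "MJ")))
})

test_that("relative strand follows gene orientation and NA without a gene", {
  expect_equal(assign_relative_strand("+", "+"), "coding")
  expect_equal(assign_relative_strand("+", "-"), "template")
  expect_equal(assign_relative_strand("-", "-"), "coding")
  expect_true(is.na(assign_relative_strand("+", NA)))
})

test_that("a 7-mer overlapping two flipons is recorded once per flipon", {
  flipons <- data.frame(chrom = "c1", start = c(10, 20), end = c(18, 30),
                        flipon_class = c("Z", "G"), motif_strand = c(".", "+"),
                        id = c("f1", "f2"), strand = ".", stringsAsFactors = FALSE)
  matches <- data.frame(chrom = "c1", start = 15, end = 22, family = "famX",
                        genome_strand = "+", stringsAsFactors = FALSE)
  cl <- classify_matches(matches, flipons)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$flipon_id, c("f1", "f2"))
  expect_equal(sort(cl$overlap_bases), c(2L, 3L))
  expect_true(all(cl$site_class == "MJ"))
})

test_that("summary tables count families per flipon, strands and composition", {
  flipons <- data.frame(chrom = "c1", start = c(10, 100), end = c(40, 140),
                        flipon_class = c("Z", "G"), motif_strand = c(".", "+"),
                        id = c("f1", "f2"), strand = ".", stringsAsFactors = FALSE)
  matches <- data.frame(
    chrom = "c1", start = c(15, 20, 15), end = c(22, 27, 22),
    family = c("famA", "famB", "famA"), genome_strand = c("+", "-", "-"),
    stringsAsFactors = FALSE)
  cl <- classify_matches(matches, flipons)
  cl$gene_id <- "gX"; cl$gene_strand <- "+"
  cl$relative_strand <- assign_relative_strand(cl$genome_strand, cl$gene_strand)
  s <- summarize_matches(cl, flipons)
  # f1 matched by two families, f2 by none
  expect_equal(s$family_per_flipon_hist$n_flipons[s$family_per_flipon_hist$n_families == 0], 1L)
  expect_equal(s$family_per_flipon_hist$n_flipons[s$family_per_flipon_hist$n_families == 2], 1L)
  # famA hits both strands at one flipon
  famA <- s$strand_counts[s$strand_counts$family == "famA", ]
  expect_equal(sort(famA$relative_strand), c("coding", "template"))
  expect_equal(famA$n_sites, c(1L, 1L))
  expect_equal(sum(s$site_class_composition$n_sites), 3L)
})
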