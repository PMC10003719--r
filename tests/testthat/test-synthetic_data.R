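test_that("generation is deterministic: same seed gives identical files", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  cfg <- default_synthetic_config(seed = 5L)
  cfg$chrom_sizes <- c(chr1 = 3e5, chr2 = 3e5)
  cfg$n_coding <- 10L; cfg$n_noncoding <- 6L
  plan <- default_flipon_plan(); plan$n <- pmax(1L, plan$n %/% 5L)
  cfg$flipon_plan <- plan
  mp <- default_mrs_plan(); mp$n <- pmax(1L, mp$n %/% 4L)
  cfg$mrs_plan <- mp
  build_synthetic_dataset(cfg, out_dir = d1)
  build_synthetic_dataset(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("digest of", f))
  }
})

test_that("planted flipons land where the plan says and SIDD lengths average 170", {
  ds <- shared_dataset()
  fl <- ds$flipons
  g <- ds$genes$genes
  pp <- fl[fl$placement %in% c("PP_coding", "PP_noncoding"), ]
  for (i in seq_len(nrow(pp))) {
    gene <- g[g$gene_id == pp$gene_id[i], ]
    mid <- (pp$start[i] + pp$end[i]) / 2
    expect_lte(abs(mid - gene$tss), 1000)
  }
  slen <- fl$end[fl$flipon_class == "S"] - fl$start[fl$flipon_class == "S"]
  expect_lt(abs(mean(slen) - 170), 5)
})

test_that("pristine flipon sequences match their class consensus patterns", {
  ds <- shared_dataset()
  pats <- motif_consensus_patterns()
  fl <- ds$flipons[ds$flipons$pristine, ]
  expect_gt(nrow(fl), 50)
  for (i in seq_len(nrow(fl))) {
    s <- substr(ds$genome[[fl$chrom[i]]], fl$start[i] + 1, fl$end[i])
    pat <- switch(fl$flipon_class[i],
                  Z = pats$Z,
                  S = pats$S,
                  G = if (fl$motif_strand[i] == "-") pats$G_minus else pats$G_plus,
                  H = if (fl$motif_strand[i] == "-") pats$H_minus else pats$H_plus)
    expect_true(grepl(pat, s), info = paste(fl$id[i], fl$flipon_class[i], s))
  }
})

test_that("no planted 7-mer occurs anywhere outside its intended site", {
  ds <- shared_dataset()
  sites <- ds$manifest$sites
  for (j in seq_len(nrow(ds$mirs))) {
    for (pat in c(ds$mirs$mrs_identity[j], ds$mirs$mrs_target[j])) {
      found <- do.call(rbind, lapply(names(ds$genome), function(chrom) {
        hits <- Biostrings::start(Biostrings::matchPattern(pat, Biostrings::DNAString(ds$genome[[chrom]]))) - 1L
        if (length(hits)) data.frame(chrom = chrom, start = hits) else NULL
      }))
      if (is.null(found)) next
      key <- paste(found$chrom, found$start)
      expect_true(all(key %in% paste(sites$chrom, sites$start)),
                  info = paste("stray occurrences of", pat))
    }
  }
})

test_that("planted J sites overlap their flipon by exactly one base", {
  ds <- shared_dataset()
  st <- ds$manifest$sites
  fl <- ds$flipons
  j <- st[st$site_class == "J", ]
  m <- match(j$flipon_id, fl$id)
  expect_true(all(j$start == fl$start[m] - 6 | j$start == fl$end[m] - 1))
  expect_true(all(j$overlap_bases == 1))
})

test_that("minus-strand plants put the reverse complement on the plus strand", {
  ds <- shared_dataset()
  st <- ds$manifest$sites
  mir <- ds$mirs
  for (i in seq_len(nrow(st))) {
    kmer <- substr(ds$genome[[st$chrom[i]]], st$start[i] + 1, st$end[i])
    ident <- mir$mrs_identity[mir$name == st$family[i]]
    expect_equal(kmer, if (st$strand[i] == "+") ident else revcomp(ident),
                 info = paste("site", i))
  }
})

test_that("the truth manifest validates, round-trips, and guards inconsistency", {
  ds <- shared_dataset()
  expect_true(validate_truth_manifest(ds$manifest))
  p <- tempfile(fileext = ".json")
  emit_truth_manifest(ds$manifest, p)
  m2 <- read_truth_manifest(p)
  expect_equal(m2$schema_version, "1.0")
  expect_equal(as.data.frame(m2$sites), ds$manifest$sites)
  expect_equal(as.data.frame(m2$flipons), ds$manifest$flipons)
  bad <- ds$manifest
  bad$sites$site_class[1] <- "J"   # a planted M site relabelled
  bad$sites$site_class[bad$sites$overlap_bases == 1][1] <- "M"
  expect_error(validate_truth_manifest(bad), "inconsistent")
})

test_that("infeasible configurations fail loudly", {
  cfg <- default_synthetic_config(seed = 3L)
  cfg$chrom_sizes <- c(chr1 = 4e4, chr2 = 4e4)   # far too small for 60 genes
  expect_error(build_synthetic_dataset(cfg), "infeasible")
})
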