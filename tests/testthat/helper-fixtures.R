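# Shared fixtures built in code. The default synthetic dataset takes a few
# seconds to generate, so it is built once per session and memoised.

.fixture_env <- new.env(parent = emptyenv())

shared_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    dir <- file.path(tempdir(), "flipmir-shared-ds")
    .fixture_env$ds <- build_synthetic_dataset(default_synthetic_config(seed = 1L),
                                               out_dir = dir)
  }
  .fixture_env$ds
}

shared_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    ds <- shared_dataset()
    .fixture_env$bundle <- run_flipon_pipeline(ds$files, seed = 1L,
                                               params = list(n_iter = 200))
  }
  .fixture_env$bundle
}

# Write a one-chromosome FASTA and return its path.
tiny_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  write_fasta(seqs, path)
  path
}

# A small two-gene annotation used across feature/promoter tests.
tiny_genes <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    start = c(5000, 20000),
    end = c(9000, 26000),
    tss = c(5000, 25999),
    biotype = c("coding", "noncoding"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1",
    start = c(5000, 8000, 25000),
    end = c(5400, 9000, 26000),
    stringsAsFactors = FALSE)
  utr5 <- data.frame(gene_id = "gA", chrom = "chr1", start = 5000, end = 5150,
                     stringsAsFactors = FALSE)
  utr3 <- data.frame(gene_id = "gA", chrom = "chr1", start = 8800, end = 9000,
                     stringsAsFactors = FALSE)
  gene_set(genes, exons = exons, utr5 = utr5, utr3 = utr3)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Independent O(n^3)-style hairpin enumerator: tries every loop interval and
# explicitly verifies every candidate stem depth pair by pair.
brute_force_best_stem <- function(seq, allow_wobble, min_loop = 3L) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  ok_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (allow_wobble && ((a == "G" && b == "T") || (a == "T" && b == "G")))
  }
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq(i, n)) {
      if (j - i + 1L < min_loop) next
      for (s in seq_len(min(i - 1L, n - j))) {
        valid <- TRUE
        for (d in seq_len(s)) {
          if (!ok_pair(ch[i - d], ch[j + d])) { valid <- FALSE; break }
        }
        if (valid) best <- max(best, s) else break
      }
    }
  }
  best
}
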