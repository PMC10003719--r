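#' Shuffle intervals uniformly within their own chromosome
#'
#' Each interval is re-placed uniformly at random on its chromosome with
#' length preserved; placements are independent, so shuffled intervals may
#' overlap one another.
#'
#' @param ivs interval data.frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param rng_seed optional integer seed for reproducibility.
#' @return interval data.frame with new starts.
#' @export
shuffle_intervals <- function(ivs, chrom_sizes, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  len <- ivs$end - ivs$start
  size <- chrom_sizes[ivs$chrom]
  if (anyNA(size)) stop("interval on chromosome absent from chrom_sizes")
  if (any(len > size)) stop("interval longer than its chromosome")
  max_start <- size - len
  new_start <- floor(stats::runif(nrow(ivs)) * (max_start + 1))
  out <- ivs
  out$start <- as.numeric(new_start)
  out$end <- as.numeric(new_start + len)
  out
}

# Merge set A per chromosome into sorted disjoint [start, end) pairs.
.merged_by_chrom <- function(ivs) {
  m <- merge_intervals(ivs)
  split(m[, c("start", "end")], m$chrom)
}

# Count B intervals overlapping (>= 1 bp) any merged-A interval.
.count_b_in_a <- function(b_chrom, b_start, b_end, merged) {
  hits <- logical(length(b_start))
  for (chrom in unique(b_chrom)) {
    ma <- merged[[chrom]]
    idx <- which(b_chrom == chrom)
    if (is.null(ma) || !nrow(ma)) next
    # only candidate for a disjoint sorted A is the last interval with
    # start < b_end
    pos <- findInterval(b_end[idx] - 0.5, ma$start)
    ok <- pos >= 1L
    ok[ok] <- ma$end[pos[ok]] > b_start[idx][ok]
    hits[idx] <- ok
  }
  sum(hits)
}

#' Monte-Carlo interval-overlap significance test
#'
#' Two regions overlap when they share at least one base pair. The observed
#' statistic is the number of `set_b` intervals overlapping any `set_a`
#' interval; the null distribution comes from `n_iter` independent
#' within-chromosome uniform re-placements of `set_b` with lengths
#' preserved. The empirical p-value uses the pseudocount estimator
#' `(1 + #\{null >= observed\}) / (n_iter + 1)`, which can never be zero.
#'
#' @param set_a,set_b interval data.frames (both non-empty).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_iter shuffles (default 1000).
#' @param rng_seed optional integer seed.
#' @return list of class `mc_test_result`: `observed`, `null_counts`,
#'   `p_value`, `n_iter`, `rng_seed`.
#' @export
mc_overlap_test <- function(set_a, set_b, chrom_sizes, n_iter = 1000, rng_seed = NULL) {
  if (!nrow(set_a) || !nrow(set_b)) stop("mc_overlap_test needs non-empty interval sets")
  stopifnot(n_iter >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  len <- set_b$end - set_b$start
  size <- unname(chrom_sizes[set_b$chrom])
  if (anyNA(size)) stop("set_b interval on chromosome absent from chrom_sizes")
  if (any(len > size)) stop("set_b interval longer than its chromosome")
  merged <- .merged_by_chrom(set_a)
  observed <- .count_b_in_a(set_b$chrom, set_b$start, set_b$end, merged)
  max_start <- size - len
  nb <- nrow(set_b)
  null_counts <- vapply(seq_len(n_iter), function(i) {
    s <- floor(stats::runif(nb) * (max_start + 1))
    .count_b_in_a(set_b$chrom, s, s + len, merged)
  }, numeric(1))
  structure(list(
    observed = observed,
    null_counts = null_counts,
    p_value = (1 + sum(null_counts >= observed)) / (n_iter + 1),
    n_iter = n_iter,
    rng_seed = rng_seed
  ), class = "mc_test_result")
}

#' Distance from anchors to the nearest peak
#'
#' Distance is 0 when the anchor lies within a peak, otherwise the distance
#' to the nearest contained base of the half-open peak interval (i.e. to
#' `start` or `end - 1`). Anchors farther than `max_dist` from every peak
#' are dropped; the remainder are binned.
#'
#' @param anchors data.frame with `chrom` and `pos` (e.g. TSS positions).
#' @param peaks interval data.frame (non-empty).
#' @param max_dist maximum distance retained, bases.
#' @param bin bin width, bases.
#' @return list: `distances` (per retained anchor) and `profile`
#'   (data.frame `distance`, `count` with one row per bin start).
#' @export
distance_profile <- function(anchors, peaks, max_dist, bin = 1) {
  if (!nrow(peaks)) stop("distance_profile needs a non-empty peak set")
  dist <- rep(NA_real_, nrow(anchors))
  for (chrom in unique(anchors$chrom)) {
    idx <- which(anchors$chrom == chrom)
    pk <- peaks[peaks$chrom == chrom, , drop = FALSE]
    if (!nrow(pk)) next
    for (i in idx) {
      p <- anchors$pos[i]
      inside <- any(p >= pk$start & p < pk$end)
      dist[i] <- if (inside) 0 else min(pmax(pk$start - p, p - (pk$end - 1)))
    }
  }
  keep <- !is.na(dist) & dist <= max_dist
  d <- dist[keep]
  breaks <- seq(0, max_dist + bin, by = bin)
  counts <- table(cut(d, breaks = breaks, right = FALSE))
  list(distances = d,
       profile = data.frame(distance = breaks[-length(breaks)],
                            count = as.integer(counts)))
}

#' Centered rolling mean
#'
#' Centered moving average; windows truncate at the series edges (no
#' padding) so the output has the length of the input. `window = 1` is the
#' identity.
#'
#' @param series numeric vector (non-empty).
#' @param window window width in elements (default 8).
#' @return numeric vector, same length as `series`.
#' @export
rolling_mean <- function(series, window = 8) {
  stopifnot(window >= 1)
  if (!length(series)) stop("rolling_mean: empty series")
  as.numeric(zoo::rollapply(zoo::zoo(series), width = window, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Hypergeometric set enrichment with Benjamini-Hochberg adjustment
#'
#' Upper-tail hypergeometric p-value per term (probability of at least the
#' observed overlap between the query set and the term set, drawing
#' `|query|` genes from the universe), adjusted across all tested terms by
#' Benjamini-Hochberg.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param terms named list: term label -> character vector of member genes.
#' @param universe character vector of all genes.
#' @return data.frame sorted by p: `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `fdr`.
#' @export
hypergeom_bh <- function(query, terms, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (any(!query %in% universe)) stop("query contains genes outside the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    tset <- unique(terms[[tm]])
    if (any(!tset %in% universe)) stop("term '", tm, "' contains genes outside the universe")
    K <- length(tset)
    k <- length(intersect(query, tset))
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
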