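#' Build strand-aware proximal promoter intervals
#'
#' Each gene's promoter spans `up` bases upstream and `down` bases
#' downstream of the TSS in transcription orientation: for `+` genes the
#' genomic interval is `[tss - up, tss + down)`; for `-` genes "upstream"
#' extends to larger coordinates, `[tss - down + 1, tss + up + 1)`.
#' Intervals are clamped to `[0, chromosome length)`.
#'
#' @param genes a [gene_set()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param up,down extent around the TSS, bases (default 1 kb each).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `biotype`.
#' @export
build_promoters <- function(genes, chrom_sizes, up = 1000, down = 1000) {
  stopifnot(up >= 0, down >= 0)
  g <- genes$genes
  start <- ifelse(g$strand == "+", g$tss - up, g$tss - down + 1)
  end <- ifelse(g$strand == "+", g$tss + down, g$tss + up + 1)
  lim <- chrom_sizes[g$chrom]
  data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = pmax(0, start), end = pmin(unname(lim), end),
    strand = g$strand, tss = g$tss, biotype = g$biotype,
    stringsAsFactors = FALSE
  )
}

# Genomic span of the promoter window with transcription-relative label
# `lab` (bp offset of the window's upstream edge from the TSS; negative =
# upstream) for one promoter row.
.window_span <- function(prom, lab, window) {
  if (prom$strand == "+") {
    c(prom$tss + lab, prom$tss + lab + window)
  } else {
    c(prom$tss - lab - window + 1, prom$tss - lab + 1)
  }
}

#' Flipon and mRS density profile in promoter windows
#'
#' Splits each promoter into consecutive 100 bp windows indexed relative to
#' the TSS in transcription orientation (labels `-up .. down - window`); a
#' flipon overlapping two windows is counted as present in both, and counts
#' are summed across every gene promoter. Also counted per window: flipons
#' with at least one mRS site, and mRS match 7-mers.
#'
#' @param flipons flipon table.
#' @param matches classified match table (may have zero rows).
#' @param promoters output of [build_promoters()].
#' @param window window width, bases.
#' @param up,down promoter extent used to label windows.
#' @return data.frame with `window` (offset label), `flipon_class`,
#'   `flipon_count`, `matched_flipon_count`, `mrs_count`.
#' @export
window_profile <- function(flipons, matches, promoters, window = 100,
                           up = 1000, down = 1000) {
  labs <- seq(-up, down - window, by = window)
  classes <- c("G", "Z", "S", "H")
  flipon_count <- matched_count <- matrix(
    0L, nrow = length(labs), ncol = length(classes),
    dimnames = list(labs, classes))
  mrs_count <- matrix(0L, nrow = length(labs), ncol = length(classes),
                      dimnames = list(labs, classes))
  hit <- matches[!is.na(matches$flipon_id) & matches$site_class != "none", , drop = FALSE]
  matched_ids <- unique(hit$flipon_id)
  for (p in seq_len(nrow(promoters))) {
    prom <- promoters[p, ]
    fl <- flipons[flipons$chrom == prom$chrom, , drop = FALSE]
    mm <- hit[hit$chrom == prom$chrom, , drop = FALSE]
    for (w in seq_along(labs)) {
      span <- .window_span(prom, labs[w], window)
      span[1] <- max(0, span[1])
      if (span[2] <= span[1]) next
      ovl_f <- fl$start < span[2] & fl$end > span[1]
      if (any(ovl_f)) {
        tab <- table(factor(fl$flipon_class[ovl_f], levels = classes))
        flipon_count[w, ] <- flipon_count[w, ] + as.integer(tab)
        tabm <- table(factor(fl$flipon_class[ovl_f & fl$id %in% matched_ids],
                             levels = classes))
        matched_count[w, ] <- matched_count[w, ] + as.integer(tabm)
      }
      ovl_m <- mm$start < span[2] & mm$end > span[1]
      if (any(ovl_m)) {
        key <- unique(mm[ovl_m, c("family", "start", "genome_strand", "flipon_class")])
        tab <- table(factor(key$flipon_class, levels = classes))
        mrs_count[w, ] <- mrs_count[w, ] + as.integer(tab)
      }
    }
  }
  out <- expand.grid(window = labs, flipon_class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$flipon_count <- as.integer(flipon_count[cbind(match(out$window, labs),
                                                    match(out$flipon_class, classes))])
  out$matched_flipon_count <- as.integer(matched_count[cbind(match(out$window, labs),
                                                             match(out$flipon_class, classes))])
  out$mrs_count <- as.integer(mrs_count[cbind(match(out$window, labs),
                                              match(out$flipon_class, classes))])
  out
}

#' Fraction of flipons in coding versus non-coding promoters or gene bodies
#'
#' Percent of all flipons overlapping (>= 1 bp) the proximal-promoter set or
#' the gene-body set of each biotype. A flipon overlapping spans of both
#' biotypes counts in both numerators.
#'
#' @param flipons flipon table.
#' @param genes a [gene_set()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param scope `"PP"` (TSS +/- 1 kb) or `"gene_body"`.
#' @param up,down promoter extent for the PP scope.
#' @return data.frame with `biotype`, `n_flipons`, `pct`.
#' @export
coding_noncoding_fractions <- function(flipons, genes, chrom_sizes,
                                       scope = c("PP", "gene_body"),
                                       up = 1000, down = 1000) {
  scope <- match.arg(scope)
  total <- nrow(flipons)
  spans <- if (scope == "PP") {
    build_promoters(genes, chrom_sizes, up = up, down = down)
  } else {
    g <- genes$genes
    data.frame(chrom = g$chrom, start = g$start, end = g$end,
               biotype = g$biotype, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c("coding", "noncoding"), function(bt) {
    sub <- spans[spans$biotype == bt, , drop = FALSE]
    n <- if (total && nrow(sub)) sum(overlaps_any(flipons, sub)) else 0L
    data.frame(biotype = bt, n_flipons = n,
               pct = if (total) 100 * n / total else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# k-mer sliding-window counts for one string; windows containing N skipped.
.count_kmers <- function(seq, k = 7L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers[!grepl("N", kmers, fixed = TRUE)]
}

#' Promoter heptamer census
#'
#' Counts every 7-mer window on the transcription-oriented sequence of each
#' promoter (overlapping promoters on the same strand are merged first so
#' shared sequence is counted once; set `merge = FALSE` to count per gene).
#' A second table counts, per heptamer, the number of distinct flipons whose
#' plus-strand sequence contains it at least once — a flipon carrying many
#' copies of a heptad still counts once, the distinction behind occurrence
#' versus flipon stoichiometry.
#'
#' @param promoters output of [build_promoters()].
#' @param genome named character vector from [load_genome()].
#' @param flipons flipon table (may be empty).
#' @param merge merge overlapping same-strand promoters before counting.
#' @param both_strands also census the reverse complement of each promoter.
#' @return list with `pp_counts` and `flipon_counts`, named integer vectors
#'   keyed by heptamer.
#' @export
heptamer_census <- function(promoters, genome, flipons, merge = TRUE,
                            both_strands = FALSE) {
  clen <- nchar(genome)[promoters$chrom]
  if (any(promoters$end > clen)) stop("promoter out of genome bounds")
  spans <- promoters[, c("chrom", "start", "end", "strand")]
  if (merge && nrow(spans)) {
    spans <- do.call(rbind, lapply(split(spans, spans$strand), function(grp) {
      m <- merge_intervals(grp)
      m$strand <- grp$strand[1]
      m
    }))
  }
  kmers <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    s <- substr(genome[[spans$chrom[i]]], spans$start[i] + 1, spans$end[i])
    if (spans$strand[i] == "-") s <- revcomp(s)
    if (both_strands) c(.count_kmers(s), .count_kmers(revcomp(s))) else .count_kmers(s)
  }))
  pp_counts <- if (length(kmers)) {
    tab <- table(kmers)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))

  fl_sets <- lapply(seq_len(nrow(flipons)), function(i) {
    s <- substr(genome[[flipons$chrom[i]]], flipons$start[i] + 1, flipons$end[i])
    sets <- unique(.count_kmers(s))
    if (both_strands) unique(c(sets, .count_kmers(revcomp(s)))) else sets
  })
  fl_kmers <- unlist(fl_sets)
  flipon_counts <- if (length(fl_kmers)) {
    tab <- table(fl_kmers)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  list(pp_counts = pp_counts, flipon_counts = flipon_counts)
}
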