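#' Feature label priority order
#'
#' The default mirrors the conventional peak-annotation precedence: promoter
#' bands first, then UTRs, exon, intron, downstream, distal intergenic.
#' @return character vector of labels in decreasing priority.
#' @export
feature_priority <- function() {
  c("Promoter<=1kb", "Promoter1-2kb", "Promoter2-3kb", "5UTR", "3UTR",
    "Exon", "Intron", "Downstream", "DistalIntergenic")
}

# Candidate labels for one midpoint against one gene row (+ its sub-features).
.labels_for_gene <- function(mid, gene, exons, utr5, utr3, downstream) {
  labs <- character(0)
  u <- if (gene$strand == "+") gene$tss - mid else mid - gene$tss
  if (u > 0) {
    if (u <= 1000) labs <- c(labs, "Promoter<=1kb")
    else if (u <= 2000) labs <- c(labs, "Promoter1-2kb")
    else if (u <= 3000) labs <- c(labs, "Promoter2-3kb")
  }
  inside <- mid >= gene$start && mid < gene$end
  if (inside) {
    in_iv <- function(tab) nrow(tab) && any(mid >= tab$start & mid < tab$end)
    if (in_iv(utr5)) labs <- c(labs, "5UTR")
    if (in_iv(utr3)) labs <- c(labs, "3UTR")
    labs <- c(labs, if (in_iv(exons)) "Exon" else "Intron")
  } else {
    d3 <- if (gene$strand == "+") mid - (gene$end - 1) else gene$start - mid
    if (d3 > 0 && d3 <= downstream) labs <- c(labs, "Downstream")
  }
  labs
}

#' Assign each interval to a genomic feature
#'
#' One label per interval, anchored at the interval midpoint and chosen by
#' distance to the nearest TSS and by containment, with the priority order
#' of [feature_priority()]: promoter bands (upstream distance to a TSS of
#' <=1 kb, 1-2 kb, 2-3 kb), 5'/3' UTR, exon, intron, downstream (within
#' `downstream` bases past the gene 3' end), else distal intergenic.
#'
#' @param ivs interval data.frame.
#' @param genes a [gene_set()].
#' @param downstream extent of the downstream window past the gene end, bp.
#' @param priority label order; earlier wins when several genes offer labels.
#' @return character vector of feature labels, one per row of `ivs`.
#' @export
assign_feature <- function(ivs, genes, downstream = 3000, priority = feature_priority()) {
  g <- genes$genes
  out <- rep("DistalIntergenic", nrow(ivs))
  if (!nrow(g)) return(out)
  ex_by_g <- split(genes$exons, genes$exons$gene_id)
  u5_by_g <- split(genes$utr5, genes$utr5$gene_id)
  u3_by_g <- split(genes$utr3, genes$utr3$gene_id)
  empty <- genes$exons[0, ]
  for (i in seq_len(nrow(ivs))) {
    mid <- floor((ivs$start[i] + ivs$end[i]) / 2)
    # genes whose span padded by 3 kb (promoter/downstream reach) covers mid
    pad <- max(3000, downstream)
    cand <- g[g$chrom == ivs$chrom[i] & mid >= g$start - pad & mid < g$end + pad, ,
              drop = FALSE]
    labs <- character(0)
    for (j in seq_len(nrow(cand))) {
      gid <- cand$gene_id[j]
      labs <- c(labs, .labels_for_gene(
        mid, cand[j, ],
        if (!is.null(ex_by_g[[gid]])) ex_by_g[[gid]] else empty,
        if (!is.null(u5_by_g[[gid]])) u5_by_g[[gid]] else empty,
        if (!is.null(u3_by_g[[gid]])) u3_by_g[[gid]] else empty,
        downstream))
    }
    if (length(labs)) out[i] <- priority[min(match(labs, priority))]
  }
  out
}

#' Merge LINE and LTR tracks into one TRE track
#'
#' LINE and LTR repeats are considered jointly as transposon repeat
#' elements (TREs).
#'
#' @param line,ltr interval data.frames (either may be empty or `NULL`).
#' @return combined interval data.frame.
#' @export
merge_tre_tracks <- function(line, ltr) {
  keep <- c("chrom", "start", "end")
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                  list(line, ltr))
  if (!length(parts)) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  out <- do.call(rbind, lapply(parts, function(x) x[, keep]))
  rownames(out) <- NULL
  out
}

#' Regulatory-context category of each flipon
#'
#' Each flipon is extended by `ext` bases on either side (clamped at 0) and
#' tested for >= 1 bp overlap against the cCRE, TRE (merged LINE/LTR) and
#' CTCF tracks; the three booleans map onto eight categories that partition
#' the input.
#'
#' @param flipons flipon interval table.
#' @param ccre,ctcf,tre interval data.frames.
#' @param ext extension in bases (default 200).
#' @return character vector of categories: `cCRE_only`, `LINE_LTR_only`,
#'   `cCRE_and_LINE_LTR`, `CTCF_only`, `cCRE_and_CTCF`, `LINE_LTR_and_CTCF`,
#'   `cCRE_and_LINE_LTR_and_CTCF`, `none`.
#' @export
categorize_regulatory <- function(flipons, ccre, ctcf, tre, ext = 200) {
  stopifnot(ext >= 0)
  extd <- flipons
  extd$start <- pmax(0, flipons$start - ext)
  extd$end <- flipons$end + ext
  has_ccre <- overlaps_any(extd, ccre)
  has_tre <- overlaps_any(extd, tre)
  has_ctcf <- overlaps_any(extd, ctcf)
  key <- paste0(as.integer(has_ccre), as.integer(has_tre), as.integer(has_ctcf))
  map <- c(`000` = "none", `100` = "cCRE_only", `010` = "LINE_LTR_only",
           `110` = "cCRE_and_LINE_LTR", `001` = "CTCF_only",
           `101` = "cCRE_and_CTCF", `011` = "LINE_LTR_and_CTCF",
           `111` = "cCRE_and_LINE_LTR_and_CTCF")
  unname(map[key])
}
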