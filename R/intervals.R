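#' Construct a table of genomic intervals
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' `start` is the first base of the interval, `end` is one past the last.
#' GTF input is converted to this convention at the I/O boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param id optional stable identifiers (recycled; `NA` allowed).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, `id`.
#' @export
genome_interval <- function(chrom, start, end, strand = ".", id = NA_character_) {
  iv <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    id = as.character(id),
    stringsAsFactors = FALSE
  )
  validate_intervals(iv)
  iv
}

#' Validate an interval table
#'
#' Checks the invariants `0 <= start < end`, non-empty chromosome names and a
#' legal strand code, stopping with an informative message on the first
#' violation.
#'
#' @param iv interval data.frame as built by [genome_interval()].
#' @return `iv`, invisibly.
#' @export
validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(iv))
  if (length(miss)) stop("interval table lacks columns: ", paste(miss, collapse = ", "))
  if (any(is.na(iv$chrom)) || any(!nzchar(iv$chrom))) stop("empty chromosome name")
  if (any(iv$start < 0)) stop("negative start coordinate")
  bad <- which(iv$start >= iv$end)
  if (length(bad)) {
    stop("zero- or negative-length interval at row ", bad[1],
         " (", iv$chrom[bad[1]], ":", iv$start[bad[1]], "-", iv$end[bad[1]], ")")
  }
  if ("strand" %in% names(iv) && !all(iv$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(iv)
}

#' Overlap length of two intervals
#'
#' Length in bases shared by `a` and `b`; 0 when they lie on different
#' chromosomes or do not intersect. Two regions overlap when they have at
#' least one base pair in common, so half-open adjacency gives 0.
#'
#' @param a,b single-row interval data.frames (or lists with `chrom`,
#'   `start`, `end`).
#' @return non-negative integer.
#' @export
overlap_len <- function(a, b) {
  if (as.character(a$chrom)[1] != as.character(b$chrom)[1]) return(0L)
  as.integer(max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1])))
}

# Vectorised overlap of one interval against many rows of `ivs` on the same
# chromosome grid; returns integer vector.
overlap_len_vec <- function(chrom, start, end, ivs) {
  out <- pmin(end, ivs$end) - pmax(start, ivs$start)
  out[ivs$chrom != chrom] <- 0
  as.integer(pmax(0L, out))
}

# Convert a 0-based half-open interval table to GRanges (1-based closed).
iv_to_granges <- function(iv) {
  strand <- if ("strand" %in% names(iv)) {
    ifelse(iv$strand %in% c("+", "-"), iv$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = strand
  )
}

#' Which query intervals overlap any subject interval
#'
#' Overlap means at least one shared base pair (half-open adjacency does
#' not count).
#'
#' @param query,subject interval data.frames.
#' @return logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  if (nrow(query) == 0L) return(logical(0))
  hits <- GenomicRanges::findOverlaps(iv_to_granges(query), iv_to_granges(subject),
                                      ignore.strand = TRUE)
  out <- rep(FALSE, nrow(query))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# All (query, subject) overlap pairs as a two-column data.frame of row indices.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(iv_to_granges(query), iv_to_granges(subject),
                                      ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits), subject = S4Vectors::subjectHits(hits))
}

# Merge overlapping/adjacent intervals; returns chrom/start/end table.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(iv_to_granges(iv), ignore.strand = TRUE)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Reverse complement of a DNA sequence
#'
#' Alphabet `{A, C, G, T, N}`; `N` maps to `N`. Vectorised over `seq`;
#' the empty string maps to itself.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seq))) stop("revcomp: sequence contains non-ACGTN characters")
  out <- chartr("ACGT", "TGCA", seq)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
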