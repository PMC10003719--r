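#' Effect of a miR seed match on G-quadruplex formation
#'
#' When the G-rich strand of a G flipon and the mRS match lie on the same
#' strand ("+,+" or "-,-") the miR sequesters the C-rich strand's partner
#' and G4 formation is promoted, with the quadruplex forming on the G-rich
#' strand; when they lie on opposite strands the miR pairs with the G-rich
#' strand itself and G4 formation is suppressed. The outcome does not
#' depend on the direction of transcription.
#'
#' @param grich_strand strand carrying the G runs (`+`/`-`), vectorised.
#' @param mrs_strand genomic strand of the match (`+`/`-`).
#' @return character vector: `"promotes"` or `"suppresses"`.
#' @export
g4_effect <- function(grich_strand, mrs_strand) {
  stopifnot(all(grich_strand %in% c("+", "-")), all(mrs_strand %in% c("+", "-")))
  ifelse(grich_strand == mrs_strand, "promotes", "suppresses")
}

#' Effect of a miR seed match on Z-DNA formation
#'
#' A miR binding either strand of a Z flipon inhibits the flip to the
#' left-handed conformation, regardless of whether the upper or lower DNA
#' strand is bound; junction-class sites (J/MJ) act by blocking formation
#' of the B-Z junction, so the site class is carried in the call.
#'
#' @param flipon single-row flipon record of class Z.
#' @param match single-row classified match.
#' @return data.frame conformation call with `flipon_id`, `family`,
#'   `effect`, `structure`, `structure_strand`, `site_class`,
#'   `relative_to_gene`.
#' @export
z_effect <- function(flipon, match) {
  if (flipon$flipon_class[1] != "Z") {
    stop("z_effect requires a Z flipon, got class ", flipon$flipon_class[1])
  }
  data.frame(
    flipon_id = flipon$id[1], family = match$family[1],
    effect = "suppresses", structure = "Z",
    structure_strand = ".",
    site_class = match$site_class[1],
    relative_to_gene = if ("relative_strand" %in% names(match))
      match$relative_strand[1] else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Conformation calls for all G and Z flipon matches
#'
#' Applies [g4_effect()] to matches on G flipons (using the flipon's
#' G-rich motif strand) and [z_effect()] to matches on Z flipons. S and H
#' flipons receive no call: no miR-directed promote/suppress rule is
#' defined for them.
#'
#' @param matches classified (and gene-annotated) match table.
#' @param flipons flipon table.
#' @return data.frame of conformation calls.
#' @export
call_conformations <- function(matches, flipons) {
  hit <- matches[!is.na(matches$flipon_id) & matches$site_class != "none", , drop = FALSE]
  hit <- hit[hit$flipon_class %in% c("G", "Z"), , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(flipon_id = character(0), family = character(0),
                      effect = character(0), structure = character(0),
                      structure_strand = character(0), site_class = character(0),
                      relative_to_gene = character(0), stringsAsFactors = FALSE))
  }
  rel <- if ("relative_strand" %in% names(hit)) hit$relative_strand else NA_character_
  isg <- hit$flipon_class == "G"
  effect <- character(nrow(hit))
  strand_out <- rep(".", nrow(hit))
  effect[!isg] <- "suppresses"
  if (any(isg)) {
    effect[isg] <- g4_effect(hit$motif_strand[isg], hit$genome_strand[isg])
    strand_out[isg] <- ifelse(effect[isg] == "promotes", hit$motif_strand[isg], ".")
  }
  out <- data.frame(
    flipon_id = hit$flipon_id, family = hit$family,
    effect = effect,
    structure = ifelse(isg, "G4", "Z"),
    structure_strand = strand_out,
    site_class = hit$site_class,
    relative_to_gene = rel,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# TRUE where the base sequence alternates purine/pyrimidine at every step.
.alternates_ry <- function(chars) {
  if (length(chars) <= 1L) return(TRUE)
  pur <- chars %in% c("A", "G")
  all(pur[-1] != pur[-length(pur)])
}

#' Best fold-back hairpin of a DNA strand
#'
#' Exhaustive search over all loop placements: for a loop spanning
#' `[i, j]` the stem pairs `seq[i-k]` with `seq[j+k]` for contiguous
#' `k = 1, 2, ...` while the pair is Watson-Crick (`A:T`, `G:C`) or, with
#' `allow_wobble`, the non-canonical `G:T` wobble. The fold maximising stem
#' length wins (ties: shorter loop, then leftmost). A stem shorter than
#' `min_stem` is reported infeasible. `z_compatible` is true when both stem
#' arms alternate purine/pyrimidine, the hallmark of Z-prone sequence.
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param allow_wobble allow `G:T` pairs in the stem.
#' @param min_stem minimum paired bases for a feasible hairpin.
#' @param min_loop minimum unpaired loop length.
#' @return list of class `hairpin_fold`: `sequence`, `loop_start` (1-based),
#'   `loop_len`, `stem_len`, `feasible`, `pairs_used`, `z_compatible`.
#' @export
fold_hairpin <- function(seq, allow_wobble = FALSE, min_stem = 4L, min_loop = 3L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < min_loop + 2) {
    stop("sequence too short to fold: need >= ", min_loop + 2, " bases")
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pair_type <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return("A:T")
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return("G:C")
    if (allow_wobble && ((a == "G" && b == "T") || (a == "T" && b == "G"))) return("G:T")
    NA_character_
  }
  best <- list(stem_len = -1L, loop_start = 1L, loop_len = n, pairs = character(0))
  for (i in seq_len(n)) {
    if (i + min_loop - 1L > n) break
    for (j in seq(i + min_loop - 1L, n)) {
      stem <- 0L
      pairs <- character(0)
      while (i - stem - 1L >= 1L && j + stem + 1L <= n) {
        pt <- pair_type(ch[i - stem - 1L], ch[j + stem + 1L])
        if (is.na(pt)) break
        stem <- stem + 1L
        pairs <- c(pairs, pt)
      }
      ll <- j - i + 1L
      if (stem > best$stem_len ||
          (stem == best$stem_len && ll < best$loop_len) ||
          (stem == best$stem_len && ll == best$loop_len && i < best$loop_start)) {
        best <- list(stem_len = stem, loop_start = i, loop_len = ll, pairs = pairs)
      }
    }
  }
  left <- if (best$stem_len > 0) ch[(best$loop_start - 1):(best$loop_start - best$stem_len)] else character(0)
  right <- if (best$stem_len > 0) {
    j <- best$loop_start + best$loop_len - 1L
    ch[(j + 1):(j + best$stem_len)]
  } else character(0)
  structure(list(
    sequence = seq,
    loop_start = best$loop_start,
    loop_len = best$loop_len,
    stem_len = max(0L, best$stem_len),
    feasible = best$stem_len >= min_stem,
    pairs_used = sort(unique(best$pairs)),
    z_compatible = best$stem_len > 0 && .alternates_ry(left) && .alternates_ry(right)
  ), class = "hairpin_fold")
}

#' Z-quadruplex candidate flag
#'
#' A strand is a Z-quadruplex candidate when it contains an uninterrupted
#' alternating G/T dinucleotide repeat longer than 11 bases — repeats of
#' that length can fold into a left-handed quadruplex instead of a wobble
#' hairpin.
#'
#' @param seq DNA string.
#' @return logical.
#' @export
zq_candidate <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  best <- run <- 0L
  prev <- ""
  for (c in ch) {
    if ((c == "G" || c == "T") && c != prev) {
      run <- run + 1L
    } else if (c == "G" || c == "T") {
      run <- 1L   # identical adjacent base restarts the alternating run
    } else {
      run <- 0L
    }
    best <- max(best, run)
    prev <- c
  }
  best > 11L
}
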