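#' Scan regions for perfect 7-mer mRS matches on both strands
#'
#' Every position where the plus-strand 7-mer equals a family's match 7-mer
#' yields a match with `genome_strand = "+"`; positions where the plus
#' strand carries the reverse complement yield `genome_strand = "-"`.
#' Each region is scanned with a 6 bp margin on either side (clamped to the
#' chromosome) so junction placements at region edges are visible. 7-mers
#' containing N never match. Matches are deduplicated by
#' (family, position, strand) and returned in coordinate order.
#'
#' @param genome named character vector from [load_genome()].
#' @param regions interval data.frame of regions to scan.
#' @param mirs miR family table from [load_mir_table()].
#' @param mode `"identity"`: the match 7-mer is the DNA transliteration of
#'   the seed (a strand matching the seed sequence); `"complement"`: the
#'   reverse-complement target 7-mer a miR would pair with.
#' @param margin bases scanned beyond each region boundary.
#' @return data.frame with columns `chrom`, `start`, `end`, `family`,
#'   `genome_strand`.
#' @export
scan_mrs_matches <- function(genome, regions, mirs, mode = c("identity", "complement"),
                             margin = 6L) {
  mode <- match.arg(mode)
  if (!nrow(mirs)) stop("no miR families supplied")
  validate_intervals(regions)
  if (any(!regions$chrom %in% names(genome))) {
    stop("region on unknown chromosome: ",
         regions$chrom[!regions$chrom %in% names(genome)][1])
  }
  clen <- nchar(genome)[regions$chrom]
  if (any(regions$end > clen)) stop("region out of genome bounds")
  pat <- if (mode == "identity") mirs$mrs_identity else mirs$mrs_target
  rc <- revcomp(pat)
  out <- vector("list", nrow(regions) * 2L)
  k <- 0L
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    s0 <- max(0, regions$start[i] - margin)
    e0 <- min(nchar(genome[[chrom]]), regions$end[i] + margin)
    if (e0 - s0 < 7L) next
    subject <- Biostrings::DNAString(substr(genome[[chrom]], s0 + 1, e0))
    for (j in seq_len(nrow(mirs))) {
      plus <- Biostrings::start(Biostrings::matchPattern(pat[j], subject))
      minus <- Biostrings::start(Biostrings::matchPattern(rc[j], subject))
      if (length(plus)) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = chrom, start = s0 + plus - 1,
                               family = mirs$name[j], genome_strand = "+",
                               stringsAsFactors = FALSE)
      }
      if (length(minus)) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = chrom, start = s0 + minus - 1,
                               family = mirs$name[j], genome_strand = "-",
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      family = character(0), genome_strand = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out[seq_len(k)])
  m <- m[!duplicated(m[, c("chrom", "start", "family", "genome_strand")]), ]
  m$end <- m$start + 7
  m <- m[order(m$chrom, m$start, m$family, m$genome_strand), ]
  rownames(m) <- NULL
  m[, c("chrom", "start", "end", "family", "genome_strand")]
}

#' Classify a 7-mer placement against a flipon interval
#'
#' The site class is a function of the overlap length `k` alone:
#' `k = 7` is a motif site (M), `2 <= k <= 6` a motif-junction site (MJ),
#' `k = 1` a junction site (J) and `k = 0` no site. For a flipon of length
#' >= 7 the only J placements are the 5'-end minus 6 bp and the 3'-end plus
#' 6 bp. Flipons shorter than 7 bp cannot host an M site; the same k rule
#' applies.
#'
#' @param match_iv single-row interval of length 7.
#' @param flipon_iv single-row flipon interval.
#' @return list with `site_class` (`"M"`, `"MJ"`, `"J"`, `"none"`) and
#'   `overlap_bases`.
#' @export
classify_site <- function(match_iv, flipon_iv) {
  stopifnot(match_iv$end[1] - match_iv$start[1] == 7)
  k <- overlap_len(match_iv, flipon_iv)
  cls <- if (k == 7L) "M" else if (k >= 2L) "MJ" else if (k == 1L) "J" else "none"
  list(site_class = cls, overlap_bases = k)
}

# Vectorised class from overlap counts.
site_class_from_overlap <- function(k) {
  ifelse(k == 7L, "M", ifelse(k >= 2L, "MJ", ifelse(k == 1L, "J", "none")))
}

#' Pair matches with flipons and classify every site
#'
#' Each match is recorded once per flipon it touches (>= 1 bp overlap, so a
#' 7-mer overlapping two flipons yields one row for each); matches touching
#' no flipon are retained with `site_class = "none"` for promoter-level
#' counts.
#'
#' @param matches output of [scan_mrs_matches()].
#' @param flipons flipon table from [parse_bed()] (needs `id`,
#'   `flipon_class`, `motif_strand`).
#' @return matches with added columns `flipon_id`, `flipon_class`,
#'   `motif_strand`, `site_class`, `overlap_bases`.
#' @export
classify_matches <- function(matches, flipons) {
  base <- matches
  base$flipon_id <- NA_character_
  base$flipon_class <- NA_character_
  base$motif_strand <- NA_character_
  base$site_class <- "none"
  base$overlap_bases <- 0L
  if (!nrow(matches)) return(base)
  pairs <- overlap_pairs(matches, flipons)
  if (nrow(pairs)) {
    hit <- matches[pairs$query, ]
    fl <- flipons[pairs$subject, ]
    hit$flipon_id <- fl$id
    hit$flipon_class <- fl$flipon_class
    hit$motif_strand <- fl$motif_strand
    hit$overlap_bases <- as.integer(pmin(hit$end, fl$end) - pmax(hit$start, fl$start))
    hit$site_class <- site_class_from_overlap(hit$overlap_bases)
    out <- rbind(hit, base[setdiff(seq_len(nrow(matches)), unique(pairs$query)), ])
  } else {
    out <- base
  }
  out <- out[order(out$chrom, out$start, out$family, out$genome_strand), ]
  rownames(out) <- NULL
  out
}

#' Strand of a match relative to a gene's transcription direction
#'
#' A match on the same genomic strand as the gene lies on the coding
#' strand; the opposite strand is the template strand read by RNA
#' polymerase. With no associated gene the value is `NA`.
#'
#' @param match_strand genomic strand of the match (`+`/`-`), vectorised.
#' @param gene_strand gene strand (`+`/`-`) or `NA`.
#' @return character vector: `"coding"`, `"template"` or `NA`.
#' @export
assign_relative_strand <- function(match_strand, gene_strand) {
  ifelse(is.na(gene_strand), NA_character_,
         ifelse(match_strand == gene_strand, "coding", "template"))
}

#' Associate matches with genes through proximal promoters
#'
#' A match is assigned to a gene when its 7-mer overlaps that gene's
#' proximal promoter span (TSS +/- 1 kb by default); ties go to the nearest
#' TSS. Adds `gene_id`, `gene_strand`, `relative_strand`.
#'
#' @param matches classified match table.
#' @param genes a [gene_set()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param up,down promoter extent around the TSS, bases.
#' @return `matches` with gene association columns.
#' @export
annotate_match_genes <- function(matches, genes, chrom_sizes, up = 1000, down = 1000) {
  matches$gene_id <- NA_character_
  matches$gene_strand <- NA_character_
  if (nrow(matches)) {
    pp <- build_promoters(genes, chrom_sizes, up = up, down = down)
    pairs <- overlap_pairs(matches, pp)
    if (nrow(pairs)) {
      mid <- (matches$start + matches$end) / 2
      d <- abs(mid[pairs$query] - pp$tss[pairs$subject])
      pairs <- pairs[order(pairs$query, d), ]
      pairs <- pairs[!duplicated(pairs$query), ]
      matches$gene_id[pairs$query] <- pp$gene_id[pairs$subject]
      matches$gene_strand[pairs$query] <- pp$strand[pairs$subject]
    }
  }
  matches$relative_strand <- assign_relative_strand(matches$genome_strand, matches$gene_strand)
  matches
}

#' Summary tables of mRS matches against flipons
#'
#' Produces (a) a histogram of distinct miR families matched per flipon
#' (including flipons with zero matches), (b) per-family by relative-strand
#' counts, both at site resolution (each distinct family/flipon/strand/
#' position once) and at flipon resolution (each family/flipon/strand pair
#' once), and (c) the M/MJ/J site composition per flipon class.
#'
#' @param matches classified (and optionally gene-annotated) match table.
#' @param flipons flipon table.
#' @return list with `family_per_flipon_hist`, `strand_counts` and
#'   `site_class_composition` data.frames.
#' @export
summarize_matches <- function(matches, flipons) {
  hit <- matches[!is.na(matches$flipon_id) & matches$site_class != "none", ]
  if (nrow(hit) && any(!hit$flipon_id %in% flipons$id)) {
    stop("match references unknown flipon id: ",
         hit$flipon_id[!hit$flipon_id %in% flipons$id][1])
  }
  fam_per_flipon <- tapply(hit$family, factor(hit$flipon_id, levels = flipons$id),
                           function(x) length(unique(x)))
  fam_per_flipon[is.na(fam_per_flipon)] <- 0L
  hist_tab <- as.data.frame(table(n_families = as.integer(fam_per_flipon)),
                            stringsAsFactors = FALSE)
  names(hist_tab) <- c("n_families", "n_flipons")
  hist_tab$n_families <- as.integer(hist_tab$n_families)

  strand_counts <- data.frame(family = character(0), relative_strand = character(0),
                              n_sites = integer(0), n_flipons = integer(0))
  if ("relative_strand" %in% names(hit) && nrow(hit)) {
    withg <- hit[!is.na(hit$relative_strand), ]
    if (nrow(withg)) {
      site_key <- unique(withg[, c("family", "relative_strand", "flipon_id", "start", "genome_strand")])
      flip_key <- unique(withg[, c("family", "relative_strand", "flipon_id", "genome_strand")])
      sc <- as.data.frame(table(site_key$family, site_key$relative_strand),
                          stringsAsFactors = FALSE)
      names(sc) <- c("family", "relative_strand", "n_sites")
      fc <- as.data.frame(table(flip_key$family, flip_key$relative_strand),
                          stringsAsFactors = FALSE)
      names(fc) <- c("family", "relative_strand", "n_flipons")
      strand_counts <- merge(sc, fc, all = TRUE)
      strand_counts <- strand_counts[strand_counts$n_sites > 0 | strand_counts$n_flipons > 0, ]
      strand_counts <- strand_counts[order(strand_counts$family, strand_counts$relative_strand), ]
      rownames(strand_counts) <- NULL
    }
  }

  comp <- as.data.frame(table(flipon_class = factor(hit$flipon_class, levels = c("G", "Z", "S", "H")),
                              site_class = factor(hit$site_class, levels = c("M", "MJ", "J"))),
                        stringsAsFactors = FALSE)
  names(comp)[3] <- "n_sites"
  list(family_per_flipon_hist = hist_tab,
       strand_counts = strand_counts,
       site_class_composition = comp)
}
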