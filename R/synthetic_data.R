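#' Default flipon placement plan
#'
#' Counts per flipon class and placement slot. The defaults emulate the
#' study conditions: G and Z flipons concentrated in proximal promoters of
#' coding genes, SIDDs in transposon repeat elements and distal intergenic
#' space, and overall fractions of ~24.5% of flipons in coding proximal
#' promoters versus 8.5% in noncoding ones, 16% versus 23% over gene
#' bodies.
#'
#' @return data.frame with `class`, `placement`, `n`.
#' @export
default_flipon_plan <- function() {
  plan <- rbind(
    data.frame(class = "G", placement = c("PP_coding", "PP_noncoding", "body_coding", "body_noncoding", "distal"),
               n = c(20, 5, 8, 8, 9)),
    data.frame(class = "Z", placement = c("PP_coding", "PP_noncoding", "body_coding", "body_noncoding", "distal"),
               n = c(20, 6, 8, 10, 6)),
    data.frame(class = "S", placement = c("PP_coding", "PP_noncoding", "body_coding", "body_noncoding", "TRE", "distal"),
               n = c(5, 3, 6, 14, 28, 4)),
    data.frame(class = "H", placement = c("PP_coding", "PP_noncoding", "body_coding", "body_noncoding", "distal"),
               n = c(4, 3, 10, 14, 9))
  )
  plan$class <- as.character(plan$class)
  plan$placement <- as.character(plan$placement)
  plan
}

#' Default planted mRS site plan
#'
#' Counts of motif (M), motif-junction (MJ) and junction (J) seed-match
#' sites planted per flipon class; strands alternate within each row.
#'
#' @return data.frame with `class`, `site_class`, `n`.
#' @export
default_mrs_plan <- function() {
  data.frame(
    class = rep(c("G", "Z", "S", "H"), each = 3),
    site_class = rep(c("M", "MJ", "J"), 4),
    n = c(12, 6, 3, 10, 12, 4, 14, 4, 3, 8, 4, 2),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic-dataset configuration
#'
#' Two 1 Mb chromosomes, 60 genes (40 coding, 20 noncoding), ~200 flipons
#' placed per [default_flipon_plan()], SIDD lengths drawn around a 170 bp
#' mean, 20 miR families (16 conserved) and promoter-enriched AGO-like
#' peaks. Generation is fully deterministic given `seed`.
#'
#' @param seed integer RNG seed; all randomness flows from it.
#' @return list of class `synthetic_config`.
#' @export
default_synthetic_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    chrom_sizes = c(chr1 = 1e6, chr2 = 1e6),
    n_coding = 40L, n_noncoding = 20L,
    gene_len_range = c(4000, 12000),
    flipon_plan = default_flipon_plan(),
    mrs_plan = default_mrs_plan(),
    sidd_len_mean = 170, sidd_len_sd = 20,
    z_len_range = c(12, 40), h_len_range = c(20, 50),
    n_families = 20L, n_conserved = 16L,
    n_peaks = 80L, peak_pp_frac = 0.6, peak_width = 150L
  ), class = "synthetic_config")
}

# ---- motif templates --------------------------------------------------------

# Each generator returns the plus-strand sequence of one motif instance.
.gen_motif <- function(class, motif_strand, cfg) {
  switch(class,
    Z = {
      unit <- sample(c("CG", "CA", "TG", "TA"), 1)
      len <- 2 * sample(seq(cfg$z_len_range[1] / 2, cfg$z_len_range[2] / 2), 1)
      strrep(unit, len / 2)
    },
    G = {
      runs <- sample(3:5, 4, replace = TRUE)
      spacers <- vapply(sample(1:7, 3, replace = TRUE),
                        function(k) paste(sample(c("A", "C", "T"), k, replace = TRUE), collapse = ""),
                        character(1))
      s <- paste0(strrep("G", runs[1]), spacers[1], strrep("G", runs[2]), spacers[2],
                  strrep("G", runs[3]), spacers[3], strrep("G", runs[4]))
      if (motif_strand == "-") revcomp(s) else s
    },
    H = {
      len <- sample(seq(cfg$h_len_range[1], cfg$h_len_range[2]), 1)
      s <- paste(sample(c("A", "G"), len, replace = TRUE), collapse = "")
      if (motif_strand == "-") revcomp(s) else s
    },
    S = {
      len <- 3 * max(10, round(stats::rnorm(1, cfg$sidd_len_mean, cfg$sidd_len_sd) / 3))
      paste(vapply(seq_len(len / 3),
                   function(i) paste0("AT", sample(c("A", "T"), 1)), character(1)),
            collapse = "")
    },
    stop("unknown flipon class: ", class))
}

#' Consensus regular expressions for the flipon motif templates
#'
#' Plus-strand regexes the generator's motifs satisfy, usable as an
#' independent oracle: Z is an alternating pyrimidine/purine dinucleotide
#' repeat d(YR)n, G four G-runs of 3-5 separated by 1-7 non-G bases
#' (C-runs when the G-rich strand is minus), H a purine run (pyrimidine on
#' plus when the motif strand is minus), S an AT-rich d(ATX)n repeat.
#'
#' @return named list of regex strings keyed `Z`, `G_plus`, `G_minus`,
#'   `H_plus`, `H_minus`, `S`.
#' @export
motif_consensus_patterns <- function() {
  list(
    Z = "^([CT][AG])+$",
    G_plus = "^G{3,5}([ACT]{1,7}G{3,5}){3}$",
    G_minus = "^C{3,5}([AGT]{1,7}C{3,5}){3}$",
    H_plus = "^[AG]+$",
    H_minus = "^[CT]+$",
    S = "^(AT[AT])+$"
  )
}

# ---- placement helpers ------------------------------------------------------

# Occupancy registry: list per chrom of matrix-like df (start, end) already
# taken (with padding applied by callers).
.free_spot <- function(occ, chrom, zone_lo, zone_hi, len, pad, tries = 200L) {
  taken <- occ[[chrom]]
  for (t in seq_len(tries)) {
    if (zone_hi - len <= zone_lo) break
    s <- floor(stats::runif(1) * (zone_hi - len - zone_lo)) + zone_lo
    e <- s + len
    if (is.null(taken) || !nrow(taken) ||
        !any(taken$start < e + pad & taken$end > s - pad)) {
      return(c(s, e))
    }
  }
  NULL
}

.occupy <- function(occ, chrom, s, e) {
  occ[[chrom]] <- rbind(occ[[chrom]], data.frame(start = s, end = e))
  occ
}

# ---- generator --------------------------------------------------------------

#' Build a fully self-contained synthetic dataset
#'
#' Generates a uniform-ACGT background genome, gene models with coding and
#' noncoding biotypes, flipon motifs planted per the placement plan,
#' regulatory tracks (cCRE, CTCF, LINE/LTR), a miR family table, planted
#' 7-mer seed-match sites at controlled M/MJ/J offsets and strands, and
#' promoter-enriched AGO-like peaks — plus a truth manifest recording every
#' planted element and the summary counts the pipeline should recover.
#'
#' Planted 7-mers are guaranteed to occur nowhere in the genome outside
#' their intended sites: the generator rescans for every family 7-mer (both
#' orientations) and resamples one unprotected base of each stray
#' occurrence until the genome is clean, so exact-count recovery tests hold
#' at zero tolerance.
#'
#' @param config a [default_synthetic_config()] (possibly modified).
#' @param out_dir optional directory; when given, all files (FASTA, GTF,
#'   BEDs, narrowPeak, miR TSV, chrom sizes, manifest JSON) are written.
#' @return list with `genome`, `genes` ([gene_set()]), `flipons`, `ccre`,
#'   `ctcf`, `line`, `ltr`, `peaks`, `mirs`, `manifest`, and `files` (paths,
#'   when `out_dir` is given).
#' @export
build_synthetic_dataset <- function(config = default_synthetic_config(), out_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  sizes <- cfg$chrom_sizes
  chroms <- names(sizes)

  # background genome as per-chrom character vectors for cheap splicing
  gchars <- lapply(sizes, function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE))
  names(gchars) <- chroms

  # ---- genes ----
  n_genes <- cfg$n_coding + cfg$n_noncoding
  biotype <- sample(c(rep("coding", cfg$n_coding), rep("noncoding", cfg$n_noncoding)))
  per_chrom <- ceiling(n_genes / length(chroms))
  gene_rows <- list()
  exon_rows <- list()
  gi <- 0L
  for (chrom in chroms) {
    cursor <- 2000
    zone_hi <- 0.7 * sizes[[chrom]]
    while (gi < n_genes && gi < per_chrom * match(chrom, chroms)) {
      len <- sample(seq(cfg$gene_len_range[1], cfg$gene_len_range[2]), 1)
      if (cursor + len > zone_hi) break
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1)
      s <- cursor
      e <- cursor + len
      gene_rows[[gi]] <- data.frame(
        gene_id = sprintf("SYNG%04d", gi), chrom = chrom, strand = strand,
        start = s, end = e, tss = if (strand == "+") s else e - 1,
        biotype = biotype[gi], stringsAsFactors = FALSE)
      exon_rows[[gi]] <- data.frame(
        gene_id = sprintf("SYNG%04d", gi), chrom = chrom,
        start = c(s, s + 1600, e - 400), end = c(s + 400, s + 2000, e),
        stringsAsFactors = FALSE)
      cursor <- e + 2200 + sample(500:2500, 1)
    }
  }
  genes_df <- do.call(rbind, gene_rows)
  if (nrow(genes_df) < n_genes) stop("config infeasible: gene zone too small for gene count")
  genes <- gene_set(genes_df, exons = do.call(rbind, exon_rows))

  # ---- flipons ----
  occ <- stats::setNames(vector("list", length(chroms)), chroms)
  plan <- cfg$flipon_plan
  flipon_rows <- list()
  tre_rows <- list()
  fi <- 0L
  for (r in seq_len(nrow(plan))) {
    for (cnt in seq_len(plan$n[r])) {
      class <- plan$class[r]
      placement <- plan$placement[r]
      motif_strand <- if (class %in% c("Z", "S")) "." else sample(c("+", "-"), 1)
      seq <- .gen_motif(class, motif_strand, cfg)
      len <- nchar(seq)
      spot <- NULL
      gene_id <- NA_character_
      if (placement %in% c("PP_coding", "PP_noncoding")) {
        bt <- sub("PP_", "", placement)
        cand <- genes_df[genes_df$biotype == bt, ]
        for (t in seq_len(200L)) {
          g <- cand[sample(nrow(cand), 1), ]
          zone <- if (g$strand == "+") c(g$tss - 950, g$tss - 30) else c(g$tss + 30, g$tss + 950)
          spot <- .free_spot(occ, g$chrom, zone[1], zone[2], len, pad = 14L, tries = 30L)
          if (!is.null(spot)) { gene_id <- g$gene_id; chrom <- g$chrom; break }
        }
      } else if (placement %in% c("body_coding", "body_noncoding")) {
        bt <- sub("body_", "", placement)
        cand <- genes_df[genes_df$biotype == bt, ]
        for (t in seq_len(200L)) {
          g <- cand[sample(nrow(cand), 1), ]
          zone <- if (g$strand == "+") c(g$tss + 1020, g$end) else c(g$start, g$tss - 1020)
          spot <- .free_spot(occ, g$chrom, zone[1], zone[2], len, pad = 14L, tries = 30L)
          if (!is.null(spot)) { gene_id <- g$gene_id; chrom <- g$chrom; break }
        }
      } else {   # TRE or distal
        chrom <- sample(chroms, 1)
        zone <- c(0.72 * sizes[[chrom]], sizes[[chrom]] - 2000)
        pad <- if (placement == "TRE") 320L else 14L
        spot <- .free_spot(occ, chrom, zone[1], zone[2], len, pad = pad)
      }
      if (is.null(spot)) stop("config infeasible: cannot place ", class, " flipon in ", placement)
      if (placement == "TRE") {
        occ <- .occupy(occ, chrom, spot[1] - 150, spot[2] + 150)
      } else {
        occ <- .occupy(occ, chrom, spot[1], spot[2])
      }
      fi <- fi + 1L
      flipon_rows[[fi]] <- data.frame(
        chrom = chrom, start = spot[1], end = spot[2],
        flipon_class = class, motif_strand = motif_strand,
        placement = placement, gene_id = gene_id, stringsAsFactors = FALSE)
      gchars[[chrom]][(spot[1] + 1):spot[2]] <- strsplit(seq, "")[[1]]
      if (placement == "TRE") {
        # labelled repeat interval around the SIDD with AT-run TSD-like flanks
        ts <- spot[1] - 150; te <- spot[2] + 150
        gchars[[chrom]][(ts + 1):(ts + 20)] <- rep(c("A", "T"), 10)
        gchars[[chrom]][(te - 19):te] <- rep(c("A", "T"), 10)
        tre_rows[[length(tre_rows) + 1L]] <- data.frame(
          chrom = chrom, start = ts, end = te,
          family = if (length(tre_rows) %% 2 == 0) "LINE" else "LTR",
          stringsAsFactors = FALSE)
      }
    }
  }
  flipons <- do.call(rbind, flipon_rows)
  flipons <- flipons[order(flipons$chrom, flipons$start), ]
  flipons$id <- sprintf("FL%04d", seq_len(nrow(flipons)))
  rownames(flipons) <- NULL
  flipons$strand <- flipons$motif_strand
  tre <- if (length(tre_rows)) do.call(rbind, tre_rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0), family = character(0))

  # ---- miR families (seeds pre-checked against motif text) ----
  motif_text <- paste(vapply(seq_len(nrow(flipons)), function(i) {
    paste(gchars[[flipons$chrom[i]]][(flipons$start[i] + 1):flipons$end[i]], collapse = "")
  }, character(1)), collapse = "|")
  seeds <- character(0)
  guard <- 0L
  while (length(seeds) < cfg$n_families) {
    guard <- guard + 1L
    if (guard > 5000L) stop("could not draw distinct non-colliding seed 7-mers")
    cand <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = "")
    rc <- revcomp(cand)
    if (cand == rc) next                                   # palindromic: strand-ambiguous
    if (cand %in% seeds || rc %in% seeds ||
        cand %in% revcomp(seeds)) next                     # cross-family ambiguity
    if (grepl(cand, motif_text, fixed = TRUE) || grepl(rc, motif_text, fixed = TRUE)) next
    seeds <- c(seeds, cand)
  }
  mature <- vapply(seeds, function(sd) {
    tail <- paste(sample(c("A", "C", "G", "U"), 14, replace = TRUE), collapse = "")
    paste0(sample(c("A", "C", "G", "U"), 1), chartr("T", "U", sd), tail)
  }, character(1))
  mirs <- data.frame(
    name = sprintf("sim-miR-%d", 100 + seq_len(cfg$n_families)),
    mature_seq = unname(mature),
    seed7 = chartr("T", "U", seeds),
    mrs_identity = seeds,
    mrs_target = revcomp(seeds),
    conserved = seq_len(cfg$n_families) <= cfg$n_conserved,
    stringsAsFactors = FALSE)

  # ---- plant mRS sites ----
  planted <- plant_mrs_sites(gchars, flipons, cfg$mrs_plan, mirs)
  gchars <- planted$gchars
  sites <- planted$sites

  # ---- scrub stray 7-mer occurrences ----
  scrub <- .scrub_stray_kmers(gchars, mirs, sites, flipons)
  gchars <- scrub$gchars
  # any planted site or scrub edit inside a flipon breaks its consensus text
  flipons$pristine <- !(flipons$id %in% c(scrub$dirty_flipons, unique(sites$flipon_id)))

  genome <- vapply(gchars, paste, character(1), collapse = "")

  # ---- regulatory tracks ----
  ccre_genes <- genes_df[(genes_df$biotype == "coding" & stats::runif(nrow(genes_df)) < 0.8) |
                         (genes_df$biotype == "noncoding" & stats::runif(nrow(genes_df)) < 0.3), ]
  ccre <- data.frame(chrom = ccre_genes$chrom, start = pmax(0, ccre_genes$tss - 300),
                     end = ccre_genes$tss + 300, stringsAsFactors = FALSE)
  ctcf_genes <- ccre_genes[stats::runif(nrow(ccre_genes)) < 0.3, ]
  ctcf <- data.frame(chrom = ctcf_genes$chrom, start = pmax(0, ctcf_genes$tss - 150),
                     end = ctcf_genes$tss + 150, stringsAsFactors = FALSE)
  line <- tre[tre$family == "LINE", c("chrom", "start", "end")]
  ltr <- tre[tre$family == "LTR", c("chrom", "start", "end")]

  # ---- AGO-like peaks ----
  n_pp <- round(cfg$n_peaks * cfg$peak_pp_frac)
  pk_rows <- list()
  for (i in seq_len(cfg$n_peaks)) {
    if (i <= n_pp) {
      g <- genes_df[sample(nrow(genes_df), 1), ]
      center <- g$tss + sample(-300:300, 1)
      chrom <- g$chrom
    } else {
      chrom <- sample(chroms, 1)
      center <- floor(stats::runif(1) * (sizes[[chrom]] - cfg$peak_width)) + cfg$peak_width / 2
    }
    s <- max(0, center - cfg$peak_width / 2)
    pk_rows[[i]] <- data.frame(chrom = chrom, start = s, end = s + cfg$peak_width,
                               stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, pk_rows)
  peaks$id <- sprintf("peak%03d", seq_len(nrow(peaks)))

  # ---- expected summaries (brute-force from planted coordinates) ----
  expected <- .expected_summaries(sites, flipons, genes_df, sizes)
  manifest <- list(
    schema_version = "1.0",
    seed = cfg$seed,
    chrom_sizes = as.list(sizes),
    genes = genes_df,
    flipons = flipons[, c("id", "chrom", "start", "end", "flipon_class",
                          "motif_strand", "placement", "gene_id", "pristine")],
    mirs = mirs,
    sites = sites,
    expected = expected)
  validate_truth_manifest(manifest)

  out <- list(genome = genome, genes = genes, flipons = flipons,
              ccre = ccre, ctcf = ctcf, line = line, ltr = ltr,
              peaks = peaks, mirs = mirs, manifest = manifest)
  if (!is.null(out_dir)) {
    out$files <- .write_dataset_files(out, sizes, out_dir)
  }
  out
}

#' Plant seed-match sites into a genome at controlled offsets
#'
#' Class M sites are written fully inside the flipon; J sites at the
#' flipon 5'-end minus 6 bp or 3'-end plus 6 bp (one-base overlap);
#' MJ sites with a 2-6 base overlap spanning a flipon end. Strand `-`
#' plants mean the plus strand carries the reverse complement of the
#' family's identity 7-mer. Each flipon hosts at most one interior and one
#' site per end so planted windows never collide.
#'
#' @param gchars list of per-chromosome character vectors.
#' @param flipons flipon table with `id`, `flipon_class`.
#' @param plan data.frame `class`, `site_class`, `n`.
#' @param mirs miR family table (conserved families are planted).
#' @return list with updated `gchars` and a `sites` data.frame.
#' @export
plant_mrs_sites <- function(gchars, flipons, plan, mirs) {
  fam <- mirs[mirs$conserved, ]
  if (!nrow(fam)) fam <- mirs
  # planted windows per flipon; new windows must keep a >= 2 base gap so no
  # 7-mer window can ever be fully covered by planted sites
  windows <- stats::setNames(vector("list", nrow(flipons)), flipons$id)
  window_free <- function(fid, s, e) {
    w <- windows[[fid]]
    is.null(w) || !any(s < w[, 2] + 2 & e > w[, 1] - 2)
  }
  site_rows <- list()
  si <- 0L
  fam_i <- 0L
  for (r in seq_len(nrow(plan))) {
    if (plan$n[r] == 0) next
    strands <- rep(c("+", "-"), length.out = plan$n[r])
    for (cnt in seq_len(plan$n[r])) {
      cls <- plan$class[r]
      stype <- plan$site_class[r]
      fam_i <- fam_i %% nrow(fam) + 1L
      fml <- fam[fam_i, ]
      pool <- which(flipons$flipon_class == cls &
                      (flipons$end - flipons$start) >= 7)
      placedq <- FALSE
      for (t in seq_len(200L)) {
        fidx <- pool[sample(length(pool), 1)]
        fs <- flipons$start[fidx]; fe <- flipons$end[fidx]
        fid <- flipons$id[fidx]
        if (stype == "M") {
          start <- fs + sample(0:(fe - fs - 7), 1)
          ovl <- 7L
        } else {
          side <- sample(c("left", "right"), 1)
          if (stype == "J") {
            start <- if (side == "left") fs - 6 else fe - 1
            ovl <- 1L
          } else {
            k <- sample(2:6, 1)
            start <- if (side == "left") fs - (7 - k) else fe - k
            ovl <- as.integer(k)
          }
          if (ovl >= min(7, fe - fs)) next   # sub-7 flipon cannot take this overlap
        }
        if (!window_free(fid, start, start + 7)) next
        chrom <- flipons$chrom[fidx]
        if (start < 0 || start + 7 > length(gchars[[chrom]])) next
        kmer <- if (strands[cnt] == "+") fml$mrs_identity else revcomp(fml$mrs_identity)
        gchars[[chrom]][(start + 1):(start + 7)] <- strsplit(kmer, "")[[1]]
        windows[[fid]] <- rbind(windows[[fid]], c(start, start + 7))
        si <- si + 1L
        site_rows[[si]] <- data.frame(
          family = fml$name, chrom = chrom, start = start, end = start + 7,
          strand = strands[cnt], flipon_id = fid, flipon_class = cls,
          site_class = stype, overlap_bases = ovl, stringsAsFactors = FALSE)
        placedq <- TRUE
        break
      }
      if (!placedq) stop("no collision-free placement for a ", stype, " site on class ", cls)
    }
  }
  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$chrom, sites$start), ]
  rownames(sites) <- NULL
  list(gchars = gchars, sites = sites)
}

# Remove every occurrence of any family 7-mer (either orientation) outside
# the intended planted windows by resampling one unprotected base per stray
# hit; iterate until the genome is clean. Returns updated gchars and ids of
# flipons whose interior had to be edited.
.scrub_stray_kmers <- function(gchars, mirs, sites, flipons, max_rounds = 25L) {
  pats <- unique(c(mirs$mrs_identity, mirs$mrs_target))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
  dirty <- character(0)
  for (round in seq_len(max_rounds)) {
    n_fixed <- 0L
    for (chrom in names(gchars)) {
      seqstr <- paste(gchars[[chrom]], collapse = "")
      hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(seqstr))
      starts0 <- unlist(Biostrings::startIndex(hits)) - 1L
      if (is.null(starts0)) starts0 <- integer(0)
      if (!length(starts0)) next
      ssites <- sites[sites$chrom == chrom, , drop = FALSE]
      sflip <- flipons[flipons$chrom == chrom, , drop = FALSE]
      intended <- starts0 %in% ssites$start
      for (h in sort(unique(starts0[!intended]))) {
        win <- h + 1:7   # 1-based positions of the stray window
        prot <- rep(FALSE, 7)
        if (nrow(ssites)) {
          for (p in seq_len(nrow(ssites))) {
            prot <- prot | (win > ssites$start[p] & win <= ssites$end[p])
          }
        }
        free <- win[!prot]
        if (!length(free)) stop("stray 7-mer fully covered by planted sites; cannot scrub")
        in_flip <- rep(FALSE, length(free))
        if (nrow(sflip)) {
          for (p in seq_len(nrow(sflip))) {
            in_flip <- in_flip | (free > sflip$start[p] & free <= sflip$end[p])
          }
        }
        # prefer mutating background; fall back to a motif base if forced
        pos <- if (any(!in_flip)) free[!in_flip][1] else free[1]
        if (all(in_flip)) {
          for (p in seq_len(nrow(sflip))) {
            if (pos > sflip$start[p] && pos <= sflip$end[p]) dirty <- c(dirty, sflip$id[p])
          }
        }
        old <- gchars[[chrom]][pos]
        gchars[[chrom]][pos] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        n_fixed <- n_fixed + 1L
      }
    }
    if (n_fixed == 0L) {
      return(list(gchars = gchars, dirty_flipons = unique(dirty)))
    }
  }
  stop("scrub did not converge after ", max_rounds, " rounds")
}

# Brute-force expected summaries derived directly from planted coordinates.
.expected_summaries <- function(sites, flipons, genes_df, sizes, up = 1000, down = 1000,
                                window = 100) {
  # gene association: site 7-mer overlaps the gene's promoter span
  pp_start <- ifelse(genes_df$strand == "+", genes_df$tss - up, genes_df$tss - down + 1)
  pp_end <- ifelse(genes_df$strand == "+", genes_df$tss + down, genes_df$tss + up + 1)
  site_gene <- rep(NA_character_, nrow(sites))
  site_gstr <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sel <- which(genes_df$chrom == sites$chrom[i] &
                   pp_start < sites$end[i] & pp_end > sites$start[i])
    if (length(sel)) {
      sel <- sel[which.min(abs(genes_df$tss[sel] - (sites$start[i] + 3.5)))]
      site_gene[i] <- genes_df$gene_id[sel]
      site_gstr[i] <- genes_df$strand[sel]
    }
  }
  relative <- ifelse(is.na(site_gstr), NA_character_,
                     ifelse(sites$strand == site_gstr, "coding", "template"))

  comp <- as.data.frame(table(
    flipon_class = factor(sites$flipon_class, levels = c("G", "Z", "S", "H")),
    site_class = factor(sites$site_class, levels = c("M", "MJ", "J"))),
    stringsAsFactors = FALSE)
  names(comp)[3] <- "n_sites"

  withg <- !is.na(relative)
  strand_counts <- if (any(withg)) {
    sc <- as.data.frame(table(sites$family[withg], relative[withg]), stringsAsFactors = FALSE)
    names(sc) <- c("family", "relative_strand", "n_sites")
    sc <- sc[sc$n_sites > 0, ]
    sc <- sc[order(sc$family, sc$relative_strand), ]
    rownames(sc) <- NULL
    sc
  } else data.frame(family = character(0), relative_strand = character(0), n_sites = integer(0))

  fam_per <- tapply(sites$family, factor(sites$flipon_id, levels = flipons$id),
                    function(x) length(unique(x)))
  fam_per[is.na(fam_per)] <- 0L
  hist_tab <- as.data.frame(table(as.integer(fam_per)), stringsAsFactors = FALSE)
  names(hist_tab) <- c("n_families", "n_flipons")
  hist_tab$n_families <- as.integer(hist_tab$n_families)

  # window profile by brute-force double loop
  classes <- c("G", "Z", "S", "H")
  labs <- seq(-up, down - window, by = window)
  matched_ids <- unique(sites$flipon_id)
  acc <- expand.grid(window = labs, flipon_class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc$flipon_count <- 0L; acc$matched_flipon_count <- 0L; acc$mrs_count <- 0L
  for (gidx in seq_len(nrow(genes_df))) {
    g <- genes_df[gidx, ]
    for (w in seq_along(labs)) {
      l <- labs[w]
      span <- if (g$strand == "+") c(g$tss + l, g$tss + l + window) else
        c(g$tss - l - window + 1, g$tss - l + 1)
      span[1] <- max(0, span[1])
      fsel <- flipons$chrom == g$chrom & flipons$start < span[2] & flipons$end > span[1]
      if (any(fsel)) {
        for (cl in unique(flipons$flipon_class[fsel])) {
          row <- acc$window == l & acc$flipon_class == cl
          acc$flipon_count[row] <- acc$flipon_count[row] + sum(flipons$flipon_class[fsel] == cl)
          acc$matched_flipon_count[row] <- acc$matched_flipon_count[row] +
            sum(flipons$flipon_class[fsel] == cl & flipons$id[fsel] %in% matched_ids)
        }
      }
      ssel <- sites$chrom == g$chrom & sites$start < span[2] & sites$end > span[1]
      if (any(ssel)) {
        for (cl in unique(sites$flipon_class[ssel])) {
          row <- acc$window == l & acc$flipon_class == cl
          acc$mrs_count[row] <- acc$mrs_count[row] + sum(sites$flipon_class[ssel] == cl)
        }
      }
    }
  }

  frac <- function(span_start, span_end, span_chrom, span_bt) {
    do.call(rbind, lapply(c("coding", "noncoding"), function(bt) {
      sel <- span_bt == bt
      n <- sum(vapply(seq_len(nrow(flipons)), function(i) {
        any(span_chrom[sel] == flipons$chrom[i] &
              span_start[sel] < flipons$end[i] & span_end[sel] > flipons$start[i])
      }, logical(1)))
      data.frame(biotype = bt, n_flipons = n, pct = 100 * n / nrow(flipons),
                 stringsAsFactors = FALSE)
    }))
  }
  fr_pp <- frac(pp_start, pp_end, genes_df$chrom, genes_df$biotype)
  fr_body <- frac(genes_df$start, genes_df$end, genes_df$chrom, genes_df$biotype)
  rownames(fr_pp) <- rownames(fr_body) <- NULL

  slen <- flipons$end[flipons$flipon_class == "S"] - flipons$start[flipons$flipon_class == "S"]
  list(site_class_by_flipon_class = comp,
       strand_counts = strand_counts,
       family_per_flipon_hist = hist_tab,
       window_profile = acc,
       fractions_pp = fr_pp,
       fractions_gene_body = fr_body,
       sidd_mean_length = mean(slen),
       n_sites = nrow(sites))
}

# ---- manifest I/O -----------------------------------------------------------

#' Write a truth manifest to JSON
#' @param manifest manifest list from [build_synthetic_dataset()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
emit_truth_manifest <- function(manifest, path) {
  validate_truth_manifest(manifest)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a truth manifest from JSON
#' @param path manifest JSON path.
#' @return manifest list.
#' @export
read_truth_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  m$chrom_sizes <- lapply(m$chrom_sizes, as.numeric)
  m
}

#' Validate a truth manifest
#'
#' Checks the schema version, flipon class tokens, and that re-deriving
#' each planted site's class from its coordinates against its flipon
#' reproduces the stored class and overlap.
#'
#' @param manifest manifest list.
#' @return `TRUE`, invisibly; stops on inconsistency.
#' @export
validate_truth_manifest <- function(manifest) {
  if (is.null(manifest$schema_version)) stop("manifest lacks schema_version")
  fl <- manifest$flipons
  if (any(!fl$flipon_class %in% c("G", "Z", "S", "H"))) stop("invalid flipon class in manifest")
  st <- manifest$sites
  m <- match(st$flipon_id, fl$id)
  if (anyNA(m)) stop("site references unknown flipon id")
  k <- pmax(0, pmin(st$end, fl$end[m]) - pmax(st$start, fl$start[m]))
  if (any(site_class_from_overlap(k) != st$site_class) || any(k != st$overlap_bases)) {
    stop("manifest inconsistent: stored site_class does not match coordinates")
  }
  invisible(TRUE)
}

# Write all dataset files in the formats the pipeline consumes.
.write_dataset_files <- function(ds, sizes, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_fasta(ds$genome, fp("genome.fa"))
  write_gtf(ds$genes, fp("genes.gtf"))
  fl <- ds$flipons
  bed <- data.frame(fl$chrom, format(fl$start, scientific = FALSE, trim = TRUE),
                    format(fl$end, scientific = FALSE, trim = TRUE),
                    fl$flipon_class, 0L, fl$motif_strand)
  utils::write.table(bed, fp("flipons.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (track in c("ccre", "ctcf", "line", "ltr")) {
    tr <- ds[[track]]
    if (!nrow(tr)) { file.create(fp(paste0(track, ".bed"))); next }
    utils::write.table(
      data.frame(tr$chrom, format(tr$start, scientific = FALSE, trim = TRUE),
                 format(tr$end, scientific = FALSE, trim = TRUE)),
      fp(paste0(track, ".bed")), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  pk <- ds$peaks
  np <- data.frame(pk$chrom, format(pk$start, scientific = FALSE, trim = TRUE),
                   format(pk$end, scientific = FALSE, trim = TRUE),
                   pk$id, 0L, ".", 0, -1, -1, -1)
  utils::write.table(np, fp("ago_peaks.narrowPeak"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$mirs[, c("name", "mature_seq", "conserved")],
                     fp("mir_table.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(names(sizes), format(sizes, scientific = FALSE, trim = TRUE)),
                     fp("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  emit_truth_manifest(ds$manifest, fp("truth_manifest.json"))
  stats::setNames(
    fp(c("genome.fa", "genes.gtf", "flipons.bed", "ccre.bed", "ctcf.bed", "line.bed",
         "ltr.bed", "ago_peaks.narrowPeak", "mir_table.tsv", "chrom_sizes.tsv",
         "truth_manifest.json")),
    c("genome", "genes", "flipons", "ccre", "ctcf", "line", "ltr", "peaks",
      "mirs", "chrom_sizes", "manifest"))
}
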