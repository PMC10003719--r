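#' Run the flipon-mRS analysis pipeline end to end
#'
#' Stages, in dependency order: load all inputs, scan flipon regions for
#' 7-mer seed matches on both strands, classify every match as M/MJ/J,
#' associate matches with genes through proximal promoters, annotate
#' flipons with genomic features and regulatory context, build the
#' TSS-window profiles, coding/noncoding fractions and heptamer census,
#' call conformation effects, and test promoter/peak overlap significance
#' by Monte-Carlo shuffling. Deterministic given `seed`.
#'
#' @param paths named list/vector of input files: `genome`, `genes`,
#'   `flipons`, `mirs`, `chrom_sizes`, and optionally `ccre`, `ctcf`,
#'   `line`, `ltr`, `peaks` (as written by [build_synthetic_dataset()]).
#' @param params list of parameters; defaults: `pp_up = pp_down = 1000`,
#'   `window = 100`, `ext = 200`, `n_iter = 1000`, `mode = "identity"`.
#' @param seed integer seed driving the Monte-Carlo stage.
#' @param out_dir optional directory for the TSV report bundle.
#' @return list (report bundle) with all tables and intermediate objects.
#' @export
run_flipon_pipeline <- function(paths, params = list(), seed = 1L, out_dir = NULL) {
  paths <- as.list(paths)
  p <- utils::modifyList(list(pp_up = 1000, pp_down = 1000, window = 100,
                              ext = 200, n_iter = 1000, mode = "identity"),
                         params)
  need <- c("genome", "genes", "flipons", "mirs", "chrom_sizes")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("pipeline stage 'load': missing inputs: ", paste(miss, collapse = ", "))
  for (nm in intersect(names(paths), c(need, "ccre", "ctcf", "line", "ltr", "peaks"))) {
    if (!file.exists(paths[[nm]])) stop("pipeline stage 'load': file not found for '", nm, "': ", paths[[nm]])
  }
  genome <- load_genome(paths$genome)
  genes <- parse_gene_annotation(paths$genes)
  flipons <- parse_bed(paths$flipons, class_field = 4L)
  chrom_sizes <- read_chrom_sizes(paths$chrom_sizes)
  mirs <- load_mir_table(paths$mirs)
  opt_bed <- function(nm) {
    if (is.null(paths[[nm]]) || !file.size(paths[[nm]]) > 0) {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    } else parse_bed(paths[[nm]])
  }
  ccre <- opt_bed("ccre"); ctcf <- opt_bed("ctcf")
  tre <- merge_tre_tracks(opt_bed("line"), opt_bed("ltr"))
  peaks <- opt_bed("peaks")

  matches <- scan_mrs_matches(genome, flipons, mirs, mode = p$mode)
  matches <- classify_matches(matches, flipons)
  matches <- annotate_match_genes(matches, genes, chrom_sizes,
                                  up = p$pp_up, down = p$pp_down)

  flipons$feature <- assign_feature(flipons, genes)
  flipons$reg_category <- categorize_regulatory(flipons, ccre, ctcf, tre, ext = p$ext)

  promoters <- build_promoters(genes, chrom_sizes, up = p$pp_up, down = p$pp_down)
  profile <- window_profile(flipons, matches, promoters, window = p$window,
                            up = p$pp_up, down = p$pp_down)
  frac_pp <- coding_noncoding_fractions(flipons, genes, chrom_sizes, scope = "PP",
                                        up = p$pp_up, down = p$pp_down)
  frac_body <- coding_noncoding_fractions(flipons, genes, chrom_sizes, scope = "gene_body")
  census <- heptamer_census(promoters, genome, flipons)
  summaries <- summarize_matches(matches, flipons)
  conformations <- call_conformations(matches, flipons)

  mc <- NULL
  if (nrow(peaks)) {
    mc <- mc_overlap_test(promoters, peaks, chrom_sizes, n_iter = p$n_iter,
                          rng_seed = seed)
  }

  bundle <- list(params = p, seed = seed,
                 genome = genome, genes = genes, flipons = flipons,
                 promoters = promoters, mirs = mirs, matches = matches,
                 summaries = summaries, window_profile = profile,
                 fractions_pp = frac_pp, fractions_gene_body = frac_body,
                 heptamer_census = census, conformations = conformations,
                 mc_promoter_peaks = mc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(paste0("seed=", seed),
             paste0(names(p), "=", unlist(p)))
    wt <- function(df, nm) write_tsv_with_header(df, file.path(out_dir, nm), hdr)
    wt(matches, "mrs_matches.tsv")
    wt(flipons, "flipon_annotation.tsv")
    wt(profile, "window_profile.tsv")
    wt(frac_pp, "fractions_pp.tsv")
    wt(frac_body, "fractions_gene_body.tsv")
    wt(summaries$site_class_composition, "site_class_composition.tsv")
    wt(summaries$family_per_flipon_hist, "family_per_flipon_hist.tsv")
    if (nrow(summaries$strand_counts)) wt(summaries$strand_counts, "strand_counts.tsv")
    wt(conformations, "conformation_calls.tsv")
    cen <- data.frame(heptamer = names(census$pp_counts),
                      pp_count = as.integer(census$pp_counts))
    cen$flipon_count <- as.integer(census$flipon_counts[cen$heptamer])
    cen$flipon_count[is.na(cen$flipon_count)] <- 0L
    wt(cen, "heptamer_census.tsv")
    if (!is.null(mc)) {
      wt(data.frame(observed = mc$observed, p_value = mc$p_value,
                    n_iter = mc$n_iter, seed = seed),
         "mc_promoter_peaks.tsv")
    }
  }
  bundle
}

#' Per-gene promoter report
#'
#' Text report reproducing, per gene, each proximal-promoter flipon with
#' its class and motif strand, the matching miR families with site class
#' and strand, the conformation call, and an alignment of the 7-mer against
#' the flipon sequence with junction offsets marked.
#'
#' @param bundle report bundle from [run_flipon_pipeline()].
#' @param gene_id optional single gene; default reports every gene with at
#'   least one promoter flipon match.
#' @param path optional output file.
#' @return character vector of report lines, invisibly when `path` given.
#' @export
write_promoter_report <- function(bundle, gene_id = NULL, path = NULL) {
  genes <- bundle$genes$genes
  if (!is.null(gene_id) && !gene_id %in% genes$gene_id) {
    stop("unknown gene id: ", gene_id)
  }
  prom <- bundle$promoters
  ids <- if (is.null(gene_id)) genes$gene_id else gene_id
  conf <- bundle$conformations
  lines <- character(0)
  for (gid in ids) {
    pr <- prom[prom$gene_id == gid, ]
    fl <- bundle$flipons[overlaps_any(bundle$flipons, pr), , drop = FALSE]
    mm <- bundle$matches[!is.na(bundle$matches$gene_id) & bundle$matches$gene_id == gid &
                           bundle$matches$site_class != "none", , drop = FALSE]
    if (!nrow(fl) && is.null(gene_id)) next
    lines <- c(lines, sprintf("== %s (%s, %s strand, TSS %d) ==", gid,
                              genes$biotype[genes$gene_id == gid],
                              genes$strand[genes$gene_id == gid],
                              as.integer(genes$tss[genes$gene_id == gid])))
    if (!nrow(fl)) { lines <- c(lines, "  no proximal-promoter flipons"); next }
    for (i in seq_len(nrow(fl))) {
      lines <- c(lines, sprintf("  flipon %s class %s motif_strand %s  %s:%d-%d",
                                fl$id[i], fl$flipon_class[i], fl$motif_strand[i],
                                fl$chrom[i], as.integer(fl$start[i]), as.integer(fl$end[i])))
      sm <- mm[mm$flipon_id == fl$id[i], , drop = FALSE]
      for (j in seq_len(nrow(sm))) {
        cc <- conf[conf$flipon_id == fl$id[i] & conf$family == sm$family[j], , drop = FALSE]
        eff <- if (nrow(cc)) sprintf("%s %s", cc$effect[1], cc$structure[1]) else "no call"
        lines <- c(lines, sprintf("    %s  strand %s (%s)  site %s overlap %d  -> %s",
                                  sm$family[j], sm$genome_strand[j],
                                  ifelse(is.na(sm$relative_strand[j]), "NA", sm$relative_strand[j]),
                                  sm$site_class[j], sm$overlap_bases[j], eff))
        # alignment: flipon context (plus strand) with the 7-mer placed under it
        ctx_lo <- min(fl$start[i], sm$start[j]) - 2
        ctx_hi <- max(fl$end[i], sm$end[j]) + 2
        ctx <- substr(bundle$genome[[fl$chrom[i]]], ctx_lo + 1, ctx_hi)
        marker <- paste0(strrep(" ", fl$start[i] - ctx_lo), strrep("=", fl$end[i] - fl$start[i]))
        kmer <- substr(bundle$genome[[fl$chrom[i]]], sm$start[j] + 1, sm$end[j])
        kline <- paste0(strrep(" ", sm$start[j] - ctx_lo), kmer,
                        if (sm$genome_strand[j] == "-") " (matches minus strand)" else "")
        lines <- c(lines, paste0("      ", ctx), paste0("      ", marker),
                   paste0("      ", kline))
      }
    }
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
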