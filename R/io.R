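#' Load a genome from FASTA
#'
#' Reads every record, uppercases the sequence and transliterates U to T so
#' that downstream matching works on a DNA alphabet. Record names are the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return named character vector, one uppercase `{A,C,G,T,N}` string per
#'   chromosome.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1])
  }
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTNU characters in FASTA record: ", nm[bad][1])
  names(seqs) <- nm
  seqs
}

#' Default flipon class aliases
#'
#' Maps the class tokens found in input BED files onto the four canonical
#' flipon classes: G (G-quadruplex), Z (Z-DNA), S (SIDD), H (triplex/H-DNA).
#' Input datasets use varying vocabularies, so the map is user-editable.
#'
#' @return named character vector, token -> class.
#' @export
default_flipon_aliases <- function() {
  c(G = "G", G4 = "G", GQ = "G", Z = "Z", ZDNA = "Z", S = "S", SIDD = "S",
    H = "H", TRIPLEX = "H", HDNA = "H")
}

#' Parse a BED file of intervals or classed flipon records
#'
#' BED coordinates are 0-based half-open and kept as-is. With `class_field`
#' set, the given column is mapped to a flipon class through `class_map`
#' and the result carries `flipon_class` and `motif_strand` columns
#' (narrowPeak and other extra columns are ignored).
#'
#' @param path tab-separated BED file with at least 3 columns.
#' @param class_field optional 1-based column index holding the class token.
#' @param class_map named vector mapping tokens to `{G,Z,S,H}`;
#'   see [default_flipon_aliases()].
#' @return data.frame of intervals, plus `flipon_class`/`motif_strand` when
#'   `class_field` is given. Flipons without an id in the file are assigned
#'   stable ids `FL0001, ...` in file order.
#' @export
parse_bed <- function(path, class_field = NULL, class_map = default_flipon_aliases()) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("malformed BED line ", which(ncol < 3L)[1], " in ", path, ": fewer than 3 columns")
  }
  grab <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.numeric(grab(2)))
  end <- suppressWarnings(as.numeric(grab(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path, ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path, ": start >= end (",
         start[bad[1]], " >= ", end[bad[1]], ")")
  }
  iv <- data.frame(chrom = grab(1), start = start, end = end, stringsAsFactors = FALSE)
  name <- grab(4)
  strand <- grab(6)
  iv$strand <- ifelse(is.na(strand) | !strand %in% c("+", "-"), ".", strand)
  if (is.null(class_field)) {
    iv$id <- name
    validate_intervals(iv)
    return(iv)
  }
  tok <- toupper(grab(class_field))
  bad <- which(is.na(tok) | !tok %in% names(class_map))
  if (length(bad)) {
    stop("unknown flipon class token '", grab(class_field)[bad[1]],
         "' at BED line ", bad[1], " in ", path)
  }
  iv$flipon_class <- unname(class_map[tok])
  # motif strand: meaningful for G (G-rich strand) and H (purine-rich strand);
  # Z and S motifs are strand-symmetric and carry ".".
  iv$motif_strand <- ifelse(iv$flipon_class %in% c("Z", "S"), ".", iv$strand)
  iv$id <- if (all(!is.na(name)) && class_field != 4L) name else sprintf("FL%04d", seq_len(nrow(iv)))
  validate_intervals(iv)
  iv
}

#' Gene model container
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tss`, `start`, `end` (0-based half-open gene span) and
#'   `biotype` (`coding`/`noncoding`).
#' @param exons,utr5,utr3 optional data.frames with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "start", "end", "biotype") %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-"))) stop("gene with no strand")
  exp_tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  if (any(genes$tss != exp_tss)) {
    stop("tss must be span start (+) or span end - 1 (-): gene ",
         genes$gene_id[genes$tss != exp_tss][1])
  }
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)
  gs <- list(genes = genes, exons = if (is.null(exons)) empty else exons,
             utr5 = if (is.null(utr5)) empty else utr5,
             utr3 = if (is.null(utr3)) empty else utr3)
  for (part in c("exons", "utr5", "utr3")) {
    sub <- gs[[part]]
    if (!nrow(sub)) next
    m <- match(sub$gene_id, genes$gene_id)
    if (anyNA(m)) stop(part, " reference unknown gene: ", sub$gene_id[is.na(m)][1])
    if (any(sub$start < genes$start[m] | sub$end > genes$end[m])) {
      stop(part, " outside gene span for gene ",
           sub$gene_id[which(sub$start < genes$start[m] | sub$end > genes$end[m])[1]])
    }
  }
  structure(gs, class = "gene_set")
}

#' Parse gene annotation from GTF
#'
#' GTF is 1-based inclusive; coordinates are converted to the package's
#' 0-based half-open convention. The TSS is the span start for `+` genes and
#' the rightmost base (`end - 1`) for `-` genes. Biotypes are collapsed to
#' `coding` (protein_coding) versus `noncoding` (everything else).
#'
#' @param path GTF file with `gene` rows and optionally `exon`,
#'   `five_prime_utr` / `three_prime_utr` rows carrying `gene_id`.
#' @return a [gene_set()].
#' @export
parse_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  bio_col <- intersect(c("gene_biotype", "gene_type"), names(df))[1]
  if (is.na(bio_col)) df$gene_biotype <- "protein_coding" else names(df)[names(df) == bio_col] <- "gene_biotype"
  g <- df[df$type == "gene", ]
  if (!nrow(g)) stop("no gene records in GTF: ", path)
  if (any(!as.character(g$strand) %in% c("+", "-"))) {
    stop("gene with no strand: ", g$gene_id[!as.character(g$strand) %in% c("+", "-")][1])
  }
  genes <- data.frame(
    gene_id = g$gene_id,
    chrom = as.character(g$seqnames),
    strand = as.character(g$strand),
    start = g$start - 1,
    end = as.numeric(g$end),
    biotype = ifelse(g$gene_biotype == "protein_coding", "coding", "noncoding"),
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  sub_tab <- function(type) {
    s <- df[df$type %in% type, ]
    if (!nrow(s)) return(NULL)
    data.frame(gene_id = s$gene_id, chrom = as.character(s$seqnames),
               start = s$start - 1, end = as.numeric(s$end), stringsAsFactors = FALSE)
  }
  gene_set(genes,
           exons = sub_tab("exon"),
           utr5 = sub_tab(c("five_prime_utr", "5UTR")),
           utr3 = sub_tab(c("three_prime_utr", "3UTR")))
}

#' Read a chromosome sizes table
#'
#' @param path two-column tab-separated file: name, length.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$size), tab$chrom)
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write intervals to BED
#'
#' @param iv interval data.frame; optional `name_col` selects the column for
#'   BED field 4 (defaults to `id`, then `flipon_class` when present).
#' @param path output file.
#' @param name_col column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path, name_col = NULL) {
  validate_intervals(iv)
  if (is.null(name_col)) {
    name_col <- if ("flipon_class" %in% names(iv)) "flipon_class" else if ("id" %in% names(iv)) "id" else NA
  }
  name <- if (!is.na(name_col) && name_col %in% names(iv)) as.character(iv[[name_col]]) else "."
  name[is.na(name)] <- "."
  strand <- if ("strand" %in% names(iv)) iv$strand else "."
  out <- data.frame(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
                    format(iv$end, scientific = FALSE, trim = TRUE),
                    name, 0L, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a gene set to GTF
#'
#' Emits `gene` and `exon` rows (1-based inclusive) with `gene_id` and
#' `gene_biotype` attributes; round-trips through [parse_gene_annotation()].
#'
#' @param gs a [gene_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gs, path) {
  fmt_line <- function(chrom, type, start0, end0, strand, gene_id, biotype) {
    sprintf("%s\tflipmir\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
            chrom, type, as.integer(start0 + 1), as.integer(end0), strand, gene_id, biotype)
  }
  g <- gs$genes
  bty <- ifelse(g$biotype == "coding", "protein_coding", "lncRNA")
  lines <- fmt_line(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id, bty)
  if (nrow(gs$exons)) {
    m <- match(gs$exons$gene_id, g$gene_id)
    lines <- c(lines, fmt_line(gs$exons$chrom, "exon", gs$exons$start, gs$exons$end,
                               g$strand[m], gs$exons$gene_id, bty[m]))
  }
  writeLines(lines, path)
  invisible(path)
}

# Write a TSV with a provenance header of "# key=value" lines.
write_tsv_with_header <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by write_tsv_with_header.
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
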