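#' Derive the seed and mRS 7-mers from a mature miR sequence
#'
#' The seed is mature positions 2-8 (1-based), the canonical 7-mer seed.
#' `mrs_identity` is the seed transliterated to DNA (U to T): the DNA
#' strand carrying this 7-mer reads the same as the seed. `mrs_target` is
#' its reverse complement: the strand a miR would base-pair with.
#'
#' @param mature_seq RNA string over `{A,C,G,U}`, length >= 8.
#' @return list with `seed7`, `mrs_identity`, `mrs_target`.
#' @export
derive_mrs <- function(mature_seq) {
  s <- toupper(mature_seq)
  if (nchar(s) < 8L) stop("mature miR sequence shorter than 8 nt: ", mature_seq)
  if (grepl("[^ACGU]", s)) stop("invalid character in mature miR sequence: ", mature_seq)
  seed7 <- substr(s, 2L, 8L)
  mrs_identity <- chartr("U", "T", seed7)
  list(seed7 = seed7, mrs_identity = mrs_identity, mrs_target = revcomp(mrs_identity))
}

# Join family names sharing a seed: common dash-delimited prefix is kept once,
# e.g. c("miR-329","miR-362") -> "miR-329/362".
join_family_names <- function(names) {
  names <- unique(names)
  if (length(names) == 1L) return(names)
  pre <- sub("[^-]+$", "", names)
  if (length(unique(pre)) == 1L && nzchar(pre[1])) {
    paste0(pre[1], paste(sub("^.*-", "", names), collapse = "/"))
  } else {
    paste(names, collapse = "/")
  }
}

#' Load a miR family table
#'
#' Accepts a miRBase-style mature FASTA (family name = first header token)
#' or a TSV with columns `name`, `mature_seq` and optionally `conserved`.
#' Records sharing an identical seed 7-mer are grouped into one family under
#' a joint label (e.g. `miR-329/362`); a family grouped this way is flagged
#' conserved if any member is.
#'
#' @param path input file.
#' @param conserved_list optional character vector of names belonging to the
#'   conserved miR set; overrides any `conserved` column.
#' @return data.frame with columns `name`, `mature_seq`, `seed7`,
#'   `mrs_identity`, `mrs_target`, `conserved`, one row per distinct seed.
#' @export
load_mir_table <- function(path, conserved_list = NULL) {
  if (!file.exists(path)) stop("miR table not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty miR file: ", path)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readBStringSet(path)
    tab <- data.frame(
      name = vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L),
      mature_seq = chartr("T", "U", toupper(as.character(ss))),
      stringsAsFactors = FALSE
    )
    tab$conserved <- NA
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("name", "mature_seq") %in% names(tab))) {
      stop("miR TSV must have columns 'name' and 'mature_seq'")
    }
    tab$mature_seq <- chartr("T", "U", toupper(tab$mature_seq))
    if (!"conserved" %in% names(tab)) tab$conserved <- NA
  }
  if (!nrow(tab)) stop("empty miR file: ", path)
  if (!is.null(conserved_list)) tab$conserved <- tab$name %in% conserved_list
  tab$conserved[is.na(tab$conserved)] <- FALSE
  drv <- lapply(tab$mature_seq, derive_mrs)
  tab$seed7 <- vapply(drv, `[[`, character(1), "seed7")
  # one name, one seed
  dup <- tab[duplicated(tab$name) | duplicated(tab$name, fromLast = TRUE), ]
  if (nrow(dup) && any(tapply(dup$seed7, dup$name, function(x) length(unique(x)) > 1L))) {
    stop("duplicate family name with conflicting seed in ", path)
  }
  out <- do.call(rbind, lapply(split(tab, tab$seed7), function(grp) {
    data.frame(
      name = join_family_names(grp$name),
      mature_seq = grp$mature_seq[1],
      seed7 = grp$seed7[1],
      conserved = any(grp$conserved),
      stringsAsFactors = FALSE
    )
  }))
  out$mrs_identity <- chartr("U", "T", out$seed7)
  out$mrs_target <- revcomp(out$mrs_identity)
  stopifnot(all(out$mrs_target == revcomp(out$mrs_identity)))
  rownames(out) <- NULL
  out[order(out$name), c("name", "mature_seq", "seed7", "mrs_identity", "mrs_target", "conserved")]
}

#' Enumerate all DNA heptamers
#'
#' @return character vector of the 16,384 (4^7) DNA 7-mers in lexicographic
#'   order.
#' @export
enumerate_heptamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, b, stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}
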