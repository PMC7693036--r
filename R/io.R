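# Readers and writers: FASTA, residue-table TSV, packaged fixtures, Newick.

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased, whitespace is stripped, and every residue must
#' come from the 20-letter amino-acid alphabet plus X. Identifiers (the first
#' whitespace-delimited token of each header) must be unique; the remainder of
#' the header, if any, is kept in the \code{description} attribute.
#'
#' @param path path to a FASTA file.
#' @return a named \code{Biostrings::AAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (file.size(path) == 0L) stop(sprintf("'%s' is empty: not FASTA", path))
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) stop(sprintf("'%s' is not valid FASTA: %s",
                                                 path, conditionMessage(e))))
  if (length(x) == 0L) stop(sprintf("'%s' contains no FASTA records", path))
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record id '%s' in '%s'",
                 ids[duplicated(ids)][1L], path))
  seqs <- toupper(gsub("\\s", "", as.character(x)))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop(sprintf("record '%s' has an empty sequence", ids[i]))
    .checkResidues(seqs[i], ids[i])
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  attr(out, "description") <- stats::setNames(desc, ids)
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param x a named \code{AAStringSet} or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(x, path) {
  seqs <- .asSeqVector(x)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

# ---- residue-table TSV ----

#' Read a residue fingerprint table from TSV
#'
#' The format is one header row and one row per entry: an \code{entry}
#' column, an optional logical \code{is_reference} column, and for every key
#' position \code{P} of the scheme a residue column \code{rP} and an integer
#' position column \code{pP} (the query numbering printed as a subscript in
#' curated tables). A \code{"-"} residue cell is stored as missing
#' (\code{NA}); additional columns are kept as per-entry metadata.
#'
#' @param path TSV path.
#' @param scheme governing \code{\link{ReferenceScheme}} (or scheme name).
#' @return a \code{\link{ResidueTable}}.
#' @export
readResidueTable <- function(path, scheme) {
  if (is.character(scheme)) scheme <- referenceScheme(scheme)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"entry" %in% names(df)) stop("residue table must have an 'entry' column")
  kp <- scheme@keyPositions
  rcols <- paste0("r", kp$refPosition)
  pcols <- paste0("p", kp$refPosition)
  missing_cols <- setdiff(rcols, names(df))
  if (length(missing_cols))
    stop(sprintf("malformed residue table '%s': missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")))
  res <- as.matrix(df[, rcols, drop = FALSE])
  res[res == GAP_CODE] <- NA_character_  # printed "-" means missing
  mode(res) <- "character"
  pos <- matrix(NA_integer_, nrow(df), length(pcols))
  for (j in seq_along(pcols)) {
    if (pcols[j] %in% names(df)) pos[, j] <- as.integer(df[[pcols[j]]])
  }
  colnames(res) <- kp$role
  colnames(pos) <- kp$role
  isref <- if ("is_reference" %in% names(df)) as.logical(df$is_reference)
           else rep(FALSE, nrow(df))
  metacols <- setdiff(names(df), c("entry", "is_reference", rcols, pcols))
  meta <- if (length(metacols)) df[, metacols, drop = FALSE] else data.frame()
  bad <- which(!(is.na(res) | res %in% AA_ALPHABET))
  if (length(bad))
    stop(sprintf("malformed residue table '%s': invalid residue '%s'",
                 path, res[bad[1L]]))
  methods::new("ResidueTable",
    scheme = scheme, entries = as.character(df$entry),
    isReference = isref, residues = res, positions = pos, meta = meta)
}

#' Write a residue fingerprint table to TSV
#'
#' Inverse of \code{\link{readResidueTable}}. Missing residues are written as
#' \code{"-"}.
#'
#' @param x a \code{\link{ResidueTable}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResidueTable <- function(x, path) {
  stopifnot(methods::is(x, "ResidueTable"))
  kp <- x@scheme@keyPositions
  df <- data.frame(entry = x@entries, is_reference = x@isReference,
                   stringsAsFactors = FALSE)
  for (j in seq_len(nrow(kp))) {
    r <- x@residues[, j]
    r[is.na(r)] <- GAP_CODE
    df[[paste0("r", kp$refPosition[j])]] <- r
    df[[paste0("p", kp$refPosition[j])]] <- x@positions[, j]
  }
  if (nrow(x@meta)) df <- cbind(df, x@meta)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# ---- packaged fixtures ----

# Expand grouped entry labels: a trailing "<n1>/<n2>" or "<n1>-<n2>" after a
# shared stem denotes several rhodopsins sharing one residue row
# (GtRh2/3 -> GtRh2, GtRh3; Cop9-10 -> Cop9, Cop10).
.expandGroupedEntries <- function(x) {
  m <- regmatches(x@entries, regexec("^(.*?)([0-9]+)[/-]([0-9]+)$", x@entries))
  grouped <- vapply(m, length, 1L) == 4L
  if (!any(grouped)) return(x)
  idx <- integer(0)
  ids <- character(0)
  for (i in seq_along(x@entries)) {
    if (grouped[i]) {
      stem <- m[[i]][2L]
      nums <- seq(as.integer(m[[i]][3L]), as.integer(m[[i]][4L]))
      idx <- c(idx, rep(i, length(nums)))
      ids <- c(ids, paste0(stem, nums))
    } else {
      idx <- c(idx, i)
      ids <- c(ids, x@entries[i])
    }
  }
  methods::new("ResidueTable",
    scheme = x@scheme, entries = ids,
    isReference = x@isReference[idx],
    residues = x@residues[idx, , drop = FALSE],
    positions = x@positions[idx, , drop = FALSE],
    meta = if (nrow(x@meta)) x@meta[idx, , drop = FALSE] else x@meta)
}

#' Load a packaged residue-table fixture
#'
#' Packaged transcriptions of the curated residue tables for modular
#' microbial rhodopsins:
#' \describe{
#'   \item{\code{"table1B"}}{channel scheme (ChR2 numbering): the ChR2
#'     reference row plus the three modular channelrhodopsins KnRh3, TsRh1,
#'     GpRh1.}
#'   \item{\code{"table2B"}}{ion-pumping scheme (BR numbering): seven
#'     reference proteins (BR, HR, KR2, ASR1, SR2, RhoGC, RhoPDE, flagged
#'     \code{is_reference}) plus the modular sensory-type entries. Grouped
#'     rows (GtRh2/3, Cop9-10, BgRh1/2) are expanded to one entry per
#'     rhodopsin, giving 46 modular entries.}
#'   \item{\code{"table3"}}{spectral-tuning scheme (proteorhodopsin position
#'     105): residue, printed polarity and printed green/blue call per entry.
#'     Rows flagged as duplicates in the source table are dropped and listed
#'     in the \code{"duplicates"} attribute.}
#'   \item{\code{"cyclase"}}{\emph{synthetic} cyclase-domain rows (the
#'     published source is an alignment figure without a printed table): a
#'     canonical cyclase reference row with both metal-binding aspartates,
#'     substrate and transition-state residues intact; an intact Cop6 row;
#'     and Cop5/Vop5 rows in which the first metal-binding aspartate is
#'     substituted and the substrate/transition-state residues are absent.}
#' }
#'
#' @param name fixture name.
#' @return a \code{\link{ResidueTable}}.
#' @examples
#' t2 <- loadFixture("table2B")
#' sum(!isReference(t2))  # 46 modular entries
#' @export
loadFixture <- function(name = c("table1B", "table2B", "table3", "cyclase")) {
  name <- match.arg(name)
  fname <- switch(name,
    table1B = "table1B.tsv", table2B = "table2B.tsv",
    table3 = "table3.tsv", cyclase = "cyclase_synthetic.tsv")
  path <- system.file("extdata", fname, package = "modrhod", mustWork = TRUE)
  sch <- switch(name, table1B = "ChR2", table2B = "BR",
                table3 = "GPR", cyclase = "CYC")
  if (name == "table3") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
    dup <- !is.na(df$flag) & df$flag == "duplicate"
    dropped <- df$entry[dup]
    df <- df[!dup, , drop = FALSE]
    res <- matrix(df$residue, ncol = 1, dimnames = list(NULL, "tuner"))
    pos <- matrix(NA_integer_, nrow(df), 1, dimnames = list(NULL, "tuner"))
    out <- methods::new("ResidueTable",
      scheme = referenceScheme("GPR"),
      entries = df$entry,
      isReference = as.logical(df$is_reference),
      residues = res, positions = pos,
      meta = df[, c("residue_name", "polarity_printed", "shift_printed",
                    "group_label"), drop = FALSE])
    attr(out, "duplicates") <- dropped
    return(out)
  }
  tab <- readResidueTable(path, referenceScheme(sch))
  .expandGroupedEntries(tab)
}

#' List the packaged fixture files
#'
#' @return data.frame of fixture names and installed paths.
#' @export
listFixtures <- function() {
  files <- c(table1B = "table1B.tsv", table2B = "table2B.tsv",
             table3 = "table3.tsv", cyclase = "cyclase_synthetic.tsv")
  data.frame(name = names(files),
             path = vapply(files, function(f)
               system.file("extdata", f, package = "modrhod"), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- Newick ----

#' Parse a Newick tree file
#'
#' Standard Newick with optional branch lengths and integer bootstrap labels
#' on internal nodes. Leaf names must be unique and branch lengths
#' non-negative.
#'
#' @param path path to a Newick file (or a literal Newick string).
#' @return an \code{ape::phylo} tree.
#' @export
parseNewick <- function(path) {
  tr <- if (file.exists(path)) {
    tryCatch(ape::read.tree(path),
             error = function(e) stop(sprintf("cannot parse Newick '%s': %s",
                                              path, conditionMessage(e))))
  } else {
    tryCatch(ape::read.tree(text = path),
             error = function(e) stop(sprintf("cannot parse Newick: %s",
                                              conditionMessage(e))))
  }
  if (is.null(tr)) stop("cannot parse Newick input (unbalanced parentheses?)")
  if (anyDuplicated(tr$tip.label))
    stop(sprintf("duplicate leaf name '%s'",
                 tr$tip.label[duplicated(tr$tip.label)][1L]))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length")
  tr
}

#' Write a tree to Newick
#'
#' Branch lengths are written with 10 significant digits; node labels
#' (bootstrap supports) are preserved.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

# ---- JSON annotation report ----

#' Write an annotation report as JSON
#'
#' Serialises the per-entry calls produced by \code{\link{annotateRows}} or
#' \code{\link{annotateSequences}} with a stable key order, so identical runs
#' give byte-identical reports.
#'
#' @param calls data.frame of annotation calls.
#' @param path output path.
#' @param params optional named list of run parameters embedded in the report.
#' @return the path, invisibly.
#' @export
writeAnnotationReport <- function(calls, path, params = list()) {
  calls <- calls[order(calls$entry), , drop = FALSE]
  report <- list(
    tool = "modrhod",
    version = as.character(utils::packageVersion("modrhod")),
    parameters = params,
    n_entries = nrow(calls),
    calls = calls)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
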