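#' ReferenceScheme: a named reference with role-annotated key positions
#'
#' A scheme names a reference protein (bacteriorhodopsin \code{"BR"},
#' channelrhodopsin-2 \code{"ChR2"}, green proteorhodopsin \code{"GPR"}, or a
#' canonical class III cyclase \code{"CYC"}) together with its functionally
#' annotated key positions. Each key position carries a role (what the residue
#' does in the photocycle or catalytic mechanism), a position in the
#' coordinate system of the \code{scaffold} slot (equal to the published
#' reference numbering for the built-in schemes), the published reference
#' number (\code{refPosition}), and the residue codes expected at that
#' position in the reference mechanism.
#'
#' @slot name scheme name, one of \code{"BR"}, \code{"ChR2"}, \code{"GPR"},
#'   \code{"CYC"}.
#' @slot scaffold amino-acid string of the reference scaffold, or
#'   \code{NA_character_} when the user supplies the reference sequence at
#'   alignment time. Synthetic scaffolds from \code{\link{makeScaffold}} fill
#'   this slot and re-base \code{position} to scaffold coordinates.
#' @slot keyPositions \code{data.frame} with columns \code{role}
#'   (character, unique), \code{position} (integer, strictly increasing,
#'   1-based in scaffold coordinates), \code{refPosition} (integer, the
#'   published reference numbering), and \code{expected} (list of character
#'   vectors of expected residue codes).
#' @name ReferenceScheme-class
#' @aliases ReferenceScheme
#' @exportClass ReferenceScheme
setClass("ReferenceScheme",
  representation(name = "character",
                 scaffold = "character",
                 keyPositions = "data.frame"))

# Published key-position sets that a scheme of each name must carry.
.SCHEME_REF_POSITIONS <- list(
  BR   = c(85L, 89L, 90L, 96L, 194L, 204L, 212L, 216L),
  ChR2 = c(120L, 128L, 156L, 253L, 257L),
  GPR  = 105L,
  CYC  = c(45L, 89L, 101L, 145L, 149L)
)

setValidity("ReferenceScheme", function(object) {
  kp <- object@keyPositions
  msgs <- character()
  if (length(object@name) != 1L || !(object@name %in% names(.SCHEME_REF_POSITIONS)))
    msgs <- c(msgs, "name must be one of BR, ChR2, GPR, CYC")
  need <- c("role", "position", "refPosition", "expected")
  if (!all(need %in% names(kp))) {
    msgs <- c(msgs, "keyPositions must have columns role, position, refPosition, expected")
    return(msgs)
  }
  if (anyDuplicated(kp$role)) msgs <- c(msgs, "roles must be unique")
  if (is.unsorted(kp$position, strictly = TRUE))
    msgs <- c(msgs, "key positions must be strictly increasing")
  if (object@name %in% names(.SCHEME_REF_POSITIONS)) {
    want <- .SCHEME_REF_POSITIONS[[object@name]]
    if (!identical(sort(as.integer(kp$refPosition)), want))
      msgs <- c(msgs, sprintf("scheme %s must carry exactly reference positions %s",
                              object@name, paste(want, collapse = ", ")))
  }
  if (!all(unlist(kp$expected) %in% AA_ALPHABET))
    msgs <- c(msgs, "expected residues must be valid amino-acid codes")
  if (!is.na(object@scaffold) && nzchar(object@scaffold)) {
    if (max(kp$position) > nchar(object@scaffold))
      msgs <- c(msgs, "key position exceeds scaffold length")
  }
  if (length(msgs)) msgs else TRUE
})

#' ResidueTable: residue fingerprints for a set of entries under one scheme
#'
#' One row per entry, one column per scheme role. The residue matrix holds
#' 1-letter codes, the gap sentinel \code{"-"} (the aligned query has a gap at
#' the projected column), or \code{NA} (value missing from the source table).
#' The position matrix holds the corresponding 1-based query positions
#' (\code{NA} when unmapped or not recorded). A single-entry table is the
#' residue fingerprint of one query.
#'
#' @slot scheme the governing \code{\link{ReferenceScheme}}.
#' @slot entries character vector of unique entry identifiers.
#' @slot isReference logical; reference (non-modular) entries are excluded
#'   from conservation counts over modular rhodopsins.
#' @slot residues character matrix, entries x roles.
#' @slot positions integer matrix, entries x roles.
#' @slot meta \code{data.frame} of optional per-entry annotation columns
#'   (e.g. the printed polarity and spectral-shift cells of the packaged
#'   spectral-tuning table).
#' @name ResidueTable-class
#' @aliases ResidueTable
#' @exportClass ResidueTable
setClass("ResidueTable",
  representation(scheme = "ReferenceScheme",
                 entries = "character",
                 isReference = "logical",
                 residues = "matrix",
                 positions = "matrix",
                 meta = "data.frame"))

setValidity("ResidueTable", function(object) {
  msgs <- character()
  n <- length(object@entries)
  roles <- object@scheme@keyPositions$role
  if (anyDuplicated(object@entries)) msgs <- c(msgs, "entry ids must be unique")
  if (length(object@isReference) != n) msgs <- c(msgs, "isReference length mismatch")
  for (mat in list(object@residues, object@positions)) {
    if (!identical(dim(mat), c(n, length(roles))))
      msgs <- c(msgs, "matrix dimensions must be entries x roles")
  }
  if (!identical(colnames(object@residues), roles))
    msgs <- c(msgs, "residue columns must match scheme roles")
  res <- object@residues
  ok <- is.na(res) | res %in% c(AA_ALPHABET, GAP_CODE)
  if (!all(ok)) msgs <- c(msgs, "residues must be valid codes, '-', or NA")
  if (nrow(object@meta) > 0L && nrow(object@meta) != n)
    msgs <- c(msgs, "meta must have one row per entry (or none)")
  if (length(msgs)) msgs else TRUE
})

#' HydropathyProfile: smoothed per-residue hydropathy scores
#'
#' @slot score numeric vector, one smoothed Kyte-Doolittle score per residue.
#'   Margin positions are scored with shrunken windows so every residue has a
#'   defined score.
#' @slot window odd integer window length used for smoothing.
#' @slot id identifier of the profiled record.
#' @name HydropathyProfile-class
#' @aliases HydropathyProfile
#' @exportClass HydropathyProfile
setClass("HydropathyProfile",
  representation(score = "numeric", window = "integer", id = "character"))

setValidity("HydropathyProfile", function(object) {
  if (length(object@window) != 1L || object@window %% 2L == 0L)
    return("window must be a single odd integer")
  TRUE
})

#' TMTopology: transmembrane helix intervals for one sequence
#'
#' @slot helices integer matrix with columns \code{start}, \code{end};
#'   1-based inclusive, non-overlapping, strictly ordered intervals.
#' @slot retinalLysine optional 1-based position of the retinal-binding
#'   lysine inside the last helix (\code{NA} when not located).
#' @slot id identifier of the segmented record.
#' @name TMTopology-class
#' @aliases TMTopology
#' @exportClass TMTopology
setClass("TMTopology",
  representation(helices = "matrix", retinalLysine = "integer", id = "character"))

setValidity("TMTopology", function(object) {
  h <- object@helices
  msgs <- character()
  if (!identical(colnames(h), c("start", "end")))
    return("helices must have columns start, end")
  if (nrow(h) > 0L) {
    if (any(h[, "end"] < h[, "start"])) msgs <- c(msgs, "helix end before start")
    if (nrow(h) > 1L && any(h[-1L, "start"] <= h[-nrow(h), "end"]))
      msgs <- c(msgs, "helices must be non-overlapping and ordered")
  }
  rk <- object@retinalLysine
  if (length(rk) == 1L && !is.na(rk) && nrow(h) > 0L) {
    last <- h[nrow(h), ]
    if (rk < last["start"] || rk > last["end"])
      msgs <- c(msgs, "retinal lysine must lie within the last helix")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConservationCount: residue conservation at one scheme position
#'
#' @slot position published reference position queried.
#' @slot residues residue set counted.
#' @slot count number of modular entries carrying a residue from the set;
#'   missing cells never count towards the numerator.
#' @slot denominator number of modular entries scored (missing cells
#'   included).
#' @name ConservationCount-class
#' @aliases ConservationCount
#' @exportClass ConservationCount
setClass("ConservationCount",
  representation(position = "integer", residues = "character",
                 count = "integer", denominator = "integer"))

setValidity("ConservationCount", function(object) {
  if (object@count < 0L || object@count > object@denominator)
    return("count must lie in [0, denominator]")
  TRUE
})

#' GlobalAlignment: a gapped global pairwise alignment
#'
#' @slot reference aligned reference string (gap character \code{"-"}).
#' @slot query aligned query string of equal length.
#' @slot score alignment score.
#' @name GlobalAlignment-class
#' @aliases GlobalAlignment
#' @exportClass GlobalAlignment
setClass("GlobalAlignment",
  representation(reference = "character", query = "character", score = "numeric"))

setValidity("GlobalAlignment", function(object) {
  a <- strsplit(object@reference, "", fixed = TRUE)[[1]]
  b <- strsplit(object@query, "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    return("aligned strings must have equal length")
  if (any(a == GAP_CODE & b == GAP_CODE))
    return("no column may be gap/gap")
  TRUE
})
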