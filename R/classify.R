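# The rule engine: functional, spectral and cyclase class calls, and
# position-conservation tabulation.

# Polarity partition for the spectral-tuning rule (overridable in
# classifySpectral): nonpolar residues at the tuning position give a
# green-shifted call, polar-uncharged a blue-shifted one; charged residues
# fall outside the published rule and return UNKNOWN.
.NONPOLAR <- c("A", "V", "L", "I", "M", "F", "W", "P", "G", "C")
.POLAR_UNCHARGED <- c("S", "T", "N", "Q", "Y")
.CHARGED <- c("D", "E", "H", "K", "R")

.requireScheme <- function(table, name, fun) {
  if (!methods::is(table, "ResidueTable"))
    stop(sprintf("%s expects a ResidueTable", fun))
  if (table@scheme@name != name)
    stop(sprintf("%s requires rows under the %s scheme, got %s",
                 fun, name, table@scheme@name))
}

.ruleOK <- function(res, allowed) !is.na(res) & res %in% allowed

#' Channel-competence calls under the ChR2 scheme
#'
#' An entry is channel-competent when all five channel rules hold: proton
#' acceptor (ChR2 253) is Asp or Glu, proton donor (156) is Asp, DC-gate
#' (128) is Cys, acceptor stabiliser (120) is Arg, and the retinal attachment
#' (257) is Lys. An entry without the attachment lysine is
#' non-retinylidene; an entry with the lysine but failing any other rule is
#' sensory/atypical.
#'
#' @param table a \code{\link{ResidueTable}} under the \code{"ChR2"} scheme.
#' @return data.frame with columns \code{entry}, \code{is_reference},
#'   \code{functional_class}, and one logical evidence column
#'   \code{ev_<role>} per rule.
#' @examples
#' classifyChannel(loadFixture("table1B"))
#' @export
classifyChannel <- function(table) {
  .requireScheme(table, "ChR2", "classifyChannel")
  r <- table@residues
  ev <- cbind(
    ev_acceptor = .ruleOK(r[, "acceptor"], c("D", "E")),
    ev_donor = .ruleOK(r[, "donor"], "D"),
    ev_dcGate = .ruleOK(r[, "dcGate"], "C"),
    ev_stabilizer = .ruleOK(r[, "stabilizer"], "R"),
    ev_attachment = .ruleOK(r[, "attachment"], "K"))
  cls <- ifelse(!ev[, "ev_attachment"], "NON_RETINYLIDENE",
         ifelse(rowSums(ev) == ncol(ev), "CHANNEL_COMPETENT",
                "SENSORY_ATYPICAL"))
  data.frame(entry = table@entries, is_reference = table@isReference,
             functional_class = cls, ev, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pump-competence calls under the BR scheme
#'
#' The gating rules for an outward proton pump are: acceptor (BR 85) Asp or
#' Glu, donor (96) Asp, counterion (212) Asp, and the retinal attachment
#' (216) Lys. The acceptor stabiliser (89, Ser/Thr), binding-pocket residue
#' (90, Thr) and the proton-release pair (194/204, Asp/Glu) are recorded as
#' evidence but do not gate the call: the release group is dispensable for a
#' minimal pump, and gating on it would misclassify pumps that release
#' protons by another route. An entry without the attachment lysine is
#' non-retinylidene; with the lysine but a failed gate, sensory/atypical.
#'
#' @param table a \code{\link{ResidueTable}} under the \code{"BR"} scheme.
#' @return data.frame as in \code{\link{classifyChannel}}; release and
#'   pocket evidence columns are informational.
#' @examples
#' calls <- classifyPump(loadFixture("table2B"))
#' subset(calls, functional_class == "PUMP_COMPETENT" & !is_reference)
#' @export
classifyPump <- function(table) {
  .requireScheme(table, "BR", "classifyPump")
  r <- table@residues
  ev <- cbind(
    ev_acceptor = .ruleOK(r[, "acceptor"], c("D", "E")),
    ev_donor = .ruleOK(r[, "donor"], "D"),
    ev_counterion = .ruleOK(r[, "counterion"], "D"),
    ev_attachment = .ruleOK(r[, "attachment"], "K"),
    ev_stabilizer = .ruleOK(r[, "stabilizer"], c("S", "T")),
    ev_pocket = .ruleOK(r[, "pocket"], "T"),
    ev_release1 = .ruleOK(r[, "release1"], c("D", "E")),
    ev_release2 = .ruleOK(r[, "release2"], c("D", "E")))
  gate <- ev[, "ev_acceptor"] & ev[, "ev_donor"] & ev[, "ev_counterion"] &
    ev[, "ev_attachment"]
  cls <- ifelse(!ev[, "ev_attachment"], "NON_RETINYLIDENE",
         ifelse(gate, "PUMP_COMPETENT", "SENSORY_ATYPICAL"))
  data.frame(entry = table@entries, is_reference = table@isReference,
             functional_class = cls, ev, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Spectral-tuning call from the proteorhodopsin position-105 residue
#'
#' A nonpolar residue at the tuning position gives a green-shifted call, a
#' polar-uncharged residue a blue-shifted one. Charged (acidic or basic)
#' residues fall outside the published green/blue rule and return
#' \code{"UNKNOWN"}; a gap or missing cell returns \code{"UNSCORED"}. The
#' call is total over the 20 residues plus gap/missing and never returns
#' \code{"UNSCORED"} for a valid residue.
#'
#' @param residue vector of 1-letter codes, \code{"-"} (gap), or \code{NA}
#'   (missing).
#' @param nonpolar,polarUncharged,charged the polarity partition; the
#'   defaults extend the published examples (Leu/Ile/Met green, Gln blue,
#'   Asp unknown) to the full alphabet.
#' @return character vector over \code{GREEN}, \code{BLUE}, \code{UNKNOWN},
#'   \code{UNSCORED}.
#' @examples
#' classifySpectral(c("L", "Q", "D", NA))
#' @export
classifySpectral <- function(residue, nonpolar = .NONPOLAR,
                             polarUncharged = .POLAR_UNCHARGED,
                             charged = .CHARGED) {
  residue <- toupper(as.character(residue))
  valid <- is.na(residue) | residue %in% c(AA_ALPHABET, GAP_CODE)
  if (!all(valid))
    stop(sprintf("invalid residue code '%s'", residue[!valid][1L]))
  out <- rep("UNSCORED", length(residue))
  out[residue %in% nonpolar] <- "GREEN"
  out[residue %in% polarUncharged] <- "BLUE"
  out[residue %in% charged] <- "UNKNOWN"
  out[!is.na(residue) & residue == "X"] <- "UNKNOWN"
  out
}

#' Cyclase-activity calls under the CYC scheme
#'
#' A cyclase domain is called active when both metal-binding roles are
#' aspartate and the substrate-specifying and transition-state roles match
#' their expected residue sets; any substituted or absent catalytic residue
#' gives a degenerate call. Entries with no cyclase row at all are handled by
#' \code{\link{annotateRows}} as \code{NOT_APPLICABLE}.
#'
#' @param table a \code{\link{ResidueTable}} under the \code{"CYC"} scheme.
#' @return data.frame with \code{entry}, \code{is_reference},
#'   \code{cyclase_class} and per-role evidence columns.
#' @examples
#' classifyCyclase(loadFixture("cyclase"))
#' @export
classifyCyclase <- function(table) {
  .requireScheme(table, "CYC", "classifyCyclase")
  r <- table@residues
  kp <- table@scheme@keyPositions
  ev <- vapply(seq_len(nrow(kp)), function(j)
    .ruleOK(r[, kp$role[j]], kp$expected[[j]]), logical(nrow(r)))
  ev <- matrix(ev, nrow = nrow(r),
               dimnames = list(NULL, paste0("ev_", kp$role)))
  cls <- ifelse(rowSums(ev) == ncol(ev), "ACTIVE", "DEGENERATE")
  data.frame(entry = table@entries, is_reference = table@isReference,
             cyclase_class = cls, ev, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Conservation of a residue set at one scheme position
#'
#' Counts, over the modular (non-reference) entries of a residue table, how
#' many carry a residue from \code{residues} at the role mapped to
#' \code{position}. Missing cells are excluded from the numerator but stay in
#' the denominator.
#'
#' @param table a \code{\link{ResidueTable}}.
#' @param position a published reference position of the governing scheme.
#' @param residues character vector of residue codes to count.
#' @return a \code{\link{ConservationCount}}.
#' @examples
#' tabulateConservation(loadFixture("table2B"), 85, c("D", "E"))
#' @export
tabulateConservation <- function(table, position, residues) {
  stopifnot(methods::is(table, "ResidueTable"))
  role <- .roleForPosition(table@scheme, position)
  residues <- toupper(residues)
  modular <- !table@isReference
  r <- table@residues[modular, role]
  methods::new("ConservationCount",
    position = as.integer(position), residues = residues,
    count = sum(!is.na(r) & r %in% residues),
    denominator = sum(modular))
}

#' Annotate pre-extracted fingerprint rows
#'
#' Applies the rule engine matching the table's scheme: channel rules for
#' ChR2 rows, pump rules for BR rows, the spectral rule for GPR rows, and
#' cyclase rules for CYC rows. A separate cyclase table can be supplied to
#' attach cyclase calls (matched by entry id) to a BR- or ChR2-scheme
#' annotation; entries without a cyclase row are \code{NOT_APPLICABLE}.
#'
#' @param table a \code{\link{ResidueTable}}.
#' @param cyclaseTable optional \code{\link{ResidueTable}} under the
#'   \code{"CYC"} scheme.
#' @return data.frame with one row per entry: \code{entry},
#'   \code{is_reference}, \code{scheme}, \code{functional_class} (NA for
#'   GPR/CYC-only rows), \code{spectral_class}, \code{cyclase_class}, and
#'   the per-rule evidence columns of the scheme applied.
#' @examples
#' annotateRows(loadFixture("table2B"))
#' @export
annotateRows <- function(table, cyclaseTable = NULL) {
  stopifnot(methods::is(table, "ResidueTable"))
  sch <- table@scheme@name
  out <- switch(sch,
    ChR2 = classifyChannel(table),
    BR = classifyPump(table),
    GPR = data.frame(entry = table@entries,
                     is_reference = table@isReference,
                     functional_class = NA_character_,
                     row.names = NULL, stringsAsFactors = FALSE),
    CYC = {
      cy <- classifyCyclase(table)
      cy$functional_class <- NA_character_
      cy
    })
  out$scheme <- rep(sch, nrow(out))
  out$spectral_class <- if (sch == "GPR")
    classifySpectral(table@residues[, "tuner"]) else
    rep("UNSCORED", nrow(out))
  if (sch != "CYC") {
    if (!is.null(cyclaseTable)) {
      cy <- classifyCyclase(cyclaseTable)
      i <- match(out$entry, cy$entry)
      out$cyclase_class <- ifelse(is.na(i), "NOT_APPLICABLE",
                                  cy$cyclase_class[i])
    } else {
      out$cyclase_class <- rep("NOT_APPLICABLE", nrow(out))
    }
  }
  front <- c("entry", "is_reference", "scheme", "functional_class",
             "spectral_class", "cyclase_class")
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}

#' Full-pipeline annotation of protein sequences
#'
#' Runs topology validation, reference mapping and the rule engine for each
#' record: hydropathy segmentation (seven helices, retinal lysine), global
#' alignment to the scheme scaffold, key-position read-out, and the scheme's
#' classification rules.
#'
#' @param records named character vector or \code{AAStringSet}.
#' @param scheme a scaffold-bearing \code{\link{ReferenceScheme}}.
#' @param ... passed to \code{\link{extractFingerprints}} (topology and
#'   alignment parameters, \code{validate}, \code{force}).
#' @return list with \code{calls} (data.frame as in
#'   \code{\link{annotateRows}}), \code{fingerprints} (the
#'   \code{\link{ResidueTable}}), and \code{failures} (named character
#'   vector of skipped records).
#' @export
annotateSequences <- function(records, scheme, ...) {
  fp <- extractFingerprints(records, scheme, ...)
  list(calls = annotateRows(fp),
       fingerprints = fp,
       failures = attr(fp, "failures"))
}
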