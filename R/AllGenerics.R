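# Generics and accessors. Slots are never reached into from user code.

#' @describeIn ReferenceScheme-class scheme name accessor
#' @param x a ReferenceScheme or ResidueTable
#' @export
setGeneric("schemeName", function(x) standardGeneric("schemeName"))

#' @describeIn ReferenceScheme-class key-position table accessor
#' @export
setGeneric("keyPositions", function(x) standardGeneric("keyPositions"))

#' @describeIn ReferenceScheme-class scaffold sequence accessor
#' @export
setGeneric("scaffoldSeq", function(x) standardGeneric("scaffoldSeq"))

#' @describeIn ResidueTable-class governing scheme accessor
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @describeIn ResidueTable-class entry identifier accessor
#' @export
setGeneric("entryIds", function(x) standardGeneric("entryIds"))

#' @describeIn ResidueTable-class reference flag accessor
#' @export
setGeneric("isReference", function(x) standardGeneric("isReference"))

#' @describeIn ResidueTable-class residue matrix accessor (entries x roles)
#' @export
setGeneric("residueMatrix", function(x) standardGeneric("residueMatrix"))

#' @describeIn ResidueTable-class query-position matrix accessor
#' @export
setGeneric("positionMatrix", function(x) standardGeneric("positionMatrix"))

#' @describeIn ResidueTable-class per-entry metadata accessor
#' @export
setGeneric("tableMeta", function(x) standardGeneric("tableMeta"))

#' @describeIn TMTopology-class helix interval matrix accessor
#' @export
setGeneric("helices", function(x) standardGeneric("helices"))

#' @describeIn HydropathyProfile-class smoothed score accessor
#' @export
setGeneric("hydropathyScore", function(x) standardGeneric("hydropathyScore"))

setMethod("schemeName", "ReferenceScheme", function(x) x@name)
setMethod("schemeName", "ResidueTable", function(x) x@scheme@name)
setMethod("keyPositions", "ReferenceScheme", function(x) x@keyPositions)
setMethod("keyPositions", "ResidueTable", function(x) x@scheme@keyPositions)
setMethod("scaffoldSeq", "ReferenceScheme", function(x) x@scaffold)
setMethod("scheme", "ResidueTable", function(x) x@scheme)
setMethod("entryIds", "ResidueTable", function(x) x@entries)
setMethod("isReference", "ResidueTable", function(x) x@isReference)
setMethod("residueMatrix", "ResidueTable", function(x) {
  m <- x@residues
  rownames(m) <- x@entries
  m
})
setMethod("positionMatrix", "ResidueTable", function(x) {
  m <- x@positions
  rownames(m) <- x@entries
  m
})
setMethod("tableMeta", "ResidueTable", function(x) x@meta)
setMethod("helices", "TMTopology", function(x) x@helices)
setMethod("hydropathyScore", "HydropathyProfile", function(x) x@score)

#' @describeIn ResidueTable-class subset entries by index, id, or logical mask
#' @param i index, entry id, or logical vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "ResidueTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@entries)
  if (anyNA(i)) stop("unknown entry id")
  methods::new("ResidueTable",
    scheme = x@scheme,
    entries = x@entries[i],
    isReference = x@isReference[i],
    residues = x@residues[i, , drop = FALSE],
    positions = x@positions[i, , drop = FALSE],
    meta = if (nrow(x@meta)) x@meta[i, , drop = FALSE] else x@meta)
})

#' Residue observed for one entry at one role
#'
#' @param x a \code{\link{ResidueTable}}
#' @param entry entry identifier
#' @param role scheme role name
#' @return single residue code, \code{"-"} for an alignment gap, or \code{NA}
#'   when missing.
#' @export
residueAt <- function(x, entry, role) {
  stopifnot(methods::is(x, "ResidueTable"))
  i <- match(entry, x@entries)
  j <- match(role, colnames(x@residues))
  if (is.na(i)) stop(sprintf("unknown entry '%s'", entry))
  if (is.na(j)) stop(sprintf("unknown role '%s'", role))
  unname(x@residues[i, j])
}

#' @export
setMethod("show", "ReferenceScheme", function(object) {
  kp <- object@keyPositions
  cat(sprintf("ReferenceScheme '%s': %d key positions%s\n",
              object@name, nrow(kp),
              if (is.na(object@scaffold)) " (no scaffold)" else
                sprintf(" on a %d-residue scaffold", nchar(object@scaffold))))
  cat(sprintf("  %s: ref %s\n", format(kp$role), kp$refPosition), sep = "")
})

#' @export
setMethod("show", "ResidueTable", function(object) {
  cat(sprintf("ResidueTable (%s scheme): %d entries (%d reference, %d modular)\n",
              object@scheme@name, length(object@entries),
              sum(object@isReference), sum(!object@isReference)))
  if (length(object@entries)) {
    head_n <- min(6L, length(object@entries))
    m <- residueMatrix(object)[seq_len(head_n), , drop = FALSE]
    print(m, quote = FALSE, na.print = ".")
    if (length(object@entries) > head_n)
      cat(sprintf("  ... and %d more entries\n", length(object@entries) - head_n))
  }
})

#' @export
setMethod("show", "TMTopology", function(object) {
  cat(sprintf("TMTopology '%s': %d helices\n", object@id, nrow(object@helices)))
  if (nrow(object@helices))
    cat(sprintf("  helix %d: %d-%d\n", seq_len(nrow(object@helices)),
                object@helices[, "start"], object@helices[, "end"]), sep = "")
  if (!is.na(object@retinalLysine))
    cat(sprintf("  retinal lysine at %d\n", object@retinalLysine))
})

#' @export
setMethod("show", "HydropathyProfile", function(object) {
  cat(sprintf("HydropathyProfile '%s': %d residues, window %d, range [%.2f, %.2f]\n",
              object@id, length(object@score), object@window,
              min(object@score), max(object@score)))
})

#' @export
setMethod("show", "ConservationCount", function(object) {
  cat(sprintf("Conservation at reference position %d, residues {%s}: %d / %d modular entries\n",
              object@position, paste(object@residues, collapse = ","),
              object@count, object@denominator))
})

#' @export
setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf("GlobalAlignment: %d columns, score %.2f\n",
              nchar(object@reference), object@score))
})

#' @describeIn ConservationCount-class numerator accessor
#' @param x a ConservationCount
#' @export
conservedCount <- function(x) {
  stopifnot(methods::is(x, "ConservationCount"))
  x@count
}

#' @describeIn ConservationCount-class denominator accessor
#' @export
conservedDenominator <- function(x) {
  stopifnot(methods::is(x, "ConservationCount"))
  x@denominator
}

#' @describeIn GlobalAlignment-class alignment score accessor
#' @param x a GlobalAlignment
#' @export
alignmentScore <- function(x) {
  stopifnot(methods::is(x, "GlobalAlignment"))
  x@score
}

#' @describeIn GlobalAlignment-class aligned strings accessor
#' @export
alignedStrings <- function(x) {
  stopifnot(methods::is(x, "GlobalAlignment"))
  c(reference = x@reference, query = x@query)
}
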