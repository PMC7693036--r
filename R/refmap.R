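# Reference-position projection: global pairwise alignment of a query to a
# scheme scaffold and read-out of the residues at the scheme's key positions.

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed with
#' the \pkg{Biostrings} alignment engine. The score of a gap run of length L
#' is \code{-(gapOpen + gapExtend * L)}; substitution scores come from
#' BLOSUM62 by default. End gaps are penalised (true global alignment).
#'
#' @param reference reference amino-acid sequence (character scalar).
#' @param query query amino-acid sequence.
#' @param substitutionMatrix a scoring matrix, or the name of one shipped
#'   with \pkg{Biostrings} (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend positive gap penalties (defaults 10 and 0.5, the
#'   de-facto protein standards).
#' @return a \code{\link{GlobalAlignment}}.
#' @examples
#' aln <- globalAlign("MKLV", "MLV")
#' alignedStrings(aln)
#' @export
globalAlign <- function(reference, query, substitutionMatrix = "BLOSUM62",
                        gapOpen = 10, gapExtend = 0.5) {
  reference <- .asSeqVector(reference)[[1L]]
  query <- .asSeqVector(query)[[1L]]
  if (!nzchar(reference) || !nzchar(query))
    stop("both sequences must be non-empty")
  .checkResidues(reference, "reference")
  .checkResidues(query, "query")
  if (is.character(substitutionMatrix)) {
    e <- new.env()
    utils::data(list = substitutionMatrix, package = "Biostrings", envir = e)
    substitutionMatrix <- get(substitutionMatrix, envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = reference, subject = query, type = "global",
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpen, gapExtension = gapExtend)
  methods::new("GlobalAlignment",
    reference = as.character(Biostrings::alignedPattern(pa)),
    query = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa))
}

#' Project scheme key positions through an alignment
#'
#' For each key position of the scheme, the alignment column holding that
#' reference residue is located; if the query side of the column is a gap the
#' role is unmapped (residue \code{"-"}, position \code{NA}), otherwise the
#' query's 1-based position and residue are recorded.
#'
#' @param alignment a \code{\link{GlobalAlignment}} whose reference side is
#'   the scheme scaffold.
#' @param scheme a \code{\link{ReferenceScheme}} with scaffold coordinates
#'   matching the alignment's reference sequence.
#' @param entryId identifier for the resulting fingerprint row.
#' @return a single-entry \code{\link{ResidueTable}} (the residue
#'   fingerprint of the query).
#' @export
mapPositions <- function(alignment, scheme, entryId = "query") {
  stopifnot(methods::is(alignment, "GlobalAlignment"),
            methods::is(scheme, "ReferenceScheme"))
  ra <- strsplit(alignment@reference, "", fixed = TRUE)[[1L]]
  qa <- strsplit(alignment@query, "", fixed = TRUE)[[1L]]
  ref_pos <- cumsum(ra != GAP_CODE)
  qry_pos <- cumsum(qa != GAP_CODE)
  ref_len <- ref_pos[length(ref_pos)]
  kp <- scheme@keyPositions
  res <- character(nrow(kp))
  pos <- integer(nrow(kp))
  for (j in seq_len(nrow(kp))) {
    p <- kp$position[j]
    if (p > ref_len)
      stop(sprintf("scheme position %d exceeds reference length %d", p, ref_len))
    col <- match(p, ref_pos)  # first column reaching p holds reference residue p
    if (qa[col] == GAP_CODE) {
      res[j] <- GAP_CODE
      pos[j] <- NA_integer_
    } else {
      res[j] <- qa[col]
      pos[j] <- qry_pos[col]
    }
  }
  methods::new("ResidueTable",
    scheme = scheme, entries = entryId, isReference = FALSE,
    residues = matrix(res, 1L, dimnames = list(NULL, kp$role)),
    positions = matrix(pos, 1L, dimnames = list(NULL, kp$role)),
    meta = data.frame())
}

#' Extract residue fingerprints for a batch of sequences
#'
#' Runs the projection stage for every record: optional topology validation
#' (seven helices plus retinal lysine), global alignment to the scheme
#' scaffold, and key-position read-out. Records failing validation are
#' skipped (unless \code{force}) and reported in the \code{"failures"}
#' attribute of the result; the batch continues.
#'
#' @param records named character vector or \code{AAStringSet}.
#' @param scheme a \code{\link{ReferenceScheme}} carrying a scaffold
#'   sequence.
#' @param validate run the topology criterion before mapping (default TRUE).
#' @param force map records even when validation fails.
#' @param window,threshold,minLen,maxGap topology parameters, see
#'   \code{\link{segmentHelices}}.
#' @param gapOpen,gapExtend alignment parameters, see
#'   \code{\link{globalAlign}}.
#' @return a \code{\link{ResidueTable}} with one row per mapped record and a
#'   \code{"failures"} attribute naming skipped records and reasons.
#' @export
extractFingerprints <- function(records, scheme, validate = TRUE, force = FALSE,
                                window = 19L, threshold = 1.6, minLen = 15L,
                                maxGap = 3L, gapOpen = 10, gapExtend = 0.5) {
  stopifnot(methods::is(scheme, "ReferenceScheme"))
  if (is.na(scheme@scaffold))
    stop("scheme carries no scaffold sequence; attach one before mapping")
  seqs <- .asSeqVector(records)
  if (length(seqs) > 0L && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all records must be named")
  kp <- scheme@keyPositions
  rows <- list()
  failures <- character()
  for (id in names(seqs)) {
    row <- tryCatch({
      if (validate) {
        prof <- hydropathyProfile(stats::setNames(seqs[id], id), window = window)
        topo <- segmentHelices(prof, threshold = threshold, minLen = minLen,
                               maxGap = maxGap)
        v <- validateRhodopsin(seqs[id], topo)
        if (!v$isRhodopsin && !force)
          stop(paste(v$reasons, collapse = "; "))
      }
      aln <- globalAlign(scheme@scaffold, seqs[[id]],
                         gapOpen = gapOpen, gapExtend = gapExtend)
      mapPositions(aln, scheme, entryId = id)
    }, error = function(e) conditionMessage(e))
    if (is.character(row)) failures[id] <- row else rows[[id]] <- row
  }
  res <- do.call(rbind, c(list(matrix(character(), 0L, nrow(kp),
                                      dimnames = list(NULL, kp$role))),
                          lapply(rows, function(r) r@residues)))
  pos <- do.call(rbind, c(list(matrix(integer(), 0L, nrow(kp),
                                      dimnames = list(NULL, kp$role))),
                          lapply(rows, function(r) r@positions)))
  out <- methods::new("ResidueTable",
    scheme = scheme, entries = as.character(names(rows)),
    isReference = rep(FALSE, length(rows)),
    residues = res, positions = pos, meta = data.frame())
  attr(out, "failures") <- failures
  out
}
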