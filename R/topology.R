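# Transmembrane topology: Kyte-Doolittle hydropathy smoothing, helix
# segmentation, and the 7-helix + retinal-lysine rhodopsin criterion.

# Kyte-Doolittle hydropathy scale; X (unknown) scores 0.
.KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0)

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector of per-residue hydropathy values (X scores 0).
#' @export
kyteDoolittleScale <- function() .KD_SCALE

#' Smoothed hydropathy profile of a protein sequence
#'
#' Each position is scored with the mean Kyte-Doolittle value over a window
#' centred on it. Near the termini the window is shrunk to the available
#' residues rather than left undefined, so the profile has the same length as
#' the sequence.
#'
#' @param record a single sequence (character scalar, named character of
#'   length 1, or \code{AAStringSet} of length 1).
#' @param window odd window length, at least 5 and at most the sequence
#'   length. Default 19, the canonical transmembrane setting.
#' @return a \code{\link{HydropathyProfile}}.
#' @export
hydropathyProfile <- function(record, window = 19L) {
  seqs <- .asSeqVector(record)
  if (length(seqs) != 1L) stop("hydropathyProfile expects a single sequence")
  id <- if (!is.null(names(seqs))) names(seqs) else "query"
  s <- seqs[[1L]]
  .checkResidues(s, id)
  n <- nchar(s)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 5L) stop("window must be at least 5")
  if (window > n) stop("window longer than the sequence")
  v <- .KD_SCALE[strsplit(s, "", fixed = TRUE)[[1L]]]
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  score <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  methods::new("HydropathyProfile", score = unname(score),
               window = window, id = id)
}

#' Segment transmembrane helices from a hydropathy profile
#'
#' Maximal runs of positions scoring at least \code{threshold} are taken as
#' candidate helices; runs separated by at most \code{maxGap} sub-threshold
#' residues are merged (the gap residues are included in the merged helix);
#' merged runs shorter than \code{minLen} are discarded. Deterministic for
#' fixed inputs; an empty helix list is a valid result.
#'
#' @param profile a \code{\link{HydropathyProfile}}.
#' @param threshold hydropathy threshold (default 1.6, the canonical
#'   transmembrane cutoff for a 19-residue Kyte-Doolittle window).
#' @param minLen minimum helix length in residues (default 15).
#' @param maxGap maximum sub-threshold gap bridged between runs (default 3).
#' @return a \code{\link{TMTopology}} (helices only).
#' @export
segmentHelices <- function(profile, threshold = 1.6, minLen = 15L, maxGap = 3L) {
  stopifnot(methods::is(profile, "HydropathyProfile"))
  above <- profile@score >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- cbind(start = starts[runs$values], end = ends[runs$values])
  if (nrow(iv) > 1L) {
    merged <- iv[1L, , drop = FALSE]
    for (k in 2L:nrow(iv)) {
      gap <- iv[k, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap <= maxGap) {
        merged[nrow(merged), "end"] <- iv[k, "end"]
      } else {
        merged <- rbind(merged, iv[k, , drop = FALSE])
      }
    }
    iv <- merged
  }
  if (nrow(iv) > 0L) {
    iv <- iv[(iv[, "end"] - iv[, "start"] + 1L) >= minLen, , drop = FALSE]
  }
  storage.mode(iv) <- "integer"
  colnames(iv) <- c("start", "end")
  methods::new("TMTopology", helices = iv, retinalLysine = NA_integer_,
               id = profile@id)
}

#' Validate the rhodopsin topology criterion
#'
#' A candidate rhodopsin must show exactly seven transmembrane helices and at
#' least one lysine (the retinal attachment site) inside the seventh helix.
#' "Seventh helix" means the last helix when exactly seven are found; the
#' lysine check is not attempted otherwise.
#'
#' @param record the sequence the topology was computed for.
#' @param topology a \code{\link{TMTopology}} from
#'   \code{\link{segmentHelices}}.
#' @return list with elements \code{isRhodopsin} (logical), \code{reasons}
#'   (character vector of failed criteria, empty on success), and
#'   \code{retinalLysine} (position of the first lysine in helix 7, or
#'   \code{NA}).
#' @export
validateRhodopsin <- function(record, topology) {
  stopifnot(methods::is(topology, "TMTopology"))
  seqs <- .asSeqVector(record)
  if (length(seqs) != 1L) stop("validateRhodopsin expects a single sequence")
  s <- seqs[[1L]]
  reasons <- character()
  lysine <- NA_integer_
  nh <- nrow(topology@helices)
  if (nh != 7L) {
    reasons <- c(reasons, sprintf("helix count %d != 7", nh))
  } else {
    last <- topology@helices[7L, ]
    chars <- strsplit(substr(s, last["start"], last["end"]), "", fixed = TRUE)[[1L]]
    k <- which(chars == "K")
    if (length(k) == 0L) {
      reasons <- c(reasons, "no retinal lysine in helix 7")
    } else {
      lysine <- unname(last["start"] + k[1L] - 1L)
    }
  }
  list(isRhodopsin = length(reasons) == 0L, reasons = reasons,
       retinalLysine = lysine)
}
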