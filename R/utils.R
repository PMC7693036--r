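# Shared constants and small helpers.

# 20 canonical amino acids; X is tolerated as "unknown residue" everywhere.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_CODES, "X")
GAP_CODE <- "-"

FUNCTIONAL_CLASSES <- c("CHANNEL_COMPETENT", "PUMP_COMPETENT",
                        "SENSORY_ATYPICAL", "NON_RETINYLIDENE")
SPECTRAL_CLASSES <- c("GREEN", "BLUE", "UNKNOWN", "UNSCORED")
CYCLASE_CLASSES <- c("ACTIVE", "DEGENERATE", "NOT_APPLICABLE")

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the global
# RNG state afterwards so generators never leak random state.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Coerce sequence input (character vector, AAString, AAStringSet) to a named
# character vector of upper-case sequences.
.asSeqVector <- function(x) {
  if (methods::is(x, "AAStringSet") || methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (methods::is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "query"
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected a character vector or Biostrings AAStringSet")
  }
  toupper(out)
}

.checkResidues <- function(seq, id = "sequence", allow_gap = FALSE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  allowed <- if (allow_gap) c(AA_ALPHABET, GAP_CODE) else AA_ALPHABET
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' in record '%s' at offset %d",
                 chars[bad[1L]], id, bad[1L]))
  }
  invisible(TRUE)
}
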