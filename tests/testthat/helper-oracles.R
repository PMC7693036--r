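# Independent oracles and small construction helpers used across the suite.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Exhaustive global-alignment oracle: enumerates every gapped alignment of a
# and b and scores it directly (substitution matrix plus affine gap cost
# open + ext * length per maximal one-sided gap run, end gaps included).
# Feasible for combined length <= 12; independent of any DP implementation.
bruteForceAlignScore <- function(a, b, sub = .blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  scoreCols <- function(sides, subs) {
    s <- subs
    r <- rle(sides)
    gaps <- r$lengths[r$values != "m"]
    s - sum(open + ext * gaps)
  }
  rec <- function(i, j, sides, subs) {
    if (i > length(A) && j > length(B)) {
      sc <- scoreCols(sides, subs)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1L, j + 1L, c(sides, "m"), subs + sub[A[i], B[j]])
    if (i <= length(A))
      rec(i + 1L, j, c(sides, "b"), subs)   # gap in b
    if (j <= length(B))
      rec(i, j + 1L, c(sides, "a"), subs)   # gap in a
  }
  rec(1L, 1L, character(), 0)
  best
}

# Direct windowed-mean oracle for the hydropathy profile (no cumsum trick).
bruteForceHydropathy <- function(seq, window) {
  v <- kyteDoolittleScale()[strsplit(seq, "", fixed = TRUE)[[1L]]]
  n <- length(v)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(v[lo:hi])
  }, 0)
}

# Direct column-count p-distance oracle.
bruteForcePDistance <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- 0L; m <- 0L
  for (k in seq_along(A)) {
    if (A[k] != "-" && B[k] != "-") {
      n <- n + 1L
      if (A[k] != B[k]) m <- m + 1L
    }
  }
  m / n
}

# Random protein sequence over the 20-letter alphabet.
randomProtein <- function(n, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1L]]
  withr::with_seed(seed, paste(sample(aa, n, replace = TRUE), collapse = ""))
}

# Fixed 8-taxon balanced tree used by the topology-recovery experiments.
recoveryTree <- function() {
  ape::read.tree(text = paste0(
    "((((t1:0.1,t2:0.1):0.1,(t3:0.1,t4:0.1):0.1):0.1,",
    "(t5:0.1,t6:0.1):0.1):0.1,(t7:0.1,t8:0.1):0.1);"))
}

# Canonical ion-pump fingerprint (the residues of the one pump-competent
# modular entry), reused by pipeline-closure experiments.
pumpSpec <- function() {
  c(acceptor = "D", stabilizer = "T", pocket = "T", donor = "D",
    release1 = "G", release2 = "E", counterion = "D", attachment = "K")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
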