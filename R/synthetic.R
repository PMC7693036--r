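# Synthetic rhodopsin-like data with known ground truth: scaffolds with
# planted topology and key residues, fingerprint variants, and sequence
# families evolved on a known tree.

# Alphabets chosen so Kyte-Doolittle segmentation at the default window /
# threshold separates helices from loops cleanly. Helix draws are weighted
# towards the strongly hydrophobic residues (as in real transmembrane
# helices); unweighted draws leave Ala/Met-rich windows hovering at the
# detection threshold.
.HYDROPHOBIC <- c("A", "V", "L", "I", "F", "M")
.HYDROPHOBIC_W <- c(A = 1, V = 3, L = 3, I = 3, F = 2, M = 1)
.HYDROPHILIC <- c("D", "E", "N", "Q", "K", "R", "S", "T", "G", "H")

# Deterministic allocation of scheme roles to helix-interior slots: the last
# role (the retinal attachment for rhodopsin schemes) goes to the middle of
# the last helix; earlier roles fill helices 2, 3, ... two per helix. Slots
# keep clear of helix edges (a smoothed-profile dent near an edge shortens
# the detected run irrecoverably, while interior dents are bridged by the
# run-merging rule) and, when a helix hosts two planted residues, the two
# slots sit a full smoothing window apart so no window sees both at once.
.allocateKeySlots <- function(nRoles, nHelices, helixLen, loopLen) {
  if (helixLen < 13L)
    stop("helixLen too short to host key positions away from helix edges")
  helixStart <- function(h) loopLen + (h - 1L) * (helixLen + loopLen) + 1L
  nOther <- nRoles - 1L
  need <- ceiling(nOther / 2)
  if (need > nHelices - 2L)
    stop("scheme key positions not representable: too many roles for the helix count")
  mid <- helixLen %/% 2L
  offsets <- if (helixLen >= 32L) c(mid - 9L, mid + 10L) else c(mid - 4L, mid + 5L)
  slots <- integer(0)
  h <- 2L
  while (length(slots) < nOther) {
    take <- min(2L, nOther - length(slots))
    slots <- c(slots, helixStart(h) - 1L + offsets[seq_len(take)])
    h <- h + 1L
  }
  c(slots, helixStart(nHelices) - 1L + helixLen %/% 2L)
}

#' Generate a rhodopsin-like scaffold with planted topology and key residues
#'
#' Builds a synthetic protein of \code{nHelices} hydrophobic helices
#' separated by hydrophilic loops, plants the scheme's expected residues at
#' deterministic helix-interior slots, and returns a copy of the scheme whose
#' \code{scaffold} slot holds the sequence and whose \code{position} column
#' is re-based to scaffold coordinates (the published \code{refPosition}
#' numbering is kept alongside). The generator is a pure function of its
#' parameters and seed.
#'
#' @param scheme a \code{\link{ReferenceScheme}} or scheme name.
#' @param nHelices number of transmembrane helices (default 7).
#' @param helixLen helix length in residues (default 36).
#' @param loopLen loop length in residues (default 14).
#' @param seed RNG seed (mandatory; generators never touch global RNG
#'   state).
#' @return a scaffold-bearing \code{\link{ReferenceScheme}}.
#' @examples
#' sc <- makeScaffold("BR", seed = 1)
#' nchar(scaffoldSeq(sc))
#' @export
makeScaffold <- function(scheme, nHelices = 7L, helixLen = 36L, loopLen = 14L,
                         seed) {
  if (is.character(scheme)) scheme <- referenceScheme(scheme)
  stopifnot(methods::is(scheme, "ReferenceScheme"),
            nHelices >= 1L, helixLen >= 1L, loopLen >= 1L)
  if (missing(seed)) stop("seed is mandatory for every stochastic generator")
  kp <- scheme@keyPositions
  slots <- .allocateKeySlots(nrow(kp), nHelices, helixLen, loopLen)
  total <- loopLen + nHelices * (helixLen + loopLen)
  chars <- withSeed(seed, {
    out <- character(total)
    pos <- 1L
    out[seq_len(loopLen)] <- sample(.HYDROPHILIC, loopLen, replace = TRUE)
    pos <- loopLen
    for (h in seq_len(nHelices)) {
      out[pos + seq_len(helixLen)] <- sample(.HYDROPHOBIC, helixLen,
                                             replace = TRUE,
                                             prob = .HYDROPHOBIC_W)
      pos <- pos + helixLen
      out[pos + seq_len(loopLen)] <- sample(.HYDROPHILIC, loopLen, replace = TRUE)
      pos <- pos + loopLen
    }
    out
  })
  for (j in seq_len(nrow(kp)))
    chars[slots[j]] <- kp$expected[[j]][1L]
  out <- scheme
  out@scaffold <- paste(chars, collapse = "")
  out@keyPositions$position <- as.integer(slots)
  methods::validObject(out)
  out
}

#' Plant a residue fingerprint on a scaffold
#'
#' Copies the scaffold, writes the requested residues at the scheme's key
#' positions, and applies background substitutions (uniform over the other
#' 19 residues) everywhere else at the given rate. The planted fingerprint is
#' attached as the \code{"planted"} attribute, giving alignment-based mapping
#' a known ground truth.
#'
#' @param scaffold a scaffold-bearing \code{\link{ReferenceScheme}} from
#'   \code{\link{makeScaffold}}.
#' @param residues named character vector, role -> residue to plant; roles
#'   not named keep the scaffold residue.
#' @param rate background substitution rate outside key positions, in
#'   [0, 0.2].
#' @param seed RNG seed (mandatory).
#' @param id entry identifier of the variant.
#' @return named character vector of length 1 (the variant sequence) with
#'   attribute \code{"planted"} (role -> residue actually planted).
#' @export
makeVariant <- function(scaffold, residues = character(), rate = 0, seed,
                        id = "variant") {
  stopifnot(methods::is(scaffold, "ReferenceScheme"))
  if (is.na(scaffold@scaffold)) stop("scaffold scheme carries no sequence")
  if (missing(seed)) stop("seed is mandatory for every stochastic generator")
  if (rate < 0 || rate > 0.2) stop("background rate must lie in [0, 0.2]")
  kp <- scaffold@keyPositions
  if (length(residues)) {
    bad <- setdiff(names(residues), kp$role)
    if (length(bad)) stop(sprintf("unknown role '%s'", bad[1L]))
    if (!all(toupper(residues) %in% AA_ALPHABET))
      stop("planted residues must be valid codes")
  }
  chars <- strsplit(scaffold@scaffold, "", fixed = TRUE)[[1L]]
  planted <- stats::setNames(chars[kp$position], kp$role)
  for (role in names(residues)) {
    planted[role] <- toupper(residues[[role]])
    chars[kp$position[match(role, kp$role)]] <- planted[role]
  }
  if (rate > 0) {
    chars <- withSeed(seed, {
      free <- setdiff(seq_along(chars), kp$position)
      hit <- free[stats::runif(length(free)) < rate]
      for (i in hit)
        chars[i] <- sample(setdiff(AA_CODES, chars[i]), 1L)
      chars
    })
  }
  out <- stats::setNames(paste(chars, collapse = ""), id)
  attr(out, "planted") <- planted
  out
}

#' Evolve a sequence family on a known tree
#'
#' Starting from the scaffold at the root, substitutions accumulate
#' independently per site along each branch: a site changes with probability
#' \code{1 - exp(-rate * branch length)} and, when it changes, draws
#' uniformly from the other 19 residues (a uniform replacement model; no
#' rate heterogeneity, no indels).
#'
#' @param tree an \code{ape::phylo} tree with named leaves and branch
#'   lengths.
#' @param scaffold a scaffold-bearing \code{\link{ReferenceScheme}} or a
#'   root sequence (character scalar).
#' @param rate expected substitutions per site per unit branch length.
#' @param seed RNG seed (mandatory).
#' @return named character vector of leaf sequences (tip-label order).
#' @export
evolveFamily <- function(tree, scaffold, rate, seed) {
  stopifnot(inherits(tree, "phylo"), rate >= 0)
  if (missing(seed)) stop("seed is mandatory for every stochastic generator")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  root_seq <- if (methods::is(scaffold, "ReferenceScheme")) {
    if (is.na(scaffold@scaffold)) stop("scaffold scheme carries no sequence")
    scaffold@scaffold
  } else {
    .asSeqVector(scaffold)[[1L]]
  }
  chars <- strsplit(root_seq, "", fixed = TRUE)[[1L]]
  tree <- stats::reorder(tree, "cladewise")  # edges in preorder
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- chars
  withSeed(seed, {
    # parents appear before children in cladewise edge order
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      s <- seqs[[parent]]
      p <- -expm1(-rate * tree$edge.length[e])
      if (p > 0) {
        hit <- which(stats::runif(length(s)) < p)
        for (i in hit) s[i] <- sample(setdiff(AA_CODES, s[i]), 1L)
      }
      seqs[[child]] <- s
    }
  })
  stats::setNames(vapply(seq_len(ntip), function(i)
    paste(seqs[[i]], collapse = ""), ""), tree$tip.label)
}
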