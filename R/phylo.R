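# Distance-based phylogeny: p-distances, neighbor-joining (Saitou-Nei
# agglomeration with deterministic tie-breaking), and bootstrap support.

#' Proportion of differing sites between two aligned sequences
#'
#' Columns where either sequence carries a gap are excluded pairwise;
#' the distance is mismatches over compared columns.
#'
#' @param alignedA,alignedB aligned sequences of equal length (gap
#'   character \code{"-"}).
#' @return p-distance in [0, 1].
#' @export
pDistance <- function(alignedA, alignedB) {
  a <- strsplit(.asSeqVector(alignedA)[[1L]], "", fixed = TRUE)[[1L]]
  b <- strsplit(.asSeqVector(alignedB)[[1L]], "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  keep <- a != GAP_CODE & b != GAP_CODE
  if (!any(keep)) stop("no comparable columns (all gapped)")
  mean(a[keep] != b[keep])
}

#' Poisson-corrected distance
#'
#' \code{-log(1 - p)} for a p-distance \code{p}; expected substitutions per
#' site under a Poisson model of equal rates. Saturated pairs (p >= 1) are an
#' error rather than infinity.
#'
#' @param p a p-distance in [0, 1).
#' @return corrected distance.
#' @export
poissonCorrect <- function(p) {
  if (any(p >= 1)) stop("saturated pair (p >= 1): Poisson correction undefined")
  -log1p(-p)
}

#' Pairwise distance matrix for aligned sequences
#'
#' @param alignedSeqs named character vector or \code{AAStringSet} of equal
#'   lengths.
#' @param model \code{"p"} (default) or \code{"poisson"}.
#' @return symmetric numeric matrix with zero diagonal, dimnames = entry ids.
#' @export
distanceMatrix <- function(alignedSeqs, model = c("p", "poisson")) {
  model <- match.arg(model)
  seqs <- .asSeqVector(alignedSeqs)
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2L) {
    for (i in 1L:(n - 1L)) for (j in (i + 1L):n) {
      d <- pDistance(seqs[[i]], seqs[[j]])
      if (model == "poisson") d <- poissonCorrect(d)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion \code{(n-2) d(i,j) - r(i) - r(j)} is joined (ties broken by
#' the lowest index pair, so the result is deterministic), branch lengths
#' follow the standard formulas, and the final three lineages are resolved by
#' the closed-form star equations. Negative branch lengths are clamped to
#' zero with the excess moved to the sister branch. The result is unrooted
#' (trifurcating root node).
#'
#' @param D symmetric distance matrix with dimnames, at least 3 taxa.
#' @return an \code{ape::phylo} tree.
#' @examples
#' D <- matrix(c(0,2,4,4, 2,0,4,4, 4,4,0,2, 4,4,2,0), 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' njTree(D)
#' @export
njTree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D must carry taxon names as dimnames")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(D)
  if (anyDuplicated(labs)) stop("duplicate taxon names")
  node <- as.list(labs)   # newick fragment per active lineage
  d <- unname(D)
  fmt <- function(x) sprintf("%.15g", x)
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index (i, j) among the minimisers, i < j
    minQ <- min(Q)
    hits <- which(Q <= minQ + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    frag <- sprintf("(%s:%s,%s:%s)", node[[i]], fmt(vi), node[[j]], fmt(vj))
    keep <- setdiff(seq_len(n), c(i, j))
    du <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    du <- pmax(du, 0)
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du), c(du, 0))
    node <- c(node[keep], frag)
    n <- n - 1L
  }
  va <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  vb <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  vc <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[[1L]], fmt(va), node[[2L]], fmt(vb), node[[3L]], fmt(vc))
  ape::read.tree(text = txt)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement \code{nReplicates}
#' times; a tree is rebuilt per replicate and each internal bipartition of
#' the full-data tree is annotated with its replicate frequency times 100.
#' Supports are matched by bipartition identity, not node order. The basal
#' (trifurcating root) node carries \code{NA}: its "bipartition" is trivial.
#'
#' @param alignedSeqs named character vector or \code{AAStringSet}, all of
#'   equal length, at least 3 sequences.
#' @param nReplicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed; identical seeds give identical supports.
#' @param model distance model, see \code{\link{distanceMatrix}}.
#' @return the full-data \code{ape::phylo} tree with \code{node.label} set
#'   to integer supports in [0, 100].
#' @export
bootstrapSupport <- function(alignedSeqs, nReplicates = 1000L, seed = 1L,
                             model = c("p", "poisson")) {
  model <- match.arg(model)
  seqs <- .asSeqVector(alignedSeqs)
  if (length(seqs) < 3L) stop("bootstrap needs at least 3 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment must be rectangular")
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  ncols <- ncol(chars)
  buildTree <- function(mat) {
    s <- apply(mat, 1L, paste, collapse = "")
    njTree(distanceMatrix(s, model = model))
  }
  main <- buildTree(chars)
  reps <- withSeed(seed, {
    lapply(seq_len(nReplicates), function(k) {
      idx <- sample.int(ncols, ncols, replace = TRUE)
      buildTree(chars[, idx, drop = FALSE])
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L  # bipartition seen in no replicate
  support <- pmin(pmax(round(100 * counts / nReplicates), 0), 100)
  main$node.label <- as.character(support)
  main$node.label[1L] <- ""  # basal node: trivial bipartition
  main
}
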