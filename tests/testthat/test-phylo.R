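# p-distances, neighbor joining, and bootstrap support.

test_that("p-distance counts mismatches over comparable columns", {
  expect_equal(pDistance("ACDE", "ACDE"), 0)
  expect_equal(pDistance("AAAA", "AAAT"), 0.25)
  # gapped columns are excluded pairwise
  expect_equal(pDistance("A-CD", "AAC-"), 0)
  expect_error(pDistance("--", "AA"), "no comparable")
  expect_error(pDistance("AC", "ACG"), "equal length")
  # brute-force column comparison on random gapped pairs
  for (i in 1:100) {
    chars <- c(strsplit("ACDEFG", "")[[1]], "-")
    ab <- withr::with_seed(i, list(
      paste(sample(chars, 30, replace = TRUE), collapse = ""),
      paste(sample(chars, 30, replace = TRUE), collapse = "")))
    ok <- tryCatch(pDistance(ab[[1]], ab[[2]]), error = function(e) NULL)
    if (!is.null(ok)) expect_equal(ok, bruteForcePDistance(ab[[1]], ab[[2]]))
  }
})

test_that("Poisson correction rejects saturated pairs", {
  expect_equal(poissonCorrect(0), 0)
  expect_equal(poissonCorrect(0.5), -log(0.5))
  expect_error(poissonCorrect(1), "saturated")
})

test_that("neighbor joining recovers the hand-computed additive quartet exactly", {
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(D)
  # topology: (a,b) vs (c,d), all pendant branches 1, internal branch 2
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
    ape::read.tree(text = "((a:1,b:1):2,c:1,d:1);"))), 0)
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], D)
})

test_that("three taxa resolve by the closed-form star equations", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- njTree(D)
  ed <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(ed[["x"]], (3 + 4 - 5) / 2)
  expect_equal(ed[["y"]], (3 + 5 - 4) / 2)
  expect_equal(ed[["z"]], (4 + 5 - 3) / 2)
  expect_error(njTree(D[1:2, 1:2]), "at least 3")
  Dasym <- D; Dasym[1, 2] <- 9
  expect_error(njTree(Dasym), "symmetric")
})

test_that("NJ is consistent: additive matrices are reproduced within 1e-9", {
  worst <- 0
  for (k in 1:100) {
    nt <- withr::with_seed(k, sample(4:8, 1))
    rt <- withr::with_seed(k + 300, ape::rtree(nt))
    Dm <- ape::cophenetic.phylo(rt)
    out <- njTree(Dm)
    Dc <- ape::cophenetic.phylo(out)[rownames(Dm), colnames(Dm)]
    worst <- max(worst, max(abs(Dc - Dm)))
  }
  expect_lt(worst, 1e-9)
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  for (k in 1:20) {
    base <- withr::with_seed(k + 900, ape::rtree(8))
    noise <- withr::with_seed(k, matrix(runif(64, 0, 0.02), 8))
    M <- ape::cophenetic.phylo(base) + noise
    M <- (M + t(M)) / 2
    diag(M) <- 0
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(njTree(M)),
                                           ape::unroot(ape::nj(M)))), 0)
  }
})

test_that("bootstrap gives near-certain support to fixed cherries and is seed-reproducible", {
  # two pairs differ at 50 fixed columns each; 100 columns separate the pairs
  base <- strrep("A", 250)
  mk <- function(subs) {
    chars <- strsplit(base, "")[[1]]
    for (nm in names(subs)) {
      idx <- as.integer(strsplit(nm, ":")[[1]])
      chars[idx[1]:idx[2]] <- subs[[nm]]
    }
    paste(chars, collapse = "")
  }
  al <- c(a = mk(list("1:100" = "C", "101:150" = "G")),
          b = mk(list("1:100" = "C", "101:150" = "T")),
          c = mk(list("151:200" = "G")),
          d = mk(list("151:200" = "T")))
  bt <- bootstrapSupport(al, nReplicates = 200, seed = 9)
  sup <- as.integer(bt$node.label[bt$node.label != ""])
  expect_true(all(sup >= 95))
  expect_true(all(sup <= 100))

  bt2 <- bootstrapSupport(al, nReplicates = 200, seed = 9)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))
  bt3 <- bootstrapSupport(al, nReplicates = 200, seed = 10)
  expect_equal(bt3$tip.label, bt$tip.label)

  # a single replicate can only give 0 or 100
  b1 <- bootstrapSupport(al, nReplicates = 1, seed = 3)
  sup1 <- as.integer(b1$node.label[b1$node.label != ""])
  expect_true(all(sup1 %in% c(0L, 100L)))
})

test_that("identical sequences collapse to a star with zero internal structure", {
  al <- setNames(rep(strrep("ACDEF", 20), 4), letters[1:4])
  tr <- njTree(distanceMatrix(al))
  expect_equal(sum(tr$edge.length), 0)
})

test_that("families evolved at low rate recover the true topology", {
  tree <- recoveryTree()
  sc <- makeScaffold("BR", seed = 50)
  hits <- 0L
  n <- 50L
  for (i in seq_len(n)) {
    leaves <- evolveFamily(tree, sc, rate = 1, seed = 8000 + i)
    out <- njTree(distanceMatrix(leaves))
    hits <- hits + (as.numeric(ape::dist.topo(ape::unroot(out), ape::unroot(tree))) == 0)
  }
  expect_gte(hits / n, 0.9)
})
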