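# Global alignment and projection of reference key positions onto queries.

test_that("self-alignment scores the substitution diagonal", {
  aln <- globalAlign("MKLV", "MKLV")
  expect_equal(unname(alignedStrings(aln)), c("MKLV", "MKLV"))
  expect_equal(alignmentScore(aln),
               sum(diag(.blosum62[c("M", "K", "L", "V"), c("M", "K", "L", "V")])))
})

test_that("alignment scores equal the exhaustive optimum on short pairs", {
  # the single-gap example, against full enumeration
  aln <- globalAlign("MKLV", "MLV")
  expect_equal(alignmentScore(aln), bruteForceAlignScore("MKLV", "MLV"))
  expect_equal(unname(alignedStrings(aln)), c("MKLV", "M-LV"))

  # seeded random pairs with combined length <= 12
  for (i in 1:40) {
    na <- withr::with_seed(i, sample(1:6, 1))
    nb <- withr::with_seed(i + 100, sample(1:(12 - na), 1))
    a <- randomProtein(na, seed = 2 * i)
    b <- randomProtein(min(nb, 12 - na), seed = 2 * i + 1)
    expect_equal(alignmentScore(globalAlign(a, b)),
                 bruteForceAlignScore(a, b),
                 info = sprintf("pair %d: %s / %s", i, a, b))
  }
})

test_that("alignment score is symmetric", {
  for (i in 1:50) {
    a <- randomProtein(withr::with_seed(i, sample(5:30, 1)), seed = 3 * i)
    b <- randomProtein(withr::with_seed(i + 500, sample(5:30, 1)), seed = 3 * i + 1)
    expect_equal(alignmentScore(globalAlign(a, b)),
                 alignmentScore(globalAlign(b, a)))
  }
})

test_that("identity queries map every role to its own scaffold position", {
  sc <- makeScaffold("BR", seed = 2)
  aln <- globalAlign(scaffoldSeq(sc), scaffoldSeq(sc))
  fp <- mapPositions(aln, sc, entryId = "self")
  kp <- keyPositions(sc)
  expect_equal(unname(positionMatrix(fp)["self", ]), kp$position)
  scaffold_chars <- strsplit(scaffoldSeq(sc), "")[[1]]
  expect_equal(unname(residueMatrix(fp)["self", ]), scaffold_chars[kp$position])
})

test_that("an N-terminal insertion shifts every mapped position by its length", {
  sc <- makeScaffold("BR", seed = 13)
  ins <- "DEKRGSNQHT"  # 10 hydrophilic residues prepended
  query <- paste0(ins, scaffoldSeq(sc))
  aln <- globalAlign(scaffoldSeq(sc), query)
  fp <- mapPositions(aln, sc, entryId = "shift")
  expect_equal(unname(positionMatrix(fp)["shift", ]),
               keyPositions(sc)$position + nchar(ins))
})

test_that("a deleted key-position column is reported as a gap", {
  sc <- makeScaffold("BR", seed = 13)
  kp <- keyPositions(sc)
  p <- kp$position[kp$role == "acceptor"]
  chars <- strsplit(scaffoldSeq(sc), "")[[1]]
  query <- paste(chars[-p], collapse = "")
  fp <- mapPositions(globalAlign(scaffoldSeq(sc), query), sc, entryId = "del")
  expect_equal(residueAt(fp, "del", "acceptor"), "-")
  expect_true(is.na(positionMatrix(fp)["del", "acceptor"]))
  # remaining roles still map
  expect_true(all(!is.na(positionMatrix(fp)["del", kp$role != "acceptor"])))
})

test_that("mapped positions are strictly increasing in reference order", {
  sc <- makeScaffold("BR", seed = 31)
  for (i in 1:20) {
    v <- makeVariant(sc, rate = 0.05, seed = 400 + i, id = "v")
    fp <- extractFingerprints(v, sc)
    if (length(entryIds(fp)) == 1L) {
      pos <- positionMatrix(fp)[1, ]
      pos <- pos[!is.na(pos)]
      expect_true(all(diff(pos) > 0))
    }
  }
})

test_that("fingerprint batches map planted residues and report failures", {
  sc <- makeScaffold("BR", seed = 17)
  spec <- pumpSpec()
  seqs <- vapply(1:5, function(i)
    makeVariant(sc, spec, rate = 0.03, seed = 600 + i, id = paste0("v", i)), "")
  names(seqs) <- paste0("v", 1:5)
  fp <- extractFingerprints(seqs, sc)
  for (id in entryIds(fp))
    expect_equal(residueMatrix(fp)[id, names(spec)], spec)

  # empty batch gives an empty table
  fp0 <- extractFingerprints(character(), sc)
  expect_length(entryIds(fp0), 0)

  # a non-rhodopsin is skipped with a reason unless forced
  bad <- c(junk = strrep("D", 120))
  fp1 <- extractFingerprints(c(seqs[1], bad), sc)
  expect_equal(entryIds(fp1), "v1")
  expect_match(attr(fp1, "failures")[["junk"]], "helix count")
  fp2 <- extractFingerprints(bad, sc, force = TRUE)
  expect_equal(entryIds(fp2), "junk")
})

test_that("planted fingerprints are read back through alignment at mutation rate 5%", {
  sc <- makeScaffold("BR", seed = 42)
  spec <- pumpSpec()
  n <- 300L
  ok <- 0L
  for (i in seq_len(n)) {
    v <- makeVariant(sc, spec, rate = 0.05, seed = 7000 + i, id = "v")
    fp <- extractFingerprints(v, sc, validate = FALSE)
    ok <- ok + (length(entryIds(fp)) == 1L &&
                  all(residueMatrix(fp)[1, names(spec)] == spec))
  }
  expect_gte(ok / n, 0.99)
})
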