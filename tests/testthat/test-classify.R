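# The rule engine: channel, pump, spectral, cyclase calls and conservation.

test_that("channel rules call the curated channel rows and falsify on single mutations", {
  t1 <- loadFixture("table1B")
  calls <- classifyChannel(t1)
  expect_equal(calls$functional_class, rep("CHANNEL_COMPETENT", 4))

  # single-rule falsification: the DC-gate cysteine of KnRh3 mutated to T
  kn <- t1["KnRh3"]
  m <- residueMatrix(kn)
  m["KnRh3", "dcGate"] <- "T"
  kn2 <- methods::new("ResidueTable", scheme = scheme(kn), entries = "KnRh3",
                      isReference = FALSE, residues = m,
                      positions = positionMatrix(kn), meta = data.frame())
  call2 <- classifyChannel(kn2)
  expect_equal(call2$functional_class, "SENSORY_ATYPICAL")
  expect_false(call2$ev_dcGate)
  expect_true(call2$ev_acceptor)

  # losing the attachment lysine makes the entry non-retinylidene
  m["KnRh3", "dcGate"] <- "C"
  m["KnRh3", "attachment"] <- "R"
  kn3 <- methods::new("ResidueTable", scheme = scheme(kn), entries = "KnRh3",
                      isReference = FALSE, residues = m,
                      positions = positionMatrix(kn), meta = data.frame())
  expect_equal(classifyChannel(kn3)$functional_class, "NON_RETINYLIDENE")

  expect_error(classifyChannel(loadFixture("table2B")), "ChR2")
})

test_that("pump rules single out the curated pump entry and keep the release group non-gating", {
  t2 <- loadFixture("table2B")
  calls <- classifyPump(t2)

  expect_equal(calls$functional_class[calls$entry == "BR"], "PUMP_COMPETENT")
  expect_equal(calls$functional_class[calls$entry == "AsRh4"], "PUMP_COMPETENT")
  # AsRh4 passes the gate despite G at the first release position
  expect_false(calls$ev_release1[calls$entry == "AsRh4"])
  expect_equal(calls$functional_class[calls$entry == "Cop6"], "SENSORY_ATYPICAL")

  modular <- subset(calls, !is_reference)
  pumps <- modular$entry[modular$functional_class == "PUMP_COMPETENT"]
  expect_equal(pumps, "AsRh4")
  # every other modular entry keeps the lysine, so none is non-retinylidene
  expect_equal(sort(unique(modular$functional_class)),
               c("PUMP_COMPETENT", "SENSORY_ATYPICAL"))
})

test_that("the rule engine is pure: calls are identical regardless of batch order", {
  t2 <- loadFixture("table2B")
  rev_idx <- rev(seq_along(entryIds(t2)))
  calls_fwd <- classifyPump(t2)
  calls_rev <- classifyPump(t2[rev_idx])
  o <- match(calls_fwd$entry, calls_rev$entry)
  expect_equal(calls_rev$functional_class[o], calls_fwd$functional_class)
})

test_that("spectral calls follow the polarity partition and are total", {
  expect_equal(classifySpectral(c("L", "I", "M")), rep("GREEN", 3))
  expect_equal(classifySpectral("Q"), "BLUE")
  expect_equal(classifySpectral("D"), "UNKNOWN")
  expect_equal(classifySpectral(NA), "UNSCORED")
  expect_equal(classifySpectral("-"), "UNSCORED")
  expect_error(classifySpectral("Z"), "invalid")

  # total over the 20 residues: never UNSCORED for a valid residue
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_false(any(classifySpectral(aa20) == "UNSCORED"))

  # agreement with every printed call of the packaged spectral table
  t3 <- loadFixture("table3")
  called <- classifySpectral(residueMatrix(t3)[, "tuner"])
  printed <- toupper(tableMeta(t3)$shift_printed)
  expect_equal(called, printed)
})

test_that("cyclase rules separate intact from degenerate catalytic fingerprints", {
  cy <- loadFixture("cyclase")
  calls <- classifyCyclase(cy)
  expect_equal(calls$cyclase_class[calls$entry == "CyaRef"], "ACTIVE")
  expect_equal(calls$cyclase_class[calls$entry == "Cop5"], "DEGENERATE")
  expect_equal(calls$cyclase_class[calls$entry == "Vop5"], "DEGENERATE")
  expect_false(calls$ev_metal1[calls$entry == "Cop5"])
  expect_error(classifyCyclase(loadFixture("table1B")), "CYC")
})

test_that("conservation counts reproduce the curated table tallies", {
  t2 <- loadFixture("table2B")
  count <- function(pos, set) conservedCount(tabulateConservation(t2, pos, set))
  expect_equal(count(85, c("D", "E")), 14L)
  expect_equal(count(85, "Q"), 17L)
  expect_equal(count(212, "N"), 6L)
  expect_equal(count(204, "E"), 25L)
  expect_equal(count(216, "K"),
               conservedDenominator(tabulateConservation(t2, 216, "K")))
  # the full alphabet counts everything with a residue present at 85
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(count(85, aa20), 46L)
  # missing cells stay out of the numerator: three entries print no residue
  # at the second release position
  cc204 <- tabulateConservation(t2, 204, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(conservedCount(cc204), 43L)
  expect_equal(conservedDenominator(cc204), 46L)
  expect_error(tabulateConservation(t2, 100, "D"), "not a key position")
})

test_that("annotateRows orchestrates scheme dispatch and cyclase attachment", {
  a1 <- annotateRows(loadFixture("table1B"))
  expect_equal(sum(a1$functional_class == "CHANNEL_COMPETENT" & !a1$is_reference), 3L)

  a2 <- annotateRows(loadFixture("table2B"), cyclaseTable = loadFixture("cyclase"))
  mod <- subset(a2, !is_reference)
  expect_equal(mod$entry[mod$functional_class == "PUMP_COMPETENT"], "AsRh4")
  expect_equal(a2$cyclase_class[a2$entry == "Cop5"], "DEGENERATE")
  expect_equal(a2$cyclase_class[a2$entry == "Cop6"], "ACTIVE")
  expect_equal(a2$cyclase_class[a2$entry == "AsRh4"], "NOT_APPLICABLE")

  a3 <- annotateRows(loadFixture("table3"))
  expect_equal(a3$spectral_class[a3$entry == "GtRh1"], "UNKNOWN")
  expect_true(all(a3$spectral_class[a3$entry != "GtRh1" & !a3$is_reference] == "GREEN"))

  # empty input gives an empty report
  t1 <- loadFixture("table1B")
  empty <- t1[integer(0)]
  expect_equal(nrow(annotateRows(empty)), 0L)
})

test_that("annotation reports serialise deterministically", {
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  calls <- annotateRows(loadFixture("table2B"))
  writeAnnotationReport(calls, f1, params = list(scheme = "BR"))
  writeAnnotationReport(calls, f2, params = list(scheme = "BR"))
  expect_identical(readLines(f1), readLines(f2))
  rep <- jsonlite::read_json(f1)
  expect_equal(rep$n_entries, 53L)
})
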