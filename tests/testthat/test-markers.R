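cutoff_table <- function() {
  utils::read.table(system.file("extdata", "marker_cutoffs.tsv",
                                package = "lporkit"),
                    header = TRUE, sep = "\t")
}

test_that("tblout parsing handles comments, cutoffs and malformed lines", {
  cuts <- cutoff_table()
  empty <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c("# only", "# comments"), empty)
  expect_equal(nrow(read_hmm_tblout(empty, cutoffs = cuts)), 0)

  f <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c(
    "# target name accession query name accession E-value score bias",
    "prot1 - TIGR01289 - 1e-30 220.0 0.0 1e-30 220.0 0.0 1 1 0 0 1 1 1 1 d",
    "prot2 - TIGR01289 - 1e-10 120.0 0.0 1e-10 120.0 0.0 1 1 0 0 1 1 1 1 d"),
    f)
  hits <- read_hmm_tblout(f, genome_id = "g1", cutoffs = cuts)
  expect_equal(hits$marker, c("LPOR", "LPOR"))
  expect_equal(hits$score, c(220, 120))
  # 220 >= trusted cutoff 200 qualifies; 120 is parsed but flagged below
  expect_equal(hits$meets_cutoff, c(TRUE, FALSE))

  bad <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c("prot1 - TIGR01289 - notanumber 220.0 0.0 x"), bad)
  expect_error(read_hmm_tblout(bad), "malformed tblout line 1")
})

test_that("presence matrix keeps the best qualifying hit as provenance", {
  cuts <- cutoff_table()
  f <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c(
    "hitA - TIGR01289 - 1e-40 260.0 0.0 . . . . . . . . . . . d",
    "hitB - TIGR01289 - 1e-30 210.0 0.0 . . . . . . . . . . . d",
    "hitC - TIGR02014 - 1e-03  80.0 0.0 . . . . . . . . . . . d"), f)
  hits <- read_hmm_tblout(f, genome_id = "g1", cutoffs = cuts)
  expect_warning(m <- presence_matrix(hits, genomes = c("g1", "g2")),
                 "zero scanned markers")
  expect_true(m["g1", "LPOR"])
  expect_false(m["g1", "BchB"])   # 80 bits below the 250 cutoff
  expect_false(any(m["g2", ]))
  prov <- attr(m, "provenance")
  expect_equal(prov$score[prov$marker == "LPOR"], 260)
  # idempotent and order-independent
  m2 <- suppressWarnings(presence_matrix(hits[rev(seq_len(nrow(hits))), ],
                                         genomes = c("g1", "g2")))
  expect_identical(unclass(m)[, ], unclass(m2)[, ])
})

test_that("shipped genome fixtures classify as expected", {
  cuts <- cutoff_table()
  hits <- lapply(c("example_aapb.tblout", "example_oxygenic.tblout"),
                 function(f) read_hmm_tblout(
                   system.file("extdata", f, package = "lporkit"),
                   cutoffs = cuts))
  m <- presence_matrix(hits)
  calls <- call_aapb(m)
  expect_true(calls$is_aapb[calls$genome_id == "example_aapb"])
  expect_false(calls$is_aapb[calls$genome_id == "example_oxygenic"])
  # the spurious sub-cutoff RuBisCO hit must not register as presence
  expect_false(m["example_aapb", "RuBisCO_large"])
})

test_that("AAPB rule matches its clause structure on hand-built rows", {
  base <- stats::setNames(rep(FALSE, length(MARKER_SET)), MARKER_SET)
  aapb <- base
  aapb[c("BchB", "BchL", "BchN", "PufL", "PufM", "AcsF")] <- TRUE
  expect_true(call_aapb(aapb)$is_aapb)
  # both Calvin markers present disqualifies
  calvin <- aapb; calvin[c("RuBisCO_large", "PRK")] <- TRUE
  cl <- call_aapb(calvin)
  expect_false(cl$is_aapb)
  expect_false(cl$reasons[["lacks_calvin"]])
  # one Calvin marker alone does not (either_absent reading)
  one <- aapb; one["RuBisCO_large"] <- TRUE
  expect_true(call_aapb(one)$is_aapb)
  # but the strict reading rejects it
  expect_false(call_aapb(one, rubisco_mode = "both_absent")$is_aapb)
  # missing any DPOR subunit disqualifies regardless of the rest
  nod <- aapb; nod["BchL"] <- FALSE
  expect_false(call_aapb(nod)$is_aapb)
  # BchE substitutes for AcsF
  bche <- aapb; bche["AcsF"] <- FALSE; bche["BchE"] <- TRUE
  expect_true(call_aapb(bche)$is_aapb)
})

test_that("AAPB rule agrees with the truth-table oracle over all patterns", {
  vars <- c("BchB", "BchL", "BchN", "PufL", "PufM", "AcsF", "BchE",
            "RuBisCO_large", "PRK")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(vars)))
  names(grid) <- vars
  for (i in seq_len(nrow(grid))) {
    row <- stats::setNames(rep(FALSE, length(MARKER_SET)), MARKER_SET)
    row[vars] <- unlist(grid[i, ])
    expected <- (grid$BchB[i] & grid$BchL[i] & grid$BchN[i]) &
      (grid$PufL[i] & grid$PufM[i]) &
      (grid$AcsF[i] | grid$BchE[i]) &
      (!grid$RuBisCO_large[i] | !grid$PRK[i])
    expect_identical(call_aapb(row)$is_aapb, expected)
  }
})
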