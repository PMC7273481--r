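fig3_sentence <- "Immunohistochemical study shows: ER (positive, 90%), PR (negative), HER2 (negative, 1+)."

test_that("locate_ihc_paragraphs finds all three dialect cues, description only", {
  rep1 <- report("L1", "Liver, biopsy --- carcinoma, metastatic, breast origin",
                 c("Sections show metastatic carcinoma.", fig3_sentence))
  expect_identical(locate_ihc_paragraphs(rep1), fig3_sentence)

  block <- "ER (positive, 80%)\nPR (positive, 30%)\nHER2 (equivocal, 2+)"
  rep2 <- report("L2", "x", c("Gross description.", block))
  expect_identical(locate_ihc_paragraphs(rep2), block)

  comma <- "ER: positive, 80%, PR: negative, HER2: negative, score 1, weak staining in 10%"
  rep3 <- report("L3", "x", comma)
  expect_identical(locate_ihc_paragraphs(rep3), comma)

  rep4 <- report("L4", "x", c("No special stains.", "Benign tissue."))
  expect_identical(locate_ihc_paragraphs(rep4), character())
  expect_identical(locate_ihc_paragraphs(report("L5", "x")), character())
})

test_that("parse_er and parse_pr handle the three ER/PR patterns", {
  r <- parse_er("ER (positive, 80%)")
  expect_equal(r$status, "positive"); expect_equal(r$percent, 80L)
  r <- parse_pr("PR: positive, 30%")
  expect_equal(r$status, "positive"); expect_equal(r$percent, 30L)
  r <- parse_er("ER (negative)")
  expect_equal(r$status, "negative"); expect_true(is.na(r$percent))
  # spacing and case variants
  expect_equal(parse_er("er ( Positive , 80 % )")$percent, 80L)
  # wrong markers are ignored entirely
  expect_equal(parse_er("CK7 (positive)")$status, "not_found")
  expect_equal(parse_er("PERT (positive, 10%)")$status, "not_found")
  expect_equal(parse_pr("ER (positive, 80%)")$status, "not_found")
})

test_that("percent ranges record the lower bound", {
  r <- parse_er("ER (positive, 80-90%)")
  expect_equal(r$percent, 80L)
  r <- parse_pr("PR: positive, 5 - 10%")
  expect_equal(r$percent, 5L)
})

test_that("unparseable marker tails give not_found with a logged warning", {
  withr::with_options(list(ihcmine.verbose = TRUE), {
    expect_message(r <- parse_er("ER shows strong staining"), "not parseable")
  })
  expect_equal(r$status, "not_found")
  # equivocal is not a 2013 ER/PR category
  withr::with_options(list(ihcmine.verbose = TRUE), {
    expect_message(r <- parse_er("ER (equivocal, 10%)"), "equivocal")
  })
  expect_equal(r$status, "not_found")
})

test_that("parse_her2 handles both patterns and all four spellings", {
  r <- parse_her2("HER2 (positive, 3+)")
  expect_equal(r$status, "positive"); expect_equal(r$score, "3+")
  r <- parse_her2("Her-2: negative, score 1, weak staining in 10%")
  expect_equal(r$status, "negative")
  expect_equal(r$score, "1+")
  expect_equal(r$intensity, "weak")
  expect_equal(r$percent, 10L)
  r <- parse_her2("her2 (equivocal, 2+)")
  expect_equal(r$status, "equivocal"); expect_equal(r$score, "2+")
  for (sp in c("Her-2", "Her2", "HER2", "HER-2")) {
    expect_equal(parse_her2(sprintf("%s (negative, 0)", sp))$score, "0",
                 info = sp)
  }
  # bare "score 2" normalises to 2+, "score 0" and bare 0 to "0"
  expect_equal(parse_her2("HER2: equivocal, score 2")$score, "2+")
  expect_equal(parse_her2("HER2: negative, score 0")$score, "0")
})

test_that("HER2 status/score mismatches are kept as written but logged", {
  withr::with_options(list(ihcmine.verbose = TRUE), {
    expect_message(r <- parse_her2("HER2 (positive, 1+)"), "inconsistent")
  })
  expect_equal(r$status, "positive")
  expect_equal(r$score, "1+")
})

test_that("receptor_result enforces the marker invariants", {
  expect_error(receptor_result("ER", "equivocal"), class = "ihcmine_parse_error")
  expect_error(receptor_result("PR", "positive", score = "2+"),
               class = "ihcmine_parse_error")
  expect_error(receptor_result("ER", "positive", percent = 150L),
               class = "ihcmine_parse_error")
})

test_that("extract_panel combines markers; first mention wins", {
  rep1 <- report("P1", "Liver, biopsy --- carcinoma, metastatic, breast origin",
                 c("Sections show metastatic carcinoma.", fig3_sentence))
  panel <- extract_panel(rep1)
  expect_equal(panel$er$status, "positive"); expect_equal(panel$er$percent, 90L)
  expect_equal(panel$pr$status, "negative")
  expect_equal(panel$her2$status, "negative")
  expect_equal(panel$her2$score, "1+")

  none <- extract_panel(report("P2", "x", "Benign tissue only."))
  expect_true(all(vapply(none, `[[`, character(1), "status") == "not_found"))

  # same status twice: first mention (paragraph order) kept
  two <- report("P3", "x", c("ER (positive, 70%)", "ER (positive, 20%)"))
  expect_equal(extract_panel(two)$er$percent, 70L)
  rev2 <- report("P4", "x", c("ER (positive, 20%)", "ER (positive, 70%)"))
  expect_equal(extract_panel(rev2)$er$percent, 20L)

  # disagreeing statuses demote the marker to not_found
  conflict <- report("P5", "x", c("ER (positive, 70%)", "ER (negative)"))
  withr::with_options(list(ihcmine.verbose = TRUE), {
    expect_message(p <- extract_panel(conflict), "conflicting")
  })
  expect_equal(p$er$status, "not_found")
})

test_that("diagnosis column content never influences extraction", {
  base <- report("Q1", "Liver, biopsy --- carcinoma, metastatic, breast origin",
                 fig3_sentence)
  spiked <- report("Q1", c(base$diagnosis_lines,
                           "ER (negative)", "HER2 (positive, 3+)"),
                   fig3_sentence)
  expect_identical(extract_panel(base), extract_panel(spiked))
})

test_that("the same logical panel parses identically from all three dialects", {
  sentence <- "Immunohistochemical study shows: ER (positive, 80%), PR (negative), HER2 (equivocal, 2+)."
  multirow <- "Immunohistochemical studies:\nER (positive, 80%)\nPR (negative)\nHER2 (equivocal, 2+)"
  comma <- "ER: positive, 80%, PR: negative, HER2: equivocal, 2+"
  panels <- lapply(c(sentence, multirow, comma), function(p)
    extract_panel(report("D1", "x", p)))
  strip <- function(panel) lapply(panel, function(rr) {
    rr$raw_span <- NULL; rr
  })
  expect_identical(strip(panels[[1]]), strip(panels[[2]]))
  expect_identical(strip(panels[[1]]), strip(panels[[3]]))
})

test_that("parsing is idempotent and order-deterministic", {
  p <- "ER (positive, 80%), PR: negative, HER2 (negative, 0)"
  expect_identical(parse_er(p), parse_er(p))
  rep1 <- report("R1", "x", p)
  expect_identical(extract_panel(rep1), extract_panel(rep1))
})

test_that("per-marker recall is 1 on supported dialects, 0 on unsupported", {
  supported <- gen_corpus(clean_spec(n_regional = 15L, n_distant = 10L,
                                     n_benign = 0L, seed = 5L))
  by_id <- stats::setNames(supported$reports,
    vapply(supported$reports, `[[`, character(1), "case_id"))
  for (i in seq_len(nrow(supported$truth))) {
    tr <- supported$truth[i, ]
    panel <- extract_panel(by_id[[tr$case_id]])
    expect_identical(unname(panel_cells_of(
      extraction_record(tr$case_id, er = panel$er, pr = panel$pr,
                        her2 = panel$her2))),
      unname(unlist(tr[c("er", "pr", "her2")])))
  }

  unsup <- gen_corpus(synth_spec(
    n_regional = 10L, n_distant = 5L, n_benign = 0L,
    dialect_mix = c(sentence = 0, multirow = 0, comma_block = 0,
                    unsupported = 1),
    confounder_counts = c(chest_wall_recurrence = 0L, sp_breast_sentinel = 0L,
                          treatment_note = 0L),
    seed = 6L))
  by_id <- stats::setNames(unsup$reports,
    vapply(unsup$reports, `[[`, character(1), "case_id"))
  for (i in seq_len(nrow(unsup$truth))) {
    panel <- extract_panel(by_id[[unsup$truth$case_id[i]]])
    expect_true(all(vapply(panel, `[[`, character(1), "status") == "not_found"))
  }
})
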