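met_line <- "Liver, biopsy --- carcinoma, metastatic, breast origin"

test_that("find_metastatic_line returns the first matching diagnosis line", {
  rep1 <- report("A1", met_line)
  hit <- find_metastatic_line(rep1, default_lex)
  expect_equal(hit$line_index, 1L)
  expect_equal(hit$phrase, "carcinoma, metastatic")

  expect_null(find_metastatic_line(
    report("A2", "Stomach, biopsy --- chronic gastritis"), default_lex))

  multi <- report("A3", c(
    "Gallbladder, cholecystectomy --- chronic cholecystitis",
    "Liver, biopsy --- carcinoma, metastatic, breast origin",
    "Skin, excision --- nevus",
    "Lung, biopsy --- carcinoma, involved, breast origin"))
  # oracle: scan every line independently, assert the minimum index returned
  matches <- which(vapply(multi$diagnosis_lines, function(l)
    match_any(default_lex$metastatic_phrases, l)$matched, logical(1)))
  expect_equal(find_metastatic_line(multi, default_lex)$line_index,
               min(matches))
  expect_equal(find_metastatic_line(multi, default_lex)$line_index, 2L)
})

test_that("confirm_breast_origin checks the same line only", {
  expect_true(confirm_breast_origin(met_line, default_lex))
  expect_true(confirm_breast_origin(
    "Lung, biopsy --- carcinoma, involved, breast primary", default_lex))
  expect_false(confirm_breast_origin(
    "Stomach, biopsy --- carcinoma, metastatic, colonic primary", default_lex))
})

test_that("excluded_by_primary scans the whole diagnosis column, nothing else", {
  both <- report("B1", c(
    met_line,
    "Breast, left, modified radical mastectomy --- invasive ductal carcinoma"))
  expect_true(excluded_by_primary(both, default_lex))
  expect_false(excluded_by_primary(report("B2", met_line), default_lex))
  # a primary phrase in the description column never excludes
  desc_only <- report("B3", met_line,
                      "Status post mastectomy for invasive ductal carcinoma.")
  expect_false(excluded_by_primary(desc_only, default_lex))
})

test_that("parse_site classifies regional and distant sites", {
  expect_equal(parse_site(
    "Lymph node, axillary, excision --- carcinoma, metastatic, breast origin",
    default_lex),
    list(site_text = "axillary lymph node", site_class = "regional"))
  expect_equal(parse_site(
    "Soft tissue, axillary, excision --- carcinoma, involved, breast primary",
    default_lex),
    list(site_text = "axillary soft tissue", site_class = "regional"))
  expect_equal(parse_site(
    "Brain, tumor, excision --- carcinoma, metastatic, breast origin",
    default_lex),
    list(site_text = "brain", site_class = "distant"))
  # non-axillary node stations are the nonregional lymph node category
  expect_equal(parse_site(
    "Lymph node, supraclavicular, biopsy --- carcinoma, metastatic, breast origin",
    default_lex),
    list(site_text = "nonregional lymph node", site_class = "distant"))
  # organs mapped to a broader canonical label
  expect_equal(parse_site(
    "Stomach, biopsy --- carcinoma, metastatic, breast origin",
    default_lex)$site_text, "GI tract")
  expect_error(parse_site("   ", default_lex), class = "ihcmine_parse_error")
})

test_that("unknown organs fall back to distant with the raw token, logged", {
  withr::with_options(list(ihcmine.verbose = TRUE), {
    expect_message(
      site <- parse_site(
        "Adrenal, biopsy --- carcinoma, metastatic, breast origin",
        default_lex),
      "not in vocabulary")
  })
  expect_equal(site, list(site_text = "adrenal", site_class = "distant"))
})

test_that("find_cases recovers the composition of a clean synthetic corpus", {
  corpus <- gen_corpus(clean_spec(n_regional = 10L, n_distant = 5L,
                                  n_benign = 5L, seed = 3L))
  calls <- find_cases(corpus$reports, default_lex)
  df <- calls_to_df(calls)
  expect_equal(nrow(df), 20L)
  expect_equal(sum(df$site_class == "regional", na.rm = TRUE), 10L)
  expect_equal(sum(df$site_class == "distant", na.rm = TRUE), 5L)
  expect_equal(sum(is.na(df$site_class)), 5L)
  # call/truth agreement case by case
  m <- merge(df, corpus$truth, by = "case_id")
  flagged <- m$is_metastatic_breast & !m$excluded_as_primary
  expect_identical(flagged, m$true_metastatic)
  expect_identical(m$site_class[flagged], m$true_site_class[flagged])
  expect_identical(find_cases(list(), default_lex), list())
})

test_that("exclusion takes precedence over metastatic evidence", {
  both <- report("C1", c(
    met_line,
    "Breast, right, mastectomy --- invasive ductal carcinoma"))
  call <- find_cases(list(both), default_lex)[[1]]
  expect_false(call$is_metastatic_breast)
  expect_true(call$excluded_as_primary)
  expect_true(is.na(call$site_class))
})

test_that("steps short-circuit in order and leave an evidence trail", {
  # fails step 1: no evidence beyond step 1 recorded
  neg <- find_cases(list(report("D1", "Stomach, biopsy --- gastritis")),
                    default_lex)[[1]]
  expect_length(neg$evidence, 0L)
  # passes step 1, fails step 2: only step-1 evidence
  s1 <- find_cases(list(report(
    "D2", "Colon, biopsy --- carcinoma, metastatic, colonic primary")),
    default_lex)[[1]]
  steps <- vapply(s1$evidence, `[[`, integer(1), "step")
  expect_identical(steps, 1L)
  expect_false(s1$is_metastatic_breast)
  # full positive: steps 1, 2, 4 present and ordered; 3 absent (no exclusion)
  pos <- find_cases(list(report("D3", met_line)), default_lex)[[1]]
  steps <- vapply(pos$evidence, `[[`, integer(1), "step")
  expect_identical(steps, c(1L, 2L, 4L))
  # excluded: trail stops at step 3
  exc <- find_cases(list(report("D4", c(met_line, "Breast, left, mastectomy"))),
                    default_lex)[[1]]
  steps <- vapply(exc$evidence, `[[`, integer(1), "step")
  expect_identical(steps[length(steps)], 3L)
  expect_false(4L %in% steps)
})

test_that("the first line passing steps 1-2 determines the site", {
  rep2 <- report("E1", c(
    "Colon, biopsy --- carcinoma, metastatic, colonic primary",
    "Brain, excision --- carcinoma, metastatic, breast origin",
    "Liver, biopsy --- carcinoma, involved, breast origin"))
  call <- find_cases(list(rep2), default_lex)[[1]]
  expect_equal(call$site_text, "brain")
  # all step-1 matches are retained as evidence
  s1_lines <- vapply(Filter(function(e) e$step == 1L, call$evidence),
                     `[[`, integer(1), "line_index")
  expect_identical(s1_lines, c(1L, 2L, 3L))
})

test_that("positive calls have exactly one site class and counts add up", {
  corpus <- gen_corpus(synth_spec(n_regional = 15L, n_distant = 10L,
                                  n_benign = 5L, seed = 8L))
  df <- calls_to_df(find_cases(corpus$reports, default_lex))
  pos <- df[df$is_metastatic_breast & !df$excluded_as_primary, ]
  expect_true(all(pos$site_class %in% c("regional", "distant")))
  expect_equal(sum(pos$site_class == "regional") +
                 sum(pos$site_class == "distant"), nrow(pos))
})
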