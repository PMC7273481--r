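# Shared fixtures: built in code at test time, nothing stored on disk.

default_lex <- load_lexicon()

# a clean synthetic spec: supported dialects only, no confounders
clean_spec <- function(n_regional = 20L, n_distant = 10L, n_benign = 10L,
                       seed = 42L, unsupported = 0) {
  stopifnot(unsupported < 1)
  rest <- 1 - unsupported
  synth_spec(
    n_regional = n_regional, n_distant = n_distant, n_benign = n_benign,
    dialect_mix = c(sentence = 0.5 * rest, multirow = 0.3 * rest,
                    comma_block = 0.2 * rest, unsupported = unsupported),
    confounder_counts = c(chest_wall_recurrence = 0L, sp_breast_sentinel = 0L,
                          treatment_note = 0L),
    seed = seed)
}

# extraction records realizing the published per-class receptor marginals
# (tested-case counts of the summary tables: distant n = 64, regional n = 322)
published_marginal_records <- function() {
  statuses <- function(counts) {
    # counts: named vector over status levels incl. not_tested
    unlist(mapply(rep, names(counts), counts, SIMPLIFY = FALSE),
           use.names = FALSE)
  }
  build <- function(class, site, n, er, pr, her2) {
    er <- statuses(er); pr <- statuses(pr); her2 <- statuses(her2)
    lapply(seq_len(n), function(i) {
      mk <- function(marker, status) {
        if (status == "not_tested") return(NULL)
        if (marker == "HER2") {
          receptor_result("HER2", status, score = switch(status,
            positive = "3+", equivocal = "2+", negative = "1+"))
        } else {
          receptor_result(marker, status,
                          percent = if (status == "positive") 50L else NA_integer_)
        }
      }
      extraction_record(sprintf("%s-%04d", toupper(substr(class, 1, 3)), i),
                        site, class,
                        er = mk("ER", er[i]), pr = mk("PR", pr[i]),
                        her2 = mk("HER2", her2[i]))
    })
  }
  c(build("distant", "bone", 64L,
          c(positive = 36, negative = 28, not_tested = 0),
          c(positive = 12, negative = 40, not_tested = 12),
          c(positive = 23, equivocal = 11, negative = 24, not_tested = 6)),
    build("regional", "axillary lymph node", 322L,
          c(positive = 198, negative = 110, not_tested = 14),
          c(positive = 52, negative = 29, not_tested = 241),
          c(positive = 103, equivocal = 95, negative = 112, not_tested = 12)))
}

# run the find -> extract stages in memory for a generated corpus
run_find_extract <- function(reports, lexicon = default_lex) {
  calls <- find_cases(reports, lexicon)
  by_id <- stats::setNames(reports,
                           vapply(reports, `[[`, character(1), "case_id"))
  positive <- Filter(function(x) x$is_metastatic_breast &&
                       !x$excluded_as_primary, calls)
  records <- lapply(positive, function(call) {
    panel <- extract_panel(by_id[[call$case_id]])
    extraction_record(call$case_id, call$site_text, call$site_class,
                      er = panel$er, pr = panel$pr, her2 = panel$her2)
  })
  list(calls = calls, records = records)
}

panel_cells_of <- function(rec) {
  cell <- function(rr) if (is.null(rr) || identical(rr$status, "not_found"))
    "None" else format_receptor(rr)
  c(er = cell(rec$er), pr = cell(rec$pr), her2 = cell(rec$her2))
}
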