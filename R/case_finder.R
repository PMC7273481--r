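# Metastatic breast cancer case finding: a four-step, line-wise protocol over
# the diagnosis column.
#
#   step 1  find a diagnosis line matching a metastatic-carcinoma phrase
#   step 2  the SAME line must carry a breast-origin phrase
#   step 3  exclusion: any diagnosis line showing primary breast cancer
#           disqualifies the whole report (exclusion beats positive evidence)
#   step 4  parse the metastatic site from the matched line and classify it
#           as regional (axillary) or distant (organ vocabulary)
#
# Steps short-circuit: a report failing step k never reaches step k+1.

#' Find the first metastatic-carcinoma diagnosis line
#'
#' Step 1 of the finding protocol: each diagnosis line is matched against the
#' lexicon's metastatic phrases; the first matching line wins.
#'
#' @param rep an `ihc_report`.
#' @param lexicon an `ihc_lexicon`.
#' @return `NULL` when no line matches; otherwise a list with `line_index`
#'   (1-based), `line`, and `phrase`.
#' @export
find_metastatic_line <- function(rep, lexicon) {
  for (i in seq_along(rep$diagnosis_lines)) {
    m <- match_any(lexicon$metastatic_phrases, rep$diagnosis_lines[i])
    if (m$matched) {
      return(list(line_index = i, line = rep$diagnosis_lines[i],
                  phrase = m$phrase))
    }
  }
  NULL
}

#' Check a matched line for breast origin
#'
#' Step 2: true iff the same diagnosis line that indicated metastatic
#' carcinoma also carries a breast-origin phrase.
#'
#' @param matched_line the line returned by [find_metastatic_line()].
#' @param lexicon an `ihc_lexicon`.
#' @return logical scalar.
#' @export
confirm_breast_origin <- function(matched_line, lexicon) {
  match_any(lexicon$breast_origin_phrases, matched_line)$matched
}

#' Check the whole diagnosis column for primary breast cancer
#'
#' Step 3: a report whose diagnosis column shows any sign of primary breast
#' cancer is excluded from further analysis, regardless of its metastatic
#' evidence. Only the diagnosis column is scanned; the description column
#' never triggers exclusion.
#'
#' @inheritParams find_metastatic_line
#' @return logical scalar (`TRUE` = excluded).
#' @export
excluded_by_primary <- function(rep, lexicon) {
  for (line in rep$diagnosis_lines) {
    if (match_any(lexicon$primary_breast_phrases, line)$matched) return(TRUE)
  }
  FALSE
}

#' Parse the metastatic site from a confirmed diagnosis line
#'
#' Step 4. Axillary phrases ("soft tissue, axillary", "lymph node, axillary")
#' classify the site as regional. Otherwise the leading specimen token (the
#' text before the first comma) is looked up in the organ vocabulary and the
#' site is distant with the canonical label; a non-axillary "lymph node"
#' specimen maps to "nonregional lymph node". An organ missing from the
#' vocabulary is still distant, with the raw token kept and a warning logged.
#'
#' @param matched_line a diagnosis line confirmed in steps 1-2.
#' @param lexicon an `ihc_lexicon`.
#' @return list with `site_text` (canonical label) and `site_class`
#'   (`"regional"` or `"distant"`).
#' @export
parse_site <- function(matched_line, lexicon) {
  if (!is_string(matched_line) || !nzchar(trimws(matched_line))) {
    ihc_stop("cannot parse site from an empty line", "ihcmine_parse_error")
  }
  reg <- match_any(lexicon$regional_site_phrases, matched_line)
  if (reg$matched) {
    canon <- c("lymph node, axillary" = "axillary lymph node",
               "soft tissue, axillary" = "axillary soft tissue")
    label <- canon[tolower(gsub("\\s+", " ", reg$phrase))]
    if (is.na(label)) label <- tolower(reg$phrase)  # user-configured phrase
    return(list(site_text = unname(label), site_class = "regional"))
  }
  token <- tolower(trimws(strsplit(matched_line, ",", fixed = TRUE)[[1]][1]))
  token <- gsub("\\s+", " ", token)
  label <- lexicon$organ_vocabulary[token]
  if (is.na(label)) {
    ihc_log("warn", sprintf("organ '%s' not in vocabulary; kept raw", token))
    label <- token
  }
  list(site_text = unname(label), site_class = "distant")
}

new_call <- function(case_id, is_met = FALSE, excluded = FALSE,
                     site_text = NA_character_, site_class = NA_character_,
                     evidence = list(), note = NA_character_) {
  structure(list(case_id = case_id, is_metastatic_breast = is_met,
                 excluded_as_primary = excluded, site_text = site_text,
                 site_class = site_class, evidence = evidence, note = note),
            class = "metastasis_call")
}

#' @export
print.metastasis_call <- function(x, ...) {
  verdict <- if (x$excluded_as_primary) "excluded (primary breast cancer)"
    else if (x$is_metastatic_breast)
      sprintf("metastatic breast, %s (%s)", x$site_class, x$site_text)
    else "negative"
  cat("<metastasis_call>", x$case_id, "-", verdict, "\n")
  invisible(x)
}

# run the 4-step protocol on one report
classify_report <- function(rep, lexicon) {
  evidence <- list()
  # step 1/2 combined per design: the first step-1 line that also passes
  # step 2 determines the site; other step-1 matches are kept as evidence
  chosen <- NULL
  for (i in seq_along(rep$diagnosis_lines)) {
    line <- rep$diagnosis_lines[i]
    m1 <- match_any(lexicon$metastatic_phrases, line)
    if (!m1$matched) next
    evidence[[length(evidence) + 1L]] <-
      list(step = 1L, phrase = m1$phrase, line_index = i)
    if (is.null(chosen)) {
      m2 <- match_any(lexicon$breast_origin_phrases, line)
      if (m2$matched) {
        evidence[[length(evidence) + 1L]] <-
          list(step = 2L, phrase = m2$phrase, line_index = i)
        chosen <- list(line = line, line_index = i)
      }
    }
  }
  if (is.null(chosen)) {
    ihc_log("info", "no metastatic-breast diagnosis line",
            case_id = rep$case_id)
    return(new_call(rep$case_id, evidence = evidence))
  }
  # step 3: exclusion scans the whole diagnosis column
  for (i in seq_along(rep$diagnosis_lines)) {
    m3 <- match_any(lexicon$primary_breast_phrases, rep$diagnosis_lines[i])
    if (m3$matched) {
      evidence[[length(evidence) + 1L]] <-
        list(step = 3L, phrase = m3$phrase, line_index = i)
      ihc_log("info", "excluded: primary breast cancer in diagnosis",
              case_id = rep$case_id)
      return(new_call(rep$case_id, excluded = TRUE, evidence = evidence))
    }
  }
  # step 4
  site <- parse_site(chosen$line, lexicon)
  evidence[[length(evidence) + 1L]] <-
    list(step = 4L, phrase = site$site_text, line_index = chosen$line_index)
  ihc_log("info", sprintf("flagged %s metastasis at %s",
                          site$site_class, site$site_text),
          case_id = rep$case_id)
  new_call(rep$case_id, is_met = TRUE, site_text = site$site_text,
           site_class = site$site_class, evidence = evidence)
}

#' Run the case-finding protocol over a corpus
#'
#' Applies the four-step protocol to every report. Per-report failures are
#' caught and returned as negative calls with a `note`, so one malformed
#' report never aborts a corpus run. Class counts are reported to the
#' structured log.
#'
#' @param corpus list of `ihc_report` objects.
#' @param lexicon an `ihc_lexicon`; defaults to [load_lexicon()].
#' @return list of `metastasis_call` objects, one per report, in corpus order.
#' @export
find_cases <- function(corpus, lexicon = load_lexicon()) {
  calls <- lapply(corpus, function(rep) {
    tryCatch(classify_report(rep, lexicon), error = function(e) {
      ihc_log("warn", sprintf("report failed: %s", conditionMessage(e)),
              case_id = rep$case_id)
      new_call(rep$case_id, note = conditionMessage(e))
    })
  })
  cls <- vapply(calls, function(x) x$site_class %||% NA_character_, character(1))
  ihc_log("info", sprintf(
    "corpus of %d reports: %d regional, %d distant, %d negative/excluded",
    length(calls), sum(cls == "regional", na.rm = TRUE),
    sum(cls == "distant", na.rm = TRUE), sum(is.na(cls))))
  calls
}

#' Tabulate metastasis calls
#'
#' @param calls list of `metastasis_call` objects.
#' @return data.frame with one row per call (case_id, flags, site, class).
#' @export
calls_to_df <- function(calls) {
  data.frame(
    case_id = vapply(calls, `[[`, character(1), "case_id"),
    is_metastatic_breast = vapply(calls, `[[`, logical(1), "is_metastatic_breast"),
    excluded_as_primary = vapply(calls, `[[`, logical(1), "excluded_as_primary"),
    site_text = vapply(calls, `[[`, character(1), "site_text"),
    site_class = vapply(calls, `[[`, character(1), "site_class"),
    stringsAsFactors = FALSE)
}
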