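# Immunohistochemistry extraction: locate result-bearing paragraphs in the
# description column, then parse ER / PR / HER2 results written in the 2013
# CAP reporting conventions.
#
# The reporting dialects handled (all case-insensitive, word-bounded so that
# e.g. "PERT" never matches "ER"):
#   ER/PR:  "ER (positive, 80%)"   "PR: positive, 30%"   "ER (negative)"
#   HER2:   "HER2 (positive, 3+)"  (spellings Her-2 / Her2 / HER2 / HER-2)
#           "Her-2: negative, score 1, weak staining in 10%"
# HER2 scores normalise to {0, 1+, 2+, 3+} ("score 2" -> "2+", "score 0" and
# bare "0" -> "0"). ER/PR percent tokens accept "80%", "80 %" and ranges
# "80-90%" (the lower bound is recorded and the range logged).

.status_rx <- "(positive|negative|equivocal)"
.pct_rx <- "([0-9]{1,3})(\\s*-\\s*[0-9]{1,3})?\\s*%"
.score_rx <- "(?:score\\s*([0-3])\\b|([0-3])\\s*\\+|(0)\\b)"

marker_token_rx <- function(marker) {
  switch(marker,
    ER = "\\bER\\b",
    PR = "\\bPR\\b",
    HER2 = "\\bHER[-\\s]?2\\b",
    ihc_stop(sprintf("unknown marker: %s", marker), "ihcmine_parse_error"))
}

#' Construct a receptor result
#'
#' @param marker `"ER"`, `"PR"` or `"HER2"`.
#' @param status `"positive"`, `"negative"`, `"equivocal"` (HER2 only) or
#'   `"not_found"`.
#' @param percent stained-cell percentage (ER/PR positivity, or the HER2
#'   staining percentage of the long colon dialect), or `NA`.
#' @param score HER2 score, one of `"0"`, `"1+"`, `"2+"`, `"3+"`, or `NA`.
#' @param intensity HER2 staining intensity (`"weak"`, `"moderate"`,
#'   `"strong"`), or `NA`.
#' @param raw_span the matched report text.
#' @return an object of class `receptor_result`.
#' @export
receptor_result <- function(marker, status = "not_found",
                            percent = NA_integer_, score = NA_character_,
                            intensity = NA_character_,
                            raw_span = NA_character_) {
  marker <- match.arg(marker, c("ER", "PR", "HER2"))
  status <- match.arg(status, c("positive", "negative", "equivocal", "not_found"))
  if (marker != "HER2") {
    if (identical(status, "equivocal")) {
      ihc_stop("equivocal status is only defined for HER2", "ihcmine_parse_error")
    }
    if (!is.na(score)) {
      ihc_stop("score is only defined for HER2", "ihcmine_parse_error")
    }
  }
  if (!is.na(percent) && (percent < 0L || percent > 100L)) {
    ihc_stop(sprintf("percent out of range: %s", percent), "ihcmine_parse_error")
  }
  structure(list(marker = marker, status = status,
                 percent = as.integer(percent), score = score,
                 intensity = intensity, raw_span = raw_span),
            class = "receptor_result")
}

#' @export
print.receptor_result <- function(x, ...) {
  cat(sprintf("<%s> %s", x$marker, format_receptor(x)), "\n")
  invisible(x)
}

her2_score_status <- c("0" = "negative", "1+" = "negative",
                       "2+" = "equivocal", "3+" = "positive")

normalize_score <- function(digit) {
  if (identical(digit, "0")) "0" else paste0(digit, "+")
}

# all parseable/unparseable marker mentions in one paragraph, in text order
parse_marker_mentions <- function(paragraph, marker) {
  token_rx <- marker_token_rx(marker)
  hits <- gregexpr(token_rx, paragraph, perl = TRUE, ignore.case = TRUE)[[1]]
  out <- list(results = list(), unparseable = 0L)
  if (hits[1] < 0L) return(out)

  if (marker == "HER2") {
    paren <- paste0("^", token_rx, "\\s*\\(\\s*", .status_rx, "\\s*,\\s*",
                    .score_rx, "\\s*\\)")
    colon <- paste0("^", token_rx, "\\s*:\\s*", .status_rx, "\\s*,\\s*",
                    .score_rx,
                    "(?:\\s*,\\s*(weak|moderate|strong)\\s+staining\\s+in\\s+",
                    "([0-9]{1,3})\\s*%)?")
  } else {
    paren <- paste0("^", token_rx, "\\s*\\(\\s*", .status_rx,
                    "(?:\\s*,\\s*([0-9]{1,3})(\\s*-\\s*[0-9]{1,3})?\\s*%?)?",
                    "\\s*\\)")
    colon <- paste0("^", token_rx, "\\s*:\\s*", .status_rx,
                    "(?:\\s*,\\s*", .pct_rx, ")?")
  }

  for (pos in as.integer(hits)) {
    tail_text <- substr(paragraph, pos, nchar(paragraph))
    m <- regexec(paren, tail_text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] < 0L) {
      m <- regexec(colon, tail_text, perl = TRUE, ignore.case = TRUE)[[1]]
    }
    if (m[1] < 0L) {
      out$unparseable <- out$unparseable + 1L
      next
    }
    groups <- substring(tail_text, m, m + attr(m, "match.length") - 1L)
    groups[attr(m, "match.length") < 0L | m < 0L] <- ""
    span <- groups[1]
    status <- tolower(groups[2])

    if (marker == "HER2") {
      digit <- groups[3:5][nzchar(groups[3:5])][1]
      score <- normalize_score(digit)
      intensity <- if (length(groups) >= 6 && nzchar(groups[6]))
        tolower(groups[6]) else NA_character_
      pct <- if (length(groups) >= 7 && nzchar(groups[7]))
        as.integer(groups[7]) else NA_integer_
      implied <- her2_score_status[[score]]
      if (!identical(implied, status)) {
        ihc_log("warn", sprintf(
          "HER2 status '%s' inconsistent with score %s (implies %s): %s",
          status, score, implied, span))
      }
      out$results[[length(out$results) + 1L]] <- receptor_result(
        "HER2", status, percent = pct, score = score, intensity = intensity,
        raw_span = span)
    } else {
      if (identical(status, "equivocal")) {
        # the 2013 ER/PR convention has no equivocal category
        ihc_log("warn", sprintf(
          "%s reported as equivocal; not a valid 2013 ER/PR category: %s",
          marker, span))
        out$unparseable <- out$unparseable + 1L
        next
      }
      pct <- if (nzchar(groups[3])) as.integer(groups[3]) else NA_integer_
      if (length(groups) >= 4 && nzchar(groups[4])) {
        ihc_log("warn", sprintf(
          "%s percent given as a range, recording lower bound: %s",
          marker, span))
      }
      out$results[[length(out$results) + 1L]] <- receptor_result(
        marker, status, percent = pct, raw_span = span)
    }
  }
  out
}

# shared single-paragraph, first-mention parse used by parse_er/parse_pr/parse_her2
parse_marker_first <- function(paragraph, marker) {
  stopifnot(is_string(paragraph))
  mentions <- parse_marker_mentions(paragraph, marker)
  if (length(mentions$results) == 0L) {
    if (mentions$unparseable > 0L) {
      ihc_log("warn", sprintf("%s token present but tail not parseable", marker))
    }
    return(receptor_result(marker, "not_found"))
  }
  mentions$results[[1L]]
}

#' Parse the first ER result in a paragraph
#'
#' @param paragraph paragraph text.
#' @return a `receptor_result` for ER (`status = "not_found"` when no ER
#'   mention parses).
#' @export
parse_er <- function(paragraph) parse_marker_first(paragraph, "ER")

#' Parse the first PR result in a paragraph
#' @inheritParams parse_er
#' @return a `receptor_result` for PR.
#' @export
parse_pr <- function(paragraph) parse_marker_first(paragraph, "PR")

#' Parse the first HER2 result in a paragraph
#'
#' Accepts the four spellings Her-2/Her2/HER2/HER-2 and both CAP dialects:
#' `HER2 (status, score)` and
#' `HER2: status, score[, intensity staining in N%]`. The score implies a
#' status (3+ positive, 2+ equivocal, 0/1+ negative); a mismatch between the
#' written status and the score is kept as written but logged.
#'
#' @inheritParams parse_er
#' @return a `receptor_result` for HER2.
#' @export
parse_her2 <- function(paragraph) parse_marker_first(paragraph, "HER2")

#' Locate immunohistochemistry-bearing paragraphs
#'
#' Scans only the description column (the diagnosis column never contributes
#' to extraction) and returns the paragraphs showing any of the dialect cues:
#' an announcing sentence containing "immunohistochem...", or a marker token
#' immediately followed by `(` or `:` (covers both the multi-row block and
#' the comma-separated block).
#'
#' @param rep an `ihc_report`.
#' @return character vector of qualifying paragraphs, in report order.
#' @export
locate_ihc_paragraphs <- function(rep) {
  paras <- rep$description_paragraphs
  if (length(paras) == 0L) return(character())
  cue <- grepl("immunohistochem", paras, ignore.case = TRUE) |
    grepl("\\b(ER|PR|HER[-\\s]?2)\\b\\s*[(:]", paras,
          perl = TRUE, ignore.case = TRUE)
  paras[cue]
}

#' Extract the full receptor panel from a report
#'
#' Runs the two-step engine: [locate_ihc_paragraphs()] then marker parsing
#' over the located paragraphs in order. The first parsed mention of each
#' marker wins, within and across paragraphs; if later mentions disagree on
#' status, the marker is demoted to `not_found` and the conflict logged.
#'
#' @param rep an `ihc_report`.
#' @return a list of class `receptor_panel` with elements `er`, `pr`, `her2`.
#' @export
extract_panel <- function(rep) {
  paras <- locate_ihc_paragraphs(rep)
  one <- function(marker) {
    parsed <- list()
    unparseable <- 0L
    for (p in paras) {
      mentions <- parse_marker_mentions(p, marker)
      parsed <- c(parsed, mentions$results)
      unparseable <- unparseable + mentions$unparseable
    }
    if (length(parsed) == 0L) {
      if (unparseable > 0L) {
        ihc_log("warn", sprintf("%s mention(s) present but none parseable",
                                marker), case_id = rep$case_id)
      }
      return(receptor_result(marker, "not_found"))
    }
    statuses <- unique(vapply(parsed, `[[`, character(1), "status"))
    if (length(statuses) > 1L) {
      ihc_log("warn", sprintf(
        "%s mentioned %d times with conflicting statuses (%s); demoted",
        marker, length(parsed), paste(statuses, collapse = "/")),
        case_id = rep$case_id)
      return(receptor_result(marker, "not_found"))
    }
    if (length(parsed) > 1L) {
      ihc_log("info", sprintf("%s mentioned %d times; first mention kept",
                              marker, length(parsed)), case_id = rep$case_id)
    }
    parsed[[1L]]
  }
  structure(list(er = one("ER"), pr = one("PR"), her2 = one("HER2")),
            class = "receptor_panel")
}

#' @export
print.receptor_panel <- function(x, ...) {
  cat("<receptor_panel>\n")
  for (m in c("er", "pr", "her2")) {
    cat(sprintf("  %-4s %s\n", toupper(m), format_receptor(x[[m]])))
  }
  invisible(x)
}

#' Serialize a receptor result to its CSV cell form
#'
#' Canonical cell forms: `"positive, 80%"` / `"negative"` for ER/PR;
#' `"equivocal, 2+"` or `"negative, 1+, weak staining in 10%"` for HER2;
#' `"None"` for a failed extraction. [parse_receptor_cell()] is the exact
#' inverse.
#'
#' @param rr a `receptor_result`.
#' @return a single string.
#' @export
format_receptor <- function(rr) {
  if (identical(rr$status, "not_found")) return("None")
  parts <- rr$status
  if (rr$marker == "HER2") {
    if (!is.na(rr$score)) parts <- c(parts, rr$score)
    if (!is.na(rr$intensity) && !is.na(rr$percent)) {
      parts <- c(parts, sprintf("%s staining in %d%%", rr$intensity, rr$percent))
    }
  } else if (!is.na(rr$percent)) {
    parts <- c(parts, sprintf("%d%%", rr$percent))
  }
  paste(parts, collapse = ", ")
}

#' Parse a results-CSV cell back into a receptor result
#'
#' @param cell cell text as written by [format_receptor()].
#' @param marker which marker the cell belongs to.
#' @return a `receptor_result`, or `NULL` for the `"None"` token.
#' @export
parse_receptor_cell <- function(cell, marker) {
  if (!is_string(cell) || identical(cell, "None") || !nzchar(cell)) return(NULL)
  if (marker == "HER2") {
    m <- regexec(paste0("^(positive|negative|equivocal), (0|[1-3]\\+)",
                        "(?:, (weak|moderate|strong) staining in ([0-9]{1,3})%)?$"),
                 cell)[[1]]
    if (m[1] < 0L) {
      ihc_stop(sprintf("unparseable HER2 cell: '%s'", cell), "ihcmine_parse_error")
    }
    g <- substring(cell, m, m + attr(m, "match.length") - 1L)
    g[m < 0L] <- ""
    receptor_result("HER2", g[2], score = g[3],
                    intensity = if (nzchar(g[4])) g[4] else NA_character_,
                    percent = if (nzchar(g[5])) as.integer(g[5]) else NA_integer_,
                    raw_span = cell)
  } else {
    m <- regexec("^(positive|negative)(?:, ([0-9]{1,3})%)?$", cell)[[1]]
    if (m[1] < 0L) {
      ihc_stop(sprintf("unparseable %s cell: '%s'", marker, cell),
               "ihcmine_parse_error")
    }
    g <- substring(cell, m, m + attr(m, "match.length") - 1L)
    g[m < 0L] <- ""
    receptor_result(marker, g[2],
                    percent = if (nzchar(g[3])) as.integer(g[3]) else NA_integer_,
                    raw_span = cell)
  }
}
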