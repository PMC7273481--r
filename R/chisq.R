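# Contingency tables of receptor status by metastatic site group, and the
# chi-squared machinery used to compare them.
#
# The statistics are written out explicitly (expected counts, Yates clamp)
# rather than delegated to chisq.test(), so the test suite can hold them
# against that independent reference implementation.

#' Construct and validate a contingency table
#'
#' @param counts non-negative integer matrix, at least 2x2.
#' @param row_labels,col_labels optional dimension labels.
#' @return a matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    ihc_stop("counts must be non-negative integers", "ihcmine_table_error")
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    ihc_stop("need at least 2 rows and 2 columns", "ihcmine_table_error")
  }
  rownames(counts) <- row_labels
  colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", "matrix"))
}

check_margins <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    deg <- c(if (any(rs == 0)) paste("row", which(rs == 0)),
             if (any(cs == 0)) paste("column", which(cs == 0)))
    ihc_stop(sprintf("degenerate margin(s): %s", paste(deg, collapse = ", ")),
             "ihcmine_table_error")
  }
}

chi2_result <- function(statistic, df, yates) {
  structure(list(statistic = statistic, df = df,
                 p_value = chi2_sf(statistic, df), yates_applied = yates),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$yates_applied) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Upper-tail chi-squared probability
#'
#' `P(X > x)` for a chi-squared variable with `df` degrees of freedom — the
#' regularized upper incomplete gamma function `Q(df/2, x/2)`. Equals
#' `erfc(sqrt(x/2))` at df = 1 and `exp(-x/2)` at df = 2.
#'
#' @param x non-negative statistic.
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability in \[0, 1\].
#' @export
chi2_sf <- function(x, df) {
  if (any(x < 0)) ihc_stop("statistic must be non-negative", "ihcmine_stat_error")
  if (any(df < 1)) ihc_stop("df must be >= 1", "ihcmine_stat_error")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Yates-corrected chi-squared test for a 2x2 table
#'
#' Statistic `sum((|O - E| - c)^2 / E)` with the clamped continuity
#' correction `c = min(0.5, |O - E|)`, so a perfectly homogeneous table
#' yields 0 rather than a negative deviation; df = 1.
#'
#' @param tab a 2x2 `contingency_table` (or plain matrix).
#' @return a `chi2_result` (statistic, df, p_value, yates_applied = TRUE).
#' @export
chi2_yates_2x2 <- function(tab) {
  tab <- contingency_table(tab)
  if (!all(dim(tab) == c(2L, 2L))) {
    ihc_stop("Yates correction applies to 2x2 tables only", "ihcmine_table_error")
  }
  check_margins(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected)
  correction <- pmin(0.5, dev)
  chi2_result(sum((dev - correction)^2 / expected), 1L, yates = TRUE)
}

#' Pearson chi-squared test for an r x c table
#'
#' Uncorrected statistic `sum((O - E)^2 / E)`, df = (r-1)(c-1). Used for
#' tables larger than 2x2, where no continuity correction applies.
#'
#' @param tab a `contingency_table` (or plain matrix).
#' @return a `chi2_result` with `yates_applied = FALSE`.
#' @export
chi2_pearson <- function(tab) {
  tab <- contingency_table(tab)
  check_margins(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  chi2_result(sum((tab - expected)^2 / expected), df, yates = FALSE)
}

status_levels <- function(marker) {
  if (marker == "HER2") c("positive", "equivocal", "negative")
  else c("positive", "negative")
}

# extraction records -> per-case data.frame of statuses and sites
records_to_status_df <- function(records) {
  do.call(rbind, lapply(records, function(rec) {
    st <- function(rr) if (is.null(rr)) "not_found" else rr$status
    data.frame(case_id = rec$case_id,
               site_text = rec$site_text %||% NA_character_,
               site_class = rec$site_class %||% NA_character_,
               ER = st(rec$er), PR = st(rec$pr), HER2 = st(rec$her2),
               stringsAsFactors = FALSE)
  }))
}

#' Build a receptor-by-site contingency table from extraction records
#'
#' Counts receptor status levels per site group. Cases with `not_found` for
#' the marker ("not tested") are excluded — the comparisons use tested cases
#' only. Grouping `"site_class"` gives columns distant/regional; grouping
#' `"major_sites"` restricts to distant cases at bone, liver and lung.
#'
#' @param records list of `extraction_record` objects.
#' @param marker `"ER"`, `"PR"` or `"HER2"`.
#' @param grouping `"site_class"` or `"major_sites"`.
#' @return a `contingency_table`.
#' @export
build_contingency <- function(records, marker = c("ER", "PR", "HER2"),
                              grouping = c("site_class", "major_sites")) {
  marker <- match.arg(marker)
  grouping <- match.arg(grouping)
  df <- records_to_status_df(records)
  if (is.null(df) || nrow(df) == 0L) {
    ihc_stop("no records to tabulate", "ihcmine_table_error")
  }
  df <- df[df[[marker]] != "not_found", , drop = FALSE]
  if (nrow(df) == 0L) {
    ihc_stop(sprintf("no tested cases for %s", marker), "ihcmine_table_error")
  }
  if (grouping == "site_class") {
    df <- df[!is.na(df$site_class), , drop = FALSE]
    groups <- factor(df$site_class, levels = c("distant", "regional"))
  } else {
    df <- df[!is.na(df$site_text) &
               df$site_text %in% c("bone", "liver", "lung"), , drop = FALSE]
    groups <- factor(df$site_text, levels = c("bone", "liver", "lung"))
  }
  if (nrow(df) == 0L) {
    ihc_stop(sprintf("empty selection for %s by %s", marker, grouping),
             "ihcmine_table_error")
  }
  lv <- status_levels(marker)
  counts <- table(factor(df[[marker]], levels = lv), groups)
  contingency_table(matrix(as.integer(counts), nrow = length(lv),
                           dimnames = list(lv, levels(groups))))
}

#' Compare receptor expression between site groups
#'
#' For each marker, tests the receptor-status by site-group table: 2x2
#' tables (ER, PR by site class) with the Yates-corrected test, larger
#' tables (HER2, and all major-site tables) with the plain Pearson test.
#' Raw p-values are reported; no multiple-testing correction is applied.
#'
#' @param records list of `extraction_record` objects.
#' @param groupings which groupings to run.
#' @param min_group_size groups smaller than this cause the marker/grouping
#'   combination to be skipped with a logged notice (default 1 = never skip
#'   non-empty groups).
#' @return object of class `site_group_comparison`: a `results` data.frame
#'   (marker, grouping, statistic, df, p_value, yates) and the underlying
#'   `tables`.
#' @export
compare_site_groups <- function(records,
                                groupings = c("site_class", "major_sites"),
                                min_group_size = 1L) {
  results <- list(); tables <- list()
  for (grouping in groupings) {
    for (marker in c("ER", "PR", "HER2")) {
      tab <- tryCatch(build_contingency(records, marker, grouping),
                      error = function(e) NULL)
      if (is.null(tab) || any(colSums(tab) < min_group_size) ||
          any(colSums(tab) == 0)) {
        ihc_log("info", sprintf("skipping %s by %s: group below minimum size",
                                marker, grouping))
        next
      }
      res <- tryCatch(
        if (all(dim(tab) == c(2L, 2L))) chi2_yates_2x2(tab)
        else chi2_pearson(tab),
        ihcmine_table_error = function(e) NULL)
      if (is.null(res)) {
        ihc_log("info", sprintf("skipping %s by %s: degenerate table",
                                marker, grouping))
        next
      }
      key <- paste(marker, grouping, sep = ".")
      tables[[key]] <- tab
      results[[key]] <- data.frame(
        marker = marker, grouping = grouping, statistic = res$statistic,
        df = res$df, p_value = res$p_value, yates = res$yates_applied,
        stringsAsFactors = FALSE)
    }
  }
  if (length(results) == 0L) {
    ihc_stop("no marker/grouping combination could be tested",
             "ihcmine_table_error")
  }
  structure(list(results = do.call(rbind, c(results, make.row.names = FALSE)),
                 tables = tables),
            class = "site_group_comparison")
}

#' @export
print.site_group_comparison <- function(x, ...) {
  cat("Receptor expression by site group (raw p-values, no multiplicity",
      "correction)\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}
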