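# Scoring against gold annotations.
#
# Metric vocabulary: the source workflow reports "specificity" for what is
# conventionally called precision / positive predictive value (correct
# flags / all flags), and "sensitivity" for detection recall. Those names are
# kept here for fidelity, but score_run() co-reports the conventional
# precision/recall/F1 (and a true negative rate when gold negatives exist) so
# the nonstandard usage never propagates silently.

metric_value <- function(fraction) {
  structure(list(fraction = fraction, percent = percent_1dp(100 * fraction)),
            class = "paper_metric")
}

#' @export
print.paper_metric <- function(x, ...) {
  cat(sprintf("%.1f%% (%.6f)\n", x$percent, x$fraction))
  invisible(x)
}

#' Labelling precision ("specificity" in the source convention)
#'
#' Fraction of tool-flagged cases that are truly positive: `correct/labeled`.
#'
#' @param labeled number of cases the tool flagged.
#' @param correct number of flagged cases that are truly positive.
#' @return a `paper_metric`: `fraction` plus `percent` (half-up, 1 decimal).
#' @export
label_precision <- function(labeled, correct) {
  if (labeled <= 0) ihc_stop("label_precision undefined for labeled = 0",
                             "ihcmine_metric_error")
  if (correct < 0 || correct > labeled) {
    ihc_stop("need 0 <= correct <= labeled", "ihcmine_metric_error")
  }
  metric_value(correct / labeled)
}

#' Result-detection sensitivity
#'
#' Fraction of true cases carrying a result in which the tool found one:
#' `detected/total_with_result`.
#'
#' @param total_with_result number of true cases carrying the attribute.
#' @param detected number of those in which the tool found a result.
#' @return a `paper_metric`.
#' @export
detection_sensitivity <- function(total_with_result, detected) {
  if (total_with_result <= 0) {
    ihc_stop("detection_sensitivity undefined for total = 0",
             "ihcmine_metric_error")
  }
  if (detected < 0 || detected > total_with_result) {
    ihc_stop("need 0 <= detected <= total_with_result", "ihcmine_metric_error")
  }
  metric_value(detected / total_with_result)
}

#' Extraction specificity
#'
#' Fraction of detected results that are correct: `correct/detected`.
#'
#' @param detected number of cases with a detected result.
#' @param correct number of those whose extracted result is right.
#' @return a `paper_metric`.
#' @export
extraction_specificity <- function(detected, correct) {
  if (detected <= 0) ihc_stop("extraction_specificity undefined for detected = 0",
                              "ihcmine_metric_error")
  if (correct < 0 || correct > detected) {
    ihc_stop("need 0 <= correct <= detected", "ihcmine_metric_error")
  }
  metric_value(correct / detected)
}

# serialized gold/record panels compare as their canonical cell strings
panel_cells <- function(rec) {
  cell <- function(rr) if (is.null(rr) || identical(rr$status, "not_found"))
    "None" else format_receptor(rr)
  c(er = cell(rec$er), pr = cell(rec$pr), her2 = cell(rec$her2))
}

#' Score a pipeline run against gold annotations
#'
#' Joins calls, extraction records and gold rows on `case_id` and aggregates:
#' per site class, the labelling counts of the detection table (labeled,
#' correct, precision) and the extraction counts (cases with a gold result,
#' detected, correct, sensitivity, specificity); plus conventional
#' case-finding precision/recall/F1 over the whole corpus and a true
#' negative rate when gold negatives exist. Flagged cases absent from gold
#' are listed as unassessable and excluded from all counts.
#'
#' @param calls list of `metastasis_call` objects.
#' @param records list of `extraction_record` objects for the positive calls.
#' @param gold gold annotation data.frame as read by [read_gold_csv()].
#' @return an object of class `ihc_evaluation`.
#' @export
score_run <- function(calls, records, gold) {
  stopifnot(is.data.frame(gold))
  calls_df <- calls_to_df(calls)
  pos <- calls_df[calls_df$is_metastatic_breast &
                    !calls_df$excluded_as_primary, , drop = FALSE]
  unassessable <- setdiff(pos$case_id, gold$case_id)
  if (length(unassessable) > 0L) {
    ihc_log("warn", sprintf("%d flagged case(s) absent from gold: %s",
                            length(unassessable),
                            paste(unassessable, collapse = ", ")))
    pos <- pos[!pos$case_id %in% unassessable, , drop = FALSE]
  }
  rec_by_id <- stats::setNames(records,
                               vapply(records, `[[`, character(1), "case_id"))
  gold_by_id <- split(gold, gold$case_id)

  per_class <- do.call(rbind, lapply(c("regional", "distant"), function(cls) {
    flagged <- pos[pos$site_class == cls, , drop = FALSE]
    g <- do.call(rbind, gold_by_id[flagged$case_id])
    correct_ids <- if (is.null(g)) character() else
      g$case_id[g$true_metastatic & g$true_site_class == cls]
    labeled <- nrow(flagged)
    correct <- length(correct_ids)

    gc <- do.call(rbind, gold_by_id[correct_ids])
    has_result <- if (is.null(gc)) logical() else
      (gc$er != "None" | gc$pr != "None" | gc$her2 != "None")
    with_result_ids <- correct_ids[has_result]
    detected <- 0L; extr_correct <- 0L
    for (id in with_result_ids) {
      rec <- rec_by_id[[id]]
      if (is.null(rec)) next
      cells <- panel_cells(rec)
      if (all(cells == "None")) next
      detected <- detected + 1L
      truth <- unlist(gold_by_id[[id]][c("er", "pr", "her2")])
      # extracted results must agree with gold wherever the tool reported one
      if (all(cells == "None" | cells == truth)) extr_correct <- extr_correct + 1L
    }
    data.frame(site_class = cls, labeled = labeled, correct = correct,
               label_precision_pct = if (labeled > 0)
                 label_precision(labeled, correct)$percent else NA_real_,
               total_with_result = length(with_result_ids),
               detected = detected,
               detection_sensitivity_pct = if (length(with_result_ids) > 0)
                 detection_sensitivity(length(with_result_ids), detected)$percent
                 else NA_real_,
               extraction_correct = extr_correct,
               extraction_specificity_pct = if (detected > 0)
                 extraction_specificity(detected, extr_correct)$percent
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))

  # conventional case-finding metrics over the assessable corpus
  gold_pos <- gold$case_id[gold$true_metastatic]
  gold_neg <- gold$case_id[!gold$true_metastatic]
  tp_ids <- pos$case_id[vapply(pos$case_id, function(id) {
    g <- gold_by_id[[id]]
    !is.null(g) && g$true_metastatic &&
      identical(g$true_site_class, pos$site_class[pos$case_id == id])
  }, logical(1))]
  tp <- length(tp_ids)
  fp <- nrow(pos) - tp
  fn <- length(setdiff(gold_pos, pos$case_id))
  tn <- length(setdiff(gold_neg, pos$case_id))
  precision <- if (nrow(pos) > 0) tp / nrow(pos) else NA_real_
  recall <- if (length(gold_pos) > 0) tp / length(gold_pos) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  tnr <- if (length(gold_neg) > 0) tn / length(gold_neg) else NA_real_

  structure(list(per_class = per_class,
                 overall = list(tp = tp, fp = fp, fn = fn, tn = tn,
                                precision = precision, recall = recall,
                                f1 = f1, true_negative_rate = tnr),
                 unassessable = unassessable),
            class = "ihc_evaluation")
}

#' @export
print.ihc_evaluation <- function(x, ...) {
  cat("Case finding and extraction vs gold\n")
  print(x$per_class, row.names = FALSE)
  o <- x$overall
  cat(sprintf(
    "overall: TP %d FP %d FN %d TN %d | precision %.3f recall %.3f F1 %.3f\n",
    o$tp, o$fp, o$fn, o$tn, o$precision, o$recall, o$f1))
  if (length(x$unassessable)) {
    cat("unassessable (not in gold):",
        paste(x$unassessable, collapse = ", "), "\n")
  }
  invisible(x)
}

gold_header <- c("case_id", "true_metastatic", "true_site_class",
                 "er", "pr", "her2", "confounder_type")

#' Write a gold annotation CSV
#'
#' Columns: `case_id, true_metastatic, true_site_class, er, pr, her2,
#' confounder_type`; receptor cells use the [format_receptor()] form, absent
#' results the token `"None"`.
#'
#' @param gold gold data.frame (as produced by [gen_corpus()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gold_csv <- function(gold, path) {
  utils::write.csv(gold[, gold_header], path, row.names = FALSE)
  invisible(path)
}

#' Read a gold annotation CSV
#' @param path CSV path written by [write_gold_csv()].
#' @return data.frame with the gold columns, logical `true_metastatic`.
#' @export
read_gold_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(gold_header %in% colnames(df))) {
    ihc_stop(sprintf("gold CSV missing column(s): %s",
                     paste(setdiff(gold_header, colnames(df)), collapse = ", ")),
             "ihcmine_parse_error")
  }
  df$true_metastatic <- df$true_metastatic %in% c("TRUE", "true", "1")
  df
}
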