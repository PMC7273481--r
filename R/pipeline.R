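# End-to-end orchestration: ingest -> find-cases -> extract -> record ->
# (evaluate) -> (stats), each stage's output re-loadable as the next stage's
# input. All artifacts are pure functions of (inputs, config), so identical
# runs produce byte-identical files; the manifest deliberately records no
# timestamps.

#' Run the full mining pipeline
#'
#' Stages, in order: parse the report export and build the corpus store;
#' run the case-finding protocol; extract receptor panels for the positive
#' calls; write the per-case results CSV; optionally score against a gold
#' CSV; optionally compare receptor expression between site groups. A stage
#' failure aborts with an error naming the stage.
#'
#' @param input path to a report export (or export text).
#' @param out_dir output directory, created if needed.
#' @param store_path corpus store location (default `corpus.sqlite` in
#'   `out_dir`).
#' @param lexicon_config optional lexicon JSON config path.
#' @param gold optional gold CSV path; enables the evaluation stage.
#' @param run_stats whether to run the chi-squared comparisons.
#' @return (invisibly) a list with the calls, records, evaluation and stats
#'   objects plus an `artifacts` vector of file paths written.
#' @export
run_pipeline <- function(input, out_dir, store_path = NULL,
                         lexicon_config = NULL, gold = NULL,
                         run_stats = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ihc_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "ihcmine_stage_error")
    })
  }
  if (is_string(input) && !grepl("\n", input) && !file.exists(input)) {
    ihc_stop(sprintf("input not found: %s", input), "ihcmine_stage_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  store_path <- store_path %||% file.path(out_dir, "corpus.sqlite")
  artifacts <- character()

  lexicon <- stage("lexicon", load_lexicon(lexicon_config))
  corpus <- stage("ingest", {
    reports <- parse_export(input)
    build_store(reports, store_path)
    iter_store(store_path)
  })
  artifacts["store"] <- store_path

  calls <- stage("find-cases", find_cases(corpus, lexicon))
  calls_path <- file.path(out_dir, "calls.csv")
  utils::write.csv(calls_to_df(calls), calls_path, row.names = FALSE)
  artifacts["calls"] <- calls_path

  records <- stage("extract", {
    by_id <- stats::setNames(corpus, vapply(corpus, `[[`, character(1),
                                            "case_id"))
    positive <- Filter(function(x) x$is_metastatic_breast &&
                         !x$excluded_as_primary, calls)
    lapply(positive, function(call) {
      panel <- extract_panel(by_id[[call$case_id]])
      extraction_record(call$case_id, call$site_text, call$site_class,
                        er = panel$er, pr = panel$pr, her2 = panel$her2)
    })
  })
  results_path <- file.path(out_dir, "results.csv")
  stage("record", write_results_csv(records, results_path))
  artifacts["results"] <- results_path

  evaluation <- NULL
  if (!is.null(gold)) {
    evaluation <- stage("evaluate", score_run(calls, records,
                                              read_gold_csv(gold)))
    eval_path <- file.path(out_dir, "evaluation.csv")
    utils::write.csv(evaluation$per_class, eval_path, row.names = FALSE)
    artifacts["evaluation"] <- eval_path
  }

  stats_res <- NULL
  if (isTRUE(run_stats) && length(records) > 0L) {
    stats_res <- tryCatch(stage("stats", compare_site_groups(records)),
                          error = function(e) {
                            ihc_log("warn", conditionMessage(e)); NULL
                          })
    if (!is.null(stats_res)) {
      stats_path <- file.path(out_dir, "stats.csv")
      utils::write.csv(stats_res$results, stats_path, row.names = FALSE)
      artifacts["stats"] <- stats_path
    }
  }

  manifest <- list(
    package = "ihcmine",
    version = as.character(utils::packageVersion("ihcmine")),
    # basename only: the manifest must be byte-identical across runs of the
    # same corpus regardless of where the export file happens to live
    input = if (grepl("\n", input)) "<inline text>" else basename(input),
    lexicon_config = lexicon_config %||% "<defaults>",
    n_reports = length(corpus),
    n_positive = length(records),
    n_regional = sum(vapply(records, function(r)
      identical(r$site_class, "regional"), logical(1))),
    n_distant = sum(vapply(records, function(r)
      identical(r$site_class, "distant"), logical(1))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  artifacts["manifest"] <- manifest_path

  invisible(list(calls = calls, records = records, evaluation = evaluation,
                 stats = stats_res, artifacts = artifacts))
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  cat(
"ihcmine <command> [options]

commands:
  synth       generate a synthetic corpus      --out DIR [--seed N] [--n-regional N]
                                               [--n-distant N] [--n-benign N]
  run         full pipeline                    --input FILE --out DIR
                                               [--lexicon FILE] [--gold FILE]
  ingest      parse an export, build the store --input FILE --store FILE
  find-cases  case finding only                --input FILE --out DIR [--lexicon FILE]
  extract     find cases + extract panels      --input FILE --out DIR [--lexicon FILE]
  evaluate    full pipeline + scoring          --input FILE --gold FILE --out DIR
  stats       chi-squared tests on a results CSV  --results FILE --out DIR
  demo        reproduce the published receptor-by-site tests from the
              packaged count tables
")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- gsub("-", "_", sub("^--", "", a))
      if (i == length(args) || grepl("^--", args[i + 1L])) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Invoke from a shell as
#' `Rscript -e 'ihcmine::ihcmine_main()' <command> --input ... --out ...`
#' or call directly with an argument vector.
#'
#' @param args character vector of command-line arguments; defaults to the
#'   process arguments.
#' @return exit status, invisibly (0 on success).
#' @export
ihcmine_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { cli_usage(); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  if (!is.null(opts$log_level) && identical(opts$log_level, "verbose")) {
    old <- options(ihcmine.verbose = TRUE); on.exit(options(old), add = TRUE)
  }
  need <- function(key) {
    if (is.null(opts[[key]])) {
      ihc_stop(sprintf("'%s' requires --%s", cmd, gsub("_", "-", key)),
               "ihcmine_cli_error")
    }
    opts[[key]]
  }
  status <- 0L
  switch(cmd,
    synth = {
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      spec <- synth_spec(
        n_regional = as.integer(opts$n_regional %||% 329L),
        n_distant = as.integer(opts$n_distant %||% 83L),
        n_benign = as.integer(opts$n_benign %||% 100L),
        seed = as.integer(opts$seed %||% 1L))
      corpus <- gen_corpus(spec)
      serialize_export(corpus$reports, file.path(out, "corpus.txt"))
      write_gold_csv(corpus$truth, file.path(out, "gold.csv"))
      cat(sprintf("wrote %d reports to %s\n", length(corpus$reports), out))
    },
    run = ,
    evaluate = {
      res <- run_pipeline(need("input"), need("out"),
                          lexicon_config = opts$lexicon,
                          gold = if (cmd == "evaluate") need("gold") else opts$gold)
      if (!is.null(res$evaluation)) print(res$evaluation)
      if (!is.null(res$stats)) print(res$stats)
      cat("artifacts:", paste(res$artifacts, collapse = " "), "\n")
    },
    ingest = {
      reports <- parse_export(need("input"))
      build_store(reports, need("store"))
      cat(sprintf("stored %d reports in %s\n", length(reports), opts$store))
    },
    `find-cases` = {
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      calls <- find_cases(parse_export(need("input")),
                          load_lexicon(opts$lexicon))
      utils::write.csv(calls_to_df(calls), file.path(out, "calls.csv"),
                       row.names = FALSE)
      cat(sprintf("wrote %s\n", file.path(out, "calls.csv")))
    },
    extract = {
      res <- run_pipeline(need("input"), need("out"),
                          lexicon_config = opts$lexicon, run_stats = FALSE)
      cat(sprintf("wrote %s\n", res$artifacts[["results"]]))
    },
    stats = {
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      records <- read_results_csv(need("results"))
      comparison <- compare_site_groups(records)
      utils::write.csv(comparison$results, file.path(out, "stats.csv"),
                       row.names = FALSE)
      print(comparison)
    },
    demo = { demo_published_tables() },
    { cli_usage(); status <- 1L })
  invisible(status)
}

#' Re-run the published receptor-by-site chi-squared tests
#'
#' Loads the packaged receptor-by-site count tables (the published 2x2 and
#' 3x2 contingency tables of receptor status by metastatic site group) and
#' runs the package's chi-squared routines on them, printing statistic, df
#' and p-value per table.
#'
#' @return data.frame of results, invisibly.
#' @export
demo_published_tables <- function() {
  path <- system.file("extdata", "receptor_site_tables.csv",
                      package = "ihcmine")
  tabs <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (nm in unique(tabs$table)) {
    sub <- tabs[tabs$table == nm, , drop = FALSE]
    statuses <- unique(sub$status)
    groups <- unique(sub$group)
    m <- matrix(0L, length(statuses), length(groups),
                dimnames = list(statuses, groups))
    m[cbind(sub$status, sub$group)] <- sub$count
    res <- if (all(dim(m) == c(2L, 2L))) chi2_yates_2x2(m) else chi2_pearson(m)
    cat(sprintf("%-28s chi2 = %8.4f  df = %d  p = %.4g%s\n", nm,
                res$statistic, res$df, res$p_value,
                if (res$yates_applied) "  (Yates)" else ""))
    out[[nm]] <- data.frame(table = nm, statistic = res$statistic,
                            df = res$df, p_value = res$p_value,
                            yates = res$yates_applied)
  }
  invisible(do.call(rbind, c(out, make.row.names = FALSE)))
}
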