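# Corpus I/O: the plain-text report export dialect, the SQLite-backed corpus
# store, and the results CSV.
#
# Export dialect (the hospital's own export format is proprietary, so the
# package defines an unambiguous, diff-friendly one):
#
#   ==========
#   CASE: S2016-00001
#   DIAGNOSIS:
#   Liver, biopsy --- carcinoma, metastatic, breast origin
#   DESCRIPTION:
#   Received in formalin is a core of tan tissue.
#
#   Immunohistochemical study shows: ER (positive, 80%), PR (negative).
#
# Records are delimited by a line of four or more '=' characters; the three
# fields are introduced by "CASE:", "DIAGNOSIS:" and "DESCRIPTION:" header
# lines. The diagnosis column is line-wise; the description column is split
# into paragraphs on blank lines.

#' Construct a pathology report
#'
#' @param case_id non-empty identifier, unique within a corpus.
#' @param diagnosis_lines character vector, one element per diagnosis line
#'   (no embedded line breaks).
#' @param description_paragraphs character vector of description paragraphs;
#'   a paragraph may contain internal single line breaks but no blank lines.
#' @return an object of class `ihc_report`.
#' @export
report <- function(case_id, diagnosis_lines = character(),
                   description_paragraphs = character()) {
  if (!is_string(case_id) || !nzchar(case_id)) {
    ihc_stop("case_id must be a non-empty string", "ihcmine_parse_error")
  }
  diagnosis_lines <- as.character(diagnosis_lines)
  description_paragraphs <- as.character(description_paragraphs)
  if (any(grepl("\n", diagnosis_lines, fixed = TRUE))) {
    ihc_stop(sprintf("diagnosis lines of %s contain embedded line breaks",
                     case_id), "ihcmine_parse_error")
  }
  if (any(grepl("\n\\s*\n", description_paragraphs))) {
    ihc_stop(sprintf("description paragraph of %s contains a blank line",
                     case_id), "ihcmine_parse_error")
  }
  structure(list(case_id = case_id,
                 diagnosis_lines = diagnosis_lines,
                 description_paragraphs = description_paragraphs),
            class = "ihc_report")
}

#' @export
print.ihc_report <- function(x, ...) {
  cat("<ihc_report>", x$case_id, "\n")
  cat("  diagnosis lines:", length(x$diagnosis_lines),
      "| description paragraphs:", length(x$description_paragraphs), "\n")
  invisible(x)
}

# normalize raw export text: UTF-8 with replacement, LF endings, no trailing
# whitespace on any line
normalize_export_text <- function(text) {
  text <- iconv(text, from = "UTF-8", to = "UTF-8", sub = "�")
  text <- gsub("\r\n?", "\n", text)
  text <- gsub("[ \t]+\n", "\n", text)
  sub("[ \t]+$", "", text)
}

split_paragraphs <- function(block_text) {
  if (!nzchar(trimws(block_text))) return(character())
  paras <- strsplit(block_text, "\n[ \t]*\n+", perl = TRUE)[[1]]
  paras <- vapply(paras, function(p) {
    trimws(paste(trimws(strsplit(p, "\n", fixed = TRUE)[[1]]), collapse = "\n"))
  }, character(1), USE.NAMES = FALSE)
  paras[nzchar(paras)]
}

#' Parse a plain-text report export
#'
#' Reads an export in the package's record dialect (see the package README)
#' and returns one [report()] per record. Line endings are normalised to LF,
#' trailing whitespace stripped, and the text decoded as UTF-8 with
#' replacement before parsing, so downstream phrase matching is
#' deterministic.
#'
#' @param path_or_text path to an export file, or a single string containing
#'   the export text itself (anything with a newline is treated as text).
#' @return list of `ihc_report` objects, in file order.
#' @export
parse_export <- function(path_or_text) {
  if (is_string(path_or_text) && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    text <- paste(readLines(path_or_text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  } else {
    text <- paste(as.character(path_or_text), collapse = "\n")
  }
  text <- normalize_export_text(text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())

  delim <- grepl("^====+$", trimws(lines))
  rec_id <- cumsum(delim)
  reports <- list()
  ids_seen <- character()
  rec_index <- 0L
  for (g in split(lines[!delim], rec_id[!delim])) {
    if (all(!nzchar(trimws(g)))) next
    rec_index <- rec_index + 1L
    case_line <- grep("^CASE:", g)
    diag_line <- grep("^DIAGNOSIS:\\s*$", g)
    desc_line <- grep("^DESCRIPTION:\\s*$", g)
    if (length(case_line) != 1L) {
      ihc_stop(sprintf("record %d: missing or repeated CASE: header", rec_index),
               "ihcmine_parse_error")
    }
    if (length(diag_line) == 0L && length(desc_line) == 0L) {
      ihc_stop(sprintf("record %d: neither DIAGNOSIS: nor DESCRIPTION: present",
                       rec_index), "ihcmine_parse_error")
    }
    case_id <- trimws(sub("^CASE:", "", g[case_line]))
    if (!nzchar(case_id)) {
      ihc_stop(sprintf("record %d: empty case id", rec_index),
               "ihcmine_parse_error")
    }
    if (case_id %in% ids_seen) {
      ihc_stop(sprintf("duplicate case_id in export: %s", case_id),
               "ihcmine_duplicate_error")
    }
    ids_seen <- c(ids_seen, case_id)

    section_starts <- sort(c(diag_line, desc_line, length(g) + 1L))
    take <- function(start_line) {
      if (length(start_line) == 0L) return(character())
      end <- min(section_starts[section_starts > start_line]) - 1L
      if (end < start_line + 1L) character() else g[(start_line + 1L):end]
    }
    diag <- take(diag_line)
    diag <- trimws(diag[nzchar(trimws(diag))])
    desc <- split_paragraphs(paste(take(desc_line), collapse = "\n"))
    reports[[length(reports) + 1L]] <- report(case_id, diag, desc)
  }
  reports
}

#' Serialize reports to the export dialect
#'
#' Inverse of [parse_export()]: `parse_export(serialize_export(x))` is the
#' identity on well-formed corpora.
#'
#' @param reports list of `ihc_report` objects.
#' @param path optional output file; when `NULL` the text is returned.
#' @return the export text (invisibly when written to `path`).
#' @export
serialize_export <- function(reports, path = NULL) {
  chunks <- vapply(reports, function(r) {
    paste0("==========\n",
           "CASE: ", r$case_id, "\n",
           "DIAGNOSIS:\n",
           paste(r$diagnosis_lines, collapse = "\n"),
           if (length(r$diagnosis_lines)) "\n" else "",
           "DESCRIPTION:\n",
           paste(r$description_paragraphs, collapse = "\n\n"),
           if (length(r$description_paragraphs)) "\n" else "")
  }, character(1))
  text <- paste(chunks, collapse = "")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path, useBytes = TRUE)
  invisible(text)
}

#' Build the corpus store
#'
#' Persists reports into a single-file SQLite database with one table
#' (`reports(case_id TEXT PRIMARY KEY, diagnosis TEXT, description TEXT)`),
#' mirroring the client-side database of the original workflow. The round
#' trip through [iter_store()] is lossless and preserves insertion order.
#'
#' @param reports list of `ihc_report` objects.
#' @param store_path path of the store file to create (overwritten).
#' @return `store_path`, invisibly.
#' @export
build_store <- function(reports, store_path) {
  ids <- vapply(reports, `[[`, character(1), "case_id")
  if (anyDuplicated(ids)) {
    ihc_stop(sprintf("duplicate case_id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "ihcmine_duplicate_error")
  }
  if (file.exists(store_path)) file.remove(store_path)
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), store_path),
                  error = function(e) ihc_stop(
                    sprintf("cannot create store at %s: %s", store_path,
                            conditionMessage(e)), "ihcmine_store_error"))
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, paste(
    "CREATE TABLE reports (",
    "  rowid_order INTEGER PRIMARY KEY AUTOINCREMENT,",
    "  case_id TEXT UNIQUE NOT NULL,",
    "  diagnosis TEXT, description TEXT)"))
  if (length(reports) > 0L) {
    df <- data.frame(
      case_id = ids,
      diagnosis = vapply(reports, function(r)
        paste(r$diagnosis_lines, collapse = "\n"), character(1)),
      description = vapply(reports, function(r)
        paste(r$description_paragraphs, collapse = "\n\n"), character(1)),
      stringsAsFactors = FALSE)
    DBI::dbWriteTable(con, "reports", df, append = TRUE)
  }
  invisible(store_path)
}

#' Read all reports back from a corpus store
#'
#' @param store_path path created by [build_store()].
#' @return list of `ihc_report` objects in insertion order.
#' @export
iter_store <- function(store_path) {
  if (!file.exists(store_path)) {
    ihc_stop(sprintf("store file not found: %s", store_path),
             "ihcmine_store_error")
  }
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), store_path),
                  error = function(e) ihc_stop(
                    sprintf("cannot open store %s: %s", store_path,
                            conditionMessage(e)), "ihcmine_store_error"))
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  df <- tryCatch(
    DBI::dbGetQuery(con,
      "SELECT case_id, diagnosis, description FROM reports ORDER BY rowid_order"),
    error = function(e) ihc_stop(
      sprintf("corrupt or foreign store %s: %s", store_path,
              conditionMessage(e)), "ihcmine_store_corrupt"))
  lapply(seq_len(nrow(df)), function(i) {
    diag <- if (nzchar(df$diagnosis[i]))
      strsplit(df$diagnosis[i], "\n", fixed = TRUE)[[1]] else character()
    desc <- if (nzchar(df$description[i]))
      strsplit(df$description[i], "\n\n", fixed = TRUE)[[1]] else character()
    report(df$case_id[i], diag, desc)
  })
}

# ---- results CSV (one row per case) ----------------------------------------

results_header <- c("case_id", "metastatic_site", "ER", "PR", "HER2")

#' Construct an extraction record
#'
#' One row of the results CSV: the case identifier, the parsed metastatic
#' site, and the three receptor results. A failed extraction is the literal
#' token `"None"` in the serialized form.
#'
#' @param case_id case identifier.
#' @param site_text canonical metastatic site label, or `NA`.
#' @param site_class `"regional"`, `"distant"`, or `NA`.
#' @param er,pr,her2 `receptor_result` objects (see [receptor_result()]), or
#'   `NULL` for a failed extraction.
#' @return an object of class `extraction_record`.
#' @export
extraction_record <- function(case_id, site_text = NA_character_,
                              site_class = NA_character_,
                              er = NULL, pr = NULL, her2 = NULL) {
  structure(list(case_id = case_id, site_text = site_text,
                 site_class = site_class, er = er, pr = pr, her2 = her2),
            class = "extraction_record")
}

record_to_row <- function(rec) {
  cell <- function(rr) {
    if (is.null(rr) || identical(rr$status, "not_found")) return("None")
    format_receptor(rr)
  }
  c(case_id = rec$case_id,
    metastatic_site = if (is_string(rec$site_text)) rec$site_text else "None",
    ER = cell(rec$er), PR = cell(rec$pr), HER2 = cell(rec$her2))
}

#' Write the results CSV
#'
#' Serializes extraction records in the fixed column order
#' `case_id, metastatic_site, ER, PR, HER2` (RFC-4180 quoting via
#' [utils::write.csv()]); failed extractions become the literal `"None"`.
#'
#' @param records list of `extraction_record` objects.
#' @param path output CSV path.
#' @return number of data rows written.
#' @export
write_results_csv <- function(records, path) {
  rows <- lapply(records, function(rec) {
    row <- tryCatch(record_to_row(rec), error = function(e) ihc_stop(
      sprintf("cannot serialize record %s: %s", rec$case_id %||% "<no id>",
              conditionMessage(e)), "ihcmine_serialize_error"))
    as.data.frame(as.list(row), stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(), ncol = 5)), results_header)
  colnames(df) <- results_header
  utils::write.csv(df, path, row.names = FALSE)
  nrow(df)
}

#' Read a results CSV back into extraction records
#'
#' Inverse of [write_results_csv()]. The site class is not a CSV column; it
#' is re-derived from the canonical site label (axillary sites are regional,
#' everything else distant), so `read_results_csv(write_results_csv(x))`
#' reproduces `x` for records produced by the pipeline.
#'
#' @param path CSV path.
#' @return list of `extraction_record` objects.
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(colnames(df), results_header)) {
    ihc_stop(sprintf("unexpected results header: %s",
                     paste(colnames(df), collapse = ",")),
             "ihcmine_parse_error")
  }
  lapply(seq_len(nrow(df)), function(i) {
    site <- df$metastatic_site[i]
    if (identical(site, "None")) site <- NA_character_
    extraction_record(
      case_id = df$case_id[i],
      site_text = site,
      site_class = site_class_of(site),
      er = parse_receptor_cell(df$ER[i], "ER"),
      pr = parse_receptor_cell(df$PR[i], "PR"),
      her2 = parse_receptor_cell(df$HER2[i], "HER2"))
  })
}

#' Semantic equality of extraction records
#'
#' Two records are equivalent when every serialized field agrees: case id,
#' site, and the status/percent/score/intensity of all three receptor
#' results. The `raw_span` provenance field (the matched report text) is not
#' part of the CSV and is ignored, so
#' `records_equivalent(x, read_results_csv(write_results_csv(x, p)))` holds
#' for any valid record list.
#'
#' @param a,b lists of `extraction_record` objects.
#' @return logical scalar.
#' @export
records_equivalent <- function(a, b) {
  strip <- function(recs) lapply(recs, function(rec) {
    rec[c("er", "pr", "her2")] <- lapply(rec[c("er", "pr", "her2")],
      function(rr) {
        if (is.null(rr) || identical(rr$status, "not_found")) return(NULL)
        rr$raw_span <- NULL
        rr
      })
    rec
  })
  isTRUE(all.equal(strip(a), strip(b)))
}

# canonical regional labels; anything else canonical is distant
site_class_of <- function(site_text) {
  if (!is_string(site_text)) return(NA_character_)
  if (site_text %in% c("axillary lymph node", "axillary soft tissue"))
    "regional" else "distant"
}
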