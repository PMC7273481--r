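# Phrase lexicon: the configurable vocabulary the case finder matches.
#
# Five phrase sets drive the four-step finding protocol:
#   * metastatic_phrases      -- diagnosis-line cues for metastatic carcinoma
#   * breast_origin_phrases   -- cues that the metastasis is of breast origin
#   * primary_breast_phrases  -- cues for primary breast cancer (exclusion)
#   * regional_site_phrases   -- axillary site phrases (regional metastasis)
#   * organ_vocabulary        -- organ token -> canonical distant-site label
#
# Phrases are matched case-insensitively and runs of internal whitespace in a
# phrase match any whitespace run in the report, so "lymph  node, axillary"
# in a report still matches the phrase "lymph node, axillary".

.default_lexicon <- function() {
  list(
    metastatic_phrases = c("carcinoma, metastatic", "carcinoma, involved"),
    breast_origin_phrases = c("breast origin", "breast primary"),
    primary_breast_phrases = c(
      "mastectomy",
      "invasive ductal carcinoma",
      "invasive lobular carcinoma",
      "ductal carcinoma in situ",
      "breast, left",
      "breast, right",
      "breast, bilateral"
    ),
    regional_site_phrases = c("soft tissue, axillary", "lymph node, axillary"),
    # distant-organ vocabulary: leading specimen token -> canonical site label.
    # Seeded from the distant sites the published tool observed; "lymph node"
    # (a non-axillary station, step 4 handles the axillary case first) maps to
    # the nonregional lymph node category.
    organ_vocabulary = c(
      "lymph node" = "nonregional lymph node",
      "bone" = "bone",
      "brain" = "brain",
      "liver" = "liver",
      "lung" = "lung",
      "stomach" = "GI tract",
      "colon" = "GI tract",
      "rectum" = "GI tract",
      "duodenum" = "GI tract",
      "small intestine" = "GI tract",
      "esophagus" = "GI tract",
      "uterus" = "uterus",
      "pleura" = "pleura",
      "pelvic cavity" = "pelvic cavity",
      "ovary" = "ovary",
      "mediastinum" = "mediastinum",
      "urinary bladder" = "urinary bladder"
    )
  )
}

# turn a literal phrase into a case-insensitive regex: escape metacharacters,
# then let any internal whitespace run match \s+
phrase_to_regex <- function(phrase) {
  escaped <- gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", phrase, perl = TRUE)
  gsub("\\s+", "\\\\s+", escaped)
}

#' Load the phrase lexicon
#'
#' Returns the shipped default lexicon, optionally merged with a JSON config
#' file. The config may supply any of the keys `metastatic_phrases`,
#' `breast_origin_phrases`, `primary_breast_phrases`, `regional_site_phrases`
#' (character vectors, appended to the defaults) and `organ_vocabulary` (a
#' named object of organ token -> canonical site label, merged over the
#' defaults). Phrase matching is case-insensitive and whitespace-elastic.
#'
#' @param config_path optional path to a JSON configuration file.
#' @return an object of class `ihc_lexicon`: the five phrase sets plus
#'   compiled regular expressions.
#' @examples
#' lex <- load_lexicon()
#' lex$metastatic_phrases
#' @export
load_lexicon <- function(config_path = NULL) {
  lex <- .default_lexicon()
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) {
      ihc_stop(sprintf("lexicon config not found: %s", config_path),
               "ihcmine_config_error")
    }
    cfg <- tryCatch(
      jsonlite::read_json(config_path, simplifyVector = TRUE),
      error = function(e) ihc_stop(
        sprintf("lexicon config is not valid JSON (%s): %s",
                config_path, conditionMessage(e)),
        "ihcmine_config_error")
    )
    for (key in c("metastatic_phrases", "breast_origin_phrases",
                  "primary_breast_phrases", "regional_site_phrases")) {
      if (!is.null(cfg[[key]])) {
        lex[[key]] <- unique(c(lex[[key]], as.character(cfg[[key]])))
      }
    }
    if (!is.null(cfg$organ_vocabulary)) {
      ov <- unlist(cfg$organ_vocabulary)
      if (is.null(names(ov)) || any(names(ov) == "")) {
        ihc_stop("organ_vocabulary entries must be named (organ = label)",
                 "ihcmine_config_error")
      }
      names(ov) <- tolower(names(ov))
      lex$organ_vocabulary[names(ov)] <- ov
    }
  }

  for (key in c("metastatic_phrases", "breast_origin_phrases",
                "primary_breast_phrases", "regional_site_phrases")) {
    if (length(lex[[key]]) == 0L) {
      ihc_stop(sprintf("phrase list '%s' is empty after loading", key),
               "ihcmine_config_error")
    }
  }

  # a site must not be classifiable as both regional and distant
  collide <- intersect(tolower(lex$regional_site_phrases),
                       names(lex$organ_vocabulary))
  if (length(collide) > 0L) {
    ihc_stop(sprintf(
      "term(s) present in both regional_site_phrases and organ_vocabulary: %s",
      paste(collide, collapse = ", ")), "ihcmine_config_error")
  }

  # compile all phrase patterns up front so bad patterns fail at load time
  lex$compiled <- lapply(
    lex[c("metastatic_phrases", "breast_origin_phrases",
          "primary_breast_phrases", "regional_site_phrases")],
    function(phrases) {
      vapply(phrases, function(p) {
        rx <- phrase_to_regex(p)
        ok <- tryCatch({ regexpr(rx, "", perl = TRUE); TRUE },
                       error = function(e) FALSE)
        if (!ok) {
          ihc_stop(sprintf("phrase does not compile to a valid pattern: '%s'", p),
                   "ihcmine_config_error")
        }
        rx
      }, character(1))
    })

  structure(lex, class = "ihc_lexicon")
}

#' Match a phrase set against one line of text
#'
#' Scans `line` with every phrase in `phrases` (case-insensitively, internal
#' whitespace elastic) and reports the leftmost match; ties on position are
#' broken by phrase list order.
#'
#' @param phrases character vector of literal phrases.
#' @param line a single line of text.
#' @return a list with `matched` (logical), and when matched, `phrase` (the
#'   winning phrase), `start` and `end` (1-based character span).
#' @export
match_any <- function(phrases, line) {
  stopifnot(is.character(phrases))
  if (!is_string(line) || nchar(line) == 0L || length(phrases) == 0L) {
    return(list(matched = FALSE, phrase = NA_character_,
                start = NA_integer_, end = NA_integer_))
  }
  best <- NULL
  for (p in phrases) {
    m <- regexpr(phrase_to_regex(p), line, perl = TRUE, ignore.case = TRUE)
    if (m[1] > 0L && (is.null(best) || m[1] < best$start)) {
      best <- list(matched = TRUE, phrase = p, start = as.integer(m[1]),
                   end = as.integer(m[1] + attr(m, "match.length") - 1L))
    }
  }
  best %||% list(matched = FALSE, phrase = NA_character_,
                 start = NA_integer_, end = NA_integer_)
}

#' @export
print.ihc_lexicon <- function(x, ...) {
  cat("<ihc_lexicon>\n")
  cat("  metastatic phrases:   ", length(x$metastatic_phrases), "\n")
  cat("  breast-origin phrases:", length(x$breast_origin_phrases), "\n")
  cat("  primary-breast phrases:", length(x$primary_breast_phrases), "\n")
  cat("  regional site phrases:", length(x$regional_site_phrases), "\n")
  cat("  organ vocabulary:     ", length(x$organ_vocabulary), "entries\n")
  invisible(x)
}
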