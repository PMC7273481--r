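# Synthetic pathology-report corpora with ground truth.
#
# The generator emulates the stated world of the source corpus: clean
# regional (axillary) and distant metastatic breast cancer reports whose
# diagnosis lines follow the "(site), (procedure) --- carcinoma,
# metastatic/involved, breast origin/primary" convention, benign filler
# reports, the three documented confounder report types that fool the finding
# protocol, and receptor panels rendered in the three supported description
# dialects plus one deliberately unsupported narrative dialect (which models
# the tool's real extraction misses). Every report is paired with a ground
# truth row, aligned by case_id and consistent with the emitted text by
# construction.

#' Specification for a synthetic corpus
#'
#' Defaults reproduce the published corpus composition: 329 clean regional
#' and 83 clean distant true positives, the documented distant false-positive
#' mix (35 chest-wall recurrence, 11 "s/p breast cancer" sentinel-node, 1
#' tamoxifen treatment-note report), a dialect mix whose unsupported share
#' (0.22 ~ 18/83) matches the reported fraction of undetected panels, and
#' per-class receptor status frequencies taken from the published summary
#' tables of tested cases.
#'
#' @param n_regional,n_distant,n_benign counts of clean regional/distant
#'   metastatic and benign reports.
#' @param dialect_mix named proportions over `sentence`, `multirow`,
#'   `comma_block`, `unsupported`; must sum to 1.
#' @param confounder_counts named counts over `chest_wall_recurrence`,
#'   `sp_breast_sentinel`, `treatment_note`.
#' @param panel_distribution per-class, per-marker status probabilities (see
#'   [default_panel_distribution()]).
#' @param seed integer seed for the corpus RNG.
#' @return a list of class `synth_spec`.
#' @export
synth_spec <- function(n_regional = 329L, n_distant = 83L, n_benign = 100L,
                       dialect_mix = c(sentence = 0.40, multirow = 0.22,
                                       comma_block = 0.16, unsupported = 0.22),
                       confounder_counts = c(chest_wall_recurrence = 35L,
                                             sp_breast_sentinel = 11L,
                                             treatment_note = 1L),
                       panel_distribution = default_panel_distribution(),
                       seed = 1L) {
  if (any(c(n_regional, n_distant, n_benign, confounder_counts) < 0)) {
    ihc_stop("counts must be non-negative", "ihcmine_spec_error")
  }
  need <- c("sentence", "multirow", "comma_block", "unsupported")
  if (!setequal(names(dialect_mix), need) ||
      abs(sum(dialect_mix) - 1) > 1e-8 || any(dialect_mix < 0)) {
    ihc_stop("dialect_mix must be non-negative proportions over sentence/multirow/comma_block/unsupported summing to 1",
             "ihcmine_spec_error")
  }
  structure(list(n_regional = as.integer(n_regional),
                 n_distant = as.integer(n_distant),
                 n_benign = as.integer(n_benign),
                 dialect_mix = dialect_mix[need],
                 confounder_counts = confounder_counts,
                 panel_distribution = panel_distribution,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default receptor status frequencies
#'
#' Per-class probabilities of each marker status, including "not tested",
#' derived from the published per-class summary counts of tested cases
#' (regional denominators over 322 correctly detected cases, distant over
#' 64).
#'
#' @return nested list `class -> marker -> named probability vector`.
#' @export
default_panel_distribution <- function() {
  list(
    regional = list(
      ER = c(positive = 198, negative = 110, not_tested = 14) / 322,
      PR = c(positive = 52, negative = 29, not_tested = 241) / 322,
      HER2 = c(positive = 103, equivocal = 95, negative = 112,
               not_tested = 12) / 322),
    distant = list(
      ER = c(positive = 36, negative = 28, not_tested = 0) / 64,
      PR = c(positive = 12, negative = 40, not_tested = 12) / 64,
      HER2 = c(positive = 23, equivocal = 11, negative = 24,
               not_tested = 6) / 64)
  )
}

# ---- site and specimen sampling --------------------------------------------

# distant site weights follow the published site tally (n = 83)
.distant_site_weights <- c(
  "nonregional lymph node" = 22, "bone" = 20, "brain" = 12, "liver" = 8,
  "GI tract" = 8, "lung" = 7, "uterus" = 1, "pleura" = 1,
  "pelvic cavity" = 1, "ovary" = 1, "mediastinum" = 1, "urinary bladder" = 1)

# specimen text whose leading token resolves to the canonical site
specimen_for_site <- function(site) {
  pick <- function(...) sample(c(...), 1L)
  switch(site,
    "axillary lymph node" = "Lymph node, axillary",
    "axillary soft tissue" = "Soft tissue, axillary",
    "nonregional lymph node" = paste0("Lymph node, ",
      pick("supraclavicular", "cervical", "inguinal", "mediastinal")),
    "bone" = paste0("Bone, ", pick("vertebra", "femur", "rib", "ilium")),
    "brain" = paste0("Brain, ", pick("tumor", "frontal lobe", "cerebellum")),
    "liver" = "Liver",
    "GI tract" = pick("Stomach", "Colon", "Rectum", "Duodenum"),
    "lung" = paste0("Lung, ", pick("right upper lobe", "left lower lobe")),
    "uterus" = "Uterus",
    "pleura" = "Pleura",
    "pelvic cavity" = "Pelvic cavity",
    "ovary" = paste0("Ovary, ", pick("left", "right")),
    "mediastinum" = "Mediastinum",
    "urinary bladder" = "Urinary bladder",
    site)
}

metastatic_diagnosis_line <- function(site) {
  procedure <- sample(c("biopsy", "excision", "dissection", "curettage"), 1L)
  met <- sample(c("carcinoma, metastatic", "carcinoma, involved"), 1L,
                prob = c(0.8, 0.2))
  origin <- sample(c("breast origin", "breast primary"), 1L, prob = c(0.7, 0.3))
  sprintf("%s, %s --- %s, %s", specimen_for_site(site), procedure, met, origin)
}

.benign_lines <- c(
  "Stomach, biopsy --- chronic gastritis",
  "Gallbladder, cholecystectomy --- chronic cholecystitis",
  "Appendix, appendectomy --- acute appendicitis",
  "Colon, polypectomy --- tubular adenoma",
  "Tonsil, tonsillectomy --- chronic tonsillitis",
  "Skin, back, excision --- epidermal inclusion cyst",
  "Uterus, myomectomy --- leiomyoma")

# ---- panel sampling and dialect rendering ----------------------------------

sample_panel <- function(class_dist, dialect) {
  draw <- function(marker) {
    probs <- class_dist[[marker]]
    status <- sample(names(probs), 1L, prob = probs)
    if (status == "not_tested") return(NULL)
    if (marker == "HER2") {
      score <- switch(status, positive = "3+", equivocal = "2+",
                      negative = sample(c("0", "1+"), 1L))
      # the long colon dialect carries the staining clause; sample it here so
      # the ground-truth cell and the rendered text agree by construction
      if (identical(dialect, "comma_block") && score != "0") {
        intensity <- c("1+" = "weak", "2+" = "moderate",
                       "3+" = "strong")[[score]]
        return(receptor_result("HER2", status, score = score,
                               intensity = intensity,
                               percent = sample(seq(10L, 90L, 10L), 1L)))
      }
      receptor_result("HER2", status, score = score)
    } else {
      pct <- if (status == "positive") sample(seq(5L, 100L, 5L), 1L)
             else NA_integer_
      receptor_result(marker, status, percent = pct)
    }
  }
  list(er = draw("ER"), pr = draw("PR"), her2 = draw("HER2"))
}

# item renderers; her2 paren form carries (status, score), colon form may add
# the "intensity staining in N%" clause of the long CAP dialect
render_item_paren <- function(rr, spelled = "HER2") {
  name <- if (rr$marker == "HER2") spelled else rr$marker
  body <- if (rr$marker == "HER2") sprintf("%s, %s", rr$status, rr$score)
    else if (!is.na(rr$percent)) sprintf("%s, %d%%", rr$status, rr$percent)
    else rr$status
  sprintf("%s (%s)", name, body)
}

render_item_colon <- function(rr, spelled = "HER2") {
  if (rr$marker != "HER2") {
    return(sprintf("%s: %s%s", rr$marker, rr$status,
                   if (!is.na(rr$percent)) sprintf(", %d%%", rr$percent) else ""))
  }
  score_digit <- sub("\\+", "", rr$score)
  clause <- if (!is.na(rr$intensity) && !is.na(rr$percent)) {
    sprintf(", %s staining in %d%%", rr$intensity, rr$percent)
  } else ""
  sprintf("%s: %s, score %s%s", spelled, rr$status, score_digit, clause)
}

her2_spellings <- c("HER2", "Her-2", "Her2", "HER-2")

render_ihc_paragraph <- function(panel, dialect) {
  items <- Filter(Negate(is.null), panel[c("er", "pr", "her2")])
  if (length(items) == 0L) return(NULL)
  spelled <- sample(her2_spellings, 1L)
  switch(dialect,
    sentence = paste0("Immunohistochemical study shows: ",
      paste(vapply(items, render_item_paren, character(1), spelled = spelled),
            collapse = ", "), "."),
    multirow = paste(c("Immunohistochemical studies:",
      vapply(items, render_item_paren, character(1), spelled = spelled)),
      collapse = "\n"),
    comma_block = paste(
      vapply(items, render_item_colon, character(1), spelled = spelled),
      collapse = ", "),
    unsupported = {
      longname <- c(ER = "estrogen receptor", PR = "progesterone receptor",
                    HER2 = "Her-2 protein")
      phrases <- vapply(items, function(rr) {
        sprintf("%s for %s", rr$status, longname[[rr$marker]])
      }, character(1))
      paste0("Immunohistochemical stains were performed; the tumor cells are ",
             paste(phrases, collapse = " and "), " by routine staining.")
    },
    ihc_stop(sprintf("unknown dialect: %s", dialect), "ihcmine_spec_error"))
}

.gross_paragraphs <- c(
  "Received in formalin is a fragment of tan soft tissue measuring up to 1.5 cm.",
  "The specimen consists of several cores of pale tissue, up to 1.2 cm in length.",
  "Received is an irregular fragment of firm, gray-white tissue, 2.0 cm in greatest dimension.")

.micro_metastatic <- c(
  "Sections show nests of atypical epithelial cells infiltrating the tissue, consistent with metastatic carcinoma.",
  "Microscopically, cohesive clusters of malignant cells with nuclear pleomorphism are seen.",
  "Sections reveal tumor cells arranged in cords and nests within a desmoplastic stroma.")

.micro_benign <- c(
  "Sections show unremarkable tissue with mild chronic inflammation.",
  "Microscopically, there is no evidence of malignancy.",
  "Sections reveal benign tissue with reactive changes only.")

truth_row <- function(case_id, true_metastatic, site_class = NA_character_,
                      site = NA_character_, panel = NULL, dialect = NA_character_,
                      confounder = "none") {
  cell <- function(rr) if (is.null(rr)) "None" else format_receptor(rr)
  data.frame(case_id = case_id, true_metastatic = true_metastatic,
             true_site_class = site_class %||% NA_character_,
             true_site = site %||% NA_character_,
             er = cell(panel$er), pr = cell(panel$pr), her2 = cell(panel$her2),
             dialect = dialect, confounder_type = confounder,
             stringsAsFactors = FALSE)
}

gen_metastatic_report <- function(case_id, site_class, site, dialect,
                                  panel_dist) {
  panel <- sample_panel(panel_dist[[site_class]], dialect)
  diag <- metastatic_diagnosis_line(site)
  if (stats::runif(1) < 0.3) {
    diag <- c(diag, sample(.benign_lines, 1L))
  }
  desc <- c(sample(.gross_paragraphs, 1L), sample(.micro_metastatic, 1L))
  ihc <- render_ihc_paragraph(panel, dialect)
  if (!is.null(ihc)) desc <- c(desc, ihc)
  list(report = report(case_id, diag, desc),
       truth = truth_row(case_id, TRUE, site_class, site, panel, dialect))
}

#' Generate one confounder report
#'
#' Builds a report of one of the three documented false-positive types. Each
#' is constructed so that the four-step finding protocol, as specified, WILL
#' flag it (the matched diagnosis line carries both a metastatic phrase and a
#' breast-origin phrase but the case is not a metastasis):
#' `chest_wall_recurrence` — chest-wall soft tissue involved by recurrent
#' breast cancer; `sp_breast_sentinel` — a negative sentinel-node report into
#' which "s/p breast cancer" wording is inserted; `treatment_note` — an
#' endometrial curettage whose diagnosis notes tamoxifen treatment for breast
#' cancer.
#'
#' @param type one of the three confounder types.
#' @param case_id identifier for the generated report.
#' @return a list with `report` (`ihc_report`) and `truth` (one gold row with
#'   `true_metastatic = FALSE` and the confounder type).
#' @export
gen_confounder <- function(type = c("chest_wall_recurrence",
                                    "sp_breast_sentinel", "treatment_note"),
                           case_id = "CONF-00001") {
  type <- match.arg(type)
  templ <- switch(type,
    chest_wall_recurrence = list(
      diag = "Soft tissue, chest wall, wide excision --- carcinoma, involved, breast origin, consistent with recurrence",
      desc = "Sections show dermal and subcutaneous infiltration by carcinoma, morphologically identical to the patient's previous breast primary, consistent with local recurrence."),
    sp_breast_sentinel = list(
      diag = "Lymph node, sentinel, biopsy --- negative for carcinoma, metastatic disease; s/p breast cancer, breast origin",
      desc = "Serial sections of the sentinel node show reactive follicular hyperplasia only. No tumor cells are identified."),
    treatment_note = list(
      diag = "Uterus, endometrium, curettage --- endometrial polyp; patient under tamoxifen treatment for carcinoma, metastatic, breast origin",
      desc = "Sections show a polypoid endometrial fragment with cystically dilated glands, compatible with tamoxifen-associated change."))
  list(report = report(case_id, templ$diag,
                       c(sample(.gross_paragraphs, 1L), templ$desc)),
       truth = truth_row(case_id, FALSE, confounder = type))
}

#' Generate a synthetic corpus with ground truth
#'
#' Deterministic for a fixed spec (including its seed): the same spec yields
#' byte-identical corpora. The report order is shuffled so case class cannot
#' be inferred from position, and case identifiers carry no class signal.
#'
#' @param spec a [synth_spec()].
#' @return list with `reports` (list of `ihc_report`) and `truth` (gold
#'   data.frame, one row per report, aligned by `case_id`; includes the
#'   extra bookkeeping columns `true_site` and `dialect` on top of the gold
#'   CSV columns).
#' @export
gen_corpus <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  items <- list()
  add <- function(x) items[[length(items) + 1L]] <<- x
  mk_dialect <- function() sample(names(spec$dialect_mix), 1L,
                                  prob = spec$dialect_mix)

  for (i in seq_len(spec$n_regional)) {
    site <- sample(c("axillary lymph node", "axillary soft tissue"), 1L,
                   prob = c(0.8, 0.2))
    add(gen_metastatic_report("tmp", "regional", site, mk_dialect(),
                              spec$panel_distribution))
  }
  for (i in seq_len(spec$n_distant)) {
    site <- sample(names(.distant_site_weights), 1L,
                   prob = .distant_site_weights)
    add(gen_metastatic_report("tmp", "distant", site, mk_dialect(),
                              spec$panel_distribution))
  }
  for (i in seq_len(spec$n_benign)) {
    rep_b <- report("tmp", sample(.benign_lines, 1L),
                    c(sample(.gross_paragraphs, 1L), sample(.micro_benign, 1L)))
    add(list(report = rep_b, truth = truth_row("tmp", FALSE)))
  }
  for (type in names(spec$confounder_counts)) {
    for (i in seq_len(spec$confounder_counts[[type]])) {
      add(gen_confounder(type, "tmp"))
    }
  }

  if (length(items) == 0L) {
    return(list(reports = list(),
                truth = truth_row("x", FALSE)[0, , drop = FALSE]))
  }
  items <- items[sample(length(items))]
  years <- sample(2013:2018, length(items), replace = TRUE)
  reports <- vector("list", length(items))
  truth <- vector("list", length(items))
  for (i in seq_along(items)) {
    id <- sprintf("S%d-%05d", years[i], i)
    items[[i]]$report$case_id <- id
    items[[i]]$truth$case_id <- id
    reports[[i]] <- items[[i]]$report
    truth[[i]] <- items[[i]]$truth
  }
  list(reports = reports, truth = do.call(rbind, truth))
}
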