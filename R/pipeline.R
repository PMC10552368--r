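# Pipeline and bookkeeping: corpus ledgers, the end-to-end run, and the
# dual-rater audit check.

#' Corpus ledger totals
#'
#' A corpus ledger records how many publications per biomarker (optionally
#' broken down by study type) enter scoring. `ledger_totals()` computes
#' exact integer publication totals per status group and overall.
#'
#' @param ledger data.frame with columns `biomarker` (or `biomarker_id`),
#'   `status`, and one or more non-negative integer count columns (e.g.
#'   `n_publications`, or one column per study type).
#' @return List with `per_biomarker` (input plus a `total` column),
#'   `per_status` (data.frame `status`, `n_biomarkers`, `total`) and
#'   `overall` (integer). An empty ledger yields an overall total of 0.
#' @export
#' @examples
#' bc <- data.frame(
#'   biomarker = c("MammaPrint", "OncoTypeDX", "PAM50", "Endopredict"),
#'   status = "successful",
#'   n_publications = c(71, 251, 35, 20))
#' ledger_totals(bc)$overall   # 377
ledger_totals <- function(ledger) {
  ledger <- as.data.frame(ledger)
  if (!"biomarker" %in% names(ledger) && "biomarker_id" %in% names(ledger))
    names(ledger)[names(ledger) == "biomarker_id"] <- "biomarker"
  if (nrow(ledger) == 0L)
    return(list(per_biomarker = ledger,
                per_status = data.frame(status = character(),
                                        n_biomarkers = integer(),
                                        total = integer()),
                overall = 0L))
  if (!all(c("biomarker", "status") %in% names(ledger)))
    stop_bm("ledger needs 'biomarker' and 'status' columns")
  count_cols <- names(ledger)[vapply(ledger, is.numeric, TRUE)]
  if (length(count_cols) == 0L)
    stop_bm("ledger has no numeric count columns")
  counts <- ledger[, count_cols, drop = FALSE]
  if (any(counts < 0, na.rm = TRUE))
    stop_bm("ledger counts must be non-negative")
  if (anyNA(counts)) stop_bm("ledger counts must not be missing")
  per_bm <- ledger
  per_bm$total <- as.integer(rowSums(counts))
  st <- unique(ledger$status)
  per_status <- data.frame(
    status = st,
    n_biomarkers = vapply(st, function(s) sum(ledger$status == s), 0L),
    total = vapply(st, function(s)
      as.integer(sum(per_bm$total[ledger$status == s])), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_biomarker = per_bm, per_status = per_status,
       overall = as.integer(sum(per_bm$total)))
}

#' Run the full scoring and comparison pipeline
#'
#' One call from raw tables to a report bundle: validates the scoring
#' sheet against the checklist before any scoring, scores the corpus,
#' builds per-biomarker gap reports, compares the groups (Mann-Whitney on
#' totals and per-category; logistic association; Cox association when
#' times are supplied), assembles the corpus ledger, and records a run
#' manifest (package version, options, seed, input content hashes) so any
#' run can be reproduced and audited. Output is a pure function of
#' (inputs, options, seed).
#'
#' @param checklist A `bm_checklist` or path to a definition document.
#' @param sheet Scoring-sheet data.frame or CSV/TSV path.
#' @param labels data.frame (`biomarker_id`, `status` in
#'   successful/stalled) or CSV path.
#' @param inventory Optional study-type inventory data.frame or path.
#' @param times Optional data.frame (`biomarker_id`, `time`, `event`) or
#'   path, enabling the Cox model.
#' @param weights,na_policy,include_rationale,amendment_weight Scoring
#'   options (see [score_corpus()]).
#' @param adjust Multiple-testing adjustment for per-category tests
#'   (default `"none"`).
#' @param alpha Significance level recorded in the manifest.
#' @param gap_n Rows per gap report.
#' @param out Optional output directory; when given, the score table, gap
#'   reports, comparison table and manifest are written there (CSV +
#'   JSON).
#' @return A `bm_run`: list with `scores` (per-biomarker table),
#'   `gap_reports` (named list), `comparison` (per-measure Mann-Whitney
#'   results), `logistic`, `cox` (or `NULL`), `ledger`, `manifest`.
#' @export
run_pipeline <- function(checklist, sheet, labels, inventory = NULL,
                         times = NULL, weights = NULL,
                         na_policy = "as_zero", include_rationale = FALSE,
                         amendment_weight = 0.5, adjust = "none",
                         alpha = 0.05, gap_n = 10L, out = NULL) {
  hashes <- character()
  grab <- function(obj, reader, name) {
    if (is.character(obj) && length(obj) == 1L) {
      if (!file.exists(obj)) stop_bm(name, " file not found: ", obj)
      hashes[[name]] <<- unname(tools::md5sum(obj))
      reader(obj)
    } else obj
  }
  checklist <- grab(checklist, read_checklist, "checklist")
  validate_checklist(checklist)
  sheet <- grab(sheet, function(p) read_scoring_sheet(p, checklist),
                "sheet")
  labels <- grab(labels, read.csv, "labels")
  inventory <- if (is.null(inventory)) NULL
               else grab(inventory, read_inventory, "inventory")
  times <- if (is.null(times)) NULL else grab(times, read.csv, "times")

  if (!all(c("biomarker_id", "status") %in% names(labels)))
    stop_bm("labels needs 'biomarker_id' and 'status' columns")
  unlabelled <- setdiff(unique(sheet$biomarker_id), labels$biomarker_id)
  if (length(unlabelled))
    stop_bm("biomarker(s) without a status label: ",
            paste(unlabelled, collapse = ", "))

  scores <- score_corpus(sheet, checklist, inventory,
                         na_policy = na_policy, weights = weights,
                         include_rationale = include_rationale,
                         amendment_weight = amendment_weight)
  summaries <- attr(scores, "summaries")
  gaps <- lapply(summaries, gap_report, checklist = checklist,
                 worst_n = gap_n)
  status <- labels$status[match(scores$biomarker_id, labels$biomarker_id)]

  measures <- c(total = "total_percent",
                analytical_validity = "analytical_validity",
                clinical_validity = "clinical_validity",
                clinical_utility = "clinical_utility_amended")
  comp_tab <- data.frame(endpoint = rep(names(measures),
                                        each = nrow(scores)),
                         group = rep(status, times = length(measures)),
                         value = unlist(scores[, measures],
                                        use.names = FALSE),
                         stringsAsFactors = FALSE)
  comparison <- compare_endpoints(comp_tab,
                                  groups = c("successful", "stalled"),
                                  adjust = adjust)
  logistic <- logistic_association(scores$total_percent,
                                   status == "successful")
  cox <- NULL
  if (!is.null(times)) {
    m <- match(scores$biomarker_id, times$biomarker_id)
    if (anyNA(m)) stop_bm("times table does not cover every biomarker")
    cox <- cox_association(scores$total_percent, times$time[m],
                           times$event[m])
  }
  pub_counts <- as.data.frame(table(biomarker = sheet$biomarker_id),
                              stringsAsFactors = FALSE)
  names(pub_counts)[2] <- "n_publications"
  pub_counts$status <- labels$status[match(pub_counts$biomarker,
                                           labels$biomarker_id)]
  ledger <- ledger_totals(pub_counts)

  manifest <- list(
    tool = "bmtoolkit",
    version = as.character(packageVersion("bmtoolkit")),
    options = list(na_policy = na_policy,
                   include_rationale = include_rationale,
                   amendment_weight = amendment_weight,
                   weights = weights, adjust = adjust, alpha = alpha),
    input_hashes = as.list(hashes),
    n_biomarkers = nrow(scores), n_publications = nrow(sheet))
  bundle <- structure(list(scores = scores, gap_reports = gaps,
                           comparison = comparison, logistic = logistic,
                           cox = cox, ledger = ledger,
                           manifest = manifest),
                      class = "bm_run")
  if (!is.null(out)) write_run(bundle, out)
  bundle
}

write_run <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- bundle$scores
  attr(sc, "summaries") <- NULL
  write.csv(sc, file.path(dir, "biomarker_scores.csv"), row.names = FALSE)
  write.csv(bundle$comparison, file.path(dir, "group_comparison.csv"),
            row.names = FALSE)
  gaps <- do.call(rbind, lapply(names(bundle$gap_reports), function(b) {
    g <- bundle$gap_reports[[b]]
    if (nrow(g) == 0L) return(NULL)
    cbind(biomarker_id = b, g)
  }))
  if (!is.null(gaps))
    write.csv(gaps, file.path(dir, "gap_reports.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.bm_run <- function(x, ...) {
  cat(sprintf("<bm_run> %d biomarkers, %d publications\n",
              x$manifest$n_biomarkers, x$manifest$n_publications))
  cat("Group comparison:\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare two raters' scoring sheets
#'
#' Supports a dual-reviewer audit protocol: both raters score the same
#' publications independently and the per-publication total scores are
#' compared. The per-publication total is the equal-weight mean of the
#' analytical-validity, clinical-validity and (non-amended)
#' clinical-utility category scores, on the 0-100 scale; flipping a
#' single indicator on a checklist therefore moves a publication total by
#' at most `100 / (3 * n_smallest_category)` points.
#'
#' @param sheet_a,sheet_b Scoring sheets (data.frames) covering the same
#'   `pub_id` set; a mismatch is an error listing the symmetric
#'   difference.
#' @param checklist A `bm_checklist`.
#' @param na_policy Passed to the scorer.
#' @return List with `per_publication` (data.frame `pub_id`, `total_a`,
#'   `total_b`, `abs_diff`), `max_abs_diff` and `mean_abs_diff`.
#' @export
dual_rater_check <- function(sheet_a, sheet_b, checklist,
                             na_policy = "as_zero") {
  only_a <- setdiff(sheet_a$pub_id, sheet_b$pub_id)
  only_b <- setdiff(sheet_b$pub_id, sheet_a$pub_id)
  if (length(only_a) || length(only_b))
    stop_bm("sheets score different publications; only in A: [",
            paste(only_a, collapse = ", "), "], only in B: [",
            paste(only_b, collapse = ", "), "]")
  pub_totals <- function(sheet) {
    # per-publication totals: score each publication as its own unit
    s2 <- sheet
    s2$biomarker_id <- s2$pub_id
    t2 <- score_corpus(s2, checklist, na_policy = na_policy,
                       amendment_weight = 0)
    setNames(t2$total_percent, t2$biomarker_id)
  }
  ta <- pub_totals(sheet_a)
  tb <- pub_totals(sheet_b)[names(ta)]
  df <- data.frame(pub_id = names(ta), total_a = as.numeric(ta),
                   total_b = as.numeric(tb),
                   abs_diff = abs(as.numeric(ta) - as.numeric(tb)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  list(per_publication = df, max_abs_diff = max(df$abs_diff),
       mean_abs_diff = mean(df$abs_diff))
}
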