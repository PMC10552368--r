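# Scoring engine: binary per-publication indicators -> sub-category and
# category means -> biomarker-level aggregation with the clinical-utility
# amendment and total % score.

#' Score one publication against a checklist
#'
#' Each checklist attribute is scored 1 if reported in the publication and
#' 0 otherwise. Sub-category scores are the mean of each sub-category's
#' attribute indicators; category scores are the flat mean over *all*
#' attributes in the category (not the mean of sub-category means).
#' Attributes absent from `indicators` count as 0 (not reported).
#'
#' @param indicators Named vector (or list) of 0/1/`NA` values keyed by
#'   attribute id. Names must be a subset of the checklist's attribute
#'   ids; unknown ids are an error.
#' @param checklist A `bm_checklist`.
#' @param na_policy `"as_zero"` (default; an `NA` indicator counts as not
#'   reported, matching a strictly binary protocol) or `"exclude"`
#'   (`NA` attributes leave the denominator — for attributes structurally
#'   inapplicable to a study, e.g. animal-experiment details in a purely
#'   clinical corpus).
#'
#' @return A `bm_publication_score`: list with `category_scores` (named
#'   fractions over [bm_categories()]), `sub_category_scores`, and the
#'   `na_policy` used. With `na_policy = "exclude"` a category whose
#'   attributes are all `NA` scores `NaN`.
#' @export
#' @examples
#' cl <- toolkit_v1()
#' rec <- setNames(rep(1, 10), cl$attributes$id[1:10])
#' score_publication(rec, cl)$category_scores
score_publication <- function(indicators, checklist,
                              na_policy = c("as_zero", "exclude")) {
  na_policy <- match.arg(na_policy)
  validate_checklist(checklist)
  ind <- unlist(indicators)
  if (length(ind) && is.null(names(ind)))
    stop_bm("indicators must be named by attribute id")
  unknown <- setdiff(names(ind), checklist$attributes$id)
  if (length(unknown))
    stop_bm("indicator(s) for unknown attribute id(s): ",
            paste(unknown, collapse = ", "))
  bad <- ind[!is.na(ind) & !ind %in% c(0, 1)]
  if (length(bad))
    stop_bm("indicators must be 0, 1 or NA")
  v <- setNames(rep(0, nrow(checklist$attributes)),
                checklist$attributes$id)
  v[names(ind)] <- ind
  if (na_policy == "as_zero") v[is.na(v)] <- 0
  cats <- attribute_categories(checklist)
  sc <- factor(checklist$attributes$sub_category,
               levels = checklist$sub_categories$id)
  cat_scores <- tapply(v, cats, mean, na.rm = TRUE)
  sc_scores <- tapply(v, sc, mean, na.rm = TRUE)
  structure(list(
    category_scores = setNames(as.numeric(cat_scores), levels(cats)),
    sub_category_scores = setNames(as.numeric(sc_scores), levels(sc)),
    na_policy = na_policy),
    class = "bm_publication_score")
}

#' @export
print.bm_publication_score <- function(x, ...) {
  cat("<bm_publication_score>\n")
  print(round(x$category_scores, 4))
  invisible(x)
}

#' Amend a clinical-utility score for study-type breadth
#'
#' The clinical-utility category score from clinical publications alone
#' understates a biomarker's translational progress when additional,
#' non-clinical study types (cost-effectiveness, human-factor,
#' implementation, ...) exist for it. The amendment pushes the base score
#' convexly towards 1 in proportion to how many of the amendable study
#' types are present:
#' \deqn{\mathrm{amended} = s + w \cdot \frac{k}{K} \cdot (1 - s)}
#' where \eqn{s} is the base clinical-utility score, \eqn{k} the number of
#' amendable study types present, \eqn{K} the number of amendable types
#' considered, and \eqn{w \in [0,1]} the amendment weight. The result
#' always lies in \eqn{[s, 1]}, equals \eqn{s} when no additional study
#' types exist, and is monotone in \eqn{k}.
#'
#' @param base_cu Base clinical-utility score in \[0, 1\].
#' @param present Character vector of study types present for the
#'   biomarker (a named logical vector also works). Types outside
#'   `amendable_types` (e.g. `"clinical"`) are ignored.
#' @param weight Amendment weight \eqn{w}, default 0.5.
#' @param amendable_types Study types counted towards \eqn{k}; default
#'   [bm_amendable_types()] (the six non-clinical types). Must be
#'   non-empty.
#' @return Amended clinical-utility score in \[`base_cu`, 1\].
#' @export
#' @examples
#' amend_clinical_utility(0.6, c("cost_effectiveness", "feasibility",
#'                               "human_factor"))   # 0.7
amend_clinical_utility <- function(base_cu, present, weight = 0.5,
                                   amendable_types = bm_amendable_types()) {
  check_prob(base_cu, "base_cu")
  check_prob(weight, "weight")
  if (length(amendable_types) == 0L)
    stop_bm("amendable_types must be non-empty when amendment is enabled")
  if (is.logical(present)) present <- names(present)[present]
  unknown <- setdiff(present, bm_study_types())
  if (length(unknown))
    stop_bm("unknown study type(s): ", paste(unknown, collapse = ", "))
  k <- length(intersect(unique(present), amendable_types))
  K <- length(unique(amendable_types))
  base_cu + weight * (k / K) * (1 - base_cu)
}

#' Aggregate publication scores to a biomarker summary
#'
#' Biomarker-level category scores are the unweighted mean over
#' publications of the per-publication category scores. The
#' clinical-utility amendment is applied once, at the biomarker level, to
#' the mean clinical-utility score, because the study-type inventory is a
#' property of the biomarker, not of any single publication. The total
#' score is \eqn{100 \sum_c w_c \, s_c} over the included categories —
#' by default analytical validity, clinical validity and the *amended*
#' clinical utility, equally weighted; rationale is excluded by default
#' (within one cancer type it is near-constant across biomarkers and
#' carries no discriminating signal).
#'
#' @param scores List of `bm_publication_score` objects (all for the same
#'   biomarker); must be non-empty.
#' @param present Study types present for the biomarker (see
#'   [amend_clinical_utility()]). Default: none.
#' @param weights Named non-negative weights over the included categories
#'   (need not be pre-normalised; they are renormalised to sum exactly
#'   to 1). `NULL` (default) means equal weights.
#' @param include_rationale Include the rationale category in the total?
#'   Default `FALSE`.
#' @param amendment_weight,amendable_types Passed to
#'   [amend_clinical_utility()]. `amendment_weight = 0` disables the
#'   amendment.
#' @param biomarker_id Optional identifier carried into the result.
#'
#' @return A `bm_biomarker_score`: list with `biomarker_id`,
#'   `n_publications`, `category_scores` (per-category means over
#'   publications), `amended_clinical_utility`, `total_percent` in
#'   \[0, 100\], `sub_category_scores` (per-sub-category means, for gap
#'   reports) and `weights` (the normalised weights actually used).
#' @export
#' @examples
#' cl <- toolkit_v1()
#' ids <- cl$attributes$id
#' s1 <- score_publication(setNames(rep(1, length(ids)), ids), cl)
#' aggregate_biomarker(list(s1), present = bm_amendable_types())$total_percent
aggregate_biomarker <- function(scores, present = character(),
                                weights = NULL, include_rationale = FALSE,
                                amendment_weight = 0.5,
                                amendable_types = bm_amendable_types(),
                                biomarker_id = NA_character_) {
  if (length(scores) == 0L)
    stop_bm("at least one publication score is required")
  if (!all(vapply(scores, inherits, TRUE, "bm_publication_score")))
    stop_bm("scores must be a list of bm_publication_score objects")
  cat_mat <- do.call(rbind, lapply(scores, `[[`, "category_scores"))
  sc_mat <- do.call(rbind, lapply(scores, `[[`, "sub_category_scores"))
  cat_means <- colMeans(cat_mat)
  sc_means <- colMeans(sc_mat)
  amended_cu <- amend_clinical_utility(cat_means[["clinical_utility"]],
                                       present, weight = amendment_weight,
                                       amendable_types = amendable_types)
  included <- c("analytical_validity", "clinical_validity",
                "clinical_utility", if (include_rationale) "rationale")
  used <- setNames(cat_means[included], included)
  used[["clinical_utility"]] <- amended_cu
  if (is.null(weights)) {
    w <- setNames(rep(1 / length(included), length(included)), included)
  } else {
    miss <- setdiff(included, names(weights))
    if (length(miss))
      stop_bm("weights missing for included category(ies): ",
              paste(miss, collapse = ", "))
    w <- weights[included]
    if (any(w < 0)) stop_bm("weights must be non-negative")
    if (sum(w) <= 0) stop_bm("weights must not all be zero")
    w <- w / sum(w)
  }
  structure(list(
    biomarker_id = biomarker_id,
    n_publications = length(scores),
    category_scores = cat_means,
    amended_clinical_utility = amended_cu,
    total_percent = 100 * sum(w * used),
    sub_category_scores = sc_means,
    weights = w),
    class = "bm_biomarker_score")
}

#' @export
print.bm_biomarker_score <- function(x, ...) {
  cat(sprintf("<bm_biomarker_score> %s (%d publication%s)\n",
              x$biomarker_id, x$n_publications,
              if (x$n_publications == 1) "" else "s"))
  print(round(x$category_scores, 4))
  cat(sprintf("  amended clinical utility: %.4f\n",
              x$amended_clinical_utility))
  cat(sprintf("  total score: %.2f%%\n", x$total_percent))
  invisible(x)
}

#' Rank a biomarker's reporting gaps by sub-category
#'
#' Returns the lowest-scoring sub-categories for a biomarker — a roadmap
#' of where its evidence base is thinnest. Sub-categories are sorted
#' ascending by mean score, ties broken by category order (analytical
#' validity, clinical validity, clinical utility, rationale) then by
#' label, so the ordering is deterministic.
#'
#' @param summary A `bm_biomarker_score` (must retain per-sub-category
#'   means, as produced by [aggregate_biomarker()]).
#' @param checklist The `bm_checklist` the scores were computed against.
#' @param worst_n Maximum number of rows to return; if it exceeds the
#'   number of gap sub-categories, all are returned.
#' @param threshold Only sub-categories with mean score strictly below
#'   this value count as gaps (default 1, i.e. anything short of complete
#'   reporting).
#' @return data.frame with columns `sub_category`, `label`, `category`,
#'   `mean_score`, ordered worst first.
#' @export
gap_report <- function(summary, checklist, worst_n = 10L, threshold = 1) {
  if (!inherits(summary, "bm_biomarker_score"))
    stop_bm("summary must be a bm_biomarker_score")
  validate_checklist(checklist)
  sc <- checklist$sub_categories
  means <- summary$sub_category_scores[sc$id]
  df <- data.frame(sub_category = sc$id, label = sc$label,
                   category = sc$category,
                   mean_score = as.numeric(means),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$mean_score) & df$mean_score < threshold, , drop = FALSE]
  ord <- order(df$mean_score,
               match(df$category, bm_categories()),
               df$label)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  head(df, n = min(worst_n, nrow(df)))
}

#' Score a whole corpus sheet
#'
#' Vectorised scoring of a tabular corpus: one row per publication, one
#' column per attribute, aggregated to one summary per biomarker. This is
#' the table-level counterpart of [score_publication()] +
#' [aggregate_biomarker()] and produces identical numbers.
#'
#' @param sheet data.frame with columns `pub_id`, `biomarker_id`,
#'   optionally `study_type` and `year`, and one 0/1/`NA` column per
#'   scored attribute. Attribute columns must be a subset of the
#'   checklist's ids; attributes without a column score 0.
#' @param checklist A `bm_checklist`.
#' @param inventory Optional data.frame with a `biomarker_id` column and
#'   one logical/0-1 column per non-clinical study type (see
#'   [bm_study_types()]); biomarkers absent from it get an empty
#'   inventory.
#' @param na_policy,weights,include_rationale,amendment_weight,amendable_types
#'   As in [score_publication()] and [aggregate_biomarker()].
#' @return data.frame, one row per biomarker: `biomarker_id`,
#'   `n_publications`, the four category means, `clinical_utility_amended`
#'   and `total_percent`; the underlying `bm_biomarker_score` objects are
#'   attached as attribute `"summaries"` (named list).
#' @export
score_corpus <- function(sheet, checklist, inventory = NULL,
                         na_policy = c("as_zero", "exclude"),
                         weights = NULL, include_rationale = FALSE,
                         amendment_weight = 0.5,
                         amendable_types = bm_amendable_types()) {
  na_policy <- match.arg(na_policy)
  validate_checklist(checklist)
  meta_cols <- intersect(c("pub_id", "biomarker_id", "study_type", "year"),
                         names(sheet))
  if (!all(c("pub_id", "biomarker_id") %in% meta_cols))
    stop_bm("sheet must have 'pub_id' and 'biomarker_id' columns")
  attr_cols <- setdiff(names(sheet), meta_cols)
  unknown <- setdiff(attr_cols, checklist$attributes$id)
  if (length(unknown))
    stop_bm("sheet column(s) not in checklist: ",
            paste(unknown, collapse = ", "))
  ids <- checklist$attributes$id
  M <- matrix(0, nrow = nrow(sheet), ncol = length(ids),
              dimnames = list(sheet$pub_id, ids))
  if (length(attr_cols)) {
    vals <- as.matrix(sheet[, attr_cols, drop = FALSE])
    storage.mode(vals) <- "double"
    if (any(!is.na(vals) & !vals %in% c(0, 1)))
      stop_bm("sheet indicators must be 0, 1 or NA")
    M[, attr_cols] <- vals
  }
  if (na_policy == "as_zero") M[is.na(M)] <- 0

  cats <- attribute_categories(checklist)
  sc_f <- factor(checklist$attributes$sub_category,
                 levels = checklist$sub_categories$id)
  group_means <- function(mat, f) {
    G <- outer(f, levels(f), `==`) * 1          # attrs x groups
    num <- ifelse(is.na(mat), 0, mat) %*% G
    den <- (!is.na(mat)) %*% G
    out <- num / den
    colnames(out) <- levels(f)
    out
  }
  cat_scores <- group_means(M, cats)            # pubs x 4
  sc_scores <- group_means(M, sc_f)             # pubs x n_subcat

  inv_of <- function(bm) {
    if (is.null(inventory)) return(character())
    row <- inventory[inventory$biomarker_id == bm, , drop = FALSE]
    if (nrow(row) == 0L) return(character())
    types <- intersect(names(row), bm_study_types())
    types[vapply(row[1, types], function(v) isTRUE(as.logical(v)), TRUE)]
  }
  bms <- unique(sheet$biomarker_id)
  summaries <- lapply(bms, function(bm) {
    rows <- which(sheet$biomarker_id == bm)
    pub_scores <- lapply(rows, function(i) {
      structure(list(category_scores = cat_scores[i, ],
                     sub_category_scores = sc_scores[i, ],
                     na_policy = na_policy),
                class = "bm_publication_score")
    })
    aggregate_biomarker(pub_scores, present = inv_of(bm),
                        weights = weights,
                        include_rationale = include_rationale,
                        amendment_weight = amendment_weight,
                        amendable_types = amendable_types,
                        biomarker_id = bm)
  })
  names(summaries) <- bms
  out <- data.frame(
    biomarker_id = bms,
    n_publications = vapply(summaries, `[[`, 0L, "n_publications"),
    analytical_validity = vapply(summaries, function(s)
      s$category_scores[["analytical_validity"]], 0),
    clinical_validity = vapply(summaries, function(s)
      s$category_scores[["clinical_validity"]], 0),
    clinical_utility = vapply(summaries, function(s)
      s$category_scores[["clinical_utility"]], 0),
    rationale = vapply(summaries, function(s)
      s$category_scores[["rationale"]], 0),
    clinical_utility_amended = vapply(summaries, `[[`, 0,
                                      "amended_clinical_utility"),
    total_percent = vapply(summaries, `[[`, 0, "total_percent"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summaries") <- summaries
  out
}

#' Read a scoring sheet or study-type inventory
#'
#' `read_scoring_sheet()` reads a delimited scoring sheet (header row of
#' attribute ids plus `pub_id`, `biomarker_id`, `study_type`, `year`;
#' cells 0/1/NA) and, when a checklist is supplied, rejects unknown
#' attribute columns before any scoring. `read_inventory()` reads a
#' per-biomarker study-type presence table.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @param checklist Optional `bm_checklist` used to validate attribute
#'   columns.
#' @return data.frame.
#' @export
read_scoring_sheet <- function(path, checklist = NULL) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  sheet <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!is.null(checklist)) {
    meta <- c("pub_id", "biomarker_id", "study_type", "year")
    unknown <- setdiff(setdiff(names(sheet), meta),
                       checklist$attributes$id)
    if (length(unknown))
      stop_bm("sheet column(s) not in checklist: ",
              paste(unknown, collapse = ", "))
  }
  sheet
}

#' @rdname read_scoring_sheet
#' @export
read_inventory <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  inv <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!"biomarker_id" %in% names(inv))
    stop_bm("inventory must have a 'biomarker_id' column")
  inv
}
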