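#' Construct a biomarker checklist
#'
#' A checklist is the hierarchical roster all scoring depends on:
#' attributes, grouped into sub-categories, each sub-category belonging to
#' one of the four main categories (see [bm_categories()]). The object is
#' versioned and carries a revision log so consensus-driven edits stay
#' auditable.
#'
#' @param attributes data.frame with columns `id` (unique token), `label`
#'   (free text), `sub_category` (token referencing `sub_categories$id`),
#'   and optionally `source` (one of `"literature"`, `"interview"`,
#'   `"guideline"`; default `"literature"`) and `active` (logical, default
#'   `TRUE`).
#' @param sub_categories data.frame with columns `id`, `label`, `category`
#'   (one of [bm_categories()]).
#' @param version Version string.
#' @param revision_log List of prior revision records (see
#'   [apply_revision()]); usually empty for a new checklist.
#'
#' @return An object of class `bm_checklist`.
#' @seealso [read_checklist()], [category_composition()],
#'   [apply_revision()], [initial_checklist()]
#' @export
#' @examples
#' cl <- checklist(
#'   attributes = data.frame(
#'     id = c("a1", "a2", "a3", "a4"),
#'     label = paste("attribute", 1:4),
#'     sub_category = c("s1", "s1", "s2", "s3")
#'   ),
#'   sub_categories = data.frame(
#'     id = c("s1", "s2", "s3"),
#'     label = c("Assay validation", "Reference standard", "Feasibility"),
#'     category = c("analytical_validity", "clinical_validity",
#'                  "clinical_utility")
#'   )
#' )
#' category_composition(cl)
checklist <- function(attributes, sub_categories, version = "1",
                      revision_log = list()) {
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  sub_categories <- as.data.frame(sub_categories, stringsAsFactors = FALSE)
  if (is.null(attributes$source))
    attributes$source <- rep("literature", nrow(attributes))
  if (is.null(attributes$active))
    attributes$active <- rep(TRUE, nrow(attributes))
  need_a <- c("id", "label", "sub_category", "source", "active")
  need_s <- c("id", "label", "category")
  miss_a <- setdiff(need_a, names(attributes))
  miss_s <- setdiff(need_s, names(sub_categories))
  if (length(miss_a))
    stop_bm("attributes is missing column(s): ", paste(miss_a, collapse = ", "))
  if (length(miss_s))
    stop_bm("sub_categories is missing column(s): ",
            paste(miss_s, collapse = ", "))
  x <- structure(
    list(version = as.character(version),
         attributes = attributes[, need_a],
         sub_categories = sub_categories[, need_s],
         revision_log = revision_log),
    class = "bm_checklist")
  validate_checklist(x)
}

#' Validate a checklist
#'
#' Enforces the structural invariants: unique attribute and sub-category
#' ids, every attribute referencing an existing sub-category, sub-category
#' categories drawn from the four main categories, no empty category and no
#' empty sub-category (a sub-category may become empty only through
#' [apply_revision()], which then drops it).
#'
#' @param x A `bm_checklist`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error listing
#'   every violation found.
#' @export
validate_checklist <- function(x) {
  if (!inherits(x, "bm_checklist")) stop_bm("not a bm_checklist object")
  a <- x$attributes; s <- x$sub_categories
  problems <- character()
  dup_a <- unique(a$id[duplicated(a$id)])
  if (length(dup_a))
    problems <- c(problems, paste0("duplicate attribute id(s): ",
                                   paste(dup_a, collapse = ", ")))
  dup_s <- unique(s$id[duplicated(s$id)])
  if (length(dup_s))
    problems <- c(problems, paste0("duplicate sub-category id(s): ",
                                   paste(dup_s, collapse = ", ")))
  bad_cat <- unique(s$category[!s$category %in% bm_categories()])
  if (length(bad_cat))
    problems <- c(problems, paste0("unknown category: ",
                                   paste(bad_cat, collapse = ", ")))
  dangling <- a$id[!a$sub_category %in% s$id]
  if (length(dangling))
    problems <- c(problems,
                  paste0("attribute(s) referencing unknown sub-category: ",
                         paste(dangling, collapse = ", ")))
  if (nrow(a) == 0L) problems <- c(problems, "checklist has no attributes")
  empty_sc <- setdiff(s$id, a$sub_category)
  if (length(empty_sc))
    problems <- c(problems, paste0("empty sub-category(ies): ",
                                   paste(empty_sc, collapse = ", ")))
  if (nrow(a) > 0L) {
    cat_of <- s$category[match(a$sub_category, s$id)]
    empty_cat <- setdiff(bm_categories(), cat_of)
    if (length(empty_cat))
      problems <- c(problems, paste0("empty category(ies): ",
                                     paste(empty_cat, collapse = ", ")))
  }
  if (length(problems))
    stop_bm("invalid checklist:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(x)
}

# category of each attribute, as a factor ordered by bm_categories()
attribute_categories <- function(x) {
  factor(x$sub_categories$category[match(x$attributes$sub_category,
                                         x$sub_categories$id)],
         levels = bm_categories())
}

#' Read a checklist definition document
#'
#' Parses a structured-text checklist definition (YAML or strict JSON) with
#' top-level keys `version`, `sub_categories` and `attributes` (an optional
#' `revision_log` is preserved). Each sub-category entry carries `id`,
#' `label`, `category`; each attribute entry carries `id`, `label`,
#' `sub_category` and optionally `source` and `active`. The document is
#' schema-checked and the resulting checklist fully validated.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param format `"auto"` (by extension, the default), `"yaml"` or
#'   `"json"`.
#' @return A validated `bm_checklist`.
#' @seealso [write_checklist()] for the inverse; the round trip is
#'   lossless.
#' @export
read_checklist <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "yaml"
  }
  doc <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  checklist_from_document(doc)
}

checklist_from_document <- function(doc) {
  for (key in c("version", "sub_categories", "attributes")) {
    if (is.null(doc[[key]]))
      stop_bm("checklist document is missing required key '", key, "'")
  }
  row_bind <- function(entries, need, optional = character()) {
    lapply(seq_along(entries), function(i) {
      e <- entries[[i]]
      miss <- setdiff(need, names(e))
      if (length(miss))
        stop_bm("entry ", i, " is missing key(s): ",
                paste(miss, collapse = ", "))
      as.data.frame(e[c(need, intersect(optional, names(e)))],
                    stringsAsFactors = FALSE)
    })
  }
  sc <- do.call(rbind, row_bind(doc$sub_categories,
                                c("id", "label", "category")))
  at_rows <- lapply(seq_along(doc$attributes), function(i) {
    e <- doc$attributes[[i]]
    miss <- setdiff(c("id", "label", "sub_category"), names(e))
    if (length(miss))
      stop_bm("attribute entry ", i, " is missing key(s): ",
              paste(miss, collapse = ", "))
    data.frame(id = e$id, label = e$label, sub_category = e$sub_category,
               source = e$source %||% "literature",
               active = e$active %||% TRUE, stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, at_rows)
  checklist(at, sc, version = doc$version,
            revision_log = doc$revision_log %||% list())
}

checklist_to_document <- function(x) {
  list(
    version = x$version,
    sub_categories = lapply(seq_len(nrow(x$sub_categories)), function(i)
      as.list(x$sub_categories[i, ])),
    attributes = lapply(seq_len(nrow(x$attributes)), function(i)
      as.list(x$attributes[i, ])),
    revision_log = x$revision_log)
}

#' Write a checklist definition document
#'
#' @param x A `bm_checklist`.
#' @param path Output path; extension selects YAML (default) or JSON unless
#'   `format` is given.
#' @param format `"auto"`, `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(x, path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  validate_checklist(x)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "yaml"
  }
  doc <- checklist_to_document(x)
  if (format == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Summarise checklist composition by category
#'
#' Counts attributes per main category and expresses each count as a
#' percentage share of the total, rounded half-up to 2 decimal places
#' (shares therefore sum to 100 within rounding).
#'
#' @param x A `bm_checklist`.
#' @return A `bm_composition` data.frame with columns `category`,
#'   `n_attributes`, `share` (percent, 2 dp), and attributes
#'   `total_attributes` and `n_sub_categories`.
#' @export
#' @examples
#' category_composition(initial_checklist())
category_composition <- function(x) {
  validate_checklist(x)
  cats <- attribute_categories(x)
  counts <- as.integer(table(cats))
  total <- nrow(x$attributes)
  out <- data.frame(
    category = bm_categories(),
    n_attributes = counts,
    share = round_half_up(100 * counts / total, 2),
    stringsAsFactors = FALSE)
  structure(out, class = c("bm_composition", "data.frame"),
            total_attributes = total,
            n_sub_categories = nrow(x$sub_categories),
            version = x$version)
}

#' @export
print.bm_composition <- function(x, ...) {
  cat(sprintf("Checklist composition (version %s): %d attributes in %d sub-categories\n",
              attr(x, "version"), attr(x, "total_attributes"),
              attr(x, "n_sub_categories")))
  df <- as.data.frame(x)
  df$share <- sprintf("%.2f%%", df$share)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Revise a checklist
#'
#' Applies a revision (e.g. attributes added after expert interviews,
#' attributes removed after a Delphi survey) and records it in the
#' revision log. Sub-categories left empty by removals are dropped from
#' the sub-category roster, so the sub-category count reflects only
#' populated sub-categories.
#'
#' @param x A `bm_checklist`.
#' @param additions data.frame of new attributes (same columns as
#'   `checklist()`'s `attributes`), or `NULL`.
#' @param removals Character vector of attribute ids to remove.
#' @param reason Free-text reason recorded in the revision log.
#' @param version New version string; by default the old version with a
#'   revision suffix appended.
#' @return A new validated `bm_checklist`.
#' @export
#' @examples
#' cl <- initial_checklist()
#' nrow(cl$attributes)                     # 129
#' v1 <- toolkit_v1()                      # +3 interview, -6 Delphi-failed
#' nrow(v1$attributes)                     # 126
apply_revision <- function(x, additions = NULL, removals = character(),
                           reason = "", version = NULL) {
  validate_checklist(x)
  a <- x$attributes
  removals <- as.character(removals)
  missing_rm <- setdiff(removals, a$id)
  if (length(missing_rm))
    stop_bm("cannot remove non-existent attribute id(s): ",
            paste(missing_rm, collapse = ", "))
  add_ids <- character()
  if (!is.null(additions) && nrow(as.data.frame(additions)) > 0) {
    additions <- as.data.frame(additions, stringsAsFactors = FALSE)
    if (is.null(additions$source)) additions$source <- "interview"
    if (is.null(additions$active)) additions$active <- TRUE
    add_ids <- additions$id
    clash <- intersect(add_ids, setdiff(a$id, removals))
    if (length(clash))
      stop_bm("cannot add duplicate attribute id(s): ",
              paste(clash, collapse = ", "))
    bad_sc <- setdiff(additions$sub_category, x$sub_categories$id)
    if (length(bad_sc))
      stop_bm("addition(s) reference unknown sub-category: ",
              paste(bad_sc, collapse = ", "))
    a <- rbind(a[, c("id", "label", "sub_category", "source", "active")],
               additions[, c("id", "label", "sub_category", "source",
                             "active")])
  }
  a <- a[!a$id %in% removals, , drop = FALSE]
  sc <- x$sub_categories
  sc <- sc[sc$id %in% a$sub_category, , drop = FALSE]
  log_entry <- list(added = add_ids, removed = removals, reason = reason)
  version <- version %||%
    paste0(x$version, "+r", length(x$revision_log) + 1L)
  checklist(a, sc, version = version,
            revision_log = c(x$revision_log, list(log_entry)))
}

#' @export
print.bm_checklist <- function(x, ...) {
  comp <- category_composition(x)
  cat(sprintf("<bm_checklist> version %s\n", x$version))
  cat(sprintf("  %d attributes, %d sub-categories, %d revision(s)\n",
              attr(comp, "total_attributes"), attr(comp, "n_sub_categories"),
              length(x$revision_log)))
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  %-20s %3d (%6.2f%%)\n", comp$category[i],
                comp$n_attributes[i], comp$share[i]))
  invisible(x)
}
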