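# Reference checklists with the canonical topology: 48 sub-categories in
# four categories, attribute counts 51/49/25/4 (total 129) before revision
# and 126 in 47 sub-categories after. Attribute labels are synthetic
# placeholders (the topology, not the wording, is what scoring depends
# on); users supply real labels through a definition document.

reference_sub_categories <- function() {
  av <- c("Analytical Modelling",
          "Specimen Anatomical or Collection Site",
          "Assay Validation/Precision/Reproducibility/Accuracy",
          "Quality Assurance of Reagents",
          "Study specifies the assay method used",
          "Study states whether Assay is Validated/Standardised/Optimised",
          "Bio-specimen Matrix/Type",
          "Biospecimen Collection",
          "Biospecimen Inclusion/Exclusion Criteria",
          "Biospecimen Quality",
          "Cell Culture",
          "Experimental Animal Details",
          "Experimental Procedure Description",
          "Mechanism of Stabilization",
          "Sample Pre-processing",
          "Storage/Shipping Transport",
          "Time between Diagnosis and Sampling")
  cv <- c("Adverse Events",
          "Vital state of Biospecimen",
          "Analytical Modelling (clinical)",
          "Blinding",
          "Experimental Outcomes",
          "Intervention",
          "Missing Data",
          "Methodology Details",
          "Patient Eligibility",
          "Reported Pre-specified Hypothesis",
          "Randomisation",
          "Reference Standard",
          "Sample size Calculation",
          "Sensitivity/Specificity",
          "Statistical Modelling",
          "Trial Design Description")
  cu <- c("Authority/Guideline Approval",
          "Decisional Analysis",
          "Cost-effectiveness",
          "Ethics",
          "Feasibility/BM Implementation",
          "Funding",
          "Harms and Toxicology",
          "Invasiveness",
          "Human Factor",
          "Biomarker Usefulness",
          "Study Type")
  ra <- c("Identify the unmet clinical need for specific disease",
          "Verify biomarker unmet need - is there an existing solution?",
          "Pre-specified hypothesis/Exploratory discovery",
          "Unmet need for the specified BM type")
  data.frame(
    id = sprintf("sc%02d", seq_len(48)),
    label = c(av, cv, cu, ra),
    category = rep(bm_categories(), times = c(17L, 16L, 11L, 4L)),
    stringsAsFactors = FALSE)
}

# Attributes per sub-category chosen so category totals are 51/49/25/4:
#  - analytical validity: 3 per sub-category, except 4 under assay
#    validation (sc03) and experimental procedure (sc13) and a single
#    attribute under experimental animal details (sc12);
#  - clinical validity: 3 each, 4 under reference standard (sc29);
#  - clinical utility: 2 each, 3 under guideline approval (sc34),
#    cost-effectiveness (sc36) and feasibility (sc38);
#  - rationale: 1 each.
reference_attribute_counts <- function() {
  n <- c(rep(3L, 17L), rep(3L, 16L), rep(2L, 11L), rep(1L, 4L))
  names(n) <- sprintf("sc%02d", seq_len(48))
  n[c("sc03", "sc13", "sc29")] <- 4L
  n["sc12"] <- 1L
  n[c("sc34", "sc36", "sc38")] <- 3L
  n
}

#' Reference checklist before revision (129 attributes)
#'
#' Builds the pre-revision reference checklist: 129 attributes in 48
#' sub-categories, with 51 attributes under analytical validity, 49 under
#' clinical validity, 25 under clinical utility and 4 under rationale.
#' Attribute labels are synthetic placeholders carrying the sub-category
#' name; the topology (counts and grouping) is the meaningful content.
#'
#' @return A `bm_checklist`, version `"0-initial"`.
#' @seealso [toolkit_v1()] for the post-revision checklist,
#'   [delphi_fixture()] for the consensus data driving the revision.
#' @export
initial_checklist <- function() {
  sc <- reference_sub_categories()
  counts <- reference_attribute_counts()
  sub_category <- rep(sc$id, times = counts[sc$id])
  k <- unlist(lapply(counts[sc$id], seq_len), use.names = FALSE)
  at <- data.frame(
    id = sprintf("attr%03d", seq_along(sub_category)),
    label = sprintf("%s - item %d (synthetic label)",
                    sc$label[match(sub_category, sc$id)], k),
    sub_category = sub_category,
    source = "literature",
    stringsAsFactors = FALSE)
  checklist(at, sc, version = "0-initial")
}

#' Attributes added after expert interviews
#'
#' The three attributes contributed by semi-structured expert interviews:
#' automated (machine-learning) biomarker assessment, applicability to
#' family members, and reimbursement — grouped under the existing
#' feasibility/implementation, human-factor and cost-effectiveness
#' sub-categories respectively.
#'
#' @return data.frame of three attributes with `source = "interview"`.
#' @export
interview_attributes <- function() {
  data.frame(
    id = c("attr130", "attr131", "attr132"),
    label = c("Use of machine learning to automate biomarker assessment",
              "Biomarker applicable to a close member of the family",
              "Ability of the biomarker to be reimbursed"),
    sub_category = c("sc38", "sc42", "sc36"),
    source = "interview",
    active = TRUE,
    stringsAsFactors = FALSE)
}

# Delphi fixture design: 51 voted items (one representative attribute per
# sub-category plus the three interview additions), of which 8 fall below
# the 0.75 agreement threshold in round 1; 2 of the 8 recover in round 2
# and 6 are removed. Which items fail is not dictated by the science, so
# the fixture designates them deterministically; the removals include the
# sole attribute of one sub-category (experimental animal details) so the
# revised roster has 47 populated sub-categories.
delphi_fixture_items <- function() {
  cl <- initial_checklist()
  first_of_sc <- cl$attributes$id[!duplicated(cl$attributes$sub_category)]
  c(first_of_sc, interview_attributes()$id)
}

delphi_removed_ids <- function() {
  cl <- initial_checklist()
  first_of <- function(sc) cl$attributes$id[cl$attributes$sub_category == sc][1L]
  vapply(c("sc12", "sc01", "sc05", "sc20", "sc24", "sc40"), first_of, "")
}

delphi_round2_survivors <- function() {
  cl <- initial_checklist()
  first_of <- function(sc) cl$attributes$id[cl$attributes$sub_category == sc][1L]
  vapply(c("sc07", "sc31"), first_of, "")
}

#' Two-round Delphi voting fixture
#'
#' Deterministic voting fixture for the two-round consensus procedure:
#' 51 items voted by 51 participants. In round 1, 43 items reach the 75%
#' agreement threshold (consensus rate 84.31%) and 8 are carried into
#' round 2, where 2 recover and 6 are removed. The removed ids are exactly
#' those whose removal (together with the interview additions) turns the
#' 129-attribute checklist into the 126-attribute [toolkit_v1()].
#'
#' @return List with `round1` and `round2` (both [delphi_responses()]
#'   objects).
#' @export
#' @examples
#' fx <- delphi_fixture()
#' run_round(fx$round1)$consensus_rate   # 84.31
delphi_fixture <- function() {
  items <- delphi_fixture_items()
  carried <- c(delphi_removed_ids(), delphi_round2_survivors())
  n_part <- 51L
  vote_block <- function(item_ids, n_agree) {
    m <- matrix(0L, nrow = n_part, ncol = length(item_ids),
                dimnames = list(sprintf("p%02d", seq_len(n_part)), item_ids))
    m[seq_len(n_agree), ] <- 1L
    m
  }
  pass1 <- setdiff(items, carried)
  r1 <- cbind(vote_block(pass1, 48L), vote_block(carried, 30L))
  r1 <- r1[, items, drop = FALSE]          # original item order
  r2 <- cbind(vote_block(delphi_round2_survivors(), 40L),
              vote_block(delphi_removed_ids(), 25L))
  list(round1 = delphi_responses(r1, round = 1L),
       round2 = delphi_responses(r2, round = 2L))
}

#' Reference checklist after revision (126 attributes)
#'
#' Applies the consensus-driven revision to [initial_checklist()]: the
#' three interview attributes are added and the six attributes that failed
#' both Delphi rounds are removed, yielding 126 attributes in 47
#' sub-categories (one sub-category is emptied by the removals and
#' dropped).
#'
#' @return A `bm_checklist`, version `"1.0"`.
#' @export
toolkit_v1 <- function() {
  apply_revision(initial_checklist(),
                 additions = interview_attributes(),
                 removals = unname(delphi_removed_ids()),
                 reason = "expert interviews (+3); Delphi round-2 failures (-6)",
                 version = "1.0")
}
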