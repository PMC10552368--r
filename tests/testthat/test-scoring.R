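toy_checklist <- function() {
  sc <- data.frame(
    id = c("av1", "av2", "cv1", "cu1", "ra1"),
    label = c("assay validation", "specimen handling", "trial design",
              "cost-effectiveness", "unmet need"),
    category = c("analytical_validity", "analytical_validity",
                 "clinical_validity", "clinical_utility", "rationale"))
  at <- data.frame(
    id = sprintf("a%02d", 1:10),
    label = sprintf("attribute %d", 1:10),
    sub_category = c("av1", "av1", "av2", "av2", "cv1", "cv1", "cv1",
                     "cu1", "cu1", "ra1"))
  checklist(at, sc)
}

test_that("publication scoring is a flat mean over category attributes", {
  cl <- toy_checklist()
  # 3 of the 4 analytical-validity attributes reported
  s <- score_publication(c(a01 = 1, a02 = 1, a03 = 1, a04 = 0), cl)
  expect_equal(s$category_scores[["analytical_validity"]], 0.75)
  expect_equal(s$sub_category_scores[["av1"]], 1)
  expect_equal(s$sub_category_scores[["av2"]], 0.5)
  # unreported attributes count as zero
  expect_equal(s$category_scores[["clinical_validity"]], 0)

  ids <- cl$attributes$id
  all1 <- score_publication(setNames(rep(1, 10), ids), cl)
  expect_equal(unname(all1$category_scores), rep(1, 4))
  all0 <- score_publication(setNames(numeric(0), character(0)), cl)
  expect_equal(unname(all0$category_scores), rep(0, 4))

  expect_error(score_publication(c(zz = 1), cl), "unknown attribute.*zz")
  expect_error(score_publication(c(a01 = 2), cl), "0, 1 or NA")
})

test_that("NA indicators follow the chosen policy", {
  cl <- toy_checklist()
  ind <- c(a01 = 1, a02 = NA, a03 = 0, a04 = 0)
  expect_equal(
    score_publication(ind, cl, "as_zero")$category_scores[["analytical_validity"]],
    0.25)
  expect_equal(
    score_publication(ind, cl, "exclude")$category_scores[["analytical_validity"]],
    1 / 3)
})

test_that("clinical-utility amendment is convex, bounded and monotone", {
  # no additional study types: score unchanged
  expect_equal(amend_clinical_utility(0.42, character()), 0.42)
  # half-weight, three of six types present
  expect_equal(amend_clinical_utility(0.6, c("cost_effectiveness",
                                             "feasibility",
                                             "human_factor")), 0.7)
  # full weight and all types present saturates at 1
  expect_equal(amend_clinical_utility(0.13, bm_amendable_types(),
                                      weight = 1), 1)
  # clinical and analytical-validation studies never amend
  expect_equal(amend_clinical_utility(0.5, c("clinical",
                                             "analytical_validation")),
               0.5)
  # monotone in the number of present types, always within [base, 1]
  types <- bm_amendable_types()
  vals <- vapply(0:6, function(k)
    amend_clinical_utility(0.3, types[seq_len(k)]), 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0.3 & vals <= 1))
  # zero weight disables the amendment
  expect_equal(amend_clinical_utility(0.3, types, weight = 0), 0.3)
  expect_error(amend_clinical_utility(0.5, "clinical",
                                      amendable_types = character()),
               "non-empty")
  expect_error(amend_clinical_utility(0.5, "spectroscopy"),
               "unknown study type")
})

test_that("biomarker aggregation averages publications then amends once", {
  cl <- toy_checklist()
  mk <- function(av, cv, cu) {
    # construct a publication score with prescribed category values
    structure(list(
      category_scores = c(analytical_validity = av,
                          clinical_validity = cv, clinical_utility = cu,
                          rationale = 0),
      sub_category_scores = c(av1 = av, av2 = av, cv1 = cv, cu1 = cu,
                              ra1 = 0),
      na_policy = "as_zero"), class = "bm_publication_score")
  }
  # two publications, AV 0.4/0.8, CV 0.5/0.5, CU 0, no study types:
  # total = 100 * (0.6 + 0.5 + 0) / 3
  agg <- aggregate_biomarker(list(mk(0.4, 0.5, 0), mk(0.8, 0.5, 0)))
  expect_equal(agg$total_percent, 100 * (0.6 + 0.5 + 0) / 3,
               tolerance = 1e-12)
  expect_equal(round(agg$total_percent, 2), 36.67)

  # explicit equal weights give exactly the unweighted total
  agg_w <- aggregate_biomarker(list(mk(0.4, 0.5, 0), mk(0.8, 0.5, 0)),
                               weights = c(analytical_validity = 1 / 3,
                                           clinical_validity = 1 / 3,
                                           clinical_utility = 1 / 3))
  expect_identical(agg_w$total_percent, agg$total_percent)

  # all categories complete with full inventory: 100%
  full <- aggregate_biomarker(list(mk(1, 1, 1)),
                              present = bm_amendable_types())
  expect_equal(full$total_percent, 100)

  # publication order never matters
  set.seed(11)
  pubs <- list(mk(0.2, 0.9, 0.1), mk(0.7, 0.3, 0.5), mk(1, 0, 0))
  a1 <- aggregate_biomarker(pubs, present = "feasibility")
  a2 <- aggregate_biomarker(pubs[c(3, 1, 2)], present = "feasibility")
  expect_equal(a1$total_percent, a2$total_percent)
  expect_equal(a1$category_scores, a2$category_scores)

  expect_error(aggregate_biomarker(list()), "at least one")
})

test_that("scores never decrease when an indicator flips 0 to 1", {
  set.seed(303)
  for (i in 1:25) {
    cl <- random_checklist()
    ind <- random_indicators(cl)
    zeros <- names(ind)[ind == 0]
    if (length(zeros) == 0) next
    flip <- sample(zeros, 1)
    ind2 <- ind; ind2[flip] <- 1
    s1 <- score_publication(ind, cl)
    s2 <- score_publication(ind2, cl)
    expect_true(all(s2$category_scores >= s1$category_scores))
    expect_true(all(s2$sub_category_scores >= s1$sub_category_scores))
    a1 <- aggregate_biomarker(list(s1))
    a2 <- aggregate_biomarker(list(s2))
    expect_gte(a2$total_percent, a1$total_percent)
  }
})

test_that("gap report ranks sub-categories worst-first, deterministically", {
  cl <- toy_checklist()
  mk_sc <- function(vals) {
    structure(list(
      category_scores = c(analytical_validity = mean(vals[1:2]),
                          clinical_validity = vals[3],
                          clinical_utility = vals[4],
                          rationale = vals[5]),
      sub_category_scores = setNames(vals,
                                     c("av1", "av2", "cv1", "cu1", "ra1")),
      na_policy = "as_zero"), class = "bm_publication_score")
  }
  agg <- aggregate_biomarker(list(mk_sc(c(0.9, 0.5, 0.2, 1, 1))))
  g <- gap_report(agg, cl, worst_n = 2)
  expect_equal(g$sub_category, c("cv1", "av2"))
  expect_equal(g$mean_score, c(0.2, 0.5))

  # everything complete: no gaps below the threshold of 1
  expect_equal(nrow(gap_report(aggregate_biomarker(list(mk_sc(rep(1, 5)))),
                               cl)), 0L)
  # a single zero sub-category ranks first even with worst_n too large
  g2 <- gap_report(aggregate_biomarker(list(mk_sc(c(1, 1, 1, 0, 1)))),
                   cl, worst_n = 99)
  expect_equal(g2$sub_category[1], "cu1")
  # ties broken by category order then label
  g3 <- gap_report(aggregate_biomarker(list(mk_sc(c(0.5, 1, 0.5, 0.5, 1)))),
                   cl, worst_n = 3)
  expect_equal(g3$sub_category, c("av1", "cv1", "cu1"))
})

test_that("sheet-level scoring agrees with per-publication scoring", {
  set.seed(99)
  cl <- toolkit_v1()
  sheet <- toy_sheet(cl, n_pubs = 8, n_bm = 2)
  inv <- data.frame(biomarker_id = c("bm01", "bm02"),
                    cost_effectiveness = c(1, 0), feasibility = c(1, 0),
                    human_factor = c(0, 0), implementation = c(1, 0),
                    decisional_analysis = c(0, 0),
                    clinical_usefulness = c(0, 0))
  tab <- score_corpus(sheet, cl, inv)
  for (bm in c("bm01", "bm02")) {
    rows <- which(sheet$biomarker_id == bm)
    pubs <- lapply(rows, function(i) {
      ind <- unlist(sheet[i, cl$attributes$id])
      score_publication(ind, cl)
    })
    types <- names(inv)[-1][unlist(inv[inv$biomarker_id == bm, -1]) == 1]
    ref <- aggregate_biomarker(pubs, present = types)
    expect_equal(tab$total_percent[tab$biomarker_id == bm],
                 ref$total_percent)
    expect_equal(tab$clinical_utility_amended[tab$biomarker_id == bm],
                 ref$amended_clinical_utility)
  }
  expect_error(score_corpus(cbind(sheet, bogus_attr = 1), cl),
               "not in checklist: bogus_attr")
})
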