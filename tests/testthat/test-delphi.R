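votes_matrix <- function(spec) {
  # spec: named list item -> c(n_agree, n_total)
  n <- max(vapply(spec, `[`, 0, 2))
  m <- matrix(NA_real_, nrow = n, ncol = length(spec),
              dimnames = list(NULL, names(spec)))
  for (it in names(spec)) {
    m[seq_len(spec[[it]][2]), it] <-
      rep(c(1, 0), c(spec[[it]][1], spec[[it]][2] - spec[[it]][1]))
  }
  m
}

test_that("item agreement is agree votes over votes cast", {
  r <- delphi_responses(votes_matrix(list(u = c(51, 51), v = c(3, 4))))
  expect_equal(item_agreement(r, "u"), 1)
  expect_equal(item_agreement(r, "v"), 0.75)
  expect_error(item_agreement(r, "w"), "unknown item")
  # an item with no votes at all is rejected at construction
  bad <- votes_matrix(list(u = c(2, 4)))
  bad <- cbind(bad, none = NA_real_)
  expect_error(delphi_responses(bad), "no votes: none")
})

test_that("a round partitions items at the inclusive threshold", {
  r <- delphi_responses(votes_matrix(list(
    exactly75 = c(3, 4), above = c(4, 4), below = c(2, 4))))
  out <- run_round(r, threshold = 0.75)
  expect_setequal(out$consensus_items, c("exactly75", "above"))
  expect_equal(out$carried_items, "below")
  expect_equal(out$consensus_rate, 66.67)

  unanimous <- run_round(delphi_responses(votes_matrix(list(
    a = c(5, 5), b = c(5, 5)))))
  expect_equal(unanimous$consensus_rate, 100)
  expect_length(unanimous$carried_items, 0L)

  all_pass <- run_round(r, threshold = 0)
  expect_length(all_pass$carried_items, 0L)

  # order of items and participants never changes the outcome
  v <- votes_matrix(list(a = c(3, 6), b = c(5, 6), c = c(6, 6)))
  o1 <- run_round(delphi_responses(v))
  o2 <- run_round(delphi_responses(v[sample(6), c("c", "a", "b")]))
  expect_equal(sort(o1$consensus_items), sort(o2$consensus_items))
  expect_equal(o1$consensus_rate, o2$consensus_rate)
})

test_that("two-round consensus retains and removes correctly", {
  r1 <- run_round(delphi_responses(votes_matrix(list(
    k1 = c(4, 4), k2 = c(4, 4), c1 = c(1, 4), c2 = c(1, 4),
    c3 = c(1, 4)))))
  r2 <- run_round(delphi_responses(votes_matrix(list(
    c1 = c(4, 4), c2 = c(1, 4), c3 = c(0, 4))), round = 2))
  res <- finalize_consensus(r1, r2)
  expect_setequal(res$retained, c("k1", "k2", "c1"))
  expect_setequal(res$removed, c("c2", "c3"))
  expect_equal(length(res$retained) + length(res$removed), 5L)
  expect_equal(res$audit$outcome[res$audit$item == "c1"], "retained")

  # all carried items failing round 2 -> removed = carried
  r2_fail <- run_round(delphi_responses(votes_matrix(list(
    c1 = c(0, 4), c2 = c(0, 4), c3 = c(0, 4))), round = 2))
  expect_setequal(finalize_consensus(r1, r2_fail)$removed,
                  c("c1", "c2", "c3"))

  # nothing carried: second round vacuous
  r1_all <- run_round(delphi_responses(votes_matrix(list(k = c(4, 4)))))
  res2 <- finalize_consensus(r1_all, NULL)
  expect_length(res2$removed, 0L)
  expect_equal(res2$retained, "k")

  # round 2 must only contain carried items
  r2_extra <- run_round(delphi_responses(votes_matrix(list(
    k1 = c(4, 4)))), threshold = 0.75)
  expect_error(finalize_consensus(r1, r2_extra), "not carried")
})

test_that("rank-derived weights invert median ranks and sum to one", {
  r <- matrix(rep(c(1, 2, 3), each = 5), nrow = 5,
              dimnames = list(NULL, c("analytical_validity",
                                      "clinical_validity",
                                      "clinical_utility")))
  w <- rank_weights(r)
  expect_equal(unname(w), c(3, 2, 1) / 6)
  expect_equal(sum(w), 1)

  # tied medians give equal weights
  r_tie <- rbind(c(1, 2), c(2, 1), c(1, 2), c(2, 1))
  colnames(r_tie) <- c("a", "b")
  expect_equal(unname(rank_weights(r_tie)), c(0.5, 0.5))

  # single category: weight 1
  one <- matrix(1, nrow = 3, ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(unname(rank_weights(one)), 1)

  # lower-median convention for even participant counts
  r_even <- rbind(c(1, 2), c(2, 1))
  colnames(r_even) <- c("a", "b")
  expect_equal(unname(rank_weights(r_even)), c(0.5, 0.5))

  # participant order is irrelevant
  set.seed(5)
  r_big <- t(replicate(9, sample(4)))
  colnames(r_big) <- bm_categories()
  expect_equal(rank_weights(r_big), rank_weights(r_big[sample(9), ]))

  bad <- rbind(c(1, 2, 3), c(1, 1, 3))
  colnames(bad) <- c("a", "b", "c")
  rownames(bad) <- c("p1", "p2")
  expect_error(rank_weights(bad), "participant p2")
})

test_that("rank weights feed aggregation and shift totals as expected", {
  cl <- toolkit_v1()
  ids <- cl$attributes$id
  cats <- cl$sub_categories$category[match(cl$attributes$sub_category,
                                           cl$sub_categories$id)]
  # AV fully reported, everything else absent
  ind <- setNames(as.numeric(cats == "analytical_validity"), ids)
  s <- score_publication(ind, cl)
  ranks <- matrix(rep(c(1, 2, 3), each = 7), nrow = 7,
                  dimnames = list(NULL, c("analytical_validity",
                                          "clinical_validity",
                                          "clinical_utility")))
  w <- rank_weights(ranks)
  weighted <- aggregate_biomarker(list(s), weights = w)
  equal <- aggregate_biomarker(list(s))
  # up-weighting the fully-reported category raises the total
  expect_gt(weighted$total_percent, equal$total_percent)
})
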