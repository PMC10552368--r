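test_that("exact Mann-Whitney matches known small-sample results", {
  out <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less",
                        mode = "exact")
  expect_equal(out$p_value, 1 / 20)
  expect_equal(out$u1, 0)

  # identical multisets: U1 = U2 = n1 n2 / 2, two-sided p = 1
  same <- mann_whitney_u(c(2, 2, 5), c(2, 2, 5), mode = "exact")
  expect_equal(same$u1, same$u2)
  expect_equal(same$u1, 9 / 2)
  expect_equal(same$p_value, 1)

  # fully separated 5 vs 5: two-sided p = 2/252
  sep <- mann_whitney_u(1:5, 6:10, mode = "exact")
  expect_equal(sep$p_value, 2 / 252)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  expect_error(mann_whitney_u(c(1, NA), 1:3), "free of NA")
})

test_that("exact p-values equal the enumeration oracle, ties included", {
  set.seed(21)
  for (rep in 1:40) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    # small alphabet forces heavy ties about half the time
    pool <- if (rep %% 2) runif(n1 + n2) else sample(1:4, n1 + n2, TRUE)
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    for (alt in c("two_sided", "less", "greater")) {
      expect_equal(mann_whitney_u(x, y, alt, mode = "exact")$p_value,
                   mwu_oracle(x, y, alt), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d alt=%s rep=%d",
                                  n1, n2, alt, rep))
    }
  }
})

test_that("tie-free exact tail agrees with the classical U distribution", {
  # cross-check against R's exact Wilcoxon distribution (no ties)
  set.seed(4)
  for (rep in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    mine <- mann_whitney_u(x, y, "less", mode = "exact")$p_value
    expect_equal(mine, stats::pwilcox(
      sum(rank(c(x, y))[1:n1]) - n1 * (n1 + 1) / 2, n1, n2),
      tolerance = 1e-12)
  }
})

test_that("normal approximation applies tie correction and continuity", {
  set.seed(8)
  x <- sample(1:5, 25, TRUE); y <- sample(2:6, 30, TRUE)
  mine <- mann_whitney_u(x, y, mode = "approx")
  expect_true(mine$tie_correction_applied)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # degenerate: every observation tied
  expect_equal(mann_whitney_u(rep(3, 4), rep(3, 5),
                              mode = "approx")$p_value, 1)
})

test_that("logistic association recovers a known slope and flags separation", {
  set.seed(31)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x))
  fit <- logistic_association(data.frame(score = x), y)
  row <- fit[fit$term == "score", ]
  expect_false(attr(fit, "separation"))
  expect_true(attr(fit, "converged"))
  expect_lt(abs(row$estimate - 1.5), 3 * row$se)
  expect_true(row$ci_lower <= row$estimate && row$estimate <= row$ci_upper)

  # covariate exactly balanced across classes: coefficient 0, p = 1
  y2 <- rep(0:1, each = 50)
  x2 <- rep(c(0, 1), 50)
  fit2 <- logistic_association(x2, y2)
  expect_equal(fit2$estimate[fit2$term == "x1"], 0, tolerance = 1e-8)
  expect_equal(fit2$p_value[fit2$term == "x1"], 1, tolerance = 1e-6)

  # perfect separation is flagged, not reported as a huge finite slope
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  ys <- rep(0:1, each = 20)
  expect_true(attr(logistic_association(xs, ys), "separation"))

  expect_error(logistic_association(rnorm(10), rep(1, 10)),
               "both classes")
})

test_that("Cox association matches a hand-maximised partial likelihood", {
  # three units, all events at distinct times, covariates 1/0/1:
  # the partial likelihood maximiser solves 2 e^{2b} = 1
  fit <- cox_association(c(1, 0, 1), time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(fit$estimate[1], -log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hazard_ratio[1], exp(-log(2) / 2), tolerance = 1e-6)

  # constant covariate: log-HR 0, HR 1
  cst <- cox_association(rep(2, 5), time = 1:5, event = c(1, 1, 0, 1, 0))
  expect_equal(cst$estimate[1], 0)
  expect_equal(cst$hazard_ratio[1], 1)

  expect_error(cox_association(rnorm(5), time = c(-1, 2:5),
                               event = rep(1, 5)), "positive")
  expect_error(cox_association(rnorm(5), time = 1:5, event = rep(0, 5)),
               "at least one event")
})

test_that("Cox association recovers a known log hazard ratio", {
  set.seed(77)
  n <- 500
  x <- rnorm(n)
  t <- rexp(n, rate = 0.1 * exp(0.8 * x))
  cens <- pmin(t, quantile(t, 0.9))
  fit <- cox_association(data.frame(score = x), cens,
                         as.integer(t <= quantile(t, 0.9)))
  row <- fit[fit$term == "score", ]
  expect_lt(abs(row$estimate - 0.8), 3 * row$se)
  expect_true(row$hr_ci_lower <= row$hazard_ratio &&
                row$hazard_ratio <= row$hr_ci_upper)
})

test_that("endpoint comparison tests each endpoint and handles gaps", {
  tab <- data.frame(
    endpoint = rep(c("sensitivity", "npv"), each = 10),
    group = rep(rep(c("successful", "stalled"), each = 5), 2),
    value = c(rep(0.8, 10), 6:10 / 10, 1:5 / 10))
  out <- compare_endpoints(tab, mode = "exact")
  # identical values: p = 1; fully separated 5 vs 5: p = 2/252
  expect_equal(out$p_value[out$endpoint == "sensitivity"], 1)
  expect_equal(out$p_value[out$endpoint == "npv"], 2 / 252)

  # an endpoint present in one group only is skipped with a warning
  lop <- rbind(tab, data.frame(endpoint = "auroc", group = "successful",
                               value = 0.9))
  expect_warning(out2 <- compare_endpoints(lop, mode = "exact"),
                 "one group only")
  expect_false("auroc" %in% out2$endpoint)

  # empty table: empty result
  expect_equal(nrow(compare_endpoints(tab[0, ])), 0L)

  # Benjamini-Hochberg adjustment is monotone and never smaller
  out_bh <- compare_endpoints(tab, mode = "exact", adjust = "BH")
  expect_true(all(out_bh$p_adjusted >= out_bh$p_value - 1e-12))
})
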