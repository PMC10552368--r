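# Group comparison: Mann-Whitney U (exact permutation null, tie-corrected
# normal approximation), logistic and Cox association models, endpoint
# comparisons.

# Exact permutation null of the group-1 rank sum, ties included. Ranks are
# midranks, so doubled ranks are integers; a generating-function dynamic
# programme counts, for every doubled rank sum s, the subsets of size n1
# attaining it. Counts stay well below double precision for the sizes the
# exact mode accepts (choose(30, 15) ~ 1.6e8).
mwu_exact_tail <- function(d, n1, wd_obs) {
  S <- sum(d)
  f <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)   # f[k+1, s+1]
  f[1L, 1L] <- 1
  for (dj in d) {
    kmax <- n1
    for (k in kmax:1) {
      src <- f[k, 1:(S + 1L - dj)]
      if (any(src != 0))
        f[k + 1L, (dj + 1L):(S + 1L)] <-
          f[k + 1L, (dj + 1L):(S + 1L)] + src
    }
  }
  counts <- f[n1 + 1L, ]
  total <- sum(counts)
  s_vals <- 0:S
  list(p_le = sum(counts[s_vals <= wd_obs]) / total,
       p_ge = sum(counts[s_vals >= wd_obs]) / total)
}

#' Mann-Whitney U test for two score samples
#'
#' Compares two groups of scores (e.g. total percentage scores of
#' successful versus stalled biomarkers) by the Mann-Whitney U statistic.
#' `mode = "exact"` computes the exact permutation null of the rank sum —
#' including under ties, via a generating-function count over midranks —
#' and is the default (`"auto"`) for tie-free samples with
#' \eqn{n_1 + n_2 \le 20}. Otherwise the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used.
#'
#' The two-sided p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`;
#' `alternative = "less"` tests whether `x` tends to be smaller than `y`.
#' For two-sided reporting the quoted statistic is `min(U1, U2)`.
#'
#' @param x,y Numeric vectors of scores (both non-empty).
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @param mode `"auto"`, `"exact"` or `"approx"`. Exact mode accepts up to
#'   `n1 + n2 = 30`.
#' @return A `bm_mwu_test`: list with `statistic` (U), `u1`, `u2`,
#'   `p_value`, `method` (`"exact"` or `"normal_approximation"`),
#'   `tie_correction_applied`, `alternative`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less",
#'                mode = "exact")$p_value   # 0.05
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "less", "greater"),
                           mode = c("auto", "exact", "approx")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop_bm("both samples must be non-empty")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop_bm("samples must be finite and free of NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  ties <- anyDuplicated(c(x, y)) > 0L
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  if (mode == "auto") mode <- if (N <= 20 && !ties) "exact" else "approx"
  if (mode == "exact" && N > 30)
    stop_bm("exact mode supports n1 + n2 <= 30; use mode = 'approx'")

  if (mode == "exact") {
    d <- as.integer(round(2 * r))
    tails <- mwu_exact_tail(d, n1, sum(d[seq_len(n1)]))
    p <- switch(alternative,
                less = tails$p_le,
                greater = tails$p_ge,
                two_sided = min(1, 2 * min(tails$p_le, tails$p_ge)))
    method <- "exact"
    tie_corr <- FALSE
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {                         # all values tied
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
                  less = pnorm((u1 - mu + 0.5) / sigma),
                  greater = pnorm(-(u1 - mu - 0.5) / sigma),
                  two_sided = min(1, 2 * pnorm(
                    -max(0, abs(u1 - mu) - 0.5) / sigma)))
    }
    method <- "normal_approximation"
    tie_corr <- ties
  }
  structure(list(
    statistic = if (alternative == "two_sided") min(u1, u2) else u1,
    u1 = u1, u2 = u2, p_value = p, method = method,
    tie_correction_applied = tie_corr, alternative = alternative,
    n1 = n1, n2 = n2),
    class = "bm_mwu_test")
}

#' @export
print.bm_mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s)\n", x$method, x$alternative))
  cat(sprintf("  n1 = %d, n2 = %d, U = %g, p = %.4g\n",
              x$n1, x$n2, x$statistic, x$p_value))
  if (x$tie_correction_applied) cat("  (tie-corrected variance)\n")
  invisible(x)
}

as_covariate_df <- function(scores) {
  X <- if (is.data.frame(scores)) scores
       else if (is.matrix(scores)) as.data.frame(scores)
       else data.frame(x1 = as.numeric(scores))
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("x", seq_along(X))
  X
}

wald_table <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(term = names(est), estimate = as.numeric(est),
             se = as.numeric(se),
             ci_lower = as.numeric(est - z * se),
             ci_upper = as.numeric(est + z * se),
             p_value = 2 * pnorm(-abs(as.numeric(est) / as.numeric(se))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Logistic association of scores with implementation status
#'
#' Fits a binary logistic regression of implementation status on one or
#' more score covariates by maximum likelihood (iteratively reweighted
#' least squares), reporting Wald standard errors and 95% confidence
#' intervals. Complete or quasi-complete separation is detected and
#' flagged rather than reported as a spuriously huge coefficient, and
#' zero-variance covariates are reported with a zero coefficient rather
#' than dropped silently.
#'
#' @param scores Numeric vector, matrix or data.frame of per-unit
#'   covariates (units = publications or biomarkers).
#' @param status Binary outcome (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @param level Confidence level, default 0.95.
#' @return A `bm_association`: data.frame with one row per model term
#'   (`term`, `estimate` on the log-odds scale, `se`, `ci_lower`,
#'   `ci_upper`, `p_value`) and attributes `model = "logistic"`,
#'   `converged` and `separation`.
#' @export
logistic_association <- function(scores, status, level = 0.95) {
  X <- as_covariate_df(scores)
  if (is.factor(status)) status <- as.integer(status) - 1L
  status <- as.integer(as.logical(status) | status == 1)
  if (length(unique(status)) < 2L)
    stop_bm("status must contain both classes")
  if (nrow(X) != length(status))
    stop_bm("scores and status must have the same number of units")
  const <- vapply(X, function(v) length(unique(v)) == 1L, TRUE)
  dat <- cbind(X[!const], .status = status)
  if (all(const)) stop_bm("all covariates are constant")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.status ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  if (!sep && (any(mu < 1e-8) || any(mu > 1 - 1e-8))) sep <- TRUE
  tab <- wald_table(coef(fit), sqrt(diag(vcov(fit))), level)
  if (any(const)) {
    extra <- data.frame(term = names(X)[const], estimate = 0, se = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE)
    tab <- rbind(tab, extra)
  }
  structure(tab, class = c("bm_association", "data.frame"),
            model = "logistic", converged = fit$converged,
            separation = sep, level = level)
}

#' Cox proportional-hazards association with time to adoption
#'
#' Fits a Cox proportional-hazards model of time-to-event (e.g. time to
#' clinical adoption) on score covariates by partial likelihood with
#' Breslow handling of tied event times. Coefficients are reported on the
#' log-hazard scale together with hazard ratios and a hazard-ratio-scale
#' confidence interval; zero-variance covariates are reported with a zero
#' coefficient (hazard ratio 1).
#'
#' @param scores Numeric vector, matrix or data.frame of per-unit
#'   covariates.
#' @param time Positive event/censoring times.
#' @param event Binary event indicator (1 = event observed); at least one
#'   event is required.
#' @param level Confidence level, default 0.95.
#' @return A `bm_association` data.frame with columns `term`, `estimate`
#'   (log hazard ratio), `se`, `ci_lower`, `ci_upper` (log scale),
#'   `hazard_ratio`, `hr_ci_lower`, `hr_ci_upper`, `p_value`; attributes
#'   `model = "proportional_hazards"` and `converged`.
#' @export
cox_association <- function(scores, time, event, level = 0.95) {
  X <- as_covariate_df(scores)
  time <- as.numeric(time); event <- as.integer(event)
  if (any(!is.finite(time)) || any(time <= 0))
    stop_bm("times must be positive and finite")
  if (sum(event) < 1L) stop_bm("at least one event is required")
  const <- vapply(X, function(v) length(unique(v)) == 1L, TRUE)
  if (all(const)) {
    tab <- data.frame(term = names(X), estimate = 0, se = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      hazard_ratio = 1, hr_ci_lower = NA_real_,
                      hr_ci_upper = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(tab, class = c("bm_association", "data.frame"),
                     model = "proportional_hazards", converged = TRUE,
                     separation = FALSE, level = level))
  }
  dat <- cbind(X[!const], .time = time, .event = event)
  fml <- stats::as.formula(
    paste("Surv(.time, .event) ~", paste(names(X)[!const], collapse = " + ")),
    env = environment())
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  tab <- wald_table(coef(fit), sqrt(diag(fit$var)), level)
  tab$hazard_ratio <- exp(tab$estimate)
  tab$hr_ci_lower <- exp(tab$ci_lower)
  tab$hr_ci_upper <- exp(tab$ci_upper)
  if (any(const)) {
    extra <- data.frame(term = names(X)[const], estimate = 0, se = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        hazard_ratio = 1, hr_ci_lower = NA_real_,
                        hr_ci_upper = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
    tab <- rbind(tab, extra)
  }
  structure(tab, class = c("bm_association", "data.frame"),
            model = "proportional_hazards",
            converged = !is.null(fit$iter), separation = FALSE,
            level = level)
}

#' @export
print.bm_association <- function(x, ...) {
  cat(sprintf("<bm_association> %s model (%.0f%% CI)%s\n",
              attr(x, "model"), 100 * attr(x, "level"),
              if (isTRUE(attr(x, "separation")))
                " -- WARNING: separation detected, estimates unreliable"
              else ""))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare performance endpoints between groups
#'
#' Applies [mann_whitney_u()] to each performance endpoint (sensitivity,
#' specificity, PPV, NPV, AUROC, ...) reported by studies in two groups.
#' Endpoints represented in only one group are skipped with a warning.
#'
#' @param table data.frame with columns `endpoint`, `group` (two levels)
#'   and `value`.
#' @param groups Length-2 character vector naming the two groups to
#'   compare, in (x, y) order; default: the groups present, successful
#'   first if labelled that way.
#' @param alternative,mode Passed to [mann_whitney_u()].
#' @param adjust Multiple-testing adjustment across endpoints
#'   (see [stats::p.adjust]); default `"none"`, `"BH"` available.
#' @return data.frame with one row per compared endpoint: `endpoint`,
#'   `n_x`, `n_y`, `statistic`, `p_value`, `p_adjusted`, `method`.
#' @export
compare_endpoints <- function(table, groups = NULL,
                              alternative = "two_sided", mode = "auto",
                              adjust = "none") {
  need <- c("endpoint", "group", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_bm("endpoint table is missing column(s): ",
            paste(miss, collapse = ", "))
  empty <- data.frame(endpoint = character(), n_x = integer(),
                      n_y = integer(), statistic = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      method = character(), stringsAsFactors = FALSE)
  if (nrow(table) == 0L) return(empty)
  if (is.null(groups)) {
    groups <- unique(as.character(table$group))
    if ("successful" %in% groups)
      groups <- c("successful", setdiff(groups, "successful"))
  }
  if (length(groups) != 2L)
    stop_bm("exactly two groups are required (got: ",
            paste(unique(table$group), collapse = ", "), ")")
  rows <- lapply(unique(table$endpoint), function(ep) {
    sub <- table[table$endpoint == ep, , drop = FALSE]
    xv <- sub$value[sub$group == groups[1]]
    yv <- sub$value[sub$group == groups[2]]
    if (length(xv) == 0L || length(yv) == 0L) {
      warning("endpoint '", ep, "' present in one group only; skipped",
              call. = FALSE)
      return(NULL)
    }
    tst <- mann_whitney_u(xv, yv, alternative = alternative, mode = mode)
    data.frame(endpoint = ep, n_x = length(xv), n_y = length(yv),
               statistic = tst$statistic, p_value = tst$p_value,
               method = tst$method, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out[, c("endpoint", "n_x", "n_y", "statistic", "p_value", "p_adjusted",
          "method")]
}
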