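# Independent oracles and generators used across the suite.

# Brute-force Mann-Whitney p-value: enumerate every assignment of the
# pooled observations to group 1 (combn) and count rank sums at least as
# extreme. Entirely independent of the package's generating-function path.
mwu_oracle <- function(x, y, alternative = "two_sided") {
  n1 <- length(x)
  N <- n1 + length(y)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- combn(N, n1, u_of)
  eps <- 1e-9
  p_le <- mean(us <= u_obs + eps)
  p_ge <- mean(us >= u_obs - eps)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}

# Small random checklist: 4 categories, 1-3 sub-categories each, 1-4
# attributes per sub-category.
random_checklist <- function() {
  sc_rows <- list()
  at_rows <- list()
  a <- 0L
  s <- 0L
  for (cat in bm_categories()) {
    for (j in seq_len(sample(1:3, 1))) {
      s <- s + 1L
      sid <- sprintf("s%02d", s)
      sc_rows[[s]] <- data.frame(id = sid, label = paste("sub", s),
                                 category = cat)
      for (k in seq_len(sample(1:4, 1))) {
        a <- a + 1L
        at_rows[[a]] <- data.frame(id = sprintf("a%03d", a),
                                   label = paste("attr", a),
                                   sub_category = sid)
      }
    }
  }
  checklist(do.call(rbind, at_rows), do.call(rbind, sc_rows))
}

# Flat-mean category scores computed by explicit looping over the raw
# indicator vector, without tapply or matrix algebra.
flat_mean_oracle <- function(indicators, cl) {
  v <- setNames(rep(0, nrow(cl$attributes)), cl$attributes$id)
  v[names(indicators)] <- indicators
  out <- numeric(0)
  for (cat in bm_categories()) {
    scs <- cl$sub_categories$id[cl$sub_categories$category == cat]
    ids <- cl$attributes$id[cl$attributes$sub_category %in% scs]
    total <- 0
    for (id in ids) total <- total + v[[id]]
    out[[cat]] <- total / length(ids)
  }
  out
}

# Fully reported / random indicator vectors for a checklist.
random_indicators <- function(cl, p = 0.5) {
  ids <- cl$attributes$id
  setNames(rbinom(length(ids), 1, p), ids)
}

toy_sheet <- function(cl, n_pubs, n_bm = 1L, p = 0.6) {
  ids <- cl$attributes$id
  ind <- matrix(rbinom(n_pubs * length(ids), 1, p), nrow = n_pubs,
                dimnames = list(NULL, ids))
  data.frame(pub_id = sprintf("p%03d", seq_len(n_pubs)),
             biomarker_id = sprintf("bm%02d",
                                    rep_len(seq_len(n_bm), n_pubs)),
             study_type = "clinical",
             ind, stringsAsFactors = FALSE, check.names = FALSE)
}
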