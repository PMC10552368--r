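# Synthetic corpus generator: biomarkers with status-dependent
# per-category reporting probabilities, study-type inventories, Delphi
# votes and adoption times, so every stage of the pipeline is testable
# without a real literature corpus.

#' Configure a synthetic corpus simulation
#'
#' Defaults encode the qualitative pattern the scoring system is built to
#' detect: successful biomarkers report attributes of every category with
#' high probability (0.8), stalled biomarkers report analytical/clinical
#' validity attributes at 0.5 but clinical-utility attributes at only 0.2,
#' and non-clinical study types exist with probability 0.7 per type for
#' successful versus 0.1 for stalled biomarkers (mirroring how few stalled
#' biomarkers have any clinical-utility-related study). Publication years
#' surge around five years after biomarker discovery.
#'
#' @param n_successful,n_stalled Biomarkers per group (default 30 each).
#' @param n_pubs Publications per biomarker: a fixed count (default 5), or
#'   the mean of a (zero-truncated) Poisson when
#'   `pub_dist = "poisson"`.
#' @param pub_dist `"fixed"` or `"poisson"`.
#' @param reporting_probs List with elements `successful` and `stalled`,
#'   each a named vector of per-category reporting probabilities over
#'   [bm_categories()].
#' @param study_type_prob Named vector: per-type presence probability of
#'   each non-clinical study type, by status.
#' @param diligence Beta shape parameter for an optional shared
#'   per-publication "diligence" random effect multiplying all of a
#'   publication's reporting probabilities (mean-1 multiplier
#'   `2 * Beta(diligence, diligence)`, truncated so probabilities stay in
#'   \[0, 1\]); `NULL` (default) disables it, leaving indicators
#'   independent within a publication.
#' @param discovery_years Range of biomarker discovery years.
#' @param year_surge_mean Mean of the Poisson offset from discovery year
#'   to publication year (default 5).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `bm_simulation_config` list.
#' @export
simulation_config <- function(n_successful = 30L, n_stalled = 30L,
                              n_pubs = 5L,
                              pub_dist = c("fixed", "poisson"),
                              reporting_probs = list(
                                successful = c(analytical_validity = 0.8,
                                               clinical_validity = 0.8,
                                               clinical_utility = 0.8,
                                               rationale = 0.8),
                                stalled = c(analytical_validity = 0.5,
                                            clinical_validity = 0.5,
                                            clinical_utility = 0.2,
                                            rationale = 0.5)),
                              study_type_prob = c(successful = 0.7,
                                                  stalled = 0.1),
                              diligence = NULL,
                              discovery_years = c(2000L, 2014L),
                              year_surge_mean = 5,
                              seed = NULL) {
  pub_dist <- match.arg(pub_dist)
  if (n_successful < 1L || n_stalled < 1L)
    stop_bm("group sizes must be positive")
  if (n_pubs <= 0) stop_bm("n_pubs must be positive")
  for (g in c("successful", "stalled")) {
    p <- reporting_probs[[g]]
    if (is.null(p) || !all(bm_categories() %in% names(p)))
      stop_bm("reporting_probs$", g,
              " must name every category in bm_categories()")
    check_prob(p, paste0("reporting_probs$", g))
  }
  check_prob(study_type_prob, "study_type_prob")
  if (!all(c("successful", "stalled") %in% names(study_type_prob)))
    stop_bm("study_type_prob must be named by status")
  structure(list(n_successful = as.integer(n_successful),
                 n_stalled = as.integer(n_stalled),
                 n_pubs = n_pubs, pub_dist = pub_dist,
                 reporting_probs = reporting_probs,
                 study_type_prob = study_type_prob,
                 diligence = diligence,
                 discovery_years = discovery_years,
                 year_surge_mean = year_surge_mean,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "bm_simulation_config")
}

#' Generate a synthetic literature corpus
#'
#' Draws a corpus of biomarkers, publications, indicator sheets,
#' study-type inventories, status labels and time-to-adoption values with
#' the statistical structure the downstream analysis assumes: each
#' indicator is an independent Bernoulli draw with its category- and
#' status-specific reporting probability, study-type flags are per-status
#' Bernoulli draws, and adoption hazard increases with the biomarker's
#' reporting level (stalled biomarkers are censored). Given the same seed
#' and configuration the output is identical across runs.
#'
#' @param cfg A [simulation_config()].
#' @param checklist A `bm_checklist` (default [toolkit_v1()]).
#' @return A `bm_corpus`: list with `checklist`, `sheet` (scoring-sheet
#'   data.frame), `inventory`, `labels` (`biomarker_id`, `status`),
#'   `times` (`biomarker_id`, `time`, `event`) and `config`.
#' @export
#' @examples
#' corpus <- generate_corpus(simulation_config(n_successful = 3,
#'                                             n_stalled = 3, seed = 1))
#' head(score_corpus(corpus$sheet, corpus$checklist,
#'                   corpus$inventory)$total_percent)
generate_corpus <- function(cfg, checklist = toolkit_v1()) {
  if (!inherits(cfg, "bm_simulation_config"))
    stop_bm("cfg must come from simulation_config()")
  validate_checklist(checklist)
  with_seed(cfg$seed, {
    n_bm <- cfg$n_successful + cfg$n_stalled
    bm_ids <- sprintf("bm%03d", seq_len(n_bm))
    status <- rep(c("successful", "stalled"),
                  c(cfg$n_successful, cfg$n_stalled))
    npub <- if (cfg$pub_dist == "fixed") rep(as.integer(cfg$n_pubs), n_bm)
            else pmax(1L, rpois(n_bm, cfg$n_pubs))
    disc <- sample(seq(cfg$discovery_years[1], cfg$discovery_years[2]),
                   n_bm, replace = TRUE)
    attr_ids <- checklist$attributes$id
    cat_of_attr <- as.character(attribute_categories(checklist))
    nontrivial_types <- setdiff(bm_study_types(), "clinical")

    sheets <- vector("list", n_bm)
    inv <- matrix(0L, nrow = n_bm, ncol = length(nontrivial_types),
                  dimnames = list(bm_ids, nontrivial_types))
    for (b in seq_len(n_bm)) {
      k <- npub[b]
      p_cat <- cfg$reporting_probs[[status[b]]]
      P <- matrix(rep(p_cat[cat_of_attr], each = k), nrow = k)
      if (!is.null(cfg$diligence)) {
        mult <- 2 * rbeta(k, cfg$diligence, cfg$diligence)
        P <- pmin(1, P * mult)
      }
      ind <- matrix(rbinom(length(P), 1L, P), nrow = k,
                    dimnames = list(NULL, attr_ids))
      sheets[[b]] <- data.frame(
        pub_id = sprintf("%s_p%02d", bm_ids[b], seq_len(k)),
        biomarker_id = bm_ids[b],
        study_type = "clinical",
        year = disc[b] + rpois(k, cfg$year_surge_mean),
        ind, stringsAsFactors = FALSE, check.names = FALSE)
      inv[b, ] <- rbinom(length(nontrivial_types), 1L,
                         cfg$study_type_prob[[status[b]]])
    }
    sheet <- do.call(rbind, sheets)
    rownames(sheet) <- NULL
    inventory <- data.frame(biomarker_id = bm_ids, inv,
                            stringsAsFactors = FALSE, check.names = FALSE)
    rownames(inventory) <- NULL
    labels <- data.frame(biomarker_id = bm_ids, status = status,
                         stringsAsFactors = FALSE)
    # adoption hazard rises with overall reporting level; stalled
    # biomarkers never adopt and are censored at the follow-up horizon
    p_bar <- vapply(seq_len(n_bm), function(b)
      mean(cfg$reporting_probs[[status[b]]]), 0)
    t_raw <- rexp(n_bm, rate = exp(-3 + 2.5 * p_bar))
    horizon <- 25
    event <- as.integer(status == "successful" & t_raw <= horizon)
    times <- data.frame(biomarker_id = bm_ids,
                        time = pmin(t_raw, horizon),
                        event = event, stringsAsFactors = FALSE)
    structure(list(checklist = checklist, sheet = sheet,
                   inventory = inventory, labels = labels, times = times,
                   config = cfg),
              class = "bm_corpus")
  })
}

#' @export
print.bm_corpus <- function(x, ...) {
  cat(sprintf("<bm_corpus> %d biomarkers (%d successful, %d stalled), %d publications\n",
              nrow(x$labels), sum(x$labels$status == "successful"),
              sum(x$labels$status == "stalled"), nrow(x$sheet)))
  invisible(x)
}

#' Write / read a corpus as delimited text
#'
#' `write_corpus()` writes the scoring sheet, inventory, labels and times
#' as CSV plus the checklist definition (YAML) into a directory, in
#' exactly the dialects [read_scoring_sheet()], [read_inventory()] and
#' [read_checklist()] parse; the round trip is lossless.
#'
#' @param corpus A `bm_corpus`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!inherits(corpus, "bm_corpus")) stop_bm("not a bm_corpus")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sheet = file.path(dir, "sheet.csv"),
             inventory = file.path(dir, "inventory.csv"),
             labels = file.path(dir, "labels.csv"),
             times = file.path(dir, "times.csv"),
             checklist = file.path(dir, "checklist.yaml"))
  write.csv(corpus$sheet, paths["sheet"], row.names = FALSE)
  write.csv(corpus$inventory, paths["inventory"], row.names = FALSE)
  write.csv(corpus$labels, paths["labels"], row.names = FALSE)
  write.csv(corpus$times, paths["times"], row.names = FALSE)
  write_checklist(corpus$checklist, paths["checklist"])
  invisible(paths)
}

#' Generate synthetic Delphi votes
#'
#' Draws a participant-by-item agreement matrix with independent
#' Bernoulli votes at prescribed per-item agreement probabilities —
#' useful for constructing response sets with a planned number of
#' sub-threshold items.
#'
#' @param n_items Number of items (ignored if `agreement_probs` is
#'   named/full length).
#' @param n_participants Number of participants.
#' @param agreement_probs Per-item agreement probability, recycled to
#'   `n_items`; names become item ids (default `item01`, ...).
#' @param seed Integer seed or `NULL`.
#' @param round Round number.
#' @return A [delphi_responses()] object.
#' @export
generate_delphi <- function(n_items, n_participants, agreement_probs,
                            seed = NULL, round = 1L) {
  check_prob(agreement_probs, "agreement_probs")
  p <- rep_len(agreement_probs, n_items)
  ids <- names(agreement_probs)
  if (is.null(ids) || length(ids) != n_items)
    ids <- sprintf("item%02d", seq_len(n_items))
  with_seed(seed, {
    votes <- vapply(p, function(pi) rbinom(n_participants, 1L, pi),
                    integer(n_participants))
    colnames(votes) <- ids
    delphi_responses(votes, round = round)
  })
}

#' Estimate discrimination power by simulation
#'
#' Repeatedly generates corpora under `cfg`, scores them, and tests
#' successful versus stalled total scores with [mann_whitney_u()];
#' reports the fraction of replicates rejecting at `alpha` with an exact
#' binomial (Clopper-Pearson) Monte-Carlo confidence interval. Under a
#' null configuration (identical groups) the rejection rate estimates the
#' realised type-I error.
#'
#' @param cfg A [simulation_config()]; its `seed` field is ignored in
#'   favour of `seed` below.
#' @param checklist A `bm_checklist` (default [toolkit_v1()]).
#' @param n_reps Number of replicates (>= 100 recommended; default 200).
#' @param alpha Nominal significance level (default 0.05). Rejection is
#'   `p <= alpha`.
#' @param seed Integer seed for the whole experiment.
#' @param mode Passed to [mann_whitney_u()].
#' @return A `bm_power`: list with `power`, `ci` (95% Monte-Carlo CI),
#'   `n_reps`, `alpha`, `rejections`.
#' @export
#' @examples
#' \donttest{
#' power_experiment(simulation_config(), n_reps = 100, seed = 7)
#' }
power_experiment <- function(cfg, checklist = toolkit_v1(), n_reps = 200L,
                             alpha = 0.05, seed = NULL, mode = "auto") {
  if (!inherits(cfg, "bm_simulation_config"))
    stop_bm("cfg must come from simulation_config()")
  if (n_reps < 1L) stop_bm("n_reps must be positive")
  check_prob(alpha, "alpha")
  validate_checklist(checklist)
  with_seed(seed, {
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      cfg_r <- cfg
      cfg_r$seed <- NULL                    # inherit the experiment stream
      corpus <- generate_corpus(cfg_r, checklist)
      tab <- score_corpus(corpus$sheet, corpus$checklist, corpus$inventory)
      s <- tab$total_percent[corpus$labels$status == "successful"]
      t <- tab$total_percent[corpus$labels$status == "stalled"]
      rej[r] <- mann_whitney_u(s, t, mode = mode)$p_value <= alpha
    }
    k <- sum(rej)
    ci <- as.numeric(stats::binom.test(k, n_reps)$conf.int)
    structure(list(power = k / n_reps, ci = ci, n_reps = n_reps,
                   alpha = alpha, rejections = k),
              class = "bm_power")
  })
}

#' @export
print.bm_power <- function(x, ...) {
  cat(sprintf("Mann-Whitney rejection rate at alpha = %g: %.3f (%d/%d; 95%% MC CI %.3f-%.3f)\n",
              x$alpha, x$power, x$rejections, x$n_reps, x$ci[1], x$ci[2]))
  invisible(x)
}
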