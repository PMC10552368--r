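# Delphi consensus machinery: per-item agreement, threshold-based round
# outcomes, two-round retention, and rank-derived category weights.

#' Construct a Delphi response set
#'
#' Holds one round of agree/disagree votes, participants in rows and items
#' in columns. Likert-scale responses should be collapsed to agree (1) /
#' disagree (0) before construction — by convention the top two boxes of
#' the scale count as agreement. `NA` marks a participant who did not vote
#' on an item.
#'
#' @param votes Numeric/logical matrix or data.frame (participants x
#'   items) of 1 (agree), 0 (disagree) or `NA`; column names are item
#'   ids. Every item needs at least one vote.
#' @param round Round number (1 or 2).
#' @return A `bm_delphi_responses` object.
#' @export
delphi_responses <- function(votes, round = 1L) {
  votes <- as.matrix(votes)
  storage.mode(votes) <- "double"
  if (is.null(colnames(votes)))
    stop_bm("votes must have item ids as column names")
  if (any(!is.na(votes) & !votes %in% c(0, 1)))
    stop_bm("votes must be 0, 1 or NA")
  no_votes <- colnames(votes)[colSums(!is.na(votes)) == 0L]
  if (length(no_votes))
    stop_bm("item(s) with no votes: ", paste(no_votes, collapse = ", "))
  if (!round %in% c(1L, 2L)) stop_bm("round must be 1 or 2")
  structure(list(votes = votes, round = as.integer(round),
                 participants = nrow(votes)),
            class = "bm_delphi_responses")
}

#' @export
print.bm_delphi_responses <- function(x, ...) {
  cat(sprintf("<bm_delphi_responses> round %d: %d participants, %d items\n",
              x$round, x$participants, ncol(x$votes)))
  invisible(x)
}

#' Per-item agreement fraction
#'
#' @param responses A `bm_delphi_responses`.
#' @param item_id Item id (must exist in the response set).
#' @return Agreement fraction in \[0, 1\]: agree votes / votes cast for
#'   the item.
#' @export
#' @examples
#' v <- matrix(c(1, 1, 1, 0), ncol = 1, dimnames = list(NULL, "it1"))
#' item_agreement(delphi_responses(v), "it1")   # 0.75
item_agreement <- function(responses, item_id) {
  if (!inherits(responses, "bm_delphi_responses"))
    stop_bm("responses must be a bm_delphi_responses")
  if (!item_id %in% colnames(responses$votes))
    stop_bm("unknown item: ", item_id)
  v <- responses$votes[, item_id]
  mean(v, na.rm = TRUE)
}

#' Run one Delphi round
#'
#' Partitions items by whether their agreement fraction reaches the
#' consensus threshold. The boundary is inclusive: an item at exactly the
#' threshold (e.g. 3 agreements out of 4 at a 75% level) reaches
#' consensus. Items below the threshold are *carried* into the next round.
#'
#' @param responses A `bm_delphi_responses`.
#' @param threshold Consensus threshold as a fraction; default 0.75.
#' @return A `bm_delphi_round`: list with `agreement` (named fractions),
#'   `consensus_items`, `carried_items`, `consensus_rate` (percent of
#'   items reaching consensus, half-up rounded to 2 dp), `threshold` and
#'   `round`.
#' @export
#' @examples
#' run_round(delphi_fixture()$round1)$consensus_rate   # 84.31
run_round <- function(responses, threshold = 0.75) {
  if (!inherits(responses, "bm_delphi_responses"))
    stop_bm("responses must be a bm_delphi_responses")
  check_prob(threshold, "threshold")
  agreement <- colMeans(responses$votes, na.rm = TRUE)
  reached <- agreement >= threshold
  structure(list(
    agreement = agreement,
    consensus_items = names(agreement)[reached],
    carried_items = names(agreement)[!reached],
    consensus_rate = round_half_up(100 * mean(reached), 2),
    threshold = threshold,
    round = responses$round),
    class = "bm_delphi_round")
}

#' @export
print.bm_delphi_round <- function(x, ...) {
  cat(sprintf("<bm_delphi_round> round %d (threshold %.0f%%)\n", x$round,
              100 * x$threshold))
  cat(sprintf("  %d of %d items reached consensus (%.2f%%); %d carried\n",
              length(x$consensus_items), length(x$agreement),
              x$consensus_rate, length(x$carried_items)))
  invisible(x)
}

#' Finalise a two-round Delphi consensus
#'
#' Retained items are those reaching consensus in either round; removed
#' items are those below the threshold in both. Round 2 may only contain
#' items carried from round 1 (anything else is an error); a carried item
#' not re-voted in round 2 is treated as removed, having found no
#' second-round support.
#'
#' @param round1,round2 `bm_delphi_round` outcomes (see [run_round()]).
#'   `round2 = NULL` treats all carried items as removed.
#' @return A `bm_delphi_consensus`: list with `retained`, `removed`, and
#'   an `audit` data.frame of per-item round-1 and round-2 agreement and
#'   outcome.
#' @export
#' @examples
#' fx <- delphi_fixture()
#' res <- finalize_consensus(run_round(fx$round1), run_round(fx$round2))
#' length(res$removed)   # 6
finalize_consensus <- function(round1, round2 = NULL) {
  if (!inherits(round1, "bm_delphi_round"))
    stop_bm("round1 must be a bm_delphi_round")
  carried <- round1$carried_items
  r2_agree <- setNames(numeric(0), character(0))
  if (!is.null(round2)) {
    if (!inherits(round2, "bm_delphi_round"))
      stop_bm("round2 must be a bm_delphi_round")
    extra <- setdiff(names(round2$agreement), carried)
    if (length(extra))
      stop_bm("round 2 contains item(s) not carried from round 1: ",
              paste(extra, collapse = ", "))
    r2_agree <- round2$agreement
    r2_pass <- round2$consensus_items
  } else {
    r2_pass <- character()
  }
  retained <- c(round1$consensus_items, r2_pass)
  removed <- setdiff(carried, r2_pass)
  items <- names(round1$agreement)
  audit <- data.frame(
    item = items,
    round1_agreement = as.numeric(round1$agreement),
    round2_agreement = as.numeric(r2_agree[items]),
    outcome = ifelse(items %in% retained, "retained", "removed"),
    stringsAsFactors = FALSE)
  structure(list(retained = retained, removed = removed, audit = audit,
                 threshold = round1$threshold),
            class = "bm_delphi_consensus")
}

#' @export
print.bm_delphi_consensus <- function(x, ...) {
  cat(sprintf("<bm_delphi_consensus> %d retained, %d removed (threshold %.0f%%)\n",
              length(x$retained), length(x$removed), 100 * x$threshold))
  invisible(x)
}

#' Derive category weights from Delphi rank responses
#'
#' Participants rank the categories by importance (1 = most important).
#' The per-category median rank (lower-median convention for even
#' participant counts) is mapped linearly and inversely to a weight:
#' \deqn{w_c = \frac{m + 1 - \tilde r_c}{\sum_{c'} (m + 1 - \tilde r_{c'})}}
#' with \eqn{m} categories and \eqn{\tilde r_c} the median rank of
#' category \eqn{c}. Weights are non-negative, sum exactly to 1, and tied
#' medians yield equal weights.
#'
#' @param ranks Matrix or data.frame (participants x categories) where
#'   each row is a complete permutation of `1..m`; incomplete or invalid
#'   rankings are rejected, naming the offending participant.
#' @param included Optional subset of category columns to use (weights
#'   are computed over this subset only).
#' @return Named numeric vector of weights summing to 1, suitable for
#'   [aggregate_biomarker()]'s `weights` argument.
#' @export
#' @examples
#' r <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 3, 2))
#' colnames(r) <- c("analytical_validity", "clinical_validity",
#'                  "clinical_utility")
#' rank_weights(r)   # 3/6, 2/6, 1/6
rank_weights <- function(ranks, included = NULL) {
  ranks <- as.matrix(ranks)
  if (is.null(colnames(ranks)))
    stop_bm("ranks must have category names as column names")
  m <- ncol(ranks)
  if (nrow(ranks) == 0L) stop_bm("at least one complete ranking is required")
  who <- rownames(ranks) %||% as.character(seq_len(nrow(ranks)))
  for (i in seq_len(nrow(ranks))) {
    r <- ranks[i, ]
    if (anyNA(r) || !setequal(r, seq_len(m)))
      stop_bm("participant ", who[i],
              " did not provide a complete ranking (permutation of 1..",
              m, ")")
  }
  if (!is.null(included)) {
    miss <- setdiff(included, colnames(ranks))
    if (length(miss))
      stop_bm("included category(ies) absent from ranks: ",
              paste(miss, collapse = ", "))
    ranks <- ranks[, included, drop = FALSE]
  }
  lower_median <- function(v) sort(v)[floor((length(v) + 1) / 2)]
  med <- apply(ranks, 2, lower_median)
  w <- (m + 1 - med)
  w <- w / sum(w)
  setNames(as.numeric(w), colnames(ranks))
}
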