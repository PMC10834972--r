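# Plurality, Borda and Copeland social choice functions on (incomplete,
# tied) ordinal ballots, and their multimodal extensions obtained by
# converting numerical ballots to rankings with rank_of() before scoring.

as_ballot_list <- function(ballots) {
  if (length(ballots) == 0L) stop("voting: empty ballot list")
  lapply(ballots, ballot_values)
}

check_supports <- function(ballots, universe) {
  ok <- all(vapply(ballots, function(b) all(names(b) %in% universe),
                   logical(1)))
  if (!ok) stop("voting: ballot support outside the universe")
}

new_score_table <- function(scores, rule, n_ballots) {
  structure(list(scores = scores, rule = rule, n_ballots = n_ballots),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table> rule =", x$rule, "over", x$n_ballots, "ballots\n")
  print(sort(x$scores, decreasing = TRUE))
  invisible(x)
}

#' Plurality scores
#'
#' Each ballot awards one point to every alternative it places in position 1
#' (co-first ties each receive the point); alternatives absent from a ballot
#' receive nothing from it.
#'
#' @param ballots list of tied rankings (named vectors or
#'   [ordinal_ballot()]s) with supports inside `universe`.
#' @param universe character vector of all image ids in the instance.
#' @return A `score_table` (named numeric `scores`, `rule`, `n_ballots`).
#' @export
plurality_scores <- function(ballots, universe) {
  ballots <- as_ballot_list(ballots)
  check_supports(ballots, universe)
  scores <- stats::setNames(numeric(length(universe)), universe)
  for (b in ballots) {
    first <- names(b)[b == 1L]
    scores[first] <- scores[first] + 1
  }
  new_score_table(scores, "plurality", length(ballots))
}

#' Borda scores
#'
#' A ballot of support size `m` contributes `m - a_i` points to each
#' alternative `i` it ranks (so its first-placed alternative receives
#' `m - 1`); unseen alternatives contribute 0.  Ballots of heterogeneous
#' sizes each use their own `m`.
#'
#' @inheritParams plurality_scores
#' @return A `score_table`.
#' @export
borda_scores <- function(ballots, universe) {
  ballots <- as_ballot_list(ballots)
  check_supports(ballots, universe)
  scores <- stats::setNames(numeric(length(universe)), universe)
  for (b in ballots) {
    scores[names(b)] <- scores[names(b)] + (length(b) - b)
  }
  new_score_table(scores, "borda", length(ballots))
}

#' Copeland scores
#'
#' Score of alternative `i` is the number of pairwise wins minus defeats,
#' summed over ballots and opponents: each ballot ranking both `i` and `j`
#' contributes +1 to `i` if it places `i` ahead of `j`, -1 if behind, and 0
#' on a tie; pairs not covered by a ballot contribute 0.
#'
#' @inheritParams plurality_scores
#' @return A `score_table` (integer-valued scores).
#' @export
copeland_scores <- function(ballots, universe) {
  ballots <- as_ballot_list(ballots)
  check_supports(ballots, universe)
  scores <- stats::setNames(numeric(length(universe)), universe)
  for (b in ballots) {
    # wins minus defeats of each supported item within this ballot
    s <- sign(outer(b, b, "-"))   # s[i,j] = +1 when i ranked after j
    contrib <- rowSums(-s)        # +1 per opponent strictly behind i
    scores[names(b)] <- scores[names(b)] + contrib
  }
  new_score_table(scores, "copeland", length(ballots))
}

score_fun <- function(rule) {
  switch(rule,
         plurality = plurality_scores,
         borda     = borda_scores,
         copeland  = copeland_scores,
         stop("unknown voting rule: ", rule))
}

#' Convert a score table to a social ordering
#'
#' Alternatives are ordered in non-increasing order of score.  Equal scores
#' are either kept as ties (`keep_ties`) or broken lexicographically by image
#' id (`by_id`, the deterministic default).
#'
#' @param table a `score_table` (or bare named numeric vector of scores).
#' @param tie_break `"by_id"` or `"keep_ties"`.
#' @return Named integer ranking over the scored universe.
#' @export
scores_to_ranking <- function(table, tie_break = c("by_id", "keep_ties")) {
  tie_break <- match.arg(tie_break)
  scores <- if (inherits(table, "score_table")) table$scores else table
  if (tie_break == "keep_ties") return(rank_of(-scores))
  ord <- order(-scores, names(scores), method = "radix")
  stats::setNames(seq_along(scores), names(scores)[ord])[names(scores)]
}

#' Multimodal aggregation of a coupled-estimate group
#'
#' Builds the ballot multiset containing, for every participant record, both
#' the ordinal ballot `a` and the converted numerical ballot `rank_of(b)`
#' (two ballots per participant), then applies the chosen voting rule and
#' orders the universe by score.
#'
#' @param records list of [participant_record()]s.
#' @param universe character vector of image ids (defaults to the union of
#'   ballot supports).
#' @param rule `"plurality"`, `"borda"` or `"copeland"`.
#' @param tie_break passed to [scores_to_ranking()].
#' @return Named integer ranking over `universe`.
#' @export
aggregate_multimodal <- function(records, universe = NULL,
                                 rule = c("borda", "plurality", "copeland"),
                                 tie_break = c("by_id", "keep_ties")) {
  rule <- match.arg(rule)
  if (length(records) == 0L) stop("aggregate_multimodal: empty records")
  ballots <- c(lapply(records, function(r) r$ordinal$positions),
               lapply(records, function(r) rank_of(r$numerical$estimates)))
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(ballots, names))))
  scores_to_ranking(score_fun(rule)(ballots, universe), tie_break)
}

#' Aggregation of separate-estimate groups
#'
#' Mixes the ordinal ballots of one participant group with the converted
#' numerical ballots of a *disjoint* group (one ballot per participant) and
#' aggregates with the chosen voting rule.
#'
#' @param ordinal_records,numerical_records lists of [participant_record()]s
#'   with disjoint participant ids.
#' @inheritParams aggregate_multimodal
#' @return Named integer ranking over `universe`.
#' @export
aggregate_mixed_groups <- function(ordinal_records, numerical_records,
                                   universe = NULL,
                                   rule = c("borda", "plurality", "copeland"),
                                   tie_break = c("by_id", "keep_ties")) {
  rule <- match.arg(rule)
  if (length(ordinal_records) == 0L || length(numerical_records) == 0L)
    stop("aggregate_mixed_groups: both groups must be nonempty")
  ids_a <- vapply(ordinal_records, function(r) as.character(r$participant_id),
                  character(1))
  ids_b <- vapply(numerical_records, function(r) as.character(r$participant_id),
                  character(1))
  if (length(intersect(ids_a, ids_b)) > 0L)
    stop("aggregate_mixed_groups: participant ids overlap between groups")
  ballots <- c(lapply(ordinal_records, function(r) r$ordinal$positions),
               lapply(numerical_records,
                      function(r) rank_of(r$numerical$estimates)))
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(ballots, names))))
  scores_to_ranking(score_fun(rule)(ballots, universe), tie_break)
}
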