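# Distance functions on rankings and numerical estimate vectors.  The
# Kemeny-Snell and Cook-Kress distances are halved double sums over ordered
# pairs; their normalized projected extensions first project both inputs onto
# the common support and then divide by a size- (and range-) dependent
# constant, with a zero branch when fewer than two alternatives are shared.

#' Range of a collection of numerical inputs
#'
#' @param low,high lowest and highest value among the inputs.
#' @return An object of class `range_info` with fields `range_low`,
#'   `range_high`, `range_width` (`R = U - L`).
#' @export
range_info <- function(low, high) {
  if (high < low) stop("range_info: high < low")
  structure(list(range_low = low, range_high = high,
                 range_width = high - low),
            class = "range_info")
}

#' Compute the range over all estimates of a ballot collection
#'
#' The range `R = U - L` used to normalize the Cook-Kress distance is taken
#' over *all* numerical inputs of an aggregation instance (instance-level,
#' not per ballot pair).
#'
#' @param ballots a list of [numerical_ballot()]s or named numeric vectors,
#'   or a single such object.
#' @return A [range_info()].
#' @export
range_of_inputs <- function(ballots) {
  if (inherits(ballots, "numerical_ballot") || !is.list(ballots))
    ballots <- list(ballots)
  vals <- unlist(lapply(ballots, ballot_values), use.names = FALSE)
  if (length(vals) == 0L) stop("range_of_inputs: no estimates")
  range_info(min(vals), max(vals))
}

# aligned pair of named vectors with identical supports
align_pair <- function(x, y, what) {
  x <- ballot_values(x); y <- ballot_values(y)
  if (!setequal(names(x), names(y)))
    stop(what, ": the two inputs must have identical supports")
  list(x = x, y = y[names(x)])
}

#' Kemeny-Snell distance between two complete tied rankings
#'
#' Computed as `(1/2) * sum_i sum_j |sign(a1_i - a1_j) - sign(a2_i - a2_j)|`.
#' A strictly reversed pair contributes 2, a tie-versus-strict pair
#' contributes 1, agreeing pairs contribute 0.
#'
#' @param a1,a2 tied rankings (named vectors or [ordinal_ballot()]s) over the
#'   same support.
#' @return Nonnegative number.
#' @export
kemeny_snell <- function(a1, a2) {
  p <- align_pair(a1, a2, "kemeny_snell")
  s1 <- sign(outer(p$x, p$x, "-"))
  s2 <- sign(outer(p$y, p$y, "-"))
  sum(abs(s1 - s2)) / 2
}

#' Discordant-pair count between two tied rankings
#'
#' The number of unordered pairs ranked in strictly opposite order by the two
#' rankings.  Tie-versus-strict pairs are not discordant.  For strict
#' rankings this equals half the Kemeny-Snell distance.
#'
#' @inheritParams kemeny_snell
#' @return Nonnegative integer.
#' @export
discordant_pairs <- function(a1, a2) {
  p <- align_pair(a1, a2, "discordant_pairs")
  s1 <- sign(outer(p$x, p$x, "-"))
  s2 <- sign(outer(p$y, p$y, "-"))
  as.integer(sum(s1 * s2 == -1) / 2)
}

#' Normalized projected Kemeny-Snell distance
#'
#' Both rankings are projected onto their common support; the Kemeny-Snell
#' distance of the projections is divided by `c(c-1)/2`, `c` the common
#' support size.  When fewer than two alternatives are shared the distance is
#' 0 by definition.
#'
#' @param a1,a2 possibly incomplete tied rankings.
#' @return Nonnegative number.
#' @export
npks <- function(a1, a2) {
  cs <- common_support(a1, a2)
  cc <- length(cs)
  if (cc < 2L) return(0)
  kemeny_snell(project_ranking(a1, cs), project_ranking(a2, cs)) /
    (cc * (cc - 1) / 2)
}

#' Cook-Kress distance between two complete numerical vectors
#'
#' Computed as `(1/2) * sum_i sum_j |(b1_i - b1_j) - (b2_i - b2_j)|`: the
#' cumulative disagreement in pairwise intensity differences.  Invariant
#' under adding a constant to either vector.
#'
#' @param b1,b2 numerical vectors (named vectors or [numerical_ballot()]s)
#'   over the same support.
#' @return Nonnegative number.
#' @export
cook_kress <- function(b1, b2) {
  p <- align_pair(b1, b2, "cook_kress")
  d <- p$x - p$y
  sum(abs(outer(d, d, "-"))) / 2
}

#' Normalized projected Cook-Kress distance
#'
#' Both vectors are projected onto their common support; the Cook-Kress
#' distance of the projections is divided by `4 R ceil(c/2) floor(c/2)`,
#' where `c` is the common support size and `R` the instance-level range of
#' the numerical inputs.  When fewer than two alternatives are shared the
#' distance is 0 by definition.
#'
#' @param b1,b2 possibly incomplete numerical vectors.
#' @param range_info a [range_info()] for the aggregation instance.
#' @return Nonnegative number.
#' @export
npck <- function(b1, b2, range_info) {
  stopifnot(inherits(range_info, "range_info"))
  cs <- common_support(b1, b2)
  cc <- length(cs)
  if (cc < 2L) return(0)
  ck <- cook_kress(ballot_values(b1)[cs], ballot_values(b2)[cs])
  if (range_info$range_width == 0) {
    if (ck > 0) stop("npck: zero range with nonzero Cook-Kress distance; ",
                     "normalization undefined")
    return(0)
  }
  ck / (4 * range_info$range_width * ceiling(cc / 2) * floor(cc / 2))
}

#' Normalized ground-truth accuracy of a collective ranking
#'
#' The discordant-pair count between an estimated ranking and the strict
#' ground-truth ranking, divided by the maximum number of pairwise reversals
#' `m(m-1)/2`.  Lies in `[0, 1]`: 0 for a sign-identical estimate, 1 for the
#' full reversal.
#'
#' @param estimate tied ranking over the support (ties are not penalized).
#' @param truth strict ranking over the same support.
#' @return Number in `[0, 1]`.
#' @export
ground_truth_accuracy <- function(estimate, truth) {
  p <- align_pair(estimate, truth, "ground_truth_accuracy")
  m <- length(p$x)
  if (m < 2L) stop("ground_truth_accuracy: support must have >= 2 items")
  if (anyDuplicated(p$y)) stop("ground_truth_accuracy: truth must be strict")
  discordant_pairs(p$x, p$y) / (m * (m - 1) / 2)
}
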