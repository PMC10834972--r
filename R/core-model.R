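# Rankings throughout the package are named integer vectors: names are image
# identifiers, values are 1-based competition-style positions (position 1 =
# fewest dots; tied items share the position 1 + number of items strictly
# ahead of them).  Numerical estimate vectors are named numerics on the same
# identifier space.

#' Construct an image universe
#'
#' A universe is the full set of alternatives (images) under evaluation
#' together with the ground-truth dot count of each image.  Counts must be
#' distinct so that the true ordering is strict.
#'
#' @param alternatives character vector of image identifiers (opaque strings;
#'   lexicographic order among them is used for deterministic tie-breaks).
#' @param true_counts integer vector of dot counts, one per alternative (named
#'   or in the order of `alternatives`).
#' @return An object of class `universe` with elements `alternatives` and
#'   `true_counts` (named integer vector).
#' @export
universe <- function(alternatives, true_counts) {
  alternatives <- as.character(alternatives)
  if (anyDuplicated(alternatives))
    stop("universe: duplicated image identifiers")
  if (length(true_counts) != length(alternatives))
    stop("universe: one true count per alternative is required")
  if (is.null(names(true_counts))) {
    names(true_counts) <- alternatives
  } else {
    if (!setequal(names(true_counts), alternatives))
      stop("universe: names of true_counts do not match alternatives")
    true_counts <- true_counts[alternatives]
  }
  if (anyDuplicated(true_counts))
    stop("universe: true counts must be distinct")
  structure(list(alternatives = alternatives,
                 true_counts = true_counts),
            class = "universe")
}

#' @export
print.universe <- function(x, ...) {
  cat("<universe> ", length(x$alternatives), " images, counts in [",
      min(x$true_counts), ", ", max(x$true_counts), "]\n", sep = "")
  invisible(x)
}

#' Ground-truth ranking of a universe
#'
#' @param u a [universe()].
#' @return Strict ranking (named integer vector) of all alternatives by
#'   increasing true count.
#' @export
truth_ranking <- function(u) {
  stopifnot(inherits(u, "universe"))
  rank_of(u$true_counts)
}

#' Ordinal ballot
#'
#' A participant's (possibly tied) ranking over a subset of the universe.
#' Positions follow the competition convention: each position equals one plus
#' the number of items ranked strictly ahead.
#'
#' @param participant_id scalar identifier.
#' @param positions named integer vector of rank positions over the ballot's
#'   support (position 1 = fewest dots).
#' @return An object of class `ordinal_ballot`.
#' @export
ordinal_ballot <- function(participant_id, positions) {
  if (length(positions) == 0L) stop("ordinal_ballot: empty ballot")
  if (is.null(names(positions)) || anyDuplicated(names(positions)))
    stop("ordinal_ballot: positions must be uniquely named by image id")
  nm <- names(positions)
  structure(list(participant_id = participant_id,
                 positions = stats::setNames(as.integer(positions), nm)),
            class = "ordinal_ballot")
}

#' @export
format.ordinal_ballot <- function(x, ...) {
  paste0("<ordinal_ballot ", x$participant_id, "> ",
         paste(names(sort(x$positions)), collapse = " ≺ "))
}

#' @export
print.ordinal_ballot <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Numerical ballot
#'
#' A participant's dot-count estimates over a subset of the universe.
#'
#' @param participant_id scalar identifier.
#' @param estimates named numeric vector of strictly positive, finite guesses.
#' @return An object of class `numerical_ballot`.
#' @export
numerical_ballot <- function(participant_id, estimates) {
  if (length(estimates) == 0L) stop("numerical_ballot: empty ballot")
  if (is.null(names(estimates)) || anyDuplicated(names(estimates)))
    stop("numerical_ballot: estimates must be uniquely named by image id")
  if (any(!is.finite(estimates)) || any(estimates <= 0))
    stop("numerical_ballot: estimates must be finite and > 0")
  structure(list(participant_id = participant_id,
                 estimates = estimates),
            class = "numerical_ballot")
}

#' @export
print.numerical_ballot <- function(x, ...) {
  cat("<numerical_ballot ", x$participant_id, "> ", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Participant record
#'
#' Couples one participant's ordinal and numerical ballots (same support)
#' with their elicitation condition and task size.
#'
#' @param participant_id scalar identifier.
#' @param interface_condition `"joint"` or `"independent"`.
#' @param task_size integer; must equal the ballot support size.
#' @param ordinal an [ordinal_ballot()].
#' @param numerical a [numerical_ballot()].
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(participant_id, interface_condition,
                               task_size, ordinal, numerical) {
  interface_condition <- match.arg(interface_condition, c("joint", "independent"))
  stopifnot(inherits(ordinal, "ordinal_ballot"),
            inherits(numerical, "numerical_ballot"))
  if (!setequal(ballot_support(ordinal), ballot_support(numerical)))
    stop("participant_record: ordinal and numerical supports differ")
  if (length(ballot_support(ordinal)) != task_size)
    stop("participant_record: support size does not equal task_size")
  structure(list(participant_id = participant_id,
                 interface_condition = interface_condition,
                 task_size = as.integer(task_size),
                 ordinal = ordinal,
                 numerical = numerical),
            class = "participant_record")
}

#' Crowd dataset
#'
#' @param universe a [universe()].
#' @param records list of [participant_record()]s.
#' @param task_size integer task size shared by the records.
#' @return An object of class `crowd_dataset`.
#' @export
crowd_dataset <- function(universe, records, task_size) {
  stopifnot(inherits(universe, "universe"))
  structure(list(universe = universe, records = records,
                 task_size = as.integer(task_size)),
            class = "crowd_dataset")
}

#' @export
print.crowd_dataset <- function(x, ...) {
  cat("<crowd_dataset> ", length(x$records), " participants, task size ",
      x$task_size, ", ", length(x$universe$alternatives), " images\n", sep = "")
  invisible(x)
}

#' Support of a ballot
#'
#' @param x an ordinal or numerical ballot, or a named vector.
#' @return Character vector of image ids the ballot evaluates.
#' @export
ballot_support <- function(x) {
  if (inherits(x, "ordinal_ballot")) return(names(x$positions))
  if (inherits(x, "numerical_ballot")) return(names(x$estimates))
  if (!is.null(names(x))) return(names(x))
  stop("ballot_support: not a ballot or named vector")
}

# named vector of positions/estimates from a ballot or pass-through
ballot_values <- function(x) {
  if (inherits(x, "ordinal_ballot")) return(x$positions)
  if (inherits(x, "numerical_ballot")) return(x$estimates)
  x
}

#' Convert numerical values to a tied competition ranking
#'
#' The ith position is the rank the ith value occupies when all values are
#' sorted in non-decreasing order, accounting for ties: the smallest value
#' receives position 1 and equal values share the position
#' `1 + number of strictly smaller values`.
#'
#' @param values named numeric vector (finite).
#' @return Named integer vector of competition rank positions.
#' @examples
#' rank_of(c(a = 57, b = 45, c = 60))  # 2 1 3
#' rank_of(c(a = 50, b = 50, c = 60))  # 1 1 3
#' @export
rank_of <- function(values) {
  values <- ballot_values(values)
  if (length(values) == 0L) stop("rank_of: empty ballot")
  if (any(!is.finite(values))) stop("rank_of: values must be finite")
  r <- rank(values, ties.method = "min")
  stats::setNames(as.integer(r), names(values))
}

#' Project a ranking onto a subset of its support
#'
#' Retains only the items in `subset` and re-compacts positions to a valid
#' competition ranking; the relative order and tie structure among retained
#' items are preserved.
#'
#' @param ranking named (tied) ranking vector or [ordinal_ballot()].
#' @param subset character vector of image ids, a subset of the support.
#' @return Named integer ranking over `subset`.
#' @export
project_ranking <- function(ranking, subset) {
  r <- ballot_values(ranking)
  subset <- as.character(subset)
  if (!all(subset %in% names(r)))
    stop("project_ranking: subset is not contained in the ranking support")
  rank_of(r[subset])
}

#' Common support of two ballots
#'
#' @param u,v ballots or named vectors.
#' @return Character vector: the intersection of the two supports.
#' @export
common_support <- function(u, v) {
  intersect(ballot_support(u), ballot_support(v))
}

#' Validate a crowd dataset
#'
#' Checks every structural invariant of the data model and reports violations
#' instead of erroring, so malformed external data can be triaged.
#'
#' @param dataset a [crowd_dataset()].
#' @return A data.frame with columns `record` (participant id or `"<dataset>"`)
#'   and `rule`; zero rows when the dataset is well formed.
#' @export
validate_dataset <- function(dataset) {
  bad <- list()
  flag <- function(record, rule) bad[[length(bad) + 1L]] <<- data.frame(
    record = as.character(record), rule = rule, stringsAsFactors = FALSE)

  u <- dataset$universe
  if (anyDuplicated(u$true_counts))
    flag("<dataset>", "universe counts not distinct")

  n_img <- length(u$alternatives)
  for (rec in dataset$records) {
    id <- rec$participant_id
    so <- ballot_support(rec$ordinal); sn <- ballot_support(rec$numerical)
    if (!setequal(so, sn)) flag(id, "ordinal and numerical supports differ")
    if (length(so) != rec$task_size) flag(id, "support size != task_size")
    if (!all(so %in% u$alternatives) || !all(sn %in% u$alternatives))
      flag(id, "ballot support outside universe")
    pos <- rec$ordinal$positions
    # competition validity: each position equals 1 + #items strictly ahead
    expected <- vapply(pos, function(p) 1L + sum(pos < p), integer(1))
    if (!all(pos == expected)) flag(id, "invalid competition ranking")
    est <- rec$numerical$estimates
    if (any(!is.finite(est)) || any(est <= 0)) flag(id, "invalid estimates")
  }

  total_views <- length(dataset$records) * dataset$task_size
  if (n_img > 0 && total_views %% n_img == 0L && length(dataset$records) > 0) {
    views <- table(factor(unlist(lapply(dataset$records,
                                        function(r) ballot_support(r$ordinal))),
                          levels = u$alternatives))
    if (length(unique(as.integer(views))) > 1L)
      flag("<dataset>", "per-image view counts unbalanced")
  }

  if (length(bad) == 0L)
    return(data.frame(record = character(), rule = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, bad)
}
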