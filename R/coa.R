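# The cardinal-and-ordinal aggregation (COA) consensus model.  COA finds a
# numerical consensus vector r over the universe whose induced ranking
# rank(r) jointly minimizes
#
#   w_card * sum_l d_NPCK(b^l, r)  +  w_ord * sum_l d_NPKS(a^l, rank(r))
#
# over all strict-ordering/value pairs.  Two solution paths are provided: an
# exhaustive oracle (all orderings, inner linear program per ordering) for
# small universes, and an anytime mixed-integer program with big-M linking,
# transitivity constraints and optimality-gap reporting for realistic sizes.

#' COA problem instance
#'
#' @param universe character vector of image ids (V).
#' @param ordinal_ballots list of [ordinal_ballot()]s with supports in V.
#' @param numerical_ballots list of [numerical_ballot()]s with supports in V.
#' @param range_info a [range_info()]; defaults to the range over all
#'   numerical inputs of the instance.
#' @param term_weights numeric length-2 `(w_ord, w_card)`; both default to 1.
#'   Exposed because the printed normalizations give the ordinal and cardinal
#'   terms different effective ranges.
#' @param epsilon strict-separation constant between consecutive consensus
#'   values (default 1, the dot-count granularity).
#' @param time_limit_seconds solver time limit for [solve_coa()] (default
#'   600, i.e. the 10-minute budget used in evaluation).
#' @return An object of class `coa_instance`.
#' @export
coa_instance <- function(universe, ordinal_ballots, numerical_ballots,
                         range_info = NULL, term_weights = c(1, 1),
                         epsilon = 1, time_limit_seconds = 600) {
  universe <- sort(as.character(universe))
  for (b in ordinal_ballots)
    if (!all(ballot_support(b) %in% universe))
      stop("coa_instance: ordinal ballot support outside the universe")
  for (b in numerical_ballots)
    if (!all(ballot_support(b) %in% universe))
      stop("coa_instance: numerical ballot support outside the universe")
  if (is.null(range_info)) {
    if (length(numerical_ballots) == 0L)
      stop("coa_instance: range_info is required without numerical ballots")
    range_info <- range_of_inputs(numerical_ballots)
  }
  if (range_info$range_width <= 0)
    stop("coa_instance: range_width must be > 0")
  if (epsilon <= 0) stop("coa_instance: epsilon must be > 0")
  structure(list(universe = universe,
                 ordinal_ballots = ordinal_ballots,
                 numerical_ballots = numerical_ballots,
                 range_info = range_info,
                 term_weights = c(w_ord = term_weights[[1]],
                                  w_card = term_weights[[2]]),
                 epsilon = epsilon,
                 time_limit_seconds = time_limit_seconds),
            class = "coa_instance")
}

new_coa_solution <- function(values, objective, gap, status) {
  structure(list(consensus_values = values,
                 consensus_ranking = rank_of(values),
                 objective = objective,
                 gap = gap,
                 status = status),
            class = "coa_solution")
}

#' @export
print.coa_solution <- function(x, ...) {
  cat("<coa_solution> status =", x$status,
      sprintf("objective = %.6g gap = %.4g\n", x$objective, x$gap))
  ord <- names(sort(x$consensus_ranking))
  cat("  consensus:", paste(ord, collapse = " < "), "\n")
  invisible(x)
}

#' COA objective value of a candidate consensus vector
#'
#' @param instance a [coa_instance()].
#' @param candidate_values named numeric vector defined on the full universe.
#' @return The weighted sum of normalized projected Cook-Kress distances from
#'   the numerical ballots to the candidate and normalized projected
#'   Kemeny-Snell distances from the ordinal ballots to its induced ranking.
#' @export
objective_value <- function(instance, candidate_values) {
  stopifnot(inherits(instance, "coa_instance"))
  if (!all(instance$universe %in% names(candidate_values)))
    stop("objective_value: candidate must cover the full universe")
  r <- candidate_values[instance$universe]
  rr <- rank_of(r)
  card <- sum(vapply(instance$numerical_ballots,
                     function(b) npck(b, r, instance$range_info), numeric(1)))
  ord <- sum(vapply(instance$ordinal_ballots,
                    function(a) npks(a, rr), numeric(1)))
  instance$term_weights[["w_card"]] * card +
    instance$term_weights[["w_ord"]] * ord
}

# ---------------------------------------------------------------------------
# shared model pieces

# Per-ordinal-ballot pair data: support pairs in lexicographic (i < j) order,
# the ballot's relation on each pair, and the d_NPKS-induced weights: a
# disagreeing strict pair costs 2/(m(m-1)/2), a ballot-tied pair costs a
# constant 1/(m(m-1)/2) against any strict consensus.
ordinal_pair_data <- function(instance) {
  w_ord <- instance$term_weights[["w_ord"]]
  out <- list()
  for (ob in instance$ordinal_ballots) {
    pos <- ob$positions
    m <- length(pos)
    if (m < 2L) next
    ids <- sort(names(pos))
    pr <- utils::combn(ids, 2L)
    rel <- sign(pos[pr[1L, ]] - pos[pr[2L, ]])
    norm <- m * (m - 1) / 2
    out[[length(out) + 1L]] <- list(
      i = pr[1L, ], j = pr[2L, ], rel = as.integer(rel),
      pair_weight = 2 * w_ord / norm,
      tie_const = sum(rel == 0L) * w_ord / norm)
  }
  out
}

# ordinal cost of a strict consensus given as a position vector over V
ordinal_cost <- function(pair_data, positions) {
  total <- 0
  for (pd in pair_data) {
    s <- sign(positions[pd$i] - positions[pd$j])
    total <- total + pd$pair_weight * sum(pd$rel * s == -1L) + pd$tie_const
  }
  total
}

# Per-numerical-ballot pair data with d_NPCK weights.
cardinal_pair_data <- function(instance) {
  w_card <- instance$term_weights[["w_card"]]
  R <- instance$range_info$range_width
  out <- list()
  for (nb in instance$numerical_ballots) {
    est <- nb$estimates
    m <- length(est)
    if (m < 2L) next
    ids <- sort(names(est))
    pr <- utils::combn(ids, 2L)
    out[[length(out) + 1L]] <- list(
      i = pr[1L, ], j = pr[2L, ],
      d = as.numeric(est[pr[1L, ]] - est[pr[2L, ]]),
      weight = w_card / (4 * R * ceiling(m / 2) * floor(m / 2)))
  }
  out
}

# all permutations of 1..n in lexicographic order (n! x n matrix)
perms_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(n - 1L)
  blocks <- lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  })
  do.call(rbind, blocks)
}

# Inner LP for one ordering: minimize the cardinal term over consensus values
# monotone along the ordering (epsilon-separated, bounded by the input range).
# `ordering` is an integer permutation of seq_along(universe).
build_inner_lp <- function(instance, card_data, ordering) {
  ids <- instance$universe
  n <- length(ids)
  nz <- sum(vapply(card_data, function(cd) length(cd$d), integer(1)))
  idx_r <- stats::setNames(seq_len(n), ids)
  c_obj <- numeric(n + nz)
  cons <- new_constraints()
  z0 <- n
  for (cd in card_data) {
    for (k in seq_along(cd$d)) {
      z0 <- z0 + 1L
      c_obj[z0] <- cd$weight
      ri <- idx_r[[cd$i[k]]]; rj <- idx_r[[cd$j[k]]]
      add_row(cons, c(z0, ri, rj), c(1, 1, -1), cd$d[k], Inf)
      add_row(cons, c(z0, ri, rj), c(1, -1, 1), -cd$d[k], Inf)
    }
  }
  for (k in seq_len(n - 1L))
    add_row(cons, c(idx_r[[ids[ordering[k + 1L]]]],
                    idx_r[[ids[ordering[k]]]]),
            c(1, -1), instance$epsilon, Inf)
  list(c_obj = c_obj, cons = cons,
       bounds_lb = c(rep(instance$range_info$range_low, n), rep(0, nz)),
       bounds_ub = c(rep(instance$range_info$range_high, n),
                     rep(Inf, nz)))
}

#' Exhaustive COA oracle for small universes
#'
#' Enumerates every strict ordering of the universe; for each, the inner
#' continuous minimization of the cardinal term (consensus values monotone
#' along the ordering, epsilon-separated, bounded by the input range) is
#' solved as a linear program, and the ordinal term is a constant.  Returns
#' the global minimizer; ties between orderings are broken by the first
#' optimum in lexicographic enumeration order.
#'
#' @param instance a [coa_instance()].
#' @param max_universe refusal threshold on `|V|` (default 7).
#' @return A `coa_solution` with `status = "optimal"` and `gap = 0`.
#' @export
brute_force_coa <- function(instance, max_universe = 7L) {
  stopifnot(inherits(instance, "coa_instance"))
  ids <- instance$universe
  n <- length(ids)
  if (n > max_universe)
    stop("brute_force_coa: universe larger than max_universe (", max_universe,
         ")")
  eps <- instance$epsilon
  L <- instance$range_info$range_low
  U <- instance$range_info$range_high
  if ((n - 1) * eps > instance$range_info$range_width)
    stop("brute_force_coa: range too narrow for ", n,
         " epsilon-separated values")
  if (n == 1L)
    return(new_coa_solution(stats::setNames(L, ids), 0, 0, "optimal"))

  ord_data <- ordinal_pair_data(instance)
  card_data <- cardinal_pair_data(instance)
  perms <- perms_lex(n)

  ord_costs <- apply(perms, 1L, function(p) {
    pos <- integer(n); pos[p] <- seq_len(n)
    ordinal_cost(ord_data, stats::setNames(pos, ids))
  })

  if (length(card_data) == 0L) {
    best <- which.min(ord_costs)  # first minimum in lexicographic order
    p <- perms[best, ]
    vals <- numeric(n); vals[p] <- L + (seq_len(n) - 1L) * eps
    vals <- stats::setNames(vals, ids)
    return(new_coa_solution(vals, ord_costs[best], 0, "optimal"))
  }

  lps <- lapply(seq_len(nrow(perms)), function(k)
    build_inner_lp(instance, card_data, perms[k, ]))
  res <- solve_backend_lp_batch(lps)
  card_costs <- vapply(res, function(r) {
    if (r$status != 0L)
      stop("brute_force_coa: inner LP failed (", r$message, ")")
    r$fun
  }, numeric(1))
  total <- ord_costs + card_costs
  best <- which.min(total)
  vals <- stats::setNames(unlist(res[[best]]$x)[seq_len(n)], ids)
  new_coa_solution(vals, objective_value(instance, vals), 0, "optimal")
}

#' Solve the COA model as a mixed-integer program
#'
#' The consensus ordering is encoded with binary precedence variables
#' `x_ij` (one per unordered pair, `x_ij = 1` meaning `r_i < r_j`) subject to
#' transitivity constraints `0 <= x_ij + x_jk - x_ik <= 1`; continuous
#' consensus values `r_i` are linked to the precedences by big-M constraints
#' `r_j - r_i >= eps - M(1 - x_ij)` and `r_i - r_j >= eps - M x_ij` with
#' `M = range_width + eps`, which enforce strict epsilon-separation.  The
#' cardinal absolute deviations are linearized with auxiliaries
#' `z >= +/-((b_i - b_j) - (r_i - r_j))` carrying the per-ballot
#' normalization weights; the ordinal term is linear in `x` with per-ballot
#' weights (plus constants for ballot-tied pairs).  The branch-and-bound
#' backend is run under the instance time limit; the incumbent and its
#' optimality gap `(incumbent - best_bound) / incumbent` are returned.
#'
#' @param instance a [coa_instance()].
#' @return A `coa_solution`; `status` is `"optimal"`, `"time_limit"` or
#'   `"infeasible"`.
#' @export
solve_coa <- function(instance) {
  stopifnot(inherits(instance, "coa_instance"))
  ids <- instance$universe
  n <- length(ids)
  eps <- instance$epsilon
  L <- instance$range_info$range_low
  U <- instance$range_info$range_high
  if (n == 1L)
    return(new_coa_solution(stats::setNames(L, ids), 0, 0, "optimal"))
  bigM <- instance$range_info$range_width + eps

  pair_i <- utils::combn(n, 2L)
  npairs <- ncol(pair_i)
  idx_x <- matrix(0L, n, n)   # x index for pair (min, max)
  for (k in seq_len(npairs))
    idx_x[pair_i[1L, k], pair_i[2L, k]] <- k
  idx_r <- stats::setNames(npairs + seq_len(n), ids)

  ord_data <- ordinal_pair_data(instance)
  card_data <- cardinal_pair_data(instance)
  nz <- sum(vapply(card_data, function(cd) length(cd$d), integer(1)))
  nvar <- npairs + n + nz

  c_obj <- numeric(nvar)
  const <- 0
  pos_of <- stats::setNames(seq_len(n), ids)  # lexicographic index of id
  for (pd in ord_data) {
    const <- const + pd$tie_const
    for (k in seq_along(pd$rel)) {
      ii <- pos_of[[pd$i[k]]]; jj <- pos_of[[pd$j[k]]]  # ii < jj by sorting
      xk <- idx_x[ii, jj]
      if (pd$rel[k] < 0L) {          # ballot says i before j: pay when x=0
        c_obj[xk] <- c_obj[xk] - pd$pair_weight
        const <- const + pd$pair_weight
      } else if (pd$rel[k] > 0L) {   # ballot says j before i: pay when x=1
        c_obj[xk] <- c_obj[xk] + pd$pair_weight
      }
    }
  }

  cons <- new_constraints()
  # transitivity on ordered triples i < j < k
  if (n >= 3L) {
    tri <- utils::combn(n, 3L)
    for (t in seq_len(ncol(tri))) {
      i <- tri[1L, t]; j <- tri[2L, t]; k <- tri[3L, t]
      add_row(cons, c(idx_x[i, j], idx_x[j, k], idx_x[i, k]),
              c(1, 1, -1), 0, 1)
    }
  }
  # big-M linking of precedences and values
  for (k in seq_len(npairs)) {
    i <- pair_i[1L, k]; j <- pair_i[2L, k]
    add_row(cons, c(idx_r[[ids[j]]], idx_r[[ids[i]]], k),
            c(1, -1, -bigM), eps - bigM, Inf)
    add_row(cons, c(idx_r[[ids[i]]], idx_r[[ids[j]]], k),
            c(1, -1, bigM), eps, Inf)
  }
  # cardinal linearization
  z0 <- npairs + n
  for (cd in card_data) {
    for (k in seq_along(cd$d)) {
      z0 <- z0 + 1L
      c_obj[z0] <- cd$weight
      ri <- idx_r[[cd$i[k]]]; rj <- idx_r[[cd$j[k]]]
      add_row(cons, c(z0, ri, rj), c(1, 1, -1), cd$d[k], Inf)
      add_row(cons, c(z0, ri, rj), c(1, -1, 1), -cd$d[k], Inf)
    }
  }

  res <- solve_backend_milp(
    c_obj, cons,
    bounds_lb = c(rep(0, npairs), rep(L, n), rep(0, nz)),
    bounds_ub = c(rep(1, npairs), rep(U, n), rep(Inf, nz)),
    integrality = c(rep(1L, npairs), rep(0L, n + nz)),
    time_limit = instance$time_limit_seconds)

  if (res$status == 2L)
    return(structure(list(consensus_values = NULL, consensus_ranking = NULL,
                          objective = NA_real_, gap = NA_real_,
                          status = "infeasible"), class = "coa_solution"))
  if (is.null(res$x))
    stop("solve_coa: backend returned no incumbent (", res$message, ")")

  vals <- stats::setNames(unlist(res$x)[npairs + seq_len(n)], ids)
  objective <- objective_value(instance, vals)
  if (res$status == 0L) {
    gap <- 0
    status <- "optimal"
  } else {
    incumbent <- res$fun + const
    bound <- res$mip_dual_bound + const
    gap <- if (incumbent > 0) max(0, (incumbent - bound) / incumbent) else 0
    status <- "time_limit"
  }
  new_coa_solution(vals, objective, gap, status)
}

#' COA consensus from participant records
#'
#' Assembles a [coa_instance()] from a list of records (instance-level range
#' over all numerical inputs) and dispatches to [brute_force_coa()] when an
#' exact solve over a small universe is requested, otherwise to
#' [solve_coa()].
#'
#' @param records list of [participant_record()]s.
#' @param universe character vector of image ids (defaults to the union of
#'   ballot supports).
#' @param exact logical; request the exhaustive oracle (only available for
#'   universes of at most 7 images).
#' @param epsilon,term_weights,time_limit_seconds passed to [coa_instance()].
#' @return A `coa_solution`.
#' @export
coa_consensus <- function(records, universe = NULL, exact = FALSE,
                          epsilon = 1, term_weights = c(1, 1),
                          time_limit_seconds = 600) {
  if (length(records) == 0L) stop("coa_consensus: empty records")
  ords <- lapply(records, function(r) r$ordinal)
  nums <- lapply(records, function(r) r$numerical)
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(ords, ballot_support))))
  inst <- coa_instance(universe, ords, nums,
                       term_weights = term_weights, epsilon = epsilon,
                       time_limit_seconds = time_limit_seconds)
  if (exact) brute_force_coa(inst) else solve_coa(inst)
}
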