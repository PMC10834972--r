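# Thin interface to the LP/MIP solver backend.  Any branch-and-bound
# mixed-integer solver with incumbent/bound (gap) reporting qualifies; the
# default backend is HiGHS, reached through scipy.optimize in a python
# subprocess with JSON round-tripping.  Problems are expressed as
#   min c'x  s.t.  lb <= A x <= ub,  bounds_lb <= x <= bounds_ub,
# with A in triplet (row/col/val, 0-based) form.

solver_python <- function() {
  py <- getOption("crowdrank.python", Sys.getenv("CROWDRANK_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("solver backend unavailable: no 'python' with scipy on the PATH ",
         "(set options(crowdrank.python=) to point at one)")
  py
}

encode_inf <- function(x) {
  lapply(x, function(v) {
    if (is.infinite(v)) { if (v > 0) "inf" else "-inf" } else v
  })
}

call_backend <- function(problem) {
  script <- system.file("python", "lp_backend.py", package = "crowdrank",
                        mustWork = TRUE)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(problem, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(solver_python(), c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outfile))
    stop("solver backend (python/scipy HiGHS) failed with exit status ",
         status)
  jsonlite::read_json(outfile, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

# Triplet-form constraint accumulator used while building models.
new_constraints <- function() {
  env <- new.env(parent = emptyenv())
  env$row <- integer(0); env$col <- integer(0); env$val <- numeric(0)
  env$lb <- numeric(0); env$ub <- numeric(0); env$n <- 0L
  env
}

# cols: 1-based variable indices; lb/ub: row bounds
add_row <- function(cons, cols, vals, lb, ub) {
  k <- length(cols)
  cons$row <- c(cons$row, rep.int(cons$n, k))  # 0-based row index
  cons$col <- c(cons$col, as.integer(cols) - 1L)
  cons$val <- c(cons$val, as.numeric(vals))
  cons$lb <- c(cons$lb, lb)
  cons$ub <- c(cons$ub, ub)
  cons$n <- cons$n + 1L
  invisible(cons)
}

constraints_payload <- function(cons) {
  list(row = cons$row, col = cons$col, val = cons$val,
       lb = encode_inf(cons$lb), ub = encode_inf(cons$ub), nrow = cons$n)
}

solve_backend_milp <- function(c_obj, cons, bounds_lb, bounds_ub,
                               integrality, time_limit = NULL,
                               mip_rel_gap = 1e-9) {
  call_backend(list(
    kind = "milp", c = c_obj, constraints = constraints_payload(cons),
    bounds_lb = encode_inf(bounds_lb), bounds_ub = encode_inf(bounds_ub),
    integrality = as.integer(integrality),
    time_limit = time_limit, mip_rel_gap = mip_rel_gap))
}

solve_backend_lp_batch <- function(problems) {
  payload <- lapply(problems, function(p) list(
    kind = "lp", c = p$c_obj, constraints = constraints_payload(p$cons),
    bounds_lb = encode_inf(p$bounds_lb), bounds_ub = encode_inf(p$bounds_ub)))
  call_backend(list(kind = "lp_batch", problems = payload))$results
}
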