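#' Replicator dynamics right-hand side
#'
#' Growth rate of the mutant fraction under imitation/selection proportional
#' to utility: `df/dt = f (1 - f) (U_m(f) - U_r(f))`, where the two utilities
#' are evaluated at the endemic equilibrium of the dimorphic contagion system
#' for the current `f` (quasi-static timescale separation: contagion dynamics
#' are assumed much faster than strategy competition).
#'
#' @param f Mutant fraction in `[0, 1]`.
#' @param model A `utility_model`.
#' @param R_r,R_m Resident and mutant good-contagion reproduction numbers.
#' @param c Relative transmissibility of the bad contagion (> 0).
#' @return Scalar `df/dt`.
#' @export
replicator_rhs <- function(f, model, R_r, R_m, c) {
  stopifnot(f >= 0, f <= 1)
  if (f == 0 || f == 1) return(0)
  u <- strategy_utilities(model, dimorphic_params(R_r, R_m, f, c))
  f * (1 - f) * (u[["U_m"]] - u[["U_r"]])
}

#' Integrate the replicator dynamics of two sociality strategies
#'
#' Adaptive integration of the mutant-fraction equation with quasi-static
#' contagion equilibria, stopping early once `f` comes within `1e-6` of a
#' boundary (strategy fixation) or the flow stalls below `tol` at an interior
#' point.
#'
#' @inheritParams replicator_rhs
#' @param f0 Initial mutant fraction in `(0, 1)`.
#' @param t_max Maximum integration time (utilities are O(1), so this is in
#'   units where a utility gap of 1 fixes in a few time units).
#' @param tol Stall tolerance on `|df/dt|` for interior classification.
#' @param n_out Number of output points per integration leg.
#' @return Object of class `replicator_trajectory`: data.frame-backed list
#'   with `times`, `f_values`, `terminal_f`, and `terminal_classification`
#'   in `{"mutant_fixed", "resident_fixed", "interior", "max_time"}`.
#' @examples
#' \donttest{
#' simulate_replicator(cobb_douglas_utility(0.75), R_r = 4, R_m = 7,
#'                     c = 0.25, f0 = 0.5)
#' }
#' @export
simulate_replicator <- function(model, R_r, R_m, c, f0, t_max = 1e5,
                                tol = 1e-10, n_out = 200) {
  stopifnot(f0 > 0, f0 < 1, t_max > 0)
  edge <- 1e-6
  rhs <- function(t, y, p) {
    f <- min(max(y[1], 0), 1)
    list(replicator_rhs(f, model, R_r, R_m, c))
  }
  rootfun <- function(t, y, p) c(y[1] - edge, (1 - edge) - y[1])
  times <- unique(c(0, exp(seq(log(1e-2), log(t_max), length.out = n_out))))
  sol <- deSolve::lsodar(y = c(f = f0), times = times, func = rhs,
                         parms = NULL, rootfunc = rootfun,
                         rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("t", "f")
  out$f <- pmin(pmax(out$f, 0), 1)
  terminal_f <- out$f[nrow(out)]
  rate <- replicator_rhs(terminal_f, model, R_r, R_m, c)
  classification <-
    if (terminal_f <= edge * (1 + 1e-9)) "resident_fixed"
    else if (terminal_f >= 1 - edge * (1 + 1e-9)) "mutant_fixed"
    else if (abs(rate) < tol) "interior"
    else "max_time"
  structure(list(times = out$t, f_values = out$f, terminal_f = terminal_f,
                 terminal_classification = classification),
            class = "replicator_trajectory")
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  cat("Replicator trajectory:", length(x$times), "time points\n")
  cat(sprintf("  terminal f = %.6f (%s)\n", x$terminal_f,
              x$terminal_classification))
  invisible(x)
}

#' @export
as.data.frame.replicator_trajectory <- function(x, ...) {
  data.frame(t = x$times, f = x$f_values)
}

#' Interior equilibrium of the replicator dynamics
#'
#' Finds the mutant fraction at which resident and mutant utilities are equal,
#' by bracketed root-finding on `U_m(f) - U_r(f)` over `[1e-6, 1 - 1e-6]`
#' with the dimorphic contagion equilibrium solved at each candidate `f`.
#' For Cobb-Douglas utility the log-utility difference is strictly decreasing
#' in `f`, so any root is unique; for other models the difference is scanned
#' on a grid and all sign changes are refined, with a warning when more than
#' one root is found.
#'
#' @inheritParams replicator_rhs
#' @param n_scan Grid size for the multiple-root scan (non-Cobb-Douglas).
#' @return The interior root(s) as a numeric vector, or `NULL` when the
#'   utility difference has the same sign at both endpoints.
#' @export
find_interior_equilibrium <- function(model, R_r, R_m, c, n_scan = 51) {
  if (R_r == R_m) stop("strategies are identical: interior equilibrium undefined")
  g <- function(f) {
    u <- strategy_utilities(model, dimorphic_params(R_r, R_m, f, c))
    u[["U_m"]] - u[["U_r"]]
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  if (inherits(model, "cobb_douglas_utility")) {
    glo <- g(lo); ghi <- g(hi)
    if (sign(glo) == sign(ghi)) return(NULL)
    return(stats::uniroot(g, c(lo, hi), f.lower = glo, f.upper = ghi,
                          tol = 1e-12)$root)
  }
  grid <- seq(lo, hi, length.out = n_scan)
  vals <- vapply(grid, g, 0)
  ix <- which(diff(sign(vals)) != 0)
  if (length(ix) == 0) return(NULL)
  roots <- vapply(ix, function(i)
    stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-12)$root, 0)
  if (length(roots) > 1)
    warning("multiple interior equilibria detected for a non-Cobb-Douglas model")
  roots
}

#' Classify the outcome of pairwise strategy competition
#'
#' Determines the long-time outcome of replicator competition from the sign
#' of the utility difference at the two boundaries, evaluated through the
#' rare-type closed forms (avoiding the degenerate dimorphic system at exact
#' boundaries): mutant dominance, resident dominance, or protected
#' coexistence at a unique interior equilibrium. For Cobb-Douglas utility
#' with both strategies above the epidemic threshold these three cases are
#' exhaustive (bistability is impossible).
#'
#' @inheritParams replicator_rhs
#' @return Object of class `pairwise_outcome`: list with `kind` in
#'   `{"MUTANT_DOMINATES", "RESIDENT_DOMINATES", "COEXISTENCE"}`, `f_eq`
#'   (only for coexistence), and `endpoint_signs`.
#' @examples
#' classify_pairwise(cobb_douglas_utility(0.25), R_r = 7, R_m = 3, c = 0.25)
#' @export
classify_pairwise <- function(model, R_r, R_m, c) {
  stopifnot(R_r >= 0, R_m >= 0, c > 0)
  if (R_r < 1 || R_m < 1)
    warning("classification outside R >= 1: endpoint-sign heuristic only")
  # f -> 0: mutant rare in resident population
  mr0 <- mutant_rare_equilibrium(R_m, R_r, c)
  U_m0 <- evaluate_utility(model, mr0[["I_m_g"]], mr0[["S_m_b"]])
  U_r0 <- monomorphic_utility(model, R_r, c)
  # f -> 1: resident rare in mutant population
  mr1 <- mutant_rare_equilibrium(R_r, R_m, c)
  U_r1 <- evaluate_utility(model, mr1[["I_m_g"]], mr1[["S_m_b"]])
  U_m1 <- monomorphic_utility(model, R_m, c)
  d0 <- U_m0 - U_r0
  d1 <- U_m1 - U_r1
  if (abs(d0) < 1e-12 && abs(d1) < 1e-12)
    stop("degenerate competition: utilities equal at both boundaries")
  kind <- if (d0 > 0 && d1 > 0) "MUTANT_DOMINATES"
  else if (d0 < 0 && d1 < 0) "RESIDENT_DOMINATES"
  else if (d0 > 0 && d1 < 0) "COEXISTENCE"
  else "BISTABILITY"
  if (kind == "BISTABILITY") {
    if (inherits(model, "cobb_douglas_utility"))
      stop("endpoint signs indicate bistability, impossible for Cobb-Douglas ",
           "utility; check inputs")
    warning("endpoint signs indicate bistability (non-Cobb-Douglas model)")
  }
  f_eq <- if (kind == "COEXISTENCE")
    find_interior_equilibrium(model, R_r, R_m, c) else NULL
  structure(list(kind = kind, f_eq = f_eq,
                 endpoint_signs = c(f0 = sign(d0), f1 = sign(d1)),
                 endpoint_differences = c(f0 = d0, f1 = d1)),
            class = "pairwise_outcome")
}

#' @export
print.pairwise_outcome <- function(x, ...) {
  cat("Pairwise competition outcome:", x$kind, "\n")
  if (!is.null(x$f_eq))
    cat(sprintf("  interior equilibrium f_eq = %.6f\n", x$f_eq))
  cat(sprintf("  U_m - U_r at f=0: %+.3e; at f=1: %+.3e\n",
              x$endpoint_differences[1], x$endpoint_differences[2]))
  invisible(x)
}
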