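#' Invasion fitness of a rare mutant sociality strategy
#'
#' Log-utility advantage of a rare mutant with reproduction number `R_m` in a
#' resident population at its endemic equilibrium:
#' `s_{R_r}(R_m) = log U[R_m, R_r] - log U[R_r, R_r]`, where `U[R_m, R_r]`
#' evaluates the utility model at the rare-mutant equilibrium exposure.
#' `s_{R_r}(R_r) = 0` exactly.
#'
#' When either utility vanishes (Cobb-Douglas with a sub-threshold strategy)
#' the result is a signed infinity with a warning rather than a silent `NaN`.
#'
#' @param R_m Mutant good-contagion reproduction number.
#' @param R_r Resident good-contagion reproduction number (> 1).
#' @param model A `utility_model`.
#' @param c Relative transmissibility of the bad contagion (> 0).
#' @return Invasion fitness (scalar); positive means the mutant can invade.
#' @examples
#' invasion_fitness(7, 4, cobb_douglas_utility(0.75), c = 0.25)
#' @export
invasion_fitness <- function(R_m, R_r, model, c) {
  stopifnot(inherits(model, "utility_model"), c > 0)
  if (R_r <= 1) stop("invasion analysis requires an endemic resident (R_r > 1)")
  if (R_m == R_r) return(0)
  mr <- mutant_rare_equilibrium(R_m, R_r, c)
  U_m <- evaluate_utility(model, mr[["I_m_g"]], mr[["S_m_b"]])
  U_r <- monomorphic_utility(model, R_r, c)
  if (U_m == 0 || U_r == 0) {
    warning("zero utility encountered in invasion fitness; returning signed infinity")
    return(log(U_m) - log(U_r))
  }
  log(U_m) - log(U_r)
}

#' Local selection gradient of the sociality trait
#'
#' Derivative of the invasion fitness with respect to the mutant trait,
#' evaluated at the resident value. For Cobb-Douglas utility the exact
#' piecewise closed form is used:
#' `alpha / R_r^2` for `R_r <= 1/c`, and
#' `(alpha - (1 - alpha) (R_r - 1/c)) / R_r^2` otherwise.
#' For general models the gradient is assembled on the log-utility scale from
#' the model's partial derivatives and the rare-mutant equilibrium
#' sensitivities:
#' `s'(R_r) = (1/U) (dU/dI_g * dI_m_g/dR_m + dU/dS_b * dS_m_b/dR_m)`.
#'
#' @param R_r Resident reproduction number (> 1).
#' @param model A `utility_model`.
#' @param c Relative transmissibility (> 0).
#' @param method `"auto"` (closed form for Cobb-Douglas, assembled
#'   otherwise), `"closed_form"`, or `"assembled"`.
#' @return The selection gradient (scalar); its zeros are singular strategies.
#' @export
selection_gradient <- function(R_r, model, c, method = c("auto", "closed_form",
                                                         "assembled")) {
  stopifnot(inherits(model, "utility_model"), c > 0)
  method <- match.arg(method)
  if (any(R_r <= 1)) stop("selection gradient requires R_r > 1")
  if (length(R_r) > 1)
    return(vapply(R_r, selection_gradient, 0, model = model, c = c,
                  method = method))
  use_cf <- (method == "closed_form") ||
    (method == "auto" && inherits(model, "cobb_douglas_utility"))
  if (use_cf) {
    if (!inherits(model, "cobb_douglas_utility"))
      stop("closed form available only for Cobb-Douglas utility")
    a <- model$alpha
    return(if (R_r <= 1 / c) a / R_r^2
           else (a - (1 - a) * (R_r - 1 / c)) / R_r^2)
  }
  eq <- mutant_rare_equilibrium(R_r, R_r, c)
  sens <- mutant_rare_sensitivities(R_r, R_r, c)
  U <- evaluate_utility(model, eq[["I_m_g"]], eq[["S_m_b"]])
  if (U <= 0) stop("zero resident utility: selection gradient undefined")
  pt <- utility_partials(model, eq[["I_m_g"]], eq[["S_m_b"]])
  (pt[["dU_dI_g"]] * sens[["dI_m_g"]] + pt[["dU_dS_b"]] * sens[["dS_m_b"]]) / U
}

#' Singular strategy and its stability classification
#'
#' Locates the singular sociality strategy (zero of the selection gradient)
#' and classifies it by the standard adaptive-dynamics criteria:
#' evolutionary stability from the curvature of invasion fitness in the
#' mutant trait, and convergence stability from the sign change of the
#' gradient through the singular point. For Cobb-Douglas utility the closed
#' form `R_ESS = max(1, 1/c + alpha/(1 - alpha))` is used; the interior
#' singular strategy is infeasible (and the boundary `R = 1` returned) when
#' `alpha < 1/2` and `c > (1 - alpha)/(1 - 2 alpha)`.
#'
#' @param model A `utility_model`.
#' @param c Relative transmissibility (> 0).
#' @param R_max Upper end of the bracket-expansion search for general models.
#' @return Object of class `singular_strategy_result`: list with `R_star`,
#'   `feasible`, `boundary`, `is_ESS`, `is_convergence_stable`, and
#'   `diagnostics`.
#' @examples
#' singular_strategy(cobb_douglas_utility(0.75), c = 0.25)
#' @export
singular_strategy <- function(model, c, R_max = 1e3) {
  stopifnot(inherits(model, "utility_model"), c > 0)
  boundary <- FALSE
  diagnostics <- list()
  if (inherits(model, "cobb_douglas_utility")) {
    a <- model$alpha
    if (a >= 1) stop("alpha = 1 places no weight on the bad contagion: no ",
                     "finite singular strategy")
    interior <- 1 / c + a / (1 - a)
    feasible <- interior > 1 && !(a < 0.5 && c > (1 - a) / (1 - 2 * a))
    R_star <- if (feasible) interior else 1
    boundary <- !feasible
    diagnostics$interior_candidate <- interior
  } else {
    lo <- max(1, 1 / c) * (1 + 1e-9) + 1e-9
    g <- function(R) selection_gradient(R, model, c, method = "assembled")
    hi <- max(2 * lo, 2)
    while (g(lo) * g(hi) > 0 && hi < R_max) hi <- min(2 * hi, R_max)
    if (g(lo) * g(hi) > 0) {
      # no sign change: gradient one-signed up to R_max
      feasible <- FALSE
      boundary <- TRUE
      R_star <- if (g(lo) < 0) 1 else R_max
      diagnostics$note <- "no sign change of the selection gradient in bracket"
    } else {
      R_star <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
      feasible <- TRUE
    }
  }
  # second-order classification at an interior singular point
  is_ESS <- NA
  is_cs <- NA
  if (feasible && R_star > 1) {
    h <- 1e-4 * R_star
    s <- function(Rm) invasion_fitness(Rm, R_star, model, c)
    curv <- (s(R_star + h) - 2 * s(R_star) + s(R_star - h)) / h^2
    is_ESS <- if (abs(curv) < 1e-8) NA else curv < 0
    gl <- selection_gradient(R_star * (1 - 1e-5), model, c)
    gr <- selection_gradient(R_star * (1 + 1e-5), model, c)
    is_cs <- gl > 0 && gr < 0
    diagnostics$curvature <- curv
  } else if (boundary && R_star == 1) {
    # gradient negative just above the boundary: no mutant with more
    # sociality can invade, collapse to the no-spread strategy
    is_ESS <- TRUE
    is_cs <- TRUE
  }
  structure(list(R_star = R_star, feasible = feasible, boundary = boundary,
                 is_ESS = is_ESS, is_convergence_stable = is_cs,
                 diagnostics = diagnostics),
            class = "singular_strategy_result")
}

#' @export
print.singular_strategy_result <- function(x, ...) {
  cat(sprintf("Singular strategy: R* = %g%s\n", x$R_star,
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  feasible: %s; ESS: %s; convergence stable: %s\n",
              x$feasible, x$is_ESS, x$is_convergence_stable))
  invisible(x)
}

#' Compare the evolutionary and social outcomes of sociality
#'
#' Computes the evolutionarily-stable and socially-optimal sociality levels
#' and classifies the resulting regime. The direction of the social dilemma
#' is governed by the relative transmissibility: the ESS exceeds the optimum
#' when the good contagion spreads more readily (`c < 1`), falls short of it
#' when the bad contagion spreads more readily (`c > 1`), and the two
#' coincide only in the structurally-unstable case `c = 1`.
#'
#' For Cobb-Douglas utility the four qualitative regimes are assigned from
#' the case conditions `c` vs `1 - alpha` and `alpha c` vs
#' `(1 - alpha)(c - 1)`:
#' bad contagion eliminated at the optimum yet endemic at the ESS; both
#' endemic with over-socialization; both endemic with under-socialization;
#' and total collapse of sociality (`R_ESS = 1`, the good contagion cannot
#' spread). Exact coincidence (`|c - 1| < 1e-12`) is reported as
#' `"ESS_equals_opt"`.
#'
#' @param model A `utility_model`.
#' @param c Relative transmissibility (> 0).
#' @param ... Passed to [social_optimum()].
#' @return Object of class `regime_classification`: list with `regime`,
#'   `R_opt`, `R_ESS`, `dilemma_direction` in
#'   `{"ESS_greater", "equal", "ESS_smaller"}`, and the underlying results.
#' @examples
#' social_dilemma_report(cobb_douglas_utility(0.75), c = 0.25)
#' @export
social_dilemma_report <- function(model, c, ...) {
  opt <- social_optimum(model, c, ...)
  sing <- singular_strategy(model, c)
  R_opt <- opt$R_opt
  R_ESS <- sing$R_star
  direction <- if (abs(c - 1) < 1e-12) "equal"
  else if (is.finite(R_opt) && R_ESS > R_opt) "ESS_greater"
  else if (is.finite(R_opt) && R_ESS < R_opt) "ESS_smaller"
  else "equal"
  regime <- if (inherits(model, "cobb_douglas_utility")) {
    a <- model$alpha
    if (abs(c - 1) < 1e-12) "ESS_equals_opt"
    else if (a * c < (1 - a) * (c - 1)) "ESS_collapse_no_sociality"
    # at c = 1 - alpha exactly, R_opt = 1/c and the bad contagion sits at its
    # threshold, i.e. is still eliminated at the optimum
    else if (c <= 1 - a) "ESS_exceeds_opt_bad_eliminated_at_opt"
    else if (c < 1) "ESS_exceeds_opt_bad_endemic"
    else "ESS_below_opt_interior"
  } else {
    if (abs(c - 1) < 1e-12) "ESS_equals_opt"
    else if (c < 1) {
      if (is.finite(R_opt) && R_opt * c <= 1 + 1e-12)
        "ESS_exceeds_opt_bad_eliminated_at_opt"
      else "ESS_exceeds_opt_bad_endemic"
    } else {
      if (sing$boundary && R_ESS == 1) "ESS_collapse_no_sociality"
      else "ESS_below_opt_interior"
    }
  }
  structure(list(regime = regime, R_opt = R_opt, R_ESS = R_ESS,
                 dilemma_direction = direction,
                 social_optimum = opt, singular_strategy = sing),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat("Social-dilemma regime:", x$regime, "\n")
  cat(sprintf("  R_ESS = %g, R_opt = %g (%s)\n", x$R_ESS, x$R_opt,
              x$dilemma_direction))
  invisible(x)
}

#' Pairwise invasibility plot grid
#'
#' Sign of the invasion fitness on an `n x n` grid of resident and mutant
#' strategies, with a companion logical matrix marking mutual invasibility
#' (each strategy invades the other when rare).
#'
#' @param model A `utility_model`.
#' @param c Relative transmissibility (> 0).
#' @param R_range Numeric length-2 range for both axes, inside `(1, Inf)`.
#' @param n Grid resolution (>= 3).
#' @return Object of class `pip_grid`: list with `resident_axis`,
#'   `mutant_axis`, `sign_matrix` (entries -1/0/+1; rows = resident), and
#'   `mutual_matrix`.
#' @examples
#' pip_grid(cobb_douglas_utility(0.75), c = 0.25, R_range = c(1.5, 12), n = 21)
#' @export
pip_grid <- function(model, c, R_range, n = 101) {
  stopifnot(length(R_range) == 2L, R_range[1] > 1, R_range[2] > R_range[1],
            n >= 3)
  axis <- seq(R_range[1], R_range[2], length.out = n)
  s <- outer(axis, axis, Vectorize(function(Rr, Rm)
    invasion_fitness(Rm, Rr, model, c)))
  sgn <- sign(s)
  diag(sgn) <- 0
  mutual <- (s > 0) & t(s > 0)
  diag(mutual) <- FALSE
  structure(list(resident_axis = axis, mutant_axis = axis,
                 sign_matrix = sgn, mutual_matrix = mutual),
            class = "pip_grid")
}

#' @export
as.data.frame.pip_grid <- function(x, ...) {
  grid <- expand.grid(R_r = x$resident_axis, R_m = x$mutant_axis)
  grid$sign <- as.vector(x$sign_matrix)
  grid$mutual <- as.vector(x$mutual_matrix)
  grid
}

#' @export
plot.pip_grid <- function(x, ...) {
  graphics::image(x$resident_axis, x$mutant_axis, x$sign_matrix,
                  col = c("white", "grey80", "firebrick"),
                  xlab = "resident R", ylab = "mutant R", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Convert a reproduction number to a social-interaction rate
#'
#' `sigma = gamma_g * R / p_g`. Because optima and ESS values in the
#' reproduction-number coordinate are proportional to those in the raw
#' interaction-rate coordinate, this conversion carries all results over.
#'
#' @param R Good-contagion reproduction number(s).
#' @param p_g Per-contact transmission probability of the good contagion,
#'   in `(0, 1]`.
#' @param gamma_g Recovery rate of the good contagion (> 0).
#' @return Interaction rate(s) `sigma`.
#' @export
sociality_rates <- function(R, p_g, gamma_g) {
  stopifnot(all(R >= 0), gamma_g > 0)
  if (p_g <= 0 || p_g > 1) stop("p_g must lie in (0, 1]")
  gamma_g * R / p_g
}
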