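#' Utility models
#'
#' A utility model maps an individual's equilibrium contagion exposure --- the
#' fraction of time `I_g` spent carrying the good contagion and the fraction
#' `S_b` spent free of the bad contagion --- to a nonnegative payoff. All
#' built-in models satisfy the monotone contract: utility strictly increases
#' in both arguments on the open unit square.
#'
#' `cobb_douglas_utility()` builds the product-form utility
#' `I_g^alpha * S_b^(1-alpha)`; `linear_utility()` the weighted sum
#' `alpha * I_g + (1-alpha) * S_b`; and `ces_utility()` the
#' constant-elasticity-of-substitution form
#' `(alpha * I_g^rho + (1-alpha) * S_b^rho)^(1/rho)`, which recovers
#' Cobb-Douglas as `rho -> 0`.
#'
#' @param alpha Weight on the good contagion, in `[0, 1]`.
#' @param rho CES substitution exponent, `rho < 1`, `rho != 0`.
#' @return An object inheriting from class `utility_model`.
#' @examples
#' cd <- cobb_douglas_utility(0.75)
#' evaluate_utility(cd, I_g = 0.75, S_b = 1)
#' @name utility_models
NULL

#' @rdname utility_models
#' @export
cobb_douglas_utility <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha),
            class = c("cobb_douglas_utility", "utility_model"))
}

#' @rdname utility_models
#' @export
linear_utility <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha),
            class = c("linear_utility", "utility_model"))
}

#' @rdname utility_models
#' @export
ces_utility <- function(alpha, rho) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(rho), length(rho) == 1L, rho < 1, rho != 0)
  structure(list(alpha = alpha, rho = rho),
            class = c("ces_utility", "utility_model"))
}

#' @export
print.utility_model <- function(x, ...) {
  cat(class(x)[1], "(", paste(names(unclass(x)),
      vapply(unclass(x), format, ""), sep = " = ", collapse = ", "), ")\n")
  invisible(x)
}

# x^p with the 0^0 := 1 convention, so degenerate weights alpha in {0, 1}
# reduce cleanly to single-argument utilities.
.pow0 <- function(x, p) if (p == 0) rep(1, length(x)) else x^p

.check_unit <- function(I_g, S_b) {
  if (any(I_g < 0 | I_g > 1) || any(S_b < 0 | S_b > 1))
    stop("I_g and S_b must lie in [0, 1]")
}

#' Evaluate a utility model
#'
#' @param model A `utility_model` object.
#' @param I_g Equilibrium prevalence of the good contagion, in `[0, 1]`.
#' @param S_b Equilibrium susceptible fraction for the bad contagion, in
#'   `[0, 1]`.
#' @return Utility value(s), nonnegative. Vectorized over `I_g` and `S_b`.
#' @export
evaluate_utility <- function(model, I_g, S_b) UseMethod("evaluate_utility")

#' @export
evaluate_utility.cobb_douglas_utility <- function(model, I_g, S_b) {
  .check_unit(I_g, S_b)
  .pow0(I_g, model$alpha) * .pow0(S_b, 1 - model$alpha)
}

#' @export
evaluate_utility.linear_utility <- function(model, I_g, S_b) {
  .check_unit(I_g, S_b)
  model$alpha * I_g + (1 - model$alpha) * S_b
}

#' @export
evaluate_utility.ces_utility <- function(model, I_g, S_b) {
  .check_unit(I_g, S_b)
  a <- model$alpha; r <- model$rho
  (a * I_g^r + (1 - a) * S_b^r)^(1 / r)
}

#' Partial derivatives of a utility model
#'
#' Signed partial derivatives with respect to the two exposure arguments,
#' analytic for the built-in models and by central finite differences for any
#' other `utility_model` subclass. On the open unit square all built-in
#' models return strictly positive partials.
#'
#' @inheritParams evaluate_utility
#' @param h Finite-difference step for the default method.
#' @return Named numeric vector `c(dU_dI_g, dU_dS_b)`.
#' @export
utility_partials <- function(model, I_g, S_b, h = 1e-6) UseMethod("utility_partials")

#' @export
utility_partials.utility_model <- function(model, I_g, S_b, h = 1e-6) {
  .check_unit(I_g, S_b)
  d <- function(f, x) (f(min(x + h, 1)) - f(max(x - h, 0))) /
    (min(x + h, 1) - max(x - h, 0))
  c(dU_dI_g = d(function(x) evaluate_utility(model, x, S_b), I_g),
    dU_dS_b = d(function(x) evaluate_utility(model, I_g, x), S_b))
}

#' @export
utility_partials.cobb_douglas_utility <- function(model, I_g, S_b, h = 1e-6) {
  .check_unit(I_g, S_b)
  a <- model$alpha
  c(dU_dI_g = a * .pow0(I_g, a - 1) * .pow0(S_b, 1 - a),
    dU_dS_b = (1 - a) * .pow0(I_g, a) * .pow0(S_b, -a))
}

#' @export
utility_partials.linear_utility <- function(model, I_g, S_b, h = 1e-6) {
  .check_unit(I_g, S_b)
  c(dU_dI_g = model$alpha, dU_dS_b = 1 - model$alpha)
}

#' @export
utility_partials.ces_utility <- function(model, I_g, S_b, h = 1e-6) {
  .check_unit(I_g, S_b)
  a <- model$alpha; r <- model$rho
  v <- (a * I_g^r + (1 - a) * S_b^r)^(1 / r - 1)
  c(dU_dI_g = v * a * I_g^(r - 1),
    dU_dS_b = v * (1 - a) * S_b^(r - 1))
}

#' Utility of a monomorphic population at its contagion equilibrium
#'
#' Composes the closed-form endemic equilibria with the utility model. For
#' Cobb-Douglas this reproduces the three-branch piecewise form: 0 for
#' `R <= 1`; `(1 - 1/R)^alpha` for `1 < R <= 1/c`; and
#' `(1 - 1/R)^alpha (1/(cR))^(1-alpha)` for `R > 1/c`.
#'
#' @param model A `utility_model`.
#' @param R Good-contagion reproduction number(s) of the shared strategy.
#' @param c Relative transmissibility of the bad contagion (> 0).
#' @return Utility value(s); vectorized over `R`.
#' @export
monomorphic_utility <- function(model, R, c) {
  stopifnot(inherits(model, "utility_model"), all(R >= 0), c > 0)
  I_g <- ifelse(R > 1, 1 - 1 / R, 0)
  S_b <- ifelse(c * R > 1, 1 / (c * R), 1)
  evaluate_utility(model, I_g, S_b)
}

#' Socially-optimal level of sociality
#'
#' Finds the strategy `R` maximizing the shared utility of a monomorphic
#' population, respecting the piecewise structure of the equilibrium map
#' (kinks at `R = 1` and `R = 1/c`). Interior branch maxima are located with
#' bounded scalar optimization and compared against the kink candidates; for
#' `c > 1` the no-contagion candidate `R = 1/c < 1` is included. For
#' Cobb-Douglas with `alpha < 1` the result matches the closed form
#' `R_opt = max(1/c, 1/(1 - alpha))`, recorded in the diagnostics.
#'
#' If the utility is still increasing at the right edge of the search
#' interval (possible e.g. for linear utility), the optimum is reported as
#' unbounded-above (`R_opt = Inf`, `status = "unbounded"`) rather than as a
#' spurious finite maximizer.
#'
#' @param model A `utility_model`.
#' @param c Relative transmissibility of the bad contagion (> 0).
#' @param search_interval Numeric length-2: finite search range for `R`.
#' @return List with `R_opt`, `value`, `status` (`"ok"` or `"unbounded"`),
#'   and `diagnostics` (winning branch, candidates, Cobb-Douglas closed form
#'   where applicable).
#' @examples
#' social_optimum(cobb_douglas_utility(0.75), c = 0.25)
#' @export
social_optimum <- function(model, c, search_interval = c(1, 1000)) {
  stopifnot(inherits(model, "utility_model"), c > 0,
            length(search_interval) == 2L, all(is.finite(search_interval)),
            search_interval[1] < search_interval[2])
  # monotone contract spot-check
  pt <- utility_partials(model, 0.5, 0.5)
  if (any(pt < 0))
    stop("utility model violates the monotone contract (negative partial)")
  U <- function(R) monomorphic_utility(model, R, c)
  lo <- max(search_interval[1], 1)
  hi <- search_interval[2]
  kink <- 1 / c

  cand <- data.frame(R = numeric(0), branch = character(0))
  add <- function(R, branch) rbind(cand, data.frame(R = R, branch = branch))
  cand <- add(1, "boundary_R1")
  if (kink >= lo && kink <= hi) cand <- add(kink, "boundary_1_over_c")
  if (kink < 1) cand <- add(kink, "no_contagion")  # c > 1: both extinct
  # interior optimum on the branch where both contagions can be endemic
  lo2 <- max(1, kink) * (1 + 1e-9)
  if (lo2 < hi) {
    opt <- stats::optimize(U, interval = c(lo2, hi), maximum = TRUE,
                           tol = 1e-10)
    cand <- add(opt$maximum, "interior")
  }
  # branch (1, 1/c]: utility increasing for monotone models; right endpoint
  # already a candidate via boundary_1_over_c
  cand$value <- vapply(cand$R, U, 0)
  best <- which.max(cand$value)
  # snap to a kink candidate when it ties the interior optimum numerically
  ties <- which(cand$value >= cand$value[best] - 1e-12)
  if (length(ties) > 1) best <- ties[which.min(cand$R[ties])]

  status <- "ok"
  R_opt <- cand$R[best]
  # unbounded-above detection: maximizer pinned at the right edge and the
  # utility still strictly increasing there
  if (R_opt > hi * (1 - 1e-6) && U(hi) > U(hi * (1 - 1e-6))) {
    status <- "unbounded"
    R_opt <- Inf
  }
  diagnostics <- list(branch = cand$branch[best], candidates = cand)
  if (inherits(model, "cobb_douglas_utility")) {
    a <- model$alpha
    diagnostics$closed_form <- if (a < 1) max(1 / c, 1 / (1 - a)) else Inf
    if (a == 1) { status <- "unbounded"; R_opt <- Inf }
  }
  list(R_opt = R_opt,
       value = if (is.finite(R_opt)) U(R_opt) else NA_real_,
       status = status, diagnostics = diagnostics)
}

#' Utilities of the two strategies at the dimorphic contagion equilibrium
#'
#' @param model A `utility_model`.
#' @param dparams A [dimorphic_params()] object.
#' @param ... Passed on to [dimorphic_equilibrium()].
#' @return Named numeric vector `c(U_r, U_m)`.
#' @export
strategy_utilities <- function(model, dparams, ...) {
  stopifnot(inherits(model, "utility_model"),
            inherits(dparams, "dimorphic_params"))
  eq <- dimorphic_equilibrium(dparams, ...)
  c(U_r = evaluate_utility(model, eq$I_r_g, eq$S_r_b),
    U_m = evaluate_utility(model, eq$I_m_g, eq$S_m_b))
}
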