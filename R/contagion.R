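#' Contagion parameters for the two SIS processes
#'
#' Bundle the reproduction number of the good (beneficial) contagion and the
#' relative transmissibility of the bad (costly) contagion. Both contagions
#' follow independent susceptible-infectious-susceptible dynamics; the bad
#' contagion's reproduction number is always `c * R_g`.
#'
#' @param R_g Basic reproduction number of the good contagion (>= 0).
#' @param c Relative transmissibility of the bad contagion (> 0), i.e. the
#'   ratio of the two basic reproduction numbers.
#' @return An object of class `contagion_params` with fields `R_g`, `c`, and
#'   the derived `R_b = c * R_g`.
#' @seealso [reproduction_numbers()] to construct from raw interaction and
#'   recovery rates, [mono_equilibrium()].
#' @examples
#' contagion_params(R_g = 4, c = 0.25)
#' @export
contagion_params <- function(R_g, c) {
  stopifnot(is.numeric(R_g), length(R_g) == 1L, is.finite(R_g),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (R_g < 0) stop("R_g must be nonnegative")
  if (c <= 0) stop("c must be positive")
  structure(list(R_g = R_g, c = c, R_b = c * R_g),
            class = "contagion_params")
}

#' @export
print.contagion_params <- function(x, ...) {
  cat("SIS contagion parameters\n")
  cat(sprintf("  R_g = %g  (good contagion)\n", x$R_g))
  cat(sprintf("  R_b = %g  (bad contagion, c = %g)\n", x$R_b, x$c))
  invisible(x)
}

#' Reproduction numbers from raw contact and recovery rates
#'
#' Converts the social-interaction rate, per-contact transmission
#' probabilities and recovery rates of the two contagions into the reduced
#' parameterization used throughout the package: `R_g = sigma * p_g / gamma_g`
#' and `c = (p_b * gamma_g) / (p_g * gamma_b)`.
#'
#' @param sigma Social interaction rate (1/time, >= 0).
#' @param p_g,p_b Per-contact transmission probabilities in `[0, 1]`; `p_g`
#'   must be positive for `c` to be defined.
#' @param gamma_g,gamma_b Recovery rates (1/time, > 0).
#' @return A [contagion_params()] object.
#' @examples
#' reproduction_numbers(sigma = 2, p_g = 0.5, p_b = 0.25, gamma_g = 1, gamma_b = 1)
#' @export
reproduction_numbers <- function(sigma, p_g, p_b, gamma_g, gamma_b) {
  stopifnot(is.numeric(sigma), sigma >= 0,
            is.numeric(p_g), p_g >= 0, p_g <= 1,
            is.numeric(p_b), p_b >= 0, p_b <= 1)
  if (gamma_g <= 0 || gamma_b <= 0) stop("recovery rates must be positive")
  if (p_g == 0) stop("p_g must be positive (relative transmissibility undefined)")
  contagion_params(R_g = sigma * p_g / gamma_g,
                   c = (p_b * gamma_g) / (p_g * gamma_b))
}

#' Monomorphic SIS dynamics (time in recovery units)
#'
#' Right-hand side of the decoupled prevalence equations for a population in
#' which everyone shares one sociality strategy. Time is measured in units of
#' each contagion's recovery time, so the equations read
#' `dI/dt = R (1 - I) I - I` with `R` the contagion's reproduction number.
#'
#' @param I_g,I_b Current prevalences, each in `[0, 1]`.
#' @param params A [contagion_params()] object.
#' @return Named numeric vector `c(dI_g, dI_b)`.
#' @export
mono_rhs <- function(I_g, I_b, params) {
  stopifnot(inherits(params, "contagion_params"))
  if (I_g < 0 || I_g > 1 || I_b < 0 || I_b > 1)
    stop("prevalences must lie in [0, 1]")
  c(dI_g = params$R_g * (1 - I_g) * I_g - I_g,
    dI_b = params$R_b * (1 - I_b) * I_b - I_b)
}

#' Endemic equilibrium of the monomorphic SIS contagions
#'
#' Globally stable equilibrium prevalences: `1 - 1/R` when a contagion's
#' reproduction number strictly exceeds 1, and 0 otherwise (the disease-free
#' branch is returned at the threshold `R = 1` exactly).
#'
#' @param params A [contagion_params()] object.
#' @return An object of class `mono_equilibrium`: list with `I_g`, `I_b`, and
#'   `S_b = 1 - I_b`.
#' @examples
#' mono_equilibrium(contagion_params(R_g = 7, c = 0.25))
#' @export
mono_equilibrium <- function(params) {
  stopifnot(inherits(params, "contagion_params"))
  I_g <- if (params$R_g > 1) 1 - 1 / params$R_g else 0
  I_b <- if (params$R_b > 1) 1 - 1 / params$R_b else 0
  structure(list(I_g = I_g, I_b = I_b, S_b = 1 - I_b),
            class = "mono_equilibrium")
}

#' Integrate the monomorphic contagion dynamics
#'
#' Numerical integration of the two decoupled SIS prevalence equations from a
#' given initial state. Provided mainly to cross-check the closed-form
#' equilibria; all downstream analysis uses equilibria directly.
#'
#' @param params A [contagion_params()] object.
#' @param init Named numeric vector with elements `I_g` and `I_b` in `[0, 1]`.
#' @param t_grid Increasing numeric vector of output times (recovery units).
#' @return A data.frame with columns `t`, `I_g`, `I_b`.
#' @export
simulate_mono <- function(params, init, t_grid) {
  stopifnot(inherits(params, "contagion_params"),
            all(c("I_g", "I_b") %in% names(init)),
            all(diff(t_grid) > 0))
  if (any(init < 0) || any(init > 1)) stop("initial prevalences must lie in [0, 1]")
  rhs <- function(t, y, p) {
    list(c(p$R_g * (1 - y[1]) * y[1] - y[1],
           p$R_b * (1 - y[2]) * y[2] - y[2]))
  }
  sol <- deSolve::ode(y = c(I_g = unname(init["I_g"]), I_b = unname(init["I_b"])),
                      times = t_grid, func = rhs, parms = params,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: istate = ", attr(sol, "istate")[1])
  out <- as.data.frame(sol)
  names(out) <- c("t", "I_g", "I_b")
  out
}

#' Net reproduction number of a two-strategy population
#'
#' Basic reproduction number of a contagion spreading through a population in
#' which a fraction `f` follows the mutant strategy (reproduction number
#' `R_m`) and `1 - f` the resident strategy (`R_r`):
#' `(f R_m^2 + (1 - f) R_r^2) / (f R_m + (1 - f) R_r)`.
#' The contact-rate weighting makes this a contact-weighted mean of the two
#' strategies' reproduction numbers.
#'
#' @param R_r,R_m Resident and mutant reproduction numbers (>= 0, not both 0
#'   when their mixture weight is positive).
#' @param f Mutant fraction in `[0, 1]`.
#' @return The net reproduction number (scalar).
#' @export
net_reproduction_number <- function(R_r, R_m, f) {
  stopifnot(R_r >= 0, R_m >= 0, f >= 0, f <= 1)
  denom <- f * R_m + (1 - f) * R_r
  if (denom == 0) stop("degenerate mixture: f * R_m + (1 - f) * R_r = 0")
  (f * R_m^2 + (1 - f) * R_r^2) / denom
}

#' Parameters of a dimorphic (resident + mutant) population
#'
#' @param R_r,R_m Good-contagion reproduction numbers of the resident and
#'   mutant strategies (>= 0).
#' @param f Mutant fraction in `[0, 1]`.
#' @param c Relative transmissibility of the bad contagion (> 0).
#' @return An object of class `dimorphic_params`.
#' @export
dimorphic_params <- function(R_r, R_m, f, c) {
  stopifnot(is.numeric(R_r), R_r >= 0, is.numeric(R_m), R_m >= 0,
            is.numeric(f), f >= 0, f <= 1, is.numeric(c), c > 0)
  structure(list(R_r = R_r, R_m = R_m, f = f, c = c),
            class = "dimorphic_params")
}

#' Dimorphic SIS dynamics (time in recovery units)
#'
#' Right-hand side of the four coupled prevalence equations for a population
#' containing resident and mutant sociality strategies. Each equation shares
#' the infectious-contact probability
#' `B = (R_r (1 - f) I_r + R_m f I_m) / (R_r (1 - f) + R_m f)`,
#' the probability that a given social contact is with an infectious
#' individual, weighted by strategy abundance and contact rate.
#'
#' @param state Named numeric vector `c(I_r_g, I_m_g, I_r_b, I_m_b)` of
#'   prevalences in `[0, 1]`.
#' @param dparams A [dimorphic_params()] object with
#'   `f * R_m + (1 - f) * R_r > 0`.
#' @return Named numeric vector of the four time derivatives.
#' @export
dimorphic_rhs <- function(state, dparams) {
  stopifnot(inherits(dparams, "dimorphic_params"))
  if (any(state < 0) || any(state > 1)) stop("prevalences must lie in [0, 1]")
  R_r <- dparams$R_r; R_m <- dparams$R_m; f <- dparams$f
  w <- R_r * (1 - f) + R_m * f
  if (w <= 0) stop("degenerate contact pool: R_r (1 - f) + R_m f must be positive")
  B_g <- (R_r * (1 - f) * state[["I_r_g"]] + R_m * f * state[["I_m_g"]]) / w
  B_b <- (R_r * (1 - f) * state[["I_r_b"]] + R_m * f * state[["I_m_b"]]) / w
  cc <- dparams$c
  c(dI_r_g = R_r * B_g * (1 - state[["I_r_g"]]) - state[["I_r_g"]],
    dI_m_g = R_m * B_g * (1 - state[["I_m_g"]]) - state[["I_m_g"]],
    dI_r_b = cc * R_r * B_b * (1 - state[["I_r_b"]]) - state[["I_r_b"]],
    dI_m_b = cc * R_m * B_b * (1 - state[["I_m_b"]]) - state[["I_m_b"]])
}

# Endemic equilibrium of one contagion in a two-strategy population.
#
# At steady state both subpopulation prevalences are slaved to the shared
# infectious-contact probability B: I_x = R_x B / (1 + R_x B).  Substituting
# into the definition of B reduces the 2D fixed-point system to a scalar
# root problem on B in (0, 1):
#   h(B) = R_r^2 (1 - f) / (1 + R_r B) + R_m^2 f / (1 + R_m B) - w = 0,
# where w = R_r (1 - f) + R_m f.  h(0) = w (R_net - 1) and h is strictly
# decreasing, so a unique positive root exists iff R_net > 1 (the endemic
# threshold of the two-group SIS system, whose equilibrium is known to be
# unique and globally attracting).
.pair_sis_equilibrium <- function(R_r, R_m, f) {
  w <- R_r * (1 - f) + R_m * f
  if (w <= 0) return(c(I_r = 0, I_m = 0))
  R_net <- (f * R_m^2 + (1 - f) * R_r^2) / w
  if (R_net <= 1) return(c(I_r = 0, I_m = 0))
  h <- function(B) R_r^2 * (1 - f) / (1 + R_r * B) + R_m^2 * f / (1 + R_m * B) - w
  root <- stats::uniroot(h, interval = c(0, 1), tol = 1e-15,
                         f.lower = w * (R_net - 1), f.upper = h(1))
  B <- root$root
  I_r <- R_r * B / (1 + R_r * B)
  I_m <- R_m * B / (1 + R_m * B)
  c(I_r = min(max(I_r, 0), 1), I_m = min(max(I_m, 0), 1))
}

#' Endemic equilibrium of the dimorphic contagion dynamics
#'
#' Unique globally-attracting equilibrium of the resident/mutant SIS system,
#' solved per contagion. The default method reduces the per-contagion
#' fixed-point system exactly to a scalar root problem in the shared
#' infectious-contact probability and solves it by safeguarded bisection;
#' `method = "ode"` instead integrates the four coupled equations to a long
#' horizon and serves as an independent cross-check.
#'
#' @param dparams A [dimorphic_params()] object.
#' @param method `"root"` (default, scalar root reduction) or `"ode"`
#'   (long-horizon integration to `t_max`).
#' @param t_max Integration horizon for `method = "ode"` (recovery units).
#' @return Object of class `dimorphic_equilibrium`: list with prevalences
#'   `I_r_g`, `I_m_g`, `I_r_b`, `I_m_b` and susceptible complements
#'   `S_r_b`, `S_m_b`.
#' @examples
#' dimorphic_equilibrium(dimorphic_params(R_r = 4, R_m = 5, f = 0.5, c = 0.25))
#' @export
dimorphic_equilibrium <- function(dparams, method = c("root", "ode"),
                                  t_max = 1e4) {
  stopifnot(inherits(dparams, "dimorphic_params"))
  method <- match.arg(method)
  R_r <- dparams$R_r; R_m <- dparams$R_m; f <- dparams$f; cc <- dparams$c
  if (method == "root") {
    good <- .pair_sis_equilibrium(R_r, R_m, f)
    bad <- .pair_sis_equilibrium(cc * R_r, cc * R_m, f)
    state <- c(I_r_g = unname(good["I_r"]), I_m_g = unname(good["I_m"]),
               I_r_b = unname(bad["I_r"]), I_m_b = unname(bad["I_m"]))
  } else {
    rhs <- function(t, y, p) {
      y <- pmin(pmax(y, 0), 1)  # guard against solver overshoot
      list(unname(dimorphic_rhs(y, p)))
    }
    init <- c(I_r_g = 0.01, I_m_g = 0.01, I_r_b = 0.01, I_m_b = 0.01)
    sol <- deSolve::ode(y = init, times = c(0, t_max), func = rhs,
                        parms = dparams, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    if (attr(sol, "istate")[1] < 0)
      stop("dimorphic ODE integration failed: istate = ",
           attr(sol, "istate")[1])
    state <- sol[nrow(sol), -1]
    # threshold clean-up: decaying transients never reach 0 in finite time
    if (net_reproduction_number(R_r, R_m, f) <= 1)
      state[c("I_r_g", "I_m_g")] <- 0
    if (net_reproduction_number(cc * R_r, cc * R_m, f) <= 1)
      state[c("I_r_b", "I_m_b")] <- 0
    state <- pmin(pmax(state, 0), 1)
  }
  res <- dimorphic_rhs(state, dparams)
  if (sqrt(sum(res^2)) > 1e-8)
    stop("dimorphic equilibrium residual too large: ", sqrt(sum(res^2)))
  structure(c(as.list(state),
              list(S_r_b = 1 - state[["I_r_b"]],
                   S_m_b = 1 - state[["I_m_b"]])),
            class = "dimorphic_equilibrium")
}

#' Rare-mutant equilibrium exposure
#'
#' Closed-form equilibrium state of a vanishingly rare mutant strategy in a
#' resident population at its endemic equilibrium: the mutant's good-contagion
#' prevalence and bad-contagion susceptible fraction,
#' `I_m_g = R_m (R_r - 1) / (R_m (R_r - 1) + R_r)` when `R_r > 1` (else 0) and
#' `S_m_b = R_r / (R_m (c R_r - 1) + R_r)` when `c R_r > 1` (else 1).
#'
#' @param R_m Mutant good-contagion reproduction number (>= 0).
#' @param R_r Resident good-contagion reproduction number (>= 0).
#' @param c Relative transmissibility of the bad contagion (> 0).
#' @return Named numeric vector `c(I_m_g, S_m_b)`.
#' @export
mutant_rare_equilibrium <- function(R_m, R_r, c) {
  stopifnot(R_m >= 0, R_r >= 0, c > 0)
  I_m_g <- if (R_r > 1) R_m * (R_r - 1) / (R_m * (R_r - 1) + R_r) else 0
  S_m_b <- if (c * R_r > 1) R_r / (R_m * (c * R_r - 1) + R_r) else 1
  c(I_m_g = I_m_g, S_m_b = S_m_b)
}

#' Sensitivities of the rare-mutant equilibrium to the mutant strategy
#'
#' Partial derivatives of the rare-mutant exposure with respect to the mutant
#' reproduction number:
#' `dI_m_g/dR_m = R_r (R_r - 1) / (R_m (R_r - 1) + R_r)^2` and
#' `dS_m_b/dR_m = -R_r (c R_r - 1) / (R_m (c R_r - 1) + R_r)^2` when
#' `c R_r > 1` (0 otherwise). The second derivative is negative: more
#' sociality always increases exposure to the bad contagion when it is
#' endemic in the resident population.
#'
#' @inheritParams mutant_rare_equilibrium
#' @return Named numeric vector `c(dI_m_g, dS_m_b)`.
#' @export
mutant_rare_sensitivities <- function(R_m, R_r, c) {
  stopifnot(R_m >= 0, c > 0)
  if (R_r <= 1) stop("sensitivities require an endemic resident: R_r > 1")
  dI <- R_r * (R_r - 1) / (R_m * (R_r - 1) + R_r)^2
  dS <- if (c * R_r > 1)
    -R_r * (c * R_r - 1) / (R_m * (c * R_r - 1) + R_r)^2
  else 0
  c(dI_m_g = dI, dS_m_b = dS)
}
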