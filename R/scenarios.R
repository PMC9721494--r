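#' Build a utility model from a config-style specification
#'
#' @param spec List with `model` in
#'   `{"cobb_douglas", "linear", "ces"}`, `alpha`, and (CES only) `rho`.
#' @return A `utility_model`.
#' @export
make_utility <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$model))
  switch(spec$model,
         cobb_douglas = cobb_douglas_utility(spec$alpha),
         linear = linear_utility(spec$alpha),
         ces = ces_utility(spec$alpha, spec$rho),
         stop("unknown utility model: ", spec$model))
}

.default_config <- function() {
  list(scenario = NULL, panel = NULL,
       utility = list(model = "cobb_douglas", alpha = 0.75, rho = NULL),
       c = NULL, R_r = NULL, R_m = NULL, f0 = 0.5,
       sigma = NULL, p_g = NULL, p_b = NULL, gamma_g = NULL, gamma_b = NULL,
       grid = list(min = 1.5, max = 12, n = 61),
       numerics = list(t_max = 1e5, tol = 1e-10),
       output_dir = NULL, seed = NULL)
}

.scenario_presets <- list(
  fig1 = list(),
  fig2 = list(panel = "A", utility = list(model = "cobb_douglas", alpha = 0.75),
              c = 0.25, R_r = 4, R_m = 5),
  fig3 = list(utility = list(model = "cobb_douglas", alpha = 0.25),
              c = 0.25, R_r = 7, R_m = 3),
  fig4 = list(),
  fig5 = list(),
  fig6 = list(),
  table1 = list()
)

# figure-preset panel parameterizations (resident fixed at the social
# optimum R = 4, alpha = 0.75 throughout)
.fig2_panels <- list(
  A = list(c = 0.25, R_m = 5),
  A_alt = list(c = 0.25, R_m = 7),  # main-text variant of the same scenario
  C = list(c = 4, R_m = 3)
)

#' Load and validate a scenario configuration
#'
#' Reads a YAML or JSON configuration file (YAML is a superset of JSON, so
#' both parse), fills defaults, applies any scenario preset named by the
#' `scenario` key, and validates every numeric field against the module
#' preconditions. Unknown top-level keys are rejected.
#'
#' @param path Path to the configuration file, or a list already in config
#'   shape (useful programmatically).
#' @return A validated object of class `scenario_config`.
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) path
  else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  defaults <- .default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  if (!is.null(cfg$scenario)) {
    if (!cfg$scenario %in% names(.scenario_presets))
      stop("unknown scenario preset: ", cfg$scenario)
    preset <- .scenario_presets[[cfg$scenario]]
    if (identical(cfg$scenario, "fig2")) {
      panel <- if (!is.null(cfg$panel)) cfg$panel else "A"
      if (!panel %in% names(.fig2_panels))
        stop("fig2 panel must be one of: ",
             paste(names(.fig2_panels), collapse = ", "))
      preset <- utils::modifyList(preset, .fig2_panels[[panel]])
      preset$panel <- panel
    }
    # preset fills only fields the user did not set explicitly
    user_set <- setdiff(names(raw), c("scenario", "panel"))
    preset <- preset[setdiff(names(preset), user_set)]
    cfg <- utils::modifyList(cfg, preset, keep.null = TRUE)
  }
  .validate_config(cfg)
  structure(cfg, class = "scenario_config")
}

.validate_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("config validation failed at '", field, "': ", msg)
  u <- cfg$utility
  chk(u$model %in% c("cobb_douglas", "linear", "ces"), "utility$model",
      "must be cobb_douglas, linear or ces")
  chk(is.numeric(u$alpha) && u$alpha >= 0 && u$alpha <= 1, "utility$alpha",
      "must lie in [0, 1]")
  if (identical(u$model, "ces"))
    chk(is.numeric(u$rho) && u$rho < 1 && u$rho != 0, "utility$rho",
        "must satisfy rho < 1, rho != 0")
  if (!is.null(cfg$c)) chk(cfg$c > 0, "c", "must be positive")
  for (f in c("R_r", "R_m"))
    if (!is.null(cfg[[f]])) chk(cfg[[f]] >= 0, f, "must be nonnegative")
  if (!is.null(cfg$f0)) chk(cfg$f0 > 0 && cfg$f0 < 1, "f0", "must lie in (0, 1)")
  g <- cfg$grid
  chk(g$min > 1 && g$max > g$min && g$n >= 3, "grid",
      "requires 1 < min < max and n >= 3")
  chk(cfg$numerics$t_max > 0 && cfg$numerics$tol > 0, "numerics",
      "t_max and tol must be positive")
  invisible(cfg)
}

#' Dump a configuration back to YAML
#'
#' @param cfg A `scenario_config`.
#' @param path Output path; the written file round-trips through
#'   [load_config()].
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Export a results table as CSV
#'
#' Writes a data.frame with numeric columns rounded to 12 significant
#' digits; re-exporting a re-loaded file is byte-identical.
#'
#' @param results A data.frame.
#' @param path Output path.
#' @export
export_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 12)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a scenario preset or custom configuration
#'
#' Executes the computation described by a configuration and returns the
#' resulting tables; when `output_dir` is set (in the config or as an
#' argument) each table is also written as CSV. All presets are
#' deterministic.
#'
#' Available presets: `fig1` (utility surfaces, equilibrium and utility
#' curves over strategy/transmissibility grids), `fig2` (two-strategy
#' equilibria and utilities across the mutant fraction, panels `A`, `A_alt`,
#' `C`), `fig3` (the coexistence scenario with its interior equilibrium),
#' `fig4` (six pairwise invasibility plots), `fig5` (regime map over the
#' transmissibility/weight plane), `fig6` (ESS and optimum versus the
#' utility weight for `c = 2` and `c = 0.5`), and `table1` (numeric check of
#' the regime case conditions on a grid).
#'
#' @param config A `scenario_config`, a path to one, or a list.
#' @param output_dir Optional output directory for CSV export.
#' @return Named list of data.frames, with a `summary` attribute of key
#'   scalars, invisibly.
#' @examples
#' \donttest{
#' run_scenario(list(scenario = "fig3"))
#' }
#' @export
run_scenario <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "scenario_config")) config else load_config(config)
  if (is.null(output_dir)) output_dir <- cfg$output_dir
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  name <- cfg$scenario
  if (is.null(name)) stop("config has no 'scenario' key")
  tables <- switch(name,
                   fig1 = .scenario_fig1(cfg),
                   fig2 = .scenario_fig2(cfg),
                   fig3 = .scenario_fig3(cfg),
                   fig4 = .scenario_fig4(cfg),
                   fig5 = .scenario_fig5(cfg),
                   fig6 = .scenario_fig6(cfg),
                   table1 = .scenario_table1(cfg),
                   stop("unknown scenario: ", name))
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    for (nm in setdiff(names(tables), "summary"))
      export_table(tables[[nm]],
                   file.path(output_dir, paste0(name, "_", nm, ".csv")))
  }
  invisible(tables)
}

.scenario_fig1 <- function(cfg) {
  alphas <- c(0.25, 0.5, 0.75)
  cs <- c(0.25, 1, 4)
  Rs <- seq(0, 20, length.out = 201)
  equil <- do.call(rbind, lapply(cs, function(cc) {
    data.frame(c = cc, R = Rs,
               I_g = ifelse(Rs > 1, 1 - 1 / Rs, 0),
               S_b = ifelse(cc * Rs > 1, 1 / (cc * Rs), 1))
  }))
  curves <- do.call(rbind, lapply(alphas, function(a) {
    m <- cobb_douglas_utility(a)
    do.call(rbind, lapply(cs, function(cc) {
      opt <- social_optimum(m, cc)
      data.frame(alpha = a, c = cc, R = Rs,
                 U = monomorphic_utility(m, Rs, cc),
                 R_opt = opt$R_opt)
    }))
  }))
  xy <- seq(0.01, 0.99, length.out = 50)
  surface <- do.call(rbind, lapply(alphas, function(a) {
    g <- expand.grid(I_g = xy, S_b = xy)
    g$alpha <- a
    g$U <- evaluate_utility(cobb_douglas_utility(a), g$I_g, g$S_b)
    g
  }))
  list(equilibria = equil, utility_curves = curves, utility_surface = surface,
       summary = list())
}

.scenario_fig2 <- function(cfg) {
  model <- make_utility(cfg$utility)
  fs <- seq(0.001, 0.999, length.out = 101)
  rows <- lapply(fs, function(f) {
    dp <- dimorphic_params(cfg$R_r, cfg$R_m, f, cfg$c)
    eq <- dimorphic_equilibrium(dp)
    u <- strategy_utilities(model, dp)
    data.frame(f = f, I_r_g = eq$I_r_g, I_m_g = eq$I_m_g,
               I_r_b = eq$I_r_b, I_m_b = eq$I_m_b,
               U_r = u[["U_r"]], U_m = u[["U_m"]])
  })
  tab <- do.call(rbind, rows)
  list(equilibria_utilities = tab,
       summary = list(all_mutant_favored = all(tab$U_m > tab$U_r)))
}

.scenario_fig3 <- function(cfg) {
  out <- .scenario_fig2(cfg)
  model <- make_utility(cfg$utility)
  f_eq <- find_interior_equilibrium(model, cfg$R_r, cfg$R_m, cfg$c)
  out$interior_equilibrium <- data.frame(
    R_r = cfg$R_r, R_m = cfg$R_m, c = cfg$c, alpha = cfg$utility$alpha,
    f_eq = if (is.null(f_eq)) NA_real_ else f_eq)
  out$summary <- list(f_eq = f_eq)
  out
}

.scenario_fig4 <- function(cfg) {
  combos <- expand.grid(c = c(0.25, 1, 4), alpha = c(0.25, 0.75))
  g <- cfg$grid
  pips <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cc <- combos$c[i]; a <- combos$alpha[i]
    m <- cobb_douglas_utility(a)
    pg <- pip_grid(m, cc, R_range = c(g$min, g$max), n = g$n)
    df <- as.data.frame(pg)
    df$c <- cc; df$alpha <- a
    df$R_ESS <- singular_strategy(m, cc)$R_star
    df$R_opt <- social_optimum(m, cc)$R_opt
    df
  }))
  list(pip = pips, summary = list())
}

.scenario_fig5 <- function(cfg) {
  cs <- exp(seq(log(0.1), log(10), length.out = 41))
  alphas <- seq(0.02, 0.98, length.out = 41)
  grid <- expand.grid(c = cs, alpha = alphas)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep_ <- social_dilemma_report(cobb_douglas_utility(grid$alpha[i]),
                                  grid$c[i])
    data.frame(c = grid$c[i], alpha = grid$alpha[i], regime = rep_$regime,
               R_ESS = rep_$R_ESS, R_opt = rep_$R_opt,
               direction = rep_$dilemma_direction)
  })
  list(regime_map = do.call(rbind, rows), summary = list())
}

.scenario_fig6 <- function(cfg) {
  alphas <- seq(0.01, 0.99, length.out = 99)
  rows <- lapply(c(2, 0.5), function(cc) {
    do.call(rbind, lapply(alphas, function(a) {
      m <- cobb_douglas_utility(a)
      data.frame(c = cc, alpha = a,
                 R_ESS = singular_strategy(m, cc)$R_star,
                 R_opt = social_optimum(m, cc)$R_opt)
    }))
  })
  tab <- do.call(rbind, rows)
  sub2 <- tab[tab$c == 2 & is.finite(tab$R_opt), ]
  list(ess_vs_opt = tab,
       summary = list(all_under_social_at_c2 =
                        all(sub2$R_ESS <= sub2$R_opt + 1e-9)))
}

.scenario_table1 <- function(cfg) {
  grid <- expand.grid(alpha = c(0.1, 0.25, 0.5, 0.75, 0.9),
                      c = c(0.1, 0.25, 0.5, 1, 2, 4, 10))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$alpha[i]; cc <- grid$c[i]
    rep_ <- social_dilemma_report(cobb_douglas_utility(a), cc)
    # predicted values from the piecewise case table
    pred_ess <- max(1, 1 / cc + a / (1 - a))
    pred_opt <- max(1 / cc, 1 / (1 - a))
    data.frame(alpha = a, c = cc, R_ESS = rep_$R_ESS, R_opt = rep_$R_opt,
               pred_R_ESS = pred_ess, pred_R_opt = pred_opt,
               regime = rep_$regime,
               agrees = abs(rep_$R_ESS - pred_ess) < 1e-8 &&
                 abs(rep_$R_opt - pred_opt) < 1e-6)
  })
  tab <- do.call(rbind, rows)
  list(case_check = tab, summary = list(all_agree = all(tab$agrees)))
}
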