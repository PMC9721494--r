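test_that("invasion fitness is zero on the diagonal and signed correctly", {
  m <- cobb_douglas_utility(0.75)
  expect_equal(invasion_fitness(4, 4, m, 0.25), 0)
  # frozen oracle: 0.75 * (log 0.84 - log 0.75)
  expect_close(invasion_fitness(7, 4, m, 0.25), 0.08499651398025232, 1e-12)
  # the ESS resident resists a less-social invader
  expect_lt(invasion_fitness(4, 7, m, 0.25), 0)
  expect_error(invasion_fitness(3, 0.9, m, 0.25), "R_r > 1")
  # only a fully asocial mutant (R_m = 0) escapes the good contagion entirely
  expect_warning(s <- invasion_fitness(0, 4, m, 0.25), "zero utility")
  expect_identical(s, -Inf)
})

test_that("selection gradient matches the closed form and finite differences", {
  m <- cobb_douglas_utility(0.75)
  expect_equal(selection_gradient(4, m, 0.25), 0.75 / 16)
  expect_close(selection_gradient(7, m, 0.25), 0, 1e-14)
  expect_equal(selection_gradient(8, m, 0.25), (0.75 - 0.25 * 4) / 64)
  # closed form vs central finite difference of invasion fitness
  h <- 1e-6
  for (a in c(0.25, 0.5, 0.75)) {
    for (cc in c(0.25, 1, 4)) {
      for (R_r in c(1.5, 3, 6, 12)) {
        mm <- cobb_douglas_utility(a)
        fd <- (invasion_fitness(R_r + h, R_r, mm, cc) -
                 invasion_fitness(R_r - h, R_r, mm, cc)) / (2 * h)
        expect_close(selection_gradient(R_r, mm, cc), fd, 1e-6)
      }
    }
  }
})

test_that("assembled general-model gradient agrees with the Cobb-Douglas form", {
  set.seed(201)
  for (i in 1:50) {
    a <- runif(1, 0.1, 0.9)
    cc <- exp(runif(1, log(0.2), log(4)))
    R_r <- runif(1, 1.2, 10)
    m <- cobb_douglas_utility(a)
    expect_close(selection_gradient(R_r, m, cc, method = "assembled"),
                 selection_gradient(R_r, m, cc, method = "closed_form"),
                 1e-10)
  }
})

test_that("gradient decomposes into utility derivative plus exposure correction", {
  # for residents above both thresholds, the (utility-scale) gradient equals
  # the monomorphic utility derivative weighted by (R-1)/R plus a
  # transmissibility correction proportional to (1/c - 1)
  set.seed(202)
  for (i in 1:100) {
    a <- runif(1, 0.1, 0.9)
    cc <- exp(runif(1, log(0.2), log(4)))
    R_r <- runif(1, max(1, 1 / cc) * 1.05 + 0.05, 12)
    m <- cobb_douglas_utility(a)
    U <- monomorphic_utility(m, R_r, cc)
    lhs <- selection_gradient(R_r, m, cc) * U  # utility-scale gradient
    # analytic d/dR of (1 - 1/R)^a (cR)^-(1-a) on the both-endemic branch
    dU_dR <- U * (a / (R_r * (R_r - 1)) - (1 - a) / R_r)
    eq <- mono_equilibrium(contagion_params(R_r, cc))
    dU_dS <- utility_partials(m, eq$I_g, eq$S_b)[["dU_dS_b"]]
    rhs <- (R_r - 1) / R_r * dU_dR + (1 / cc - 1) / (cc * R_r^3) * dU_dS
    expect_close(lhs, rhs, 1e-6)
  }
})

test_that("singular strategy follows the piecewise closed form", {
  s1 <- singular_strategy(cobb_douglas_utility(0.75), 0.25)
  expect_equal(s1$R_star, 7)
  expect_true(s1$feasible && s1$is_ESS && s1$is_convergence_stable)
  # at c = 1 the singular strategy coincides with the social optimum
  for (a in c(0.25, 0.5, 0.75)) {
    s <- singular_strategy(cobb_douglas_utility(a), 1)
    expect_close(s$R_star, 1 / (1 - a), 1e-10)
    expect_close(social_optimum(cobb_douglas_utility(a), 1)$R_opt,
                 s$R_star, 1e-5)
  }
  # infeasible interior point collapses sociality to the boundary
  s0 <- singular_strategy(cobb_douglas_utility(0.25), 4)
  expect_equal(s0$R_star, 1)
  expect_true(s0$boundary)
  expect_false(s0$feasible)
})

test_that("general-model root-finding reproduces the Cobb-Douglas ESS", {
  # drive the generic bracketed search with a CES model near the
  # Cobb-Douglas limit; the singular strategy must approach the closed form
  # CES near the Cobb-Douglas limit: same singular strategy (classification
  # there is reported as degenerate because the curvature is below numerical
  # resolution at tiny rho)
  s_ces <- singular_strategy(ces_utility(0.75, 1e-7), 0.25)
  expect_close(s_ces$R_star, 7, 1e-3)
  # a well-conditioned concave CES classifies cleanly
  s2 <- singular_strategy(ces_utility(0.75, 0.5), 0.25)
  expect_true(s2$feasible)
  expect_gt(s2$R_star, 1 / 0.25)
  expect_true(s2$is_ESS)
  expect_true(s2$is_convergence_stable)
})

test_that("the social optimum at 1/c is never evolutionarily stable (c < 1)", {
  for (cc in c(0.2, 0.5, 0.8)) {
    for (a in c(0.3, 0.6)) {
      g <- selection_gradient((1 / cc) * (1 + 1e-9),
                              cobb_douglas_utility(a), cc)
      expect_gt(g, 0)
    }
  }
})

test_that("dilemma direction is set by the relative transmissibility", {
  r1 <- social_dilemma_report(cobb_douglas_utility(0.75), 0.25)
  expect_equal(r1$R_ESS, 7)
  expect_equal(r1$R_opt, 4)
  expect_equal(r1$dilemma_direction, "ESS_greater")
  r2 <- social_dilemma_report(cobb_douglas_utility(0.75), 4)
  expect_equal(r2$R_ESS, 3.25)
  expect_equal(r2$R_opt, 4)
  expect_equal(r2$dilemma_direction, "ESS_smaller")
  r3 <- social_dilemma_report(cobb_douglas_utility(0.6), 1)
  expect_equal(r3$dilemma_direction, "equal")
  expect_equal(r3$regime, "ESS_equals_opt")
  # grid law: sign(R_ESS - R_opt) = sign(1 - c) when both interior
  for (a in c(0.3, 0.55, 0.8)) {
    for (cc in c(0.3, 0.7, 1, 1.5, 3)) {
      rep_ <- social_dilemma_report(cobb_douglas_utility(a), cc)
      if (cc == 1) {
        expect_equal(rep_$dilemma_direction, "equal")
      } else if (rep_$R_ESS > 1 && is.finite(rep_$R_opt)) {
        expect_equal(sign(rep_$R_ESS - rep_$R_opt), sign(1 - cc),
                     label = sprintf("alpha=%g c=%g", a, cc))
      }
    }
  }
})

test_that("regime classification reproduces the four qualitative cases", {
  # bad contagion eliminated at the optimum, endemic at the ESS
  ra <- social_dilemma_report(cobb_douglas_utility(0.2), 0.25)
  expect_equal(ra$regime, "ESS_exceeds_opt_bad_eliminated_at_opt")
  expect_equal(ra$R_opt, 4)       # 1/c: elimination branch
  expect_gt(ra$R_ESS, 1 / 0.25)   # ESS keeps the bad contagion endemic
  # both endemic, over-socialized
  rb <- social_dilemma_report(cobb_douglas_utility(0.75), 0.5)
  expect_equal(rb$regime, "ESS_exceeds_opt_bad_endemic")
  # both endemic, under-socialized
  rc <- social_dilemma_report(cobb_douglas_utility(0.75), 4)
  expect_equal(rc$regime, "ESS_below_opt_interior")
  # collapse: no sociality at all evolves
  rd <- social_dilemma_report(cobb_douglas_utility(0.25), 4)
  expect_equal(rd$regime, "ESS_collapse_no_sociality")
  expect_equal(rd$R_ESS, 1)
  expect_gt(rd$R_opt, 1)
})

test_that("PIP zero-contours cross at the analytic singular strategy", {
  for (a in c(0.25, 0.75)) {
    for (cc in c(0.25, 1, 4)) {
      m <- cobb_douglas_utility(a)
      R_ess <- singular_strategy(m, cc)$R_star
      lo <- max(1.05, R_ess / 3); hi <- max(R_ess * 2, lo + 2)
      n <- 41
      pg <- pip_grid(m, cc, R_range = c(lo, hi), n = n)
      expect_true(all(diag(pg$sign_matrix) == 0))
      # locate the off-diagonal sign change of s(R_m; R_r) along R_r for a
      # mutant step just above the resident
      cell <- diff(pg$resident_axis)[1]
      s_up <- vapply(pg$resident_axis, function(Rr)
        invasion_fitness(Rr + cell / 2, Rr, m, cc), 0)
      if (R_ess > lo && R_ess < hi) {
        ix <- which(diff(sign(s_up)) != 0)
        expect_true(length(ix) >= 1)
        crossing <- pg$resident_axis[ix[1]]
        expect_lt(abs(crossing - R_ess), 2 * cell)
      }
    }
  }
})

test_that("mutual invasibility appears off-diagonal around coexistence pairs", {
  m <- cobb_douglas_utility(0.25)
  pg <- pip_grid(m, 0.25, R_range = c(2, 10), n = 33)
  df <- as.data.frame(pg)
  expect_equal(nrow(df), 33^2)
  # the Fig-3-style pair straddling the optimum is mutually invasible
  expect_gt(invasion_fitness(3, 7, m, 0.25), 0)
  expect_gt(invasion_fitness(7, 3, m, 0.25), 0)
  expect_true(any(df$mutual))
})

test_that("interaction-rate conversion is proportional to R", {
  expect_equal(sociality_rates(4, 1, 1), 4)
  expect_equal(sociality_rates(7, 0.5, 2), 28)
  expect_equal(sociality_rates(7, 0.3, 1.7) / sociality_rates(4, 0.3, 1.7),
               7 / 4)
  expect_error(sociality_rates(4, 0, 1), "p_g")
})
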