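test_that("the solver finds the analytic LV equilibrium", {
  p <- lv_pair(a = 0.5)
  rep1 <- solve_equilibrium(p, c(0.5, 0.5))
  expect_true(rep1$converged)
  expect_equal(rep1$state$abundances, c(2 / 3, 2 / 3), tolerance = 1e-8)
  expect_lt(rep1$residual_norm, 1e-10)
  # starting at the exact equilibrium returns immediately
  rep0 <- solve_equilibrium(p, c(2 / 3, 2 / 3))
  expect_true(rep0$converged)
  expect_lte(rep0$iterations, 1L)
  expect_lt(rep0$residual_norm, 1e-12)
  expect_error(solve_equilibrium(p, c(0, 0.5)), "strictly positive")
})

test_that("MacArthur equilibria match stiff time integration", {
  skip_if_not_installed("deSolve")
  p <- macarthur_params(w = c(1, 1.15), uptake = matrix(c(1, 0.25, 0.2, 1), 2),
                        m = c(0.45, 0.5), resource_rate = c(1, 1),
                        resource_capacity = c(1, 1))
  rep1 <- solve_equilibrium(p, community_state(c(0.2, 0.2), c(0.5, 0.5)))
  expect_true(rep1$converged)
  end <- integrate_mac(p, c(0.2, 0.2), c(0.5, 0.5), tmax = 4000)
  expect_equal(rep1$state$abundances, end$N, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rep1$state$resources, end$R, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("pruning is idempotent and keeps survivors above threshold", {
  com <- accepted_lv_community(4, seed_base = 300)
  E <- { set.seed(61); sample_effects(4, 4) }
  stressed <- set_focal_traits(com$params,
                               apply_stressors(focal_traits(com$params), E))
  pr <- prune_extinctions(stressed, carrying = com$screen$carrying,
                          start = com$screen$state)
  expect_true(pr$converged)
  thr <- 0.01 * com$screen$carrying
  surv <- pr$state$abundances > 0
  expect_true(all(pr$state$abundances[surv] >= thr[surv]))
  expect_true(all(pr$state$abundances[pr$pruned_species] == 0))
  # re-running on its own output changes nothing
  pr2 <- prune_extinctions(stressed, carrying = com$screen$carrying,
                           start = pr$state)
  expect_equal(pr2$state$abundances, pr$state$abundances, tolerance = 1e-9)
  expect_length(setdiff(pr2$pruned_species, pr$pruned_species),
                sum(!surv) - length(pr$pruned_species))
})

test_that("a pair violating the coexistence band collapses to one survivor", {
  p <- lv_pair(a = 0.6)
  # effect products with rho = 0.3 < alpha/alpha11 = 0.6: species 2 excluded
  e <- c(0.9, 0.27)
  expect_false(coexistence_test(p$mu, p$alpha, e))
  stressed <- set_focal_traits(p, p$mu * e)
  pr <- prune_extinctions(stressed, carrying = carrying_capacity(p),
                          start = community_state(c(0.5, 0.5)))
  expect_true(pr$converged)
  expect_equal(pr$pruned_species, 2L)
  # lone survivor sits at its stressed monoculture equilibrium mu*e/alpha11
  expect_equal(pr$state$abundances, c(0.9, 0), tolerance = 1e-9)
})

test_that("pruned LV solutions agree with brute-force subset enumeration", {
  skip_if_not_installed("deSolve")
  checked <- 0
  k <- 0
  while (checked < 8 && k < 400) {
    k <- k + 1
    spec <- community_spec("lotka_volterra", 4)
    pars <- sample_community(spec, seed = 5000 + k)
    scr <- screen_coexistence(pars)
    if (!scr$accept) next
    set.seed(6000 + k)
    E <- sample_effects(4, 3)
    stressed <- set_focal_traits(pars, apply_stressors(focal_traits(pars), E))
    pr <- prune_extinctions(stressed, carrying = scr$carrying,
                            start = scr$state)
    if (!pr$converged) next
    # oracle: integrate the stressed dynamics from the unstressed equilibrium
    # and apply the 1% threshold to the attractor reached
    Nend <- integrate_lv(stressed, scr$state$abundances, tmax = 4000)
    surv_o <- Nend >= 0.01 * scr$carrying
    expect_equal(pr$state$abundances > 0, surv_o)
    expect_equal(pr$state$abundances, as.numeric(Nend * surv_o),
                 tolerance = 1e-5)
    # ... and with the survivor subset, the enumerated subset equilibrium
    if (any(surv_o)) {
      sub <- which(surv_o)
      Nsub <- solve(stressed$alpha[sub, sub, drop = FALSE], stressed$mu[sub])
      expect_equal(pr$state$abundances[sub], as.numeric(Nsub),
                   tolerance = 1e-8)
    }
    checked <- checked + 1
  }
  expect_gte(checked, 8)
})

test_that("pruned solutions are invariant under species permutation", {
  com <- accepted_lv_community(4, seed_base = 700)
  E <- { set.seed(71); sample_effects(4, 5) }
  theta <- apply_stressors(focal_traits(com$params), E)
  stressed <- set_focal_traits(com$params, theta)
  pr <- prune_extinctions(stressed, carrying = com$screen$carrying,
                          start = com$screen$state)
  perm <- c(3, 1, 4, 2)
  pp <- lv_params(stressed$mu[perm], stressed$alpha[perm, perm])
  prp <- prune_extinctions(pp, carrying = com$screen$carrying[perm],
                           start = community_state(
                             com$screen$state$abundances[perm]))
  expect_equal(prp$state$abundances, pr$state$abundances[perm],
               tolerance = 1e-8)
})

test_that("non-convergence is reported, not thrown", {
  # a singular LV system (identical competition rows, different mu) has no
  # equilibrium at all; the solver must flag failure gracefully
  p <- lv_params(c(1, 1.2), matrix(1, 2, 2))
  rep1 <- solve_equilibrium(p, c(0.5, 0.5), maxit = 50)
  expect_s3_class(rep1, "solve_report")
  expect_false(rep1$converged)
  expect_false(rep1$residual_norm < 1e-10)
})
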