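test_that("LV per-capita growth matches the analytic symmetric equilibrium", {
  p <- lv_pair(a = 0.5)
  # N* = mu / (1 + alpha) for the symmetric pair
  expect_equal(per_capita_growth(p, c(2 / 3, 2 / 3)), c(0, 0), tolerance = 1e-12)
  # no competition at the origin: growth equals mu
  expect_equal(per_capita_growth(p, c(0, 0)), p$mu)
  expect_error(per_capita_growth(p, c(1, 1, 1)), "species")
  expect_error(per_capita_growth(p, c(-0.1, 1)), "negative|>= 0")
})

test_that("constructors enforce model invariants", {
  expect_error(lv_params(c(1, -1), diag(2)), "mu")
  expect_error(lv_params(c(1, 1), matrix(c(0, 1, 1, 1), 2)), "diagonal")
  expect_error(macarthur_params(1, matrix(0, 1, 1), 1, 1, 1), "resource")
  expect_error(stomp_params(rep(1, 5), rep(1, 5), 10), "4 species")
  expect_error(community_state(c(-1, 2)), ">= 0")
})

test_that("MacArthur growth and resource dynamics behave at boundary states", {
  p <- macarthur_params(w = c(1, 1.2), uptake = matrix(c(1, 0.1, 0.1, 1), 2),
                        m = c(0.4, 0.5), resource_rate = c(1, 1),
                        resource_capacity = c(1, 1))
  # no resources: consumption term vanishes, growth is -m
  expect_equal(per_capita_growth(p, community_state(c(1, 1), c(0, 0))), -p$m)
  # no consumers at capacity: logistic term is zero
  expect_equal(resource_dynamics(p, community_state(c(0, 0), c(1, 1))), c(0, 0))
  # no consumers below capacity: strictly positive renewal
  expect_true(all(resource_dynamics(p, community_state(c(0, 0), c(0.3, 0.7))) > 0))
  expect_error(resource_dynamics(lv_pair(), c(1, 1)), "MacArthur")
})

test_that("MacArthur dynamics agree with an independent time-stepped oracle", {
  skip_if_not_installed("deSolve")
  p <- macarthur_params(w = 1.1, uptake = matrix(1, 1, 1), m = 0.4,
                        resource_rate = 1, resource_capacity = 1)
  # single species / single resource closed form of the coupled linear system:
  # R* = m/(w c), N* = r (1 - R*/K) / c
  Rstar <- 0.4 / 1.1
  Nstar <- 1 * (1 - Rstar)
  end <- integrate_mac(p, N0 = 0.2, R0 = 0.9, tmax = 3000)
  expect_equal(end$N, Nstar, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(end$R, Rstar, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(carrying_capacity(p, 1), Nstar, tolerance = 1e-10)
  # rates vanish at the closed-form equilibrium
  st <- community_state(Nstar, Rstar)
  expect_equal(per_capita_growth(p, st), 0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(resource_dynamics(p, st), 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("absorbed light follows Beer-Lambert", {
  flat <- matrix(2e-3, 1, 31)
  p <- stomp_params(phi = 1, loss = 0.5, depth = 10, absorption = flat,
                    incident = 40, background = 0.1)
  # single species, wavelength-flat spectrum: closed-form attenuation
  N <- 300
  k <- 2e-3 * N + 0.1
  for (z in c(0, 3, 10)) {
    gamma_exact <- 2e-3 * 40 * 300 * exp(-k * z)  # a * I0 * bandwidth * e^{-kz}
    expect_equal(absorbed_light_profile(p, N, z), gamma_exact,
                 tolerance = 1e-10)
  }
  expect_error(absorbed_light_profile(p, N, 11), "depth")
  # zero incident spectrum absorbs nothing
  p0 <- stomp_params(phi = 1, loss = 0.5, depth = 10, absorption = flat,
                     incident = 0, background = 0.1)
  expect_equal(absorbed_light_profile(p0, N, 5), 0)
  # empty water column, no background: absorption in proportion to the
  # species' own spectrum against the unattenuated incident light
  p2 <- stomp_params(phi = c(1, 1), loss = c(0.5, 0.5), depth = 10,
                     peak_wavelength = c(480, 620), background = 0)
  g0 <- absorbed_light_profile(p2, c(0, 0), 7)
  wlw <- diff(p2$wavelengths)
  manual <- sapply(1:2, function(i) {
    f <- p2$absorption[i, ] * p2$incident
    sum((f[-1] + f[-31]) / 2 * wlw)
  })
  expect_equal(g0, manual, tolerance = 1e-12)
})

test_that("Stomp depth-averaged growth matches the single-wavelength closed form", {
  flat <- matrix(2e-3, 1, 31)
  p <- stomp_params(phi = 1.3, loss = 0.5, depth = 10, absorption = flat,
                    incident = 40, background = 0.1, n_depth = 1601)
  N <- 250
  k <- 2e-3 * N + 0.1
  # (phi/z) int_0^z a I0 W e^{-kz'} dz' - l
  exact <- 1.3 * 2e-3 * 40 * 300 * (1 - exp(-k * 10)) / (k * 10) - 0.5
  expect_equal(per_capita_growth(p, N), exact, tolerance = 1e-5)
})

test_that("Stomp quadrature converges under grid doubling", {
  base <- function(nw, nz) {
    p <- stomp_params(phi = c(1, 1.2), loss = c(0.5, 0.6), depth = 10,
                      peak_wavelength = c(480, 620),
                      wavelengths = seq(400, 700, length.out = nw),
                      n_depth = nz)
    per_capita_growth(p, c(100, 150))
  }
  g1 <- base(31, 51)
  g2 <- base(61, 101)
  g4 <- base(121, 201)
  # halving the step shrinks the deviation from the finest grid (O(h^2))
  err1 <- max(abs(g1 - g4))
  err2 <- max(abs(g2 - g4))
  expect_lt(err2, err1 / 2)
  expect_lt(err1, 1e-3)
})

test_that("Stomp growth is monotone in phi and carrying capacity matches the ODE", {
  p <- stomp_params(phi = c(1, 1), loss = c(0.5, 0.55), depth = 10,
                    peak_wavelength = c(480, 620))
  g_lo <- per_capita_growth(p, c(100, 100))
  p_hi <- set_focal_traits(p, c(1.4, 1))
  g_hi <- per_capita_growth(p_hi, c(100, 100))
  expect_gt(g_hi[1], g_lo[1])
  expect_equal(g_hi[2], g_lo[2])

  skip_if_not_installed("deSolve")
  K1 <- carrying_capacity(p, 1)
  end <- integrate_stomp(p, c(50, 0))
  expect_equal(end[1], K1, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("LV carrying capacity is mu/alpha_ii and linear in stressor products", {
  p <- lv_params(1, matrix(2, 1, 1))
  expect_equal(carrying_capacity(p, 1), 0.5)
  p2 <- set_focal_traits(p, apply_stressors(1, matrix(0.5, 1, 1)))
  expect_equal(carrying_capacity(p2, 1), 0.25)
  expect_error(carrying_capacity(p, 3), "index")
})

test_that("per-capita growth vanishes at solved equilibria for every model", {
  tol <- 1e-10
  p_lv <- lv_pair(a = 0.3)
  st <- solve_equilibrium(p_lv, c(0.4, 0.4))$state
  expect_lt(max(abs(per_capita_growth(p_lv, st))), tol)

  p_mac <- macarthur_params(w = c(1, 1.1), uptake = matrix(c(1, 0.2, 0.2, 1), 2),
                            m = c(0.4, 0.45), resource_rate = c(1, 1),
                            resource_capacity = c(1, 1))
  rep_mac <- solve_equilibrium(p_mac, community_state(c(0.3, 0.3), c(0.5, 0.5)))
  expect_true(rep_mac$converged)
  expect_lt(max(abs(per_capita_growth(p_mac, rep_mac$state))), tol)
  expect_lt(max(abs(resource_dynamics(p_mac, rep_mac$state))), tol)

  p_st <- stomp_params(phi = c(1, 1.1), loss = c(0.5, 0.55), depth = 10,
                       peak_wavelength = c(480, 620))
  rep_st <- solve_equilibrium(p_st, c(100, 100))
  expect_true(rep_st$converged)
  expect_lt(max(abs(per_capita_growth(p_st, rep_st$state))), tol)
})
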