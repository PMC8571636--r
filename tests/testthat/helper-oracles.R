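# Independent time-integration oracles (deSolve) and small fixture builders.
# The ODE right-hand sides are written out here from the model definitions,
# independent of the package's per-capita / solver code paths.

lv_pair <- function(mu = c(1, 1), a = 0.5, a11 = 1, a22 = 1) {
  lv_params(mu, matrix(c(a11, a, a, a22), 2))
}

# integrate LV dynamics and return final abundances
integrate_lv <- function(params, N0, tmax = 2000) {
  rhs <- function(t, N, p) {
    N <- pmax(N, 0)
    list(N * (p$mu - as.vector(p$alpha %*% N)))
  }
  out <- deSolve::ode(N0, c(0, tmax), rhs,
                      list(mu = params$mu, alpha = params$alpha),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  unname(pmax(out[nrow(out), -1], 0))
}

# integrate MacArthur consumer-resource dynamics (logistic resources, linear
# uptake) and return the final state
integrate_mac <- function(params, N0, R0, tmax = 2000) {
  n <- length(N0)
  rhs <- function(t, y, p) {
    N <- pmax(y[seq_len(n)], 0); R <- pmax(y[-seq_len(n)], 0)
    dN <- N * (p$w * as.vector(p$uptake %*% R) - p$m)
    dR <- p$rr * R * (1 - R / p$K) - as.vector(crossprod(p$uptake, N)) * R
    list(c(dN, dR))
  }
  out <- deSolve::ode(c(N0, R0), c(0, tmax), rhs,
                      list(w = params$w, uptake = params$uptake, m = params$m,
                           rr = params$resource_rate,
                           K = params$resource_capacity),
                      method = "lsoda", rtol = 1e-11, atol = 1e-12)
  y <- unname(pmax(out[nrow(out), -1], 0))
  list(N = y[seq_len(n)], R = y[-seq_len(n)])
}

# integrate Stomp dynamics using the package's growth evaluation only through
# per_capita_growth (public surface), as a steady-state cross-check
integrate_stomp <- function(params, N0, tmax = 5000) {
  rhs <- function(t, N, p) {
    N <- pmax(N, 0)
    list(N * per_capita_growth(p, community_state(N)))
  }
  out <- deSolve::ode(N0, c(0, tmax), rhs, params,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  unname(pmax(out[nrow(out), -1], 0))
}

# sample a screened (coexisting) LV community, retrying seeds until accepted
accepted_lv_community <- function(n = 4, seed_base = 1, threshold = 0.01) {
  spec <- community_spec("lotka_volterra", n)
  for (k in 1:500) {
    pars <- sample_community(spec, seed = seed_base + k)
    scr <- screen_coexistence(pars, threshold)
    if (scr$accept) return(list(params = pars, screen = scr))
  }
  stop("no accepted community found")
}
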