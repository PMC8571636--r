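# Equilibrium solving. Communities are solved to steady state with Broyden's
# quasi-Newton method (pracma::broyden) on the per-capita rates of the
# currently extant species (and resources), which is equivalent to rooting
# the full dynamics on the positive orthant while avoiding the trivial
# N_i = 0 roots. Species falling below the extinction threshold (a fraction
# of their unstressed carrying capacity) are removed and the reduced
# community is re-solved until the survivor set is a fixed point.

# Unchecked per-capita rates usable at solver iterates (which may stray
# slightly negative).
.percap_growth <- function(params, N, R) {
  if (inherits(params, "lv_params")) {
    as.vector(params$mu - params$alpha %*% N)
  } else if (inherits(params, "macarthur_params")) {
    as.vector(params$w * (params$uptake %*% R) - params$m)
  } else {
    params$phi * .stomp_mean_absorbed(params, N) - params$loss
  }
}

# scalar secant iteration (the 1-d degenerate case of the quasi-Newton
# update; pracma::broyden requires at least two dimensions)
.secant_root <- function(f, x0, tol, maxit) {
  x1 <- x0 * 1.05 + 1e-9
  f0 <- f(x0); f1 <- f(x1)
  for (it in seq_len(maxit)) {
    if (!is.finite(f1)) break
    if (abs(f1) < tol) return(list(zero = x1, fnorm = abs(f1), niter = it))
    d <- f1 - f0
    if (d == 0) break
    x2 <- x1 - f1 * (x1 - x0) / d
    x0 <- x1; f0 <- f1
    x1 <- x2; f1 <- f(x1)
  }
  list(zero = x1, fnorm = abs(f1), niter = maxit)
}

.solve_active <- function(params, N0, R0, active_sp, active_res,
                          tol = 1e-10, maxit = 200L) {
  n <- params$n
  r <- n_resources(params)
  ka <- sum(active_sp)
  if (ka == 0L) {
    # no consumers left: resources relax to capacity
    R <- if (r > 0) params$resource_capacity else numeric(0)
    return(list(N = numeric(n), R = R, converged = TRUE,
                residual_norm = 0, iterations = 0L))
  }
  embed <- function(x) {
    N <- numeric(n); N[active_sp] <- x[seq_len(ka)]
    R <- numeric(r)
    if (r > 0) R[active_res] <- x[-seq_len(ka)]
    list(N = N, R = R)
  }
  fres <- function(x) {
    st <- embed(x)
    out <- .percap_growth(params, st$N, st$R)[active_sp]
    if (r > 0)
      out <- c(out, .resource_percapita(params, st$N, st$R)[active_res])
    out
  }
  x0 <- c(N0[active_sp], if (r > 0) R0[active_res])
  f0 <- fres(x0)
  if (all(is.finite(f0)) && max(abs(f0)) < tol) {
    st <- embed(x0)
    return(list(N = st$N, R = st$R, converged = TRUE,
                residual_norm = max(abs(f0)), iterations = 0L))
  }
  # deterministic multi-start: warm start first, then fixed multiplicative
  # jitters (no RNG use inside the solver)
  jitter <- c(1, 0.5, 1.6, 0.8, 1.25, 0.64)
  best <- NULL
  for (fac in jitter) {
    sol <- tryCatch(
      suppressWarnings(
        if (length(x0) == 1L) {
          .secant_root(fres, x0 * fac, tol = tol / 10, maxit = maxit)
        } else {
          pracma::broyden(fres, x0 * fac, maxiter = maxit, tol = tol / 10)
        }),
      error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol$zero))) next
    res <- tryCatch(max(abs(fres(sol$zero))), error = function(e) Inf)
    if (!is.finite(res)) next
    cand <- list(zero = sol$zero, res = res, niter = sol$niter)
    if (is.null(best) || res < best$res) best <- cand
    if (res < tol) break
  }
  if (is.null(best)) {
    return(list(N = N0, R = R0, converged = FALSE,
                residual_norm = Inf, iterations = maxit))
  }
  st <- embed(best$zero)
  list(N = st$N, R = st$R, converged = best$res < tol,
       residual_norm = best$res, iterations = as.integer(best$niter))
}

.new_report <- function(params, N, R, converged, residual_norm, iterations,
                        pruned = integer(0), rounds = 1L) {
  structure(list(state = community_state(pmax(N, 0), pmax(R, 0)),
                 converged = converged, residual_norm = residual_norm,
                 iterations = iterations, pruned_species = sort(pruned),
                 rounds = rounds),
            class = "solve_report")
}

#' Solve a community equilibrium
#'
#' Finds a root of the community dynamics (\eqn{dN_i/dt = 0} for all extant
#' species, and \eqn{dR_k/dt = 0} for MacArthur resources) by Broyden's
#' quasi-Newton method, starting from `start`. A start that is already an
#' equilibrium returns immediately (0 iterations). On failure the solver
#' restarts from deterministically perturbed points; persistent failure is
#' reported via `converged = FALSE`, never an error.
#'
#' @param params A `community_model` object.
#' @param start A [community_state()] (or abundance vector), strictly
#'   positive for all modeled species and resources.
#' @param tol Convergence tolerance on the residual max-norm (default 1e-10).
#' @param maxit Maximum Broyden iterations per start (default 200).
#' @return A `solve_report`: the state, `converged`, `residual_norm`,
#'   `iterations` and (always empty here) `pruned_species`.
#' @examples
#' p <- lv_params(c(1, 1), matrix(c(1, 0.5, 0.5, 1), 2))
#' solve_equilibrium(p, c(0.5, 0.5))$state$abundances  # 2/3, 2/3
#' @export
solve_equilibrium <- function(params, start, tol = 1e-10, maxit = 200L) {
  start <- .check_state(params, start)
  if (any(start$abundances <= 0))
    stop("initial abundances must be strictly positive")
  r <- n_resources(params)
  if (r > 0 && any(start$resources <= 0))
    stop("initial resources must be strictly positive")
  sol <- .solve_active(params, start$abundances, start$resources,
                       active_sp = rep(TRUE, params$n),
                       active_res = rep(TRUE, r), tol = tol, maxit = maxit)
  .new_report(params, sol$N, sol$R, sol$converged, sol$residual_norm,
              sol$iterations)
}

#' Solve to equilibrium with extinction pruning
#'
#' Iterates: solve the equilibrium of the currently extant set; remove every
#' species whose abundance falls below `threshold_fraction` of its
#' (unstressed) carrying capacity, treating negative or non-finite candidate
#' abundances as below threshold; re-solve the reduced community; repeat
#' until the survivor set is a fixed point of the procedure (idempotent) or
#' no species remain. Resources driven to or below zero are deactivated and
#' reactivated if their invasion rate turns positive.
#'
#' @param params A `community_model` object (typically carrying stressed
#'   traits).
#' @param threshold_fraction Extinction threshold as a fraction of carrying
#'   capacity (default 0.01).
#' @param carrying Carrying capacities defining the threshold. Defaults to
#'   `carrying_capacity(params)`; pass the unstressed capacities explicitly
#'   when `params` hold stressed traits.
#' @param start Optional warm start ([community_state()]); defaults to half
#'   the carrying capacities (and half resource capacity).
#' @param tol,maxit Solver controls, as in [solve_equilibrium()].
#' @param max_rounds Cap on prune/re-solve rounds before aborting with
#'   `converged = FALSE` (guards against oscillating removal sets).
#' @return A `solve_report` with `pruned_species` listing removed species
#'   (their abundance is 0 in the returned state).
#' @export
prune_extinctions <- function(params, threshold_fraction = 0.01,
                              carrying = NULL, start = NULL,
                              tol = 1e-10, maxit = 200L,
                              max_rounds = NULL) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  n <- params$n
  r <- n_resources(params)
  if (is.null(carrying)) carrying <- carrying_capacity(params)
  thr <- threshold_fraction * carrying
  if (is.null(max_rounds)) max_rounds <- n + r + 4L
  if (is.null(start)) {
    N <- pmax(carrying, 1e-6) / 2
    R <- if (r > 0) params$resource_capacity / 2 else numeric(0)
  } else {
    start <- .check_state(params, start)
    N <- start$abundances
    R <- start$resources
  }
  active_sp <- N > 0
  active_res <- rep(TRUE, r)
  pruned <- which(!active_sp)
  for (round in seq_len(max_rounds)) {
    sol <- .solve_active(params, pmax(N, thr / 2)[], R, active_sp, active_res,
                         tol = tol, maxit = maxit)
    if (!sol$converged && !all(!active_sp)) {
      return(.new_report(params, sol$N * as.numeric(active_sp), sol$R,
                         FALSE, sol$residual_norm, sol$iterations,
                         pruned, round))
    }
    N <- sol$N; R <- sol$R
    bad_sp <- active_sp & (!is.finite(N) | N < thr)
    bad_res <- if (r > 0) active_res & (!is.finite(R) | R <= 0) else logical(0)
    # resources pushed to zero can re-invade once consumers thin out
    revive <- if (r > 0) {
      !active_res & .resource_percapita(params, pmax(N, 0), pmax(R, 0)) > tol
    } else logical(0)
    if (!any(bad_sp) && !any(bad_res) && !any(revive)) {
      N[!active_sp] <- 0
      if (r > 0) R[!active_res] <- 0
      return(.new_report(params, N, R, TRUE, sol$residual_norm,
                         sol$iterations, pruned, round))
    }
    pruned <- union(pruned, which(bad_sp))
    active_sp <- active_sp & !bad_sp
    active_res <- (active_res & !bad_res) | revive
    N[!active_sp] <- 0
    if (r > 0) {
      R[!active_res] <- 0
      R[revive] <- params$resource_capacity[revive] / 2
    }
    if (!any(active_sp)) {
      sol <- .solve_active(params, N, R, active_sp, active_res, tol, maxit)
      return(.new_report(params, sol$N, sol$R, TRUE, sol$residual_norm,
                         sol$iterations, pruned, round))
    }
  }
  .new_report(params, N * as.numeric(active_sp), R, FALSE, NA_real_,
              maxit, pruned, max_rounds)
}

#' @export
print.solve_report <- function(x, ...) {
  cat("equilibrium solve:",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(residual %.3g, %d iterations, %d round%s)\n",
              x$residual_norm, x$iterations, x$rounds,
              if (x$rounds == 1) "" else "s"))
  if (length(x$pruned_species))
    cat("  pruned species:", paste(x$pruned_species, collapse = ", "), "\n")
  print(x$state)
  invisible(x)
}
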