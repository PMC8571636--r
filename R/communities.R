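# Community generation: sample model parameters (focal traits theta from a
# log-normal distribution; other parameters from documented default ranges)
# and screen for communities in which every species persists at >= 1% of its
# carrying capacity in the unstressed environment.
#
# The non-focal sampling ranges below are this package's own reconstructions
# of plausible coexistence-friendly ranges; they are deliberately centralised
# here and surfaced through community_spec() so they can be overridden.

#' Specification for sampling a community
#'
#' @param model One of `"lotka_volterra"`, `"macarthur"`, `"stomp"`.
#' @param n_species Initial species richness (>= 2; the Stomp model supports
#'   at most 4 species, since coexistence of more than four species on light
#'   spectrum differentiation alone is impossible).
#' @param theta_meanlog,theta_sdlog Log-normal parameters of the focal trait
#'   distribution (defaults 0 and 0.25).
#' @param control Named list of model-specific sampling settings overriding
#'   the defaults: for Lotka-Volterra `alpha_range` (off-diagonal interaction
#'   strength range as a fraction of the diagonal, default c(0.1, 0.9)); for
#'   MacArthur `shared_uptake_range` (off-diagonal uptake, default
#'   c(0.05, 0.3)) and `maintenance_fraction_range` (maintenance as a
#'   fraction of resource-saturated growth, default c(0.25, 0.45)); for Stomp
#'   `loss_fraction_range` (loss as a fraction of unshaded growth, default
#'   c(0.25, 0.45)) plus any [stomp_params()] optical argument.
#' @return A `community_spec` object.
#' @export
community_spec <- function(model = c("lotka_volterra", "macarthur", "stomp"),
                           n_species = 4, theta_meanlog = 0,
                           theta_sdlog = 0.25, control = list()) {
  model <- match.arg(model)
  n_species <- as.integer(n_species)
  if (n_species < 2) stop("n_species must be >= 2")
  if (model == "stomp" && n_species > 4)
    stop("the Stomp model supports at most 4 species")
  if (theta_sdlog < 0) stop("theta_sdlog must be >= 0")
  structure(list(model = model, n_species = n_species,
                 theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
                 control = control),
            class = "community_spec")
}

.ctl <- function(spec, name, default) {
  if (!is.null(spec$control[[name]])) spec$control[[name]] else default
}

#' Sample one community's model parameters
#'
#' Focal traits (\eqn{\mu_i}, \eqn{w_i} or \eqn{\phi_i}) are drawn from a
#' log-normal distribution; the remaining parameters come from the default
#' ranges documented in [community_spec()]. Uses the current RNG state; set
#' `seed` (or call `set.seed()`) for reproducibility.
#'
#' @param spec A [community_spec()].
#' @param seed Optional integer seed applied before sampling.
#' @return A `community_model` parameter object.
#' @export
sample_community <- function(spec, seed = NULL) {
  if (!inherits(spec, "community_spec")) stop("spec must be a community_spec")
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_species
  theta <- stats::rlnorm(n, spec$theta_meanlog, spec$theta_sdlog)
  switch(spec$model,
    lotka_volterra = {
      rng <- .ctl(spec, "alpha_range", c(0.1, 0.9))
      # interspecific competition scaled so the summed competitive load is
      # comparable across richness levels (the raw range at the 4-species
      # baseline); without this, random 8- and 16-species communities almost
      # never coexist
      sc <- .ctl(spec, "alpha_richness_scaling", 3 / (n - 1))
      alpha <- matrix(stats::runif(n * n, rng[1], rng[2]) * sc, n, n)
      diag(alpha) <- 1
      lv_params(mu = theta, alpha = alpha)
    },
    macarthur = {
      srng <- .ctl(spec, "shared_uptake_range", c(0.05, 0.3))
      mrng <- .ctl(spec, "maintenance_fraction_range", c(0.25, 0.45))
      # same richness scaling as for LV competition: shared uptake per
      # competitor shrinks as richness grows, keeping the total overlap load
      # comparable across richness levels
      sc <- .ctl(spec, "uptake_richness_scaling", 3 / (n - 1))
      uptake <- matrix(stats::runif(n * n, srng[1], srng[2]) * sc, n, n)
      diag(uptake) <- 1
      Kr <- rep(1, n)
      sat <- theta * as.vector(uptake %*% Kr)  # growth at resource capacity
      m <- stats::runif(n, mrng[1], mrng[2]) * sat
      macarthur_params(w = theta, uptake = uptake, m = m,
                       resource_rate = rep(1, n), resource_capacity = Kr)
    },
    stomp = {
      lrng <- .ctl(spec, "loss_fraction_range", c(0.25, 0.45))
      p0 <- stomp_params(
        phi = theta, loss = rep(1, n),
        depth = .ctl(spec, "depth", 10),
        peak_wavelength = .ctl(spec, "peak_wavelength",
                               seq(450, 650, length.out = n)),
        peak_height = .ctl(spec, "peak_height", 2e-3),
        spectral_width = .ctl(spec, "spectral_width", 50),
        incident = .ctl(spec, "incident", 40),
        background = .ctl(spec, "background", 0.2),
        wavelengths = .ctl(spec, "wavelengths", seq(400, 700, length.out = 31)),
        n_depth = .ctl(spec, "n_depth", 51))
      # loss as a fraction of each species' unshaded depth-averaged growth,
      # so monocultures are viable by construction
      g0 <- theta * .stomp_mean_absorbed(p0, numeric(n))
      p0$loss <- stats::runif(n, lrng[1], lrng[2]) * g0
      p0
    })
}

#' Screen a community for unstressed coexistence
#'
#' Solves the unstressed equilibrium and accepts the community iff every
#' species' abundance is at least `threshold_fraction` of its carrying
#' capacity. Solver non-convergence rejects with status
#' `"solver_failure"` rather than throwing.
#'
#' @param params A `community_model` object.
#' @param threshold_fraction Persistence threshold (default 0.01).
#' @param tol,maxit Solver controls.
#' @return A list: `accept` (logical), `state` (the equilibrium
#'   [community_state()] when accepted, else `NULL`), `carrying` (monoculture
#'   equilibria), and `status` (`"accepted"`, `"below_threshold"`,
#'   `"solver_failure"`, or `"infeasible_monoculture"`).
#' @export
screen_coexistence <- function(params, threshold_fraction = 0.01,
                               tol = 1e-10, maxit = 200L) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  K <- tryCatch(carrying_capacity(params), error = function(e) NULL)
  if (is.null(K) || any(!is.finite(K)) || any(K <= 0))
    return(list(accept = FALSE, state = NULL, carrying = K,
                status = "infeasible_monoculture"))
  r <- n_resources(params)
  start <- community_state(K / 2, if (r > 0) params$resource_capacity / 2)
  rep0 <- solve_equilibrium(params, start, tol = tol, maxit = maxit)
  if (!rep0$converged)
    return(list(accept = FALSE, state = NULL, carrying = K,
                status = "solver_failure"))
  N <- rep0$state$abundances
  ok <- all(N >= threshold_fraction * K)
  list(accept = ok, state = if (ok) rep0$state else NULL, carrying = K,
       status = if (ok) "accepted" else "below_threshold")
}

#' Generate a batch of coexisting communities
#'
#' Repeatedly samples communities under `spec` until `n_communities` pass
#' [screen_coexistence()]. Each attempt uses its own seed
#' (`base_seed + attempt`), recorded with the community so every replicate is
#' reproducible in isolation. Non-convergent screens count as rejections.
#'
#' @param spec A [community_spec()].
#' @param n_communities Number of accepted communities required.
#' @param base_seed Integer seed base.
#' @param max_attempts Cap on sampling attempts (default `200 * n_communities`).
#' @param threshold_fraction Persistence threshold (default 0.01).
#' @return A `community_batch`: list with `communities` (each holding
#'   `params`, `state`, `carrying`, `seed`), `attempts`, `acceptance_rate`,
#'   and the generating `spec`. Errors (reporting the acceptance rate) if the
#'   quota is not met within `max_attempts`.
#' @export
generate_batch <- function(spec, n_communities, base_seed = 1L,
                           max_attempts = 200L * n_communities,
                           threshold_fraction = 0.01) {
  if (n_communities < 1) stop("n_communities must be >= 1")
  out <- vector("list", n_communities)
  got <- 0L; attempts <- 0L
  while (got < n_communities && attempts < max_attempts) {
    attempts <- attempts + 1L
    sd_i <- (base_seed + attempts) %% .Machine$integer.max
    params <- sample_community(spec, seed = sd_i)
    scr <- screen_coexistence(params, threshold_fraction)
    if (scr$accept) {
      got <- got + 1L
      out[[got]] <- list(params = params, state = scr$state,
                         carrying = scr$carrying, seed = sd_i)
    }
  }
  if (got < n_communities)
    stop(sprintf(
      "only %d/%d communities accepted after %d attempts (acceptance rate %.3f)",
      got, n_communities, attempts, got / attempts))
  structure(list(communities = out, attempts = attempts,
                 acceptance_rate = got / attempts, spec = spec,
                 base_seed = base_seed),
            class = "community_batch")
}

#' @export
print.community_batch <- function(x, ...) {
  cat("community batch:", length(x$communities), "accepted",
      sprintf("(%s, n = %d, acceptance rate %.3f)\n",
              x$spec$model, x$spec$n_species, x$acceptance_rate))
  invisible(x)
}

#' Write / read model parameters as a flat CSV
#'
#' One row per species, matrix-valued fields in wide columns; values are
#' printed with 17 significant digits so round-trips are lossless to full
#' double precision. The model type and scalar settings travel in commented
#' header lines.
#'
#' @param params A `community_model` object.
#' @param path CSV file path.
#' @return `write_model_params()` returns `path` invisibly;
#'   `read_model_params()` returns the reconstructed parameter object.
#' @export
write_model_params <- function(params, path) {
  fmt <- function(x) sprintf("%.17g", x)
  con <- file(path, "w"); on.exit(close(con))
  hdr <- function(...) writeLines(paste0("# ", paste0(...)), con)
  if (inherits(params, "lv_params")) {
    hdr("model: lotka_volterra")
    df <- data.frame(mu = fmt(params$mu))
    for (j in seq_len(params$n)) df[[paste0("alpha_", j)]] <- fmt(params$alpha[, j])
  } else if (inherits(params, "macarthur_params")) {
    hdr("model: macarthur")
    hdr("resource_rate: ", paste(fmt(params$resource_rate), collapse = " "))
    hdr("resource_capacity: ", paste(fmt(params$resource_capacity), collapse = " "))
    df <- data.frame(w = fmt(params$w), m = fmt(params$m))
    for (j in seq_len(params$r)) df[[paste0("uptake_", j)]] <- fmt(params$uptake[, j])
  } else if (inherits(params, "stomp_params")) {
    hdr("model: stomp")
    hdr("depth: ", fmt(params$depth))
    hdr("n_depth: ", params$n_depth)
    hdr("wavelengths: ", paste(fmt(params$wavelengths), collapse = " "))
    hdr("incident: ", paste(fmt(params$incident), collapse = " "))
    hdr("background: ", paste(fmt(params$background), collapse = " "))
    df <- data.frame(phi = fmt(params$phi), loss = fmt(params$loss))
    for (j in seq_along(params$wavelengths))
      df[[paste0("absorption_", j)]] <- fmt(params$absorption[, j])
  } else stop("unknown model class")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*: ?", "", kv))
  }
  num <- function(key) as.numeric(strsplit(meta[[key]], " +")[[1]])
  df <- utils::read.csv(text = lines[!startsWith(lines, "# ")],
                        colClasses = "character")
  col <- function(name) as.numeric(df[[name]])
  wide <- function(prefix) {
    js <- grep(paste0("^", prefix, "_[0-9]+$"), names(df), value = TRUE)
    js <- js[order(as.integer(sub(paste0(prefix, "_"), "", js)))]
    mat <- sapply(js, function(j) as.numeric(df[[j]]))
    matrix(mat, nrow = nrow(df))
  }
  switch(meta$model,
    lotka_volterra = lv_params(col("mu"), wide("alpha")),
    macarthur = macarthur_params(col("w"), wide("uptake"), col("m"),
                                 num("resource_rate"), num("resource_capacity")),
    stomp = stomp_params(col("phi"), col("loss"), depth = num("depth"),
                         absorption = wide("absorption"),
                         incident = num("incident"),
                         background = num("background"),
                         wavelengths = num("wavelengths"),
                         n_depth = as.integer(num("n_depth"))),
    stop("unknown model in file: ", meta$model))
}

#' Write a community batch to a directory
#'
#' Creates `manifest.csv` (model, n, seeds, acceptance rate) and one
#' parameter CSV per community.
#'
#' @param batch A `community_batch`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_batch <- function(batch, dir) {
  if (!inherits(batch, "community_batch")) stop("not a community_batch")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("community_%03d.csv", seq_along(batch$communities))
  for (i in seq_along(batch$communities))
    write_model_params(batch$communities[[i]]$params, file.path(dir, files[i]))
  manifest <- data.frame(
    file = files,
    model = batch$spec$model,
    n_species = batch$spec$n_species,
    seed = vapply(batch$communities, `[[`, numeric(1), "seed"),
    acceptance_rate = batch$acceptance_rate)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
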