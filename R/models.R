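# Community models: Lotka-Volterra, MacArthur consumer-resource, and
# Stomp-type light-spectrum competition. Each model exposes the same surface:
# a parameter object carrying a focal trait vector theta that stressors
# multiply, per-capita growth rates, and carrying capacities (monoculture
# equilibria) used by the 1% persistence threshold.

#' Lotka-Volterra community parameters
#'
#' Per-capita growth of species \eqn{i} is \eqn{\mu_i - \sum_j \alpha_{ij} N_j}.
#' The focal trait acted on by stressors is the intrinsic growth rate
#' \eqn{\mu_i}.
#'
#' @param mu Numeric vector of intrinsic growth rates (all > 0 pre-stress).
#' @param alpha Interaction matrix \eqn{\alpha_{ij}} (effect of species j on
#'   species i); the diagonal must be strictly positive.
#' @return An object of class `c("lv_params", "community_model")`.
#' @examples
#' p <- lv_params(mu = c(1, 1), alpha = matrix(c(1, 0.5, 0.5, 1), 2))
#' carrying_capacity(p)
#' @export
lv_params <- function(mu, alpha) {
  mu <- as.numeric(mu)
  alpha <- as.matrix(alpha)
  n <- length(mu)
  if (n < 1L) stop("need at least one species")
  if (!all(dim(alpha) == c(n, n))) stop("alpha must be ", n, "x", n)
  if (any(!is.finite(mu)) || any(!is.finite(alpha))) stop("non-finite parameters")
  if (any(diag(alpha) <= 0)) stop("diagonal alpha_ii must be > 0")
  if (any(mu <= 0)) stop("mu must be > 0 (pre-stress)")
  structure(list(mu = mu, alpha = alpha, n = n),
            class = c("lv_params", "community_model"))
}

#' MacArthur consumer-resource community parameters
#'
#' Per-capita consumer growth is \eqn{\sum_k w_i c_{ik} R_k - m_i}; resources
#' grow logistically and are taken up linearly (mass action):
#' \eqn{dR_k/dt = r_k R_k (1 - R_k/K_k) - \sum_i c_{ik} N_i R_k}.
#' The focal trait acted on by stressors is the resource value \eqn{w_i}
#' (species-specific here, for comparability with the other models).
#'
#' @param w Vector of species-specific resource values (> 0).
#' @param uptake n x r matrix \eqn{c_{ik}} of uptake rates (>= 0; every
#'   species needs at least one positive entry).
#' @param m Vector of maintenance rates (> 0).
#' @param resource_rate Per-resource logistic growth rates (> 0).
#' @param resource_capacity Per-resource carrying capacities (> 0).
#' @return An object of class `c("macarthur_params", "community_model")`.
#' @export
macarthur_params <- function(w, uptake, m, resource_rate, resource_capacity) {
  w <- as.numeric(w); m <- as.numeric(m)
  uptake <- as.matrix(uptake)
  n <- length(w); r <- ncol(uptake)
  if (nrow(uptake) != n || length(m) != n) stop("inconsistent species dimensions")
  resource_rate <- rep_len(as.numeric(resource_rate), r)
  resource_capacity <- rep_len(as.numeric(resource_capacity), r)
  if (any(w <= 0) || any(m <= 0)) stop("w and m must be > 0")
  if (any(uptake < 0)) stop("uptake rates must be >= 0")
  if (any(rowSums(uptake) == 0)) stop("every species needs at least one resource")
  if (any(resource_rate <= 0) || any(resource_capacity <= 0))
    stop("resource rates and capacities must be > 0")
  structure(list(w = w, uptake = uptake, m = m,
                 resource_rate = resource_rate,
                 resource_capacity = resource_capacity,
                 n = n, r = r),
            class = c("macarthur_params", "community_model"))
}

#' Stomp light-spectrum competition parameters
#'
#' Phytoplankton species compete for light and coexist by absorbing different
#' parts of the incident spectrum. Per-capita growth is the depth-averaged
#' absorbed photon flux times the photosynthetic efficiency, minus losses:
#' \deqn{(\phi_i / z) \int_0^z \gamma_i(z')\,dz' - l_i,}
#' where \eqn{\gamma_i(z) = \int a_i(\lambda) I(\lambda, z)\,d\lambda} and the
#' light field follows Beer-Lambert attenuation through all species plus a
#' non-biological background:
#' \eqn{I(\lambda,z) = I_{in}(\lambda)\exp\{-z(\sum_j a_j(\lambda) N_j +
#' a_{bg}(\lambda))\}}. Integrals use the trapezoid rule on fixed wavelength
#' and depth grids. The focal trait acted on by stressors is \eqn{\phi_i}.
#' At most four species can coexist on spectrum differentiation alone.
#'
#' @param phi Photosynthetic efficiencies (> 0), at most 4 species.
#' @param loss Specific loss rates (> 0).
#' @param depth Water column depth z in m (> 0).
#' @param absorption Optional n x length(wavelengths) matrix of absorption
#'   coefficients. If `NULL`, Gaussian absorption spectra are built from
#'   `peak_wavelength`, `peak_height` and `spectral_width`.
#' @param peak_wavelength Per-species absorption peak positions (nm).
#' @param peak_height Peak absorption coefficient (per abundance per m).
#' @param spectral_width Gaussian width of the absorption spectra (nm).
#' @param incident Incident photon flux density per wavelength (scalar or
#'   vector on the wavelength grid).
#' @param background Background (non-biological) attenuation per wavelength.
#' @param wavelengths Wavelength grid in nm (default 31 points on 400-700).
#' @param n_depth Number of depth quadrature points (default 51).
#' @return An object of class `c("stomp_params", "community_model")`.
#' @export
stomp_params <- function(phi, loss, depth,
                         absorption = NULL,
                         peak_wavelength = NULL,
                         peak_height = 2e-3,
                         spectral_width = 50,
                         incident = 40,
                         background = 0.2,
                         wavelengths = seq(400, 700, length.out = 31),
                         n_depth = 51) {
  phi <- as.numeric(phi); loss <- as.numeric(loss)
  n <- length(phi)
  if (n < 1L || n > 4L) stop("Stomp model supports 1 to 4 species")
  if (length(loss) != n) stop("loss must have one entry per species")
  if (any(phi <= 0) || any(loss <= 0) || depth <= 0)
    stop("phi, loss and depth must be > 0")
  nw <- length(wavelengths)
  if (nw < 3L) stop("wavelength grid too coarse")
  incident <- rep_len(as.numeric(incident), nw)
  background <- rep_len(as.numeric(background), nw)
  if (any(incident < 0) || any(background < 0))
    stop("spectra must be non-negative")
  if (is.null(absorption)) {
    if (is.null(peak_wavelength))
      peak_wavelength <- seq(450, 650, length.out = n)
    if (length(peak_wavelength) != n) stop("one peak wavelength per species")
    absorption <- peak_height *
      exp(-outer(peak_wavelength, wavelengths, function(p, l) (l - p)^2) /
            (2 * spectral_width^2))
  } else {
    absorption <- as.matrix(absorption)
    if (!all(dim(absorption) == c(n, nw))) stop("absorption must be n x n_wavelengths")
  }
  if (any(absorption < 0)) stop("absorption spectra must be non-negative")
  structure(list(phi = phi, loss = loss, depth = depth,
                 absorption = absorption, incident = incident,
                 background = background, wavelengths = wavelengths,
                 n_depth = as.integer(n_depth), n = n),
            class = c("stomp_params", "community_model"))
}

#' Community state at (or en route to) an equilibrium
#'
#' @param abundances Non-negative species abundances.
#' @param resources Non-negative resource densities (MacArthur only; empty
#'   otherwise).
#' @return An object of class `"community_state"` with a logical `survivors`
#'   mask (`abundances > 0`).
#' @export
community_state <- function(abundances, resources = numeric(0)) {
  abundances <- as.numeric(abundances)
  resources <- as.numeric(resources)
  if (any(abundances < 0) || any(resources < 0))
    stop("abundances and resources must be >= 0")
  structure(list(abundances = abundances, resources = resources,
                 survivors = abundances > 0),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat("community state:", sum(x$survivors), "of", length(x$abundances),
      "species extant\n")
  cat("  N =", format(x$abundances, digits = 4), "\n")
  if (length(x$resources))
    cat("  R =", format(x$resources, digits = 4), "\n")
  invisible(x)
}

#' Number of species in a model
#' @param params A `community_model` object.
#' @return Integer species count.
#' @export
n_species <- function(params) UseMethod("n_species")
#' @export
n_species.community_model <- function(params) params$n

#' Number of resources (0 for models without explicit resources)
#' @param params A `community_model` object.
#' @export
n_resources <- function(params) UseMethod("n_resources")
#' @export
n_resources.community_model <- function(params) 0L
#' @export
n_resources.macarthur_params <- function(params) params$r

#' Focal traits theta that stressors act on
#'
#' \eqn{\mu_i} for Lotka-Volterra, \eqn{w_i} for MacArthur, \eqn{\phi_i} for
#' the Stomp model.
#' @param params A `community_model` object.
#' @return Numeric vector of focal trait values.
#' @export
focal_traits <- function(params) UseMethod("focal_traits")
#' @export
focal_traits.lv_params <- function(params) params$mu
#' @export
focal_traits.macarthur_params <- function(params) params$w
#' @export
focal_traits.stomp_params <- function(params) params$phi

#' Replace the focal traits (e.g. after stressor application)
#'
#' Only the focal trait vector changes; all other parameters (including any
#' that were derived from the unstressed traits at sampling time) are kept.
#' @param params A `community_model` object.
#' @param theta New strictly positive trait vector.
#' @return A modified copy of `params`.
#' @export
set_focal_traits <- function(params, theta) UseMethod("set_focal_traits")

.check_theta <- function(params, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != params$n) stop("theta length must match species count")
  if (any(theta <= 0) || any(!is.finite(theta))) stop("traits must be > 0")
  theta
}
#' @export
set_focal_traits.lv_params <- function(params, theta) {
  params$mu <- .check_theta(params, theta); params
}
#' @export
set_focal_traits.macarthur_params <- function(params, theta) {
  params$w <- .check_theta(params, theta); params
}
#' @export
set_focal_traits.stomp_params <- function(params, theta) {
  params$phi <- .check_theta(params, theta); params
}

.check_state <- function(params, state) {
  if (!inherits(state, "community_state")) state <- community_state(state)
  if (length(state$abundances) != params$n)
    stop("state has ", length(state$abundances), " species, model has ", params$n)
  r <- n_resources(params)
  if (r > 0 && length(state$resources) != r)
    stop("state has ", length(state$resources), " resources, model has ", r)
  if (any(state$abundances < 0)) stop("negative abundance")
  state
}

#' Per-capita growth rates
#'
#' Evaluates \eqn{(dN_i/dt)/N_i} at the given state; the per-capita
#' expressions are finite at \eqn{N_i = 0}, so growth of absent species is
#' their invasion rate.
#'
#' @param params A `community_model` object.
#' @param state A [community_state()] (or abundance vector for models without
#'   resources).
#' @return Numeric vector of per-capita growth rates.
#' @examples
#' p <- lv_params(c(1, 1), matrix(c(1, 0.5, 0.5, 1), 2))
#' per_capita_growth(p, c(2/3, 2/3))  # ~ (0, 0): the coexistence equilibrium
#' @export
per_capita_growth <- function(params, state) UseMethod("per_capita_growth")

#' @export
per_capita_growth.lv_params <- function(params, state) {
  state <- .check_state(params, state)
  as.vector(params$mu - params$alpha %*% state$abundances)
}

#' @export
per_capita_growth.macarthur_params <- function(params, state) {
  state <- .check_state(params, state)
  as.vector(params$w * (params$uptake %*% state$resources) - params$m)
}

#' @export
per_capita_growth.stomp_params <- function(params, state) {
  state <- .check_state(params, state)
  params$phi * .stomp_mean_absorbed(params, state$abundances) - params$loss
}

# Trapezoid weights for an arbitrary monotone grid.
.trapz_weights <- function(x) {
  nx <- length(x)
  d <- diff(x)
  c(d[1] / 2, (d[-1] + d[-(nx - 1)]) / 2, d[nx - 1] / 2)
}

# Depth-averaged absorbed flux (1/z) * int_0^z gamma_i(z') dz' for all species.
# Accepts negative N (solver iterates): the Beer-Lambert exponent is capped to
# keep the residual finite while preserving its sign structure.
.stomp_mean_absorbed <- function(params, N) {
  k <- as.vector(crossprod(params$absorption, N)) + params$background
  zq <- seq(0, params$depth, length.out = params$n_depth)
  light <- params$incident * exp(pmin(-outer(k, zq), 40))  # nw x nz
  wl_w <- .trapz_weights(params$wavelengths)
  gam <- params$absorption %*% (light * wl_w)        # n x nz
  as.vector(gam %*% .trapz_weights(zq)) / params$depth
}

#' Resource rates of change (MacArthur model)
#'
#' Logistic resource renewal minus linear (mass-action) consumption:
#' \eqn{dR_k/dt = r_k R_k (1 - R_k/K_k) - \sum_i c_{ik} N_i R_k}.
#'
#' @param params A [macarthur_params()] object.
#' @param state A [community_state()].
#' @return Vector of \eqn{dR_k/dt}.
#' @export
resource_dynamics <- function(params, state) UseMethod("resource_dynamics")
#' @export
resource_dynamics.community_model <- function(params, state)
  stop("resource_dynamics is only defined for the MacArthur model")
#' @export
resource_dynamics.macarthur_params <- function(params, state) {
  state <- .check_state(params, state)
  R <- state$resources
  as.vector(params$resource_rate * R * (1 - R / params$resource_capacity) -
              (crossprod(params$uptake, state$abundances)) * R)
}

# Per-capita resource rates (finite at R = 0); used by the equilibrium solver.
.resource_percapita <- function(params, N, R) {
  as.vector(params$resource_rate * (1 - R / params$resource_capacity) -
              crossprod(params$uptake, N))
}

#' Absorbed light spectrum integral at one depth (Stomp model)
#'
#' \eqn{\gamma_i(z) = \int a_i(\lambda) I(\lambda, z)\, d\lambda} with the
#' light field attenuated (Beer-Lambert) by all species plus background.
#'
#' @param params A [stomp_params()] object.
#' @param abundances Non-negative abundance vector.
#' @param depth_point Depth in `[0, depth]` at which to evaluate.
#' @return Per-species absorbed flux \eqn{\gamma_i} at that depth.
#' @export
absorbed_light_profile <- function(params, abundances, depth_point) {
  if (!inherits(params, "stomp_params")) stop("requires a stomp_params object")
  abundances <- as.numeric(abundances)
  if (length(abundances) != params$n) stop("abundance length mismatch")
  if (any(abundances < 0)) stop("negative abundance")
  if (depth_point < 0 || depth_point > params$depth)
    stop("depth_point outside [0, depth]")
  k <- as.vector(crossprod(params$absorption, abundances)) + params$background
  light <- params$incident * exp(-k * depth_point)
  as.vector(params$absorption %*% (light * .trapz_weights(params$wavelengths)))
}

#' Carrying capacities (monoculture equilibrium abundances)
#'
#' For Lotka-Volterra this is \eqn{\mu_i/\alpha_{ii}}; for the MacArthur and
#' Stomp models it is the species' monoculture equilibrium, solved in closed
#' form (MacArthur, with depleted resources handled by an active-set
#' reduction) or by 1-d root bracketing (Stomp). A species that cannot
#' maintain itself alone has carrying capacity 0.
#'
#' @param params A `community_model` object.
#' @param species Optional species index; default all.
#' @return Carrying capacity (scalar if `species` given, else vector).
#' @export
carrying_capacity <- function(params, species = NULL) UseMethod("carrying_capacity")

.pick_species <- function(K, species, n) {
  if (is.null(species)) return(K)
  if (!species %in% seq_len(n)) stop("invalid species index")
  K[species]
}

#' @export
carrying_capacity.lv_params <- function(params, species = NULL) {
  .pick_species(params$mu / diag(params$alpha), species, params$n)
}

#' @export
carrying_capacity.macarthur_params <- function(params, species = NULL) {
  K <- vapply(seq_len(params$n), function(i) .mac_monoculture(params, i)$N,
              numeric(1))
  .pick_species(K, species, params$n)
}

# Monoculture equilibrium of MacArthur species i: with active resources A,
# R_k = K_k (1 - c_ik N / r_k) and w_i sum_{k in A} c_ik R_k = m_i, linear in
# N. Resources driven below 0 are removed and the system re-solved.
.mac_monoculture <- function(params, i) {
  ci <- params$uptake[i, ]
  K <- params$resource_capacity; rr <- params$resource_rate
  active <- ci > 0
  for (round in seq_len(params$r + 1L)) {
    a <- params$w[i] * sum(ci[active] * K[active]) - params$m[i]
    b <- params$w[i] * sum(ci[active]^2 * K[active] / rr[active])
    if (a <= 0 || b <= 0 || !any(active))
      return(list(N = 0, R = K))
    N <- a / b
    R <- ifelse(active, K * pmax(0, 1 - ci * N / rr), K)
    newly_dead <- active & (1 - ci * N / rr) <= 0
    if (!any(newly_dead)) return(list(N = N, R = R))
    active <- active & !newly_dead
  }
  list(N = N, R = R)
}

#' @export
carrying_capacity.stomp_params <- function(params, species = NULL) {
  K <- vapply(seq_len(params$n), function(i) .stomp_monoculture(params, i),
              numeric(1))
  .pick_species(K, species, params$n)
}

.stomp_monoculture <- function(params, i) {
  g <- function(N) {
    Nv <- numeric(params$n); Nv[i] <- N
    params$phi[i] * .stomp_mean_absorbed(params, Nv)[i] - params$loss[i]
  }
  if (g(0) <= 0) return(0)
  upper <- 1
  for (j in 1:60) {
    if (g(upper) < 0) break
    upper <- upper * 4
  }
  if (g(upper) >= 0) stop("non-convergent monoculture equilibrium")
  stats::uniroot(g, c(0, upper), tol = 1e-12)$root
}

#' @export
print.community_model <- function(x, ...) {
  lbl <- c(lv_params = "Lotka-Volterra", macarthur_params = "MacArthur",
           stomp_params = "Stomp")[class(x)[1]]
  cat(lbl, "community model:", x$n, "species")
  if (n_resources(x) > 0) cat(",", n_resources(x), "resources")
  cat("\n  focal traits theta:", format(focal_traits(x), digits = 4), "\n")
  invisible(x)
}
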