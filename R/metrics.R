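# Community-level outcome metrics: ecosystem-function ratio (stressed yield /
# unstressed yield), species persistence, Bray-Curtis compositional
# resistance, and the Loreau-Hector additive partition of the net
# biodiversity effect into complementarity and selection.

.abund <- function(x) {
  if (inherits(x, "community_state")) x$abundances
  else if (inherits(x, "solve_report")) x$state$abundances
  else as.numeric(x)
}

#' Ecosystem function ratio
#'
#' Total abundance (yield) of surviving species in the stressed community
#' divided by total unstressed yield.
#'
#' @param stressed,unstressed [community_state()] objects (or abundance
#'   vectors) from the same community.
#' @return Non-negative scalar; 1 means no functional loss.
#' @export
ecosystem_function <- function(stressed, unstressed) {
  ns <- .abund(stressed); nu <- .abund(unstressed)
  if (length(ns) != length(nu)) stop("states must come from the same community")
  denom <- sum(nu)
  if (denom <= 0) stop("zero unstressed yield")
  sum(ns) / denom
}

#' Species persistence
#'
#' @param stressed Stressed [community_state()] (or abundance vector).
#' @param initial_richness Initial species count; defaults to the state's
#'   length.
#' @return List with `count` (surviving species) and `fraction`
#'   (count / initial richness).
#' @export
persistence <- function(stressed, initial_richness = NULL) {
  ns <- .abund(stressed)
  if (is.null(initial_richness)) initial_richness <- length(ns)
  count <- sum(ns > 0)
  list(count = count, fraction = count / initial_richness)
}

#' Bray-Curtis similarity
#'
#' \eqn{1 - \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, equivalently
#' \eqn{2\sum_i \min(x_i, y_i) / \sum_i (x_i + y_i)}. Used as compositional
#' resistance: similarity between stressed and unstressed abundance vectors.
#'
#' @param x,y Equal-length non-negative vectors, not both all-zero.
#' @return Similarity in `[0, 1]` (1 = identical composition).
#' @export
bray_curtis_similarity <- function(x, y) {
  x <- .abund(x); y <- .abund(y)
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero")
  1 - sum(abs(x - y)) / tot
}

#' Loreau-Hector biodiversity-effect partition
#'
#' Partitions the net biodiversity effect \eqn{\Delta Y} (observed total
#' yield minus expected yield from monocultures) into complementarity and
#' selection:
#' \deqn{\Delta Y = n\,\overline{\Delta RY}\,\overline{M} +
#'   n\,\mathrm{cov}(\Delta RY, M),}
#' where \eqn{\Delta RY_i = Y_{o,i}/M_i - RY_{e,i}} is the deviation from the
#' expected relative yield (default \eqn{1/n}), \eqn{M_i} the monoculture
#' yields, and the covariance uses the population (1/n) divisor. Extinct
#' species enter with observed yield 0 but keep their monoculture yield.
#' Scaled effects divide by \eqn{\Delta Y}; they are `NA` (flagged missing)
#' when \eqn{\Delta Y = 0}, and sum to 1 otherwise.
#'
#' @param observed Observed per-species yields in mixture (0 for extinct
#'   species).
#' @param monoculture Strictly positive monoculture yields.
#' @param expected_relative_yield Expected relative yield (default `1/n`).
#' @return List with `delta_y`, `complementarity`, `selection`,
#'   `scaled_complementarity`, `scaled_selection`.
#' @examples
#' biodiversity_effects(c(0.6, 0.6), c(1, 1), 0.5)  # delta_y 0.2, all C
#' @export
biodiversity_effects <- function(observed, monoculture,
                                 expected_relative_yield = NULL) {
  observed <- as.numeric(observed); monoculture <- as.numeric(monoculture)
  n <- length(observed)
  if (length(monoculture) != n) stop("length mismatch")
  if (any(monoculture <= 0)) stop("monoculture yields must be > 0")
  if (any(observed < 0)) stop("observed yields must be >= 0")
  if (is.null(expected_relative_yield)) expected_relative_yield <- 1 / n
  dRY <- observed / monoculture - expected_relative_yield
  covp <- mean(dRY * monoculture) - mean(dRY) * mean(monoculture)
  C <- n * mean(dRY) * mean(monoculture)
  S <- n * covp
  dY <- C + S
  if (dY == 0) {
    sc <- ss <- NA_real_
  } else {
    ss <- S / dY
    sc <- C / dY
  }
  list(delta_y = dY, complementarity = C, selection = S,
       scaled_complementarity = sc, scaled_selection = ss)
}
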