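# Stressor algebra: the n x s effect matrix E (entries eps in (0,1], the
# multiplicative effect of stressor l on the focal trait of species i), the
# optional trait-level interaction tensor eta, total stressor intensity (TSI),
# the power rescaling that fixes TSI, and the stressor coefficient of
# variation (SCV).

#' Sample a stressor effect matrix
#'
#' Entries are i.i.d. Beta(6.5, 0.25): effects lie strictly in (0, 1) with
#' mild stressors most common. Stressors hit species independently, so there
#' is no cotolerance structure.
#'
#' @param n Number of species (rows).
#' @param s Stressor richness (columns).
#' @param shape1,shape2 Beta parameters (defaults 6.5 and 0.25).
#' @return An n x s matrix of stressor effects.
#' @export
sample_effects <- function(n, s, shape1 = 6.5, shape2 = 0.25) {
  if (n < 1 || s < 1) stop("n and s must be >= 1")
  matrix(stats::rbeta(n * s, shape1, shape2), nrow = n, ncol = s)
}

#' Sample a trait-level stressor interaction tensor
#'
#' For each species, the coefficient \eqn{\eta_{i l_1 l_2}} making the pair
#' \eqn{(l_1, l_2)} of stressors deviate from log-additivity is standard
#' normal (mean zero: additive on average), symmetric in the stressor pair,
#' and zero on the diagonal (stressors do not interact with themselves).
#'
#' @param n Number of species.
#' @param s Stressor richness; `s < 2` yields an all-zero tensor.
#' @param sd Standard deviation of the interaction coefficients.
#' @return An n x s x s array.
#' @export
sample_interactions <- function(n, s, sd = 1) {
  if (n < 1 || s < 1) stop("n and s must be >= 1")
  eta <- array(0, dim = c(n, s, s))
  if (s >= 2) {
    for (l1 in seq_len(s - 1)) {
      for (l2 in (l1 + 1):s) {
        z <- stats::rnorm(n, 0, sd)
        eta[, l1, l2] <- z
        eta[, l2, l1] <- z
      }
    }
  }
  eta
}

.check_effects <- function(E) {
  E <- as.matrix(E)
  if (any(!is.finite(E)) || any(E <= 0) || any(E > 1))
    stop("stressor effects must lie in (0, 1]")
  E
}

#' Total stressor intensity
#'
#' \eqn{TSI = 1 - \prod_i \prod_l \epsilon_{il}}: one minus the product of
#' all stressor effects over all species and stressors, so strong overall
#' stress approaches 1. Computed in log space.
#'
#' @param E Effect matrix with entries in (0, 1].
#' @return TSI in `[0, 1)`.
#' @examples
#' total_stressor_intensity(matrix(c(0.8, 0.4, 0.5, 0.7), 2))  # 0.888
#' @export
total_stressor_intensity <- function(E) {
  E <- .check_effects(E)
  1 - exp(sum(log(E)))
}

#' Rescale an effect matrix to a fixed total stressor intensity
#'
#' Applies the power transform \eqn{\epsilon'_{il} = \epsilon_{il}^k} with
#' \eqn{k = \log(d) / \log(\prod_i \prod_l \epsilon_{il})}, so that the
#' product of all rescaled entries equals \eqn{d = 1 - TSI} exactly while the
#' stressors still affect species in a proportionally similar manner (rank
#' order preserved).
#'
#' @param E Effect matrix with entries in (0, 1], at least one entry < 1.
#' @param d Target product \eqn{d = 1 - TSI}, in (0, 1).
#' @return The rescaled matrix, with `prod(E') == d` to 1e-10.
#' @examples
#' E <- matrix(c(0.8, 0.4, 0.5, 0.7), 2)
#' round(rescale_to_fixed_tsi(E, 0.1), 3)  # 0.791 0.482 / 0.381 0.687
#' @export
rescale_to_fixed_tsi <- function(E, d) {
  E <- .check_effects(E)
  if (d <= 0 || d >= 1) stop("d must be in (0, 1)")
  lp <- sum(log(E))
  if (lp == 0) stop("degenerate input: all effects equal 1, TSI cannot be fixed")
  exp(log(E) * (log(d) / lp))
}

#' Apply stressors to focal traits
#'
#' Composes the multiplicative stressor effects on the baseline traits, in
#' log space (base 10 by default, matching the worked two-stressor example
#' where log(0.6) = -0.22):
#' \deqn{\log\theta_i = \log\theta_{i,0} + \sum_l \log\epsilon_{il} +
#'   \sum_{l_1}\sum_{l_2} \log(\epsilon_{il_1})\log(\epsilon_{il_2})
#'   \eta_{i l_1 l_2}.}
#' With `eta` absent or zero this is exactly
#' \eqn{\theta_i = \theta_{i,0} \prod_l \epsilon_{il}} (base-independent).
#' Positive \eqn{\eta} is antagonistic (weaker joint effect), negative
#' \eqn{\eta} synergistic. The double sum runs over both orders of each
#' stressor pair as written, so a symmetric pair's effective weight is
#' \eqn{2\eta \log\epsilon_1 \log\epsilon_2}; set `ordered_pairs = FALSE` to
#' count each unordered pair once.
#'
#' @param theta0 Baseline focal traits (> 0).
#' @param E Effect matrix (rows = species); 0 columns leaves traits unchanged.
#' @param eta Optional n x s x s interaction tensor (zero diagonal).
#' @param log_base Base of the logarithm in the interaction term (default 10).
#' @param ordered_pairs Count both (l1, l2) orders (default TRUE).
#' @return Stressed trait vector, strictly positive.
#' @examples
#' apply_stressors(1, matrix(c(0.6, 0.8), 1))  # 0.48
#' @export
apply_stressors <- function(theta0, E, eta = NULL, log_base = 10,
                            ordered_pairs = TRUE) {
  theta0 <- as.numeric(theta0)
  if (any(theta0 <= 0)) stop("baseline traits must be > 0")
  E <- as.matrix(E)
  if (ncol(E) == 0) return(theta0)
  E <- .check_effects(E)
  if (nrow(E) != length(theta0)) stop("E must have one row per species")
  logE <- log(E, base = log_base)
  shift <- rowSums(logE)
  if (!is.null(eta)) {
    dm <- dim(eta)
    if (length(dm) != 3 || dm[1] != nrow(E) || dm[2] != ncol(E) || dm[3] != ncol(E))
      stop("eta must be an n x s x s array")
    for (i in seq_len(nrow(E))) {
      li <- logE[i, ]
      inter <- sum(tcrossprod(li) * eta[i, , ])
      if (!ordered_pairs) inter <- inter / 2
      shift[i] <- shift[i] + inter
    }
  }
  theta0 * log_base^shift
}

#' Stressor coefficient of variation (SCV)
#'
#' The coefficient of variation of the combined stressor effects experienced
#' by each species, i.e. of the row products \eqn{\prod_l \epsilon_{il}} of
#' E. Measures how unequally the stressors hit species. Uses the sample
#' (n - 1) standard deviation; a single-species matrix returns 0 by
#' convention.
#'
#' @param E Effect matrix.
#' @return SCV >= 0.
#' @export
stressor_cv <- function(E) {
  E <- .check_effects(E)
  p <- exp(rowSums(log(E)))
  if (length(p) < 2) return(0)
  stats::sd(p) / mean(p)
}

#' Write / read a stressor field as plain text
#'
#' The effect matrix is written as a species x stressor CSV; the interaction
#' tensor (if any) as long-format `(species, l1, l2, eta)` triples alongside.
#' Round-trips are lossless to full double precision.
#'
#' @param E Effect matrix.
#' @param path CSV path for E.
#' @param eta Optional interaction tensor.
#' @param eta_path Path for the long-format eta file (default `path` with an
#'   `_eta.csv` suffix).
#' @return `write_stressor_field()` returns `path` invisibly;
#'   `read_stressor_field()` returns `list(E, eta)`.
#' @export
write_stressor_field <- function(E, path, eta = NULL, eta_path = NULL) {
  E <- .check_effects(E)
  df <- as.data.frame(apply(E, 2, function(x) sprintf("%.17g", x)))
  names(df) <- paste0("stressor_", seq_len(ncol(E)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(eta)) {
    if (is.null(eta_path)) eta_path <- sub("\\.csv$", "_eta.csv", path)
    idx <- which(eta != 0, arr.ind = TRUE)
    long <- data.frame(species = idx[, 1], l1 = idx[, 2], l2 = idx[, 3],
                       eta = sprintf("%.17g", eta[idx]))
    utils::write.csv(long, eta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_stressor_field
#' @param path CSV path to read.
#' @param s Stressor richness (needed to rebuild eta's dimensions when only
#'   some entries are non-zero); default inferred from E.
#' @export
read_stressor_field <- function(path, eta_path = NULL, s = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  E <- apply(as.matrix(df), c(1, 2), as.numeric)
  dimnames(E) <- NULL
  if (is.null(s)) s <- ncol(E)
  eta <- NULL
  if (is.null(eta_path)) {
    cand <- sub("\\.csv$", "_eta.csv", path)
    if (file.exists(cand)) eta_path <- cand
  }
  if (!is.null(eta_path) && file.exists(eta_path)) {
    long <- utils::read.csv(eta_path, colClasses = "character")
    eta <- array(0, dim = c(nrow(E), s, s))
    eta[cbind(as.integer(long$species), as.integer(long$l1),
              as.integer(long$l2))] <- as.numeric(long$eta)
  }
  list(E = E, eta = eta)
}
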