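# Closed-form analytics for a symmetric two-species Lotka-Volterra pair under
# multiplicative stress, and the stressor-effect-ratio (rho) experiment.
# rho = prod_l eps_2l / prod_l eps_1l is the ratio of the two species'
# combined stressor effects; deviations of rho from 1 drive competitive
# exclusion.

#' Two-species coexistence condition under stress
#'
#' With symmetric interspecific competition \eqn{\alpha_{12} = \alpha_{21} =
#' \alpha}, the stressed pair coexists iff
#' \deqn{\alpha/\alpha_{11} < \frac{\mu_2 \prod_l \epsilon_{2l}}
#'   {\mu_1 \prod_l \epsilon_{1l}} < \alpha_{22}/\alpha}
#' (strict inequalities).
#'
#' @param mu Length-2 vector of intrinsic growth rates.
#' @param alpha_matrix 2 x 2 interaction matrix with equal off-diagonals.
#' @param effect_products Length-2 vector of combined stressor effects
#'   \eqn{\prod_l \epsilon_{il}} (default `c(1, 1)`: unstressed).
#' @return `TRUE` iff the double inequality holds.
#' @export
coexistence_test <- function(mu, alpha_matrix, effect_products = c(1, 1)) {
  alpha_matrix <- as.matrix(alpha_matrix)
  if (!all(dim(alpha_matrix) == c(2, 2))) stop("alpha_matrix must be 2 x 2")
  if (alpha_matrix[1, 2] != alpha_matrix[2, 1])
    stop("requires a symmetric interaction matrix (alpha12 = alpha21)")
  if (any(mu <= 0) || any(effect_products <= 0) || any(diag(alpha_matrix) <= 0))
    stop("all inputs must be positive")
  a <- alpha_matrix[1, 2]
  mid <- (mu[2] * effect_products[2]) / (mu[1] * effect_products[1])
  if (a == 0) return(TRUE)
  (a / alpha_matrix[1, 1]) < mid && mid < (alpha_matrix[2, 2] / a)
}

#' Stressed-to-pristine yield ratio for a symmetric pair
#'
#' With \eqn{\alpha_{11} = \alpha_{22} = 1} and \eqn{\mu_1 = \mu_2 = 1}, the
#' total yield under stress divided by the pristine total yield is simply the
#' mean of the two species' combined stressor effects, \eqn{(e_1 + e_2)/2},
#' independent of \eqn{\alpha} — valid while both species coexist.
#'
#' @param e1,e2 Combined stressor effects (row products) in (0, 1].
#' @return Yield ratio \eqn{Y_o / Y_{o,p}}.
#' @export
yield_ratio <- function(e1, e2) {
  if (any(c(e1, e2) <= 0) || any(c(e1, e2) > 1))
    stop("effect products must lie in (0, 1]")
  (e1 + e2) / 2
}

#' Scaled selection effect for a symmetric pair
#'
#' Closed form \eqn{S/\Delta Y = \alpha(1/\rho - 2 + \rho)/(\alpha - 1)^2};
#' non-negative for \eqn{\alpha \in (0, 1)} since \eqn{1/\rho - 2 + \rho \ge
#' 0}, zero at \eqn{\rho = 1}, and symmetric under \eqn{\rho \to 1/\rho}.
#'
#' @param rho Stressor effect ratio \eqn{\prod_l\epsilon_{2l} /
#'   \prod_l\epsilon_{1l}} (> 0).
#' @param alpha Symmetric interspecific competition coefficient, != 1.
#' @return \eqn{S/\Delta Y}.
#' @export
scaled_selection <- function(rho, alpha) {
  if (any(rho <= 0)) stop("rho must be > 0")
  if (any(alpha == 1)) stop("alpha = 1 is degenerate")
  alpha * (1 / rho - 2 + rho) / (alpha - 1)^2
}

#' Scaled complementarity effect for a symmetric pair
#'
#' The complement \eqn{C/\Delta Y = 1 - S/\Delta Y} (the two scaled effects
#' sum to one by construction); equals 1 at \eqn{\rho = 1} and decreases as
#' \eqn{\rho} deviates from 1.
#'
#' @inheritParams scaled_selection
#' @return \eqn{C/\Delta Y}.
#' @export
scaled_complementarity <- function(rho, alpha) {
  1 - scaled_selection(rho, alpha)
}

#' Distribution of the stressor effect ratio across stressor richness
#'
#' For each stressor richness `s`, samples `iterations` two-species effect
#' matrices (Beta(6.5, 0.25) entries), optionally rescales each to a fixed
#' total stressor intensity, and summarises \eqn{\log\rho}. With TSI unfixed,
#' \eqn{var(\log\rho) = 2s\,var(\log\epsilon)} grows with richness; with TSI
#' fixed, it shrinks.
#'
#' @param s_values Stressor richness levels (default `c(1, 5, 10, 20)`).
#' @param tsi_mode `"unfixed"` or `"fixed"`.
#' @param d Target product \eqn{d = 1 - TSI} used when fixed (default 0.1,
#'   i.e. TSI = 90\%).
#' @param iterations Monte-Carlo iterations per level (>= 100, default 1000).
#' @param seed Optional seed.
#' @return A `rho_experiment` data frame with columns `s`, `tsi_mode`,
#'   `mean`, `var`, `q10`, `q90`; the raw `log_rho` draws are kept in the
#'   `"samples"` attribute for plotting.
#' @export
rho_experiment <- function(s_values = c(1, 5, 10, 20),
                           tsi_mode = c("unfixed", "fixed"), d = 0.1,
                           iterations = 1000, seed = NULL) {
  tsi_mode <- match.arg(tsi_mode)
  if (iterations < 100) stop("iterations must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  samples <- lapply(s_values, function(s) {
    vapply(seq_len(iterations), function(it) {
      E <- sample_effects(2, s)
      if (tsi_mode == "fixed") E <- rescale_to_fixed_tsi(E, d)
      sum(log(E[2, ])) - sum(log(E[1, ]))
    }, numeric(1))
  })
  out <- data.frame(
    s = s_values, tsi_mode = tsi_mode,
    mean = vapply(samples, mean, numeric(1)),
    var = vapply(samples, stats::var, numeric(1)),
    q10 = vapply(samples, stats::quantile, numeric(1), probs = 0.1),
    q90 = vapply(samples, stats::quantile, numeric(1), probs = 0.9))
  attr(out, "samples") <- samples
  class(out) <- c("rho_experiment", "data.frame")
  out
}

#' @export
plot.rho_experiment <- function(x, ...) {
  samples <- attr(x, "samples")
  graphics::boxplot(samples, names = x$s, xlab = "stressor richness s",
                    ylab = expression(log(rho)),
                    main = sprintf("TSI %s", x$tsi_mode[1]), ...)
  graphics::points(seq_along(samples), x$mean, pch = 19)
  invisible(x)
}
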