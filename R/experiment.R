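# Factorial experiment pipeline: enumerate the design (total stressor
# intensity x stressor richness x model x initial species richness x
# trait-level stressor interactions), run replicates end-to-end (generate a
# coexisting community, stress it, re-solve, prune, measure), and aggregate
# to means with 10th-90th percentile bands.

.tsi_levels_default <- c("10%", "50%", "90%", "unfixed")

# d = 1 - TSI for a fixed level, NA for "unfixed"
.tsi_d <- function(level) {
  if (identical(level, "unfixed")) return(NA_real_)
  pct <- suppressWarnings(as.numeric(sub("%", "", level)))
  if (is.na(pct) || pct <= 0 || pct >= 100)
    stop("TSI level must be a percentage in (0, 100) or 'unfixed': ", level)
  1 - pct / 100
}

#' Enumerate the factorial design
#'
#' Builds the Cartesian product of the factor levels, excluding Stomp cells
#' with more than four species (light-spectrum differentiation cannot
#' support them). The full default grid — 4 TSI levels x 20 stressor
#' richness levels x (Lotka-Volterra and MacArthur at 3 species richness
#' levels + Stomp at one) x 2 interaction settings — has 1120 cells; at the
#' default 1000 replicates that is 1,120,000 requested simulations. Cell
#' ordering is deterministic and per-cell seeds derive from `base_seed`.
#'
#' @param tsi_levels Character TSI levels, percentages or `"unfixed"`.
#' @param stressor_richness Integer vector of stressor counts (default 1:20).
#' @param models Subset of `c("lotka_volterra", "macarthur", "stomp")`.
#' @param species_richness Initial species richness levels (default 4, 8, 16).
#' @param interactions Logical levels for trait-level stressor interactions.
#' @param replicates Requested replicates per cell (default 1000).
#' @param base_seed Integer; per-cell seeds derive from it.
#' @param strict Error if the Stomp exclusion empties a requested model
#'   (default `FALSE`: silently drop excluded cells).
#' @param config Optional named list (e.g. from [read_design_config()]) whose
#'   entries override the matching arguments.
#' @return A `design` data frame, one row per cell, with `cell_id`,
#'   `cell_seed` and `replicates` columns.
#' @export
build_design <- function(tsi_levels = .tsi_levels_default,
                         stressor_richness = 1:20,
                         models = c("lotka_volterra", "macarthur", "stomp"),
                         species_richness = c(4, 8, 16),
                         interactions = c(FALSE, TRUE),
                         replicates = 1000, base_seed = 1L,
                         strict = FALSE, config = NULL) {
  if (!is.null(config)) {
    for (nm in names(config)) assign(nm, config[[nm]])
  }
  if (!length(tsi_levels) || !length(stressor_richness) || !length(models) ||
      !length(species_richness) || !length(interactions))
    stop("empty factor level list")
  vapply(tsi_levels, .tsi_d, numeric(1))  # validate
  cells <- expand.grid(interactions = as.logical(interactions),
                       n_species = as.integer(species_richness),
                       model = as.character(models),
                       stressor_richness = as.integer(stressor_richness),
                       tsi = as.character(tsi_levels),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  drop <- cells$model == "stomp" & cells$n_species > 4
  if (strict && any(drop) && all(drop[cells$model == "stomp"]))
    stop("requested Stomp cells all exceed 4 species")
  cells <- cells[!drop, , drop = FALSE]
  if (!nrow(cells)) stop("design is empty after the Stomp exclusion")
  cells <- cells[, c("tsi", "stressor_richness", "model", "n_species",
                     "interactions")]
  rownames(cells) <- NULL
  cells$replicates <- as.integer(replicates)
  cells$cell_id <- seq_len(nrow(cells))
  cells$cell_seed <- as.integer((as.numeric(base_seed) +
                                   cells$cell_id * 2654435) %% 2147483647)
  class(cells) <- c("stressor_design", "data.frame")
  cells
}

#' Read an experiment configuration file
#'
#' YAML with any subset of the [build_design()] arguments, e.g.
#' `models: [lotka_volterra]`, `tsi_levels: ["90%", unfixed]`.
#'
#' @param path YAML file path.
#' @return Named list, usable as `build_design(config = ...)`.
#' @examples
#' cfg <- read_design_config(system.file("extdata", "example-design.yml",
#'                                       package = "stresscomm"))
#' nrow(build_design(config = cfg))
#' @export
read_design_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  yaml::read_yaml(path)
}

# One end-to-end replicate; returns a one-row data.frame or NULL on failure.
.run_replicate <- function(cell, rep_seed, threshold_fraction,
                           community_attempts) {
  spec <- community_spec(cell$model, cell$n_species)
  batch <- tryCatch(
    generate_batch(spec, 1L, base_seed = rep_seed,
                   max_attempts = community_attempts,
                   threshold_fraction = threshold_fraction),
    error = function(e) NULL)
  if (is.null(batch)) return(NULL)
  com <- batch$communities[[1]]
  params <- com$params
  n <- params$n
  s <- cell$stressor_richness
  theta0 <- focal_traits(params)
  set.seed((rep_seed + 611953) %% 2147483647)
  E <- sample_effects(n, s)
  eta <- if (cell$interactions) sample_interactions(n, s) else NULL
  d <- .tsi_d(cell$tsi)
  if (!is.na(d)) E <- rescale_to_fixed_tsi(E, d)
  theta <- apply_stressors(theta0, E, eta)
  stressed <- set_focal_traits(params, theta)
  rep_s <- prune_extinctions(stressed, threshold_fraction,
                             carrying = com$carrying, start = com$state)
  if (!rep_s$converged) return(NULL)
  Ns <- rep_s$state$abundances
  Nu <- com$state$abundances
  mono <- carrying_capacity(stressed)  # stressed monoculture equilibria
  inc <- mono > 0
  be <- if (sum(inc) >= 2) {
    biodiversity_effects(Ns[inc], mono[inc], 1 / sum(inc))
  } else {
    list(delta_y = NA_real_, complementarity = NA_real_, selection = NA_real_,
         scaled_complementarity = NA_real_, scaled_selection = NA_real_)
  }
  pers <- persistence(Ns, n)
  data.frame(
    cell_id = cell$cell_id, replicate = NA_integer_, seed = rep_seed,
    model = cell$model, n_species = n, stressor_richness = s,
    tsi = cell$tsi, interactions = cell$interactions,
    community_attempts = batch$attempts,
    tsi_realized = total_stressor_intensity(E),
    scv = stressor_cv(E),
    function_ratio = ecosystem_function(Ns, Nu),
    persistence_count = pers$count,
    persistence_fraction = pers$fraction,
    bray_curtis = bray_curtis_similarity(Ns, Nu),
    delta_y = be$delta_y,
    complementarity = be$complementarity,
    selection = be$selection,
    scaled_complementarity = be$scaled_complementarity,
    scaled_selection = be$scaled_selection)
}

#' Run all replicates of one design cell
#'
#' Each replicate: generate a coexisting community, solve its unstressed
#' equilibrium, sample the effect matrix E (and the interaction tensor when
#' the cell includes trait-level interactions), rescale E when the cell
#' fixes TSI, apply the stressors to the focal traits, re-solve with
#' extinction pruning, and record all outcome metrics. Replicates whose
#' community generation or stressed solve fails are replaced from a fresh
#' derived seed (up to `max_retries` each); replacements are counted in the
#' `regenerated` column.
#'
#' @param cell One row of a [build_design()] data frame (or an equivalent
#'   list with fields `tsi`, `stressor_richness`, `model`, `n_species`,
#'   `interactions`, `cell_id`, `cell_seed`).
#' @param replicates Override of the cell's replicate count.
#' @param threshold_fraction Persistence/extinction threshold (default 0.01).
#' @param community_attempts Sampling attempts allowed per community
#'   (default 500).
#' @param max_retries Replacement attempts per failed replicate (default 5).
#' @return Data frame of metric records, one row per completed replicate.
#' @export
run_cell <- function(cell, replicates = NULL, threshold_fraction = 0.01,
                     community_attempts = 500L, max_retries = 5L) {
  cell <- as.list(cell)
  if (is.null(replicates)) replicates <- cell$replicates
  if (is.null(cell$cell_id)) cell$cell_id <- 0L
  if (is.null(cell$cell_seed)) cell$cell_seed <- 1L
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    row <- NULL
    for (try_i in 0:max_retries) {
      rep_seed <- as.integer((as.numeric(cell$cell_seed) + r * 1009 +
                                try_i * 7368787) %% 2147483647)
      row <- .run_replicate(cell, rep_seed, threshold_fraction,
                            community_attempts)
      if (!is.null(row)) {
        row$replicate <- r
        row$regenerated <- try_i
        break
      }
    }
    if (is.null(row))
      stop(sprintf("cell %d replicate %d failed after %d replacements",
                   cell$cell_id, r, max_retries))
    rows[[r]] <- row
  }
  do.call(rbind, rows)
}

#' Run several design cells
#'
#' @param design A [build_design()] data frame (or subset of rows).
#' @param ... Passed to [run_cell()].
#' @param progress Emit a message per cell (default `FALSE`).
#' @return Row-bound metric records for all cells.
#' @export
run_design <- function(design, ..., progress = FALSE) {
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    if (progress)
      message(sprintf("cell %d/%d: %s n=%d s=%d tsi=%s", i, nrow(design),
                      design$model[i], design$n_species[i],
                      design$stressor_richness[i], design$tsi[i]))
    out[[i]] <- run_cell(design[i, ], ...)
  }
  do.call(rbind, out)
}

.metric_cols <- c("tsi_realized", "scv", "function_ratio",
                  "persistence_count", "persistence_fraction", "bray_curtis",
                  "delta_y", "complementarity", "selection",
                  "scaled_complementarity", "scaled_selection")

#' Aggregate metric records per design cell
#'
#' Mean and empirical 10th/90th percentiles (linear interpolation between
#' order statistics) of each metric within each cell; missing values (e.g.
#' undefined scaled partition terms) are excluded, with counts reported.
#'
#' @param records Metric records from [run_cell()]/[run_design()].
#' @param metrics Metric columns to summarise (default: all).
#' @return A long-format `stressor_aggregate` data frame: cell identifiers +
#'   `metric`, `mean`, `q10`, `q90`, `n`, `n_missing`.
#' @export
aggregate_metrics <- function(records, metrics = .metric_cols) {
  metrics <- intersect(metrics, names(records))
  idcols <- c("cell_id", "model", "n_species", "stressor_richness", "tsi",
              "interactions")
  idcols <- intersect(idcols, names(records))
  key <- do.call(paste, c(records[idcols], sep = "\r"))
  out <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    head_row <- records[ix[1], idcols, drop = FALSE]
    do.call(rbind, lapply(metrics, function(mc) {
      v <- records[[mc]][ix]
      miss <- sum(is.na(v))
      v <- v[!is.na(v)]
      cbind(head_row, data.frame(
        metric = mc,
        mean = if (length(v)) mean(v) else NA_real_,
        q10 = if (length(v)) unname(stats::quantile(v, 0.1, type = 7)) else NA_real_,
        q90 = if (length(v)) unname(stats::quantile(v, 0.9, type = 7)) else NA_real_,
        n = length(v), n_missing = miss))
    }))
  })
  out <- do.call(rbind, out)
  ord <- order(out$cell_id, match(out$metric, metrics))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stressor_aggregate", "data.frame")
  out
}

#' @export
plot.stressor_aggregate <- function(x, metric = "function_ratio", ...) {
  d <- x[x$metric == metric, , drop = FALSE]
  if (!nrow(d)) stop("metric not present: ", metric)
  tsis <- unique(d$tsi)
  cols <- seq_along(tsis)
  graphics::plot(NA, xlim = range(d$stressor_richness),
                 ylim = range(c(d$q10, d$q90), na.rm = TRUE),
                 xlab = "stressor richness s", ylab = metric, ...)
  for (i in seq_along(tsis)) {
    di <- d[d$tsi == tsis[i], ]
    di <- di[order(di$stressor_richness), ]
    graphics::arrows(di$stressor_richness, di$q10, di$stressor_richness,
                     di$q90, angle = 90, code = 3, length = 0.03,
                     col = cols[i])
    graphics::lines(di$stressor_richness, di$mean, type = "b", pch = 19,
                    col = cols[i])
  }
  graphics::legend("topright", legend = paste("TSI", tsis), col = cols,
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
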