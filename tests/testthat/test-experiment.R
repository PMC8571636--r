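test_that("the full factorial design enumerates 1120 cells", {
  d <- build_design()
  expect_equal(nrow(d), 1120)
  expect_equal(sum(d$replicates), 1120000)
  # no Stomp cells above four species
  expect_false(any(d$model == "stomp" & d$n_species > 4))
  # deterministic ordering and seeds
  d2 <- build_design()
  expect_identical(d, d2)
})

test_that("design subsets and exclusions follow the factor arithmetic", {
  d <- build_design(models = "lotka_volterra", species_richness = 4)
  expect_equal(nrow(d), 4 * 20 * 1 * 1 * 2)  # 160
  # Stomp at 8 species is excluded entirely
  expect_error(build_design(models = "stomp", species_richness = 8,
                            strict = TRUE), "Stomp")
  expect_error(suppressWarnings(build_design(models = "stomp",
                                             species_richness = 8)), "empty")
  expect_error(build_design(tsi_levels = character(0)), "empty factor")
  expect_error(build_design(tsi_levels = "110%"), "percentage")
})

test_that("design configuration can come from a YAML file", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yml")
  writeLines(c("models: [lotka_volterra]",
               "species_richness: [4]",
               "stressor_richness: [1, 5]",
               "tsi_levels: ['90%', unfixed]",
               "replicates: 10"), path)
  d <- build_design(config = read_design_config(path))
  expect_equal(nrow(d), 2 * 2 * 1 * 1 * 2)
  expect_equal(unique(d$replicates), 10L)
  # packaged example profile
  cfg <- read_design_config(system.file("extdata", "example-design.yml",
                                        package = "stresscomm"))
  dp <- build_design(config = cfg)
  expect_equal(nrow(dp), 2 * 5 * 1 * 1 * 1)
  expect_equal(unique(dp$replicates), 200L)
})

test_that("cells rerun identically and honour the fixed-TSI contract", {
  d <- build_design(models = "lotka_volterra", species_richness = 4,
                    stressor_richness = 3, tsi_levels = "50%",
                    interactions = FALSE, replicates = 8, base_seed = 7)
  r1 <- run_cell(d[1, ])
  r2 <- run_cell(d[1, ])
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 8)
  # every replicate's realised TSI equals the 50% target
  expect_equal(r1$tsi_realized, rep(0.5, 8), tolerance = 1e-10)
  expect_true(all(r1$persistence_fraction >= 0 & r1$persistence_fraction <= 1))
  expect_true(all(r1$bray_curtis >= 0 & r1$bray_curtis <= 1))
})

test_that("with a single stressor, the interaction factor is inert", {
  # s = 1 admits no stressor pairs, so eta is identically zero and the
  # absent/present settings must give identical replicates (same seeds)
  base <- build_design(models = "lotka_volterra", species_richness = 4,
                       stressor_richness = 1, tsi_levels = "unfixed",
                       interactions = FALSE, replicates = 5, base_seed = 3)
  pres <- build_design(models = "lotka_volterra", species_richness = 4,
                       stressor_richness = 1, tsi_levels = "unfixed",
                       interactions = TRUE, replicates = 5, base_seed = 3)
  ra <- run_cell(base[1, ]); rp <- run_cell(pres[1, ])
  drop_cols <- c("interactions", "cell_id")
  expect_identical(ra[setdiff(names(ra), drop_cols)],
                   rp[setdiff(names(rp), drop_cols)])
})

test_that("aggregation reports means and interpolated percentile bands", {
  d <- build_design(models = "lotka_volterra", species_richness = 4,
                    stressor_richness = c(2, 6), tsi_levels = "unfixed",
                    interactions = FALSE, replicates = 7, base_seed = 11)
  rec <- run_design(d)
  agg <- aggregate_metrics(rec)
  expect_s3_class(agg, "stressor_aggregate")
  # independent sort-based order-statistic oracle (linear interpolation)
  manual_q <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p
    lo <- floor(h)
    v[lo + 1] + (h - lo) * (v[min(lo + 2, length(v))] - v[lo + 1])
  }
  for (mc in c("function_ratio", "bray_curtis", "scv")) {
    v <- rec[[mc]][rec$stressor_richness == 2]
    a <- agg[agg$metric == mc & agg$stressor_richness == 2, ]
    expect_equal(a$mean, mean(v))
    expect_equal(a$q10, manual_q(v, 0.1), tolerance = 1e-12)
    expect_equal(a$q90, manual_q(v, 0.9), tolerance = 1e-12)
    expect_equal(a$n, 7)
  }
  # single replicate: mean and both percentiles collapse to the value
  one <- aggregate_metrics(rec[rec$replicate == 1 &
                                 rec$stressor_richness == 2, ])
  fr <- one[one$metric == "function_ratio", ]
  expect_equal(fr$mean, fr$q10)
  expect_equal(fr$mean, fr$q90)
  # constant metric: zero-width band
  tr <- rec; tr$scv <- 1
  cg <- aggregate_metrics(tr)
  expect_true(all(cg[cg$metric == "scv", "q10"] == 1 &
                    cg[cg$metric == "scv", "q90"] == 1))
  # missing scaled terms are excluded with counts
  tr2 <- rec
  tr2$scaled_selection[1:2] <- NA
  a2 <- aggregate_metrics(tr2)
  ss <- a2[a2$metric == "scaled_selection", ]
  expect_equal(sum(ss$n_missing), 2)
})

test_that("MacArthur and Stomp cells run end-to-end", {
  dm <- build_design(models = "macarthur", species_richness = 4,
                     stressor_richness = 5, tsi_levels = "90%",
                     interactions = TRUE, replicates = 4, base_seed = 13)
  rm_ <- run_cell(dm[1, ])
  expect_equal(nrow(rm_), 4)
  expect_equal(rm_$tsi_realized, rep(0.9, 4), tolerance = 1e-10)
  ds <- build_design(models = "stomp", species_richness = 4,
                     stressor_richness = 2, tsi_levels = "unfixed",
                     interactions = FALSE, replicates = 2, base_seed = 17)
  rs <- run_cell(ds[1, ])
  expect_equal(nrow(rs), 2)
  expect_true(all(rs$function_ratio >= 0))
  expect_true(all(rs$persistence_count <= 4))
})
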