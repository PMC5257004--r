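test_that("sweep tables have the induction-design shape", {
  cfg <- generator_config(cells_per_condition = 100)
  tab <- generate_sweep(fix_micF(), cfg)
  expect_s3_class(tab, "snapshot_table")
  expect_equal(nrow(tab), 1200)                 # 12 conditions x 100 cells
  expect_length(unique(tab$condition_id), 12)
  expect_true(all(tab$A >= 0 & tab$B >= 0))
  expect_true(all(table(tab$condition_id) == 100))
})

test_that("zero-noise sweeps are point masses exactly on the Hill curve", {
  cfg <- quiet_cfg(cells_per_condition = 20)
  p <- fix_micF()
  tab <- generate_sweep(p, cfg)
  for (cond in unique(tab$condition_id)) {
    d <- tab[tab$condition_id == cond, ]
    expect_equal(length(unique(d$A)), 1)
    expect_equal(length(unique(d$B)), 1)
    expect_equal(d$B[1], hill_mean(d$A[1], p))
  }
  expect_equal(unname(sort(unique(tab$A))),
               unname(sort(cfg$induction_levels)))
})

test_that("generated reporter means agree with an independent Monte-Carlo oracle", {
  p <- promoter_spec("toy", V = 1, b = 0.1, Kd = 50, n = 2,
                     klass = "amplifying")
  cfg <- generator_config(induction_levels = c(one = 60),
                          cells_per_condition = 1e4,
                          extrinsic_cv = 0.35, reporter_intrinsic_cv = 0.15,
                          measurement_floor_sd = 0, seed = 4)
  tab <- generate_sweep(p, cfg)
  set.seed(991)
  orc <- oracle_reporter_mean(p, 60, 0.35, 0.15)
  se_gen <- sd(tab$B) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$B) - orc$mean),
            3 * sqrt(se_gen^2 + orc$se^2))
})

test_that("generation is byte-identical under its seed", {
  cfg <- generator_config(cells_per_condition = 50, seed = 77)
  expect_identical(generate_sweep(fix_micF(), cfg),
                   generate_sweep(fix_micF(), cfg))
  expect_identical(generate_background(fix_micF(), "wildtype", cfg),
                   generate_background(fix_micF(), "wildtype", cfg))
  # and different under a different seed
  expect_false(identical(generate_sweep(fix_micF(), cfg),
                         generate_sweep(fix_micF(), cfg, seed = 78)))
})

test_that("conditions with higher activator means give stochastically larger A", {
  cfg <- generator_config(cells_per_condition = 400, seed = 9)
  tab <- generate_sweep(fix_micF(), cfg)
  med <- tapply(tab$A, tab$condition_id, median)
  med <- med[names(cfg$induction_levels)]       # design order = rising means
  expect_true(all(diff(med) > 0))
})

test_that("background strains separate and their latent activator matches the configured quantiles", {
  p <- fix_micF()
  cfg <- generator_config(cells_per_condition = 1e4, seed = 21)
  wt <- generate_background(p, "wildtype", cfg)
  ma <- generate_background(p, "marAplus", cfg)
  expect_gt(median(ma$B), median(wt$B))         # distinctly different levels
  # latent-truth A percentiles match the log-normal quantile function to 2%
  sdlog <- sqrt(log(1 + cfg$background_cv^2))
  q_theory <- qlnorm(seq(0.1, 0.9, by = 0.1),
                     log(cfg$wildtype_mean) - sdlog^2 / 2, sdlog)
  q_emp <- quantile(wt$A, seq(0.1, 0.9, by = 0.1), names = FALSE)
  expect_true(all(abs(q_emp / q_theory - 1) < 0.02))
  # zero-noise background collapses to the Hill value of the mean
  wt0 <- generate_background(p, "wildtype", quiet_cfg(background_cv = 0))
  expect_equal(unique(wt0$B), hill_mean(cfg$wildtype_mean, p))
})

test_that("background masking hides the activator but keeps the latent truth", {
  cfg <- generator_config(cells_per_condition = 30, seed = 3)
  bg <- generate_background(fix_micF(), "wildtype", cfg, mask_activator = TRUE)
  expect_true(all(is.na(bg$A)))
  expect_length(attr(bg, "A_latent"), 30)
  expect_true(all(attr(bg, "A_latent") > 0))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(induction_levels = c(10, NA)), "induction")
  expect_error(generator_config(extrinsic_cv = -0.1), "extrinsic_cv")
  expect_error(generator_config(cells_per_condition = 0), "cells_per_condition")
  expect_error(generator_config(wildtype_mean = 700, marAplus_mean = 600),
               "wildtype_mean")
  expect_error(generator_config(measurement_floor_sd = Inf),
               "measurement_floor_sd")
})
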