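test_that("closed-form transmitted noise obeys its limits", {
  # b = 0: eta = n/(1 + (A/Kd)^n); n at the origin, n/2 at Kd, 0 saturated
  for (case in list(c(Kd = 50, n = 2), c(Kd = 700, n = 1.2))) {
    p <- hill_params(V = 1000, b = 0, Kd = case[["Kd"]], n = case[["n"]])
    expect_equal(transmitted_noise_analytic(case[["Kd"]], p), case[["n"]] / 2)
    expect_equal(transmitted_noise_analytic(case[["Kd"]] * 1e-6, p),
                 case[["n"]], tolerance = 1e-5)
    expect_lt(transmitted_noise_analytic(case[["Kd"]] * 1e4, p), 1e-3)
    # strictly decreasing in A when basal expression is zero
    A <- exp(seq(log(1), log(1e5), length.out = 40))
    expect_true(all(diff(transmitted_noise_analytic(A, p)) < 0))
  }
})

test_that("general-case analytic noise matches the log-derivative numerically", {
  p <- hill_params(V = 2500, b = 85, Kd = 120, n = 1.9)
  for (A in c(20, 120, 600, 4000)) {
    h <- 1e-4   # balances truncation against roundoff in the log difference
    num <- (log(hill_mean(A * exp(h), p)) -
              log(hill_mean(A * exp(-h), p))) / (2 * h)
    expect_equal(transmitted_noise_analytic(A, p), num, tolerance = 1e-8)
  }
  # with basal expression the curve is unimodal with an interior maximum
  A <- exp(seq(log(1), log(1e5), length.out = 300))
  eta <- transmitted_noise_analytic(A, p)
  i <- which.max(eta)
  expect_true(i > 1 && i < length(A))
})

test_that("empirical transmitted noise is the CV ratio minus the floor", {
  tab <- generate_sweep(fix_micF(), generator_config(seed = 31))
  bc <- bin_cells(tab)
  nc0 <- transmitted_noise_empirical(bc, S = 0)
  nc2 <- transmitted_noise_empirical(bc, S = 0.25)
  expect_equal(nc0$eta - 0.25, nc2$eta)
  # hand-check one bin
  b1 <- bc[bc$bin == nc0$bin[1], ]
  expect_equal(nc0$eta[1], (b1$sd_B / b1$mean_B) / (b1$sd_A / b1$mean_A))
})

test_that("bins with undefined input CV are excluded, and a deterministic linear map has zero bootstrap spread", {
  # two point-mass conditions per bin: sd_A = 0 within a condition
  cfg <- quiet_cfg(induction_levels = c(a = 50), cells_per_condition = 60)
  tab <- generate_sweep(fix_micF(), cfg)
  bc <- bin_cells(tab, n_bins = 3, min_count = 10)
  nc <- transmitted_noise_empirical(bc)
  expect_equal(nrow(nc), 0)                      # the single bin is undefined
  expect_true(length(attr(nc, "excluded_bins")) >= 1)
  # linear response: eta is exactly 1 in every subsample, so spread is 0
  set.seed(40)
  A <- rlnorm(600, log(50), 0.5)
  lin <- structure(data.frame(cell_id = paste0("c", seq_along(A)),
                              condition_id = "x", strain = "sweep",
                              promoter = "lin", A = A, B = 3 * A),
                   class = c("snapshot_table", "data.frame"))
  esd <- bootstrap_eta(lin, n_bins = 5, min_count = 20, n_boot = 30, seed = 2)
  expect_true(all(esd[!is.na(esd)] < 1e-12))
})

test_that("bootstrap spread shrinks roughly as one over root cell count", {
  p <- fix_micF()
  mk <- function(k, seed) generate_sweep(
    p, generator_config(cells_per_condition = k, seed = seed))
  small <- mk(100, 51); big <- mk(400, 52)
  edges_s <- attr(bin_cells(small, 8, 25), "edges")
  sd_small <- median(bootstrap_eta(small, 8, 25, seed = 1, edges = edges_s),
                     na.rm = TRUE)
  sd_big <- median(bootstrap_eta(big, 8, 25, seed = 1, edges = edges_s),
                   na.rm = TRUE)
  ratio <- sd_small / sd_big                     # expect about sqrt(4) = 2
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("transmitted noise is invariant to rescaling either channel", {
  tab <- generate_sweep(fix_micF(), generator_config(seed = 61))
  nc <- transmitted_noise_empirical(bin_cells(tab))
  tabB <- tab; tabB$B <- tab$B * 7.3              # CV is scale-free
  expect_equal(transmitted_noise_empirical(bin_cells(tabB))$eta, nc$eta)
  tabA <- tab; tabA$A <- tab$A * 4.2              # abscissa rescales with A
  ncA <- transmitted_noise_empirical(bin_cells(tabA))
  expect_equal(ncA$eta, nc$eta)
  expect_equal(ncA$mean_A, nc$mean_A * 4.2)
})

test_that("per-condition transmitted noise is available for labelled data", {
  tab <- generate_sweep(fix_micF(), generator_config(seed = 71))
  pc <- transmitted_noise_by_condition(tab)
  expect_equal(nrow(pc), 12)
  expect_true(all(diff(pc$mean_A) > 0))
  expect_true(all(is.finite(pc$eta)))
})

test_that("the control-table floor estimator returns the control CV", {
  cfg <- generator_config(cells_per_condition = 500, seed = 81)
  ctrl <- generate_sweep(fix_control(), cfg)
  expect_equal(noise_floor_from_control(ctrl),
               sd(ctrl$B) / mean(ctrl$B))
})
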