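test_that("exact output matches return exactly the matched cells' activator", {
  sweep <- generate_sweep(fix_micF(), generator_config(seed = 17))
  # query with the sweep's own B values: nearest neighbour is the cell itself
  got <- hillnoise:::nearest_neighbour_A(sweep$B[1:50], sweep)
  expect_equal(got, sweep$A[1:50])
})

test_that("nearest-neighbour estimation recovers a low-noise latent input", {
  p <- fix_micF()
  cfg <- generator_config(cells_per_condition = 300,
                          reporter_intrinsic_cv = 0.02,
                          measurement_floor_sd = 0, seed = 18)
  sweep <- generate_sweep(p, cfg, seed = 7)
  bg <- generate_background(p, "wildtype", cfg, mask_activator = TRUE,
                            seed = 11)
  est <- estimate_input_distribution(bg, list(micF = sweep),
                                     label = "wildtype")
  truth <- quantile(attr(bg, "A_latent"), c(0.05, 0.95), names = FALSE)
  expect_lt(abs(est$A_min / truth[1] - 1), 0.1)
  expect_lt(abs(est$A_max / truth[2] - 1), 0.1)
})

test_that("excluded promoters are skipped and non-overlap warns", {
  sweep <- generate_sweep(fix_micF(), generator_config(seed = 19))
  bg <- generate_background(fix_micF(), "wildtype", generator_config(seed = 2),
                            mask_activator = TRUE)
  expect_error(estimate_input_distribution(bg, list(marRAB = sweep),
                                           exclude = "marRAB"), "excluded")
  far <- sweep; far$B <- far$B + 1e7             # disjoint output ranges
  expect_warning(
    est <- estimate_input_distribution(bg, list(ok = sweep, far = far),
                                       exclude = ""),
    "does not overlap")
  expect_s3_class(est, "input_distribution")
})

test_that("capacity integral behaves at its degenerate and nested limits", {
  mod <- channel_model(fix_micF(), A0 = 1)
  expect_error(capacity_small_noise(mod, 60, 50), "A_min")
  empty <- capacity_small_noise(mod, 50, 50)
  expect_identical(empty$capacity_rel, -Inf)
  expect_match(empty$note, "empty")
  # widening the bounds never decreases Z
  zs <- sapply(list(c(30, 60), c(20, 100), c(10, 500), c(5, 2000)),
               function(b) capacity_small_noise(mod, b[1], b[2])$Z)
  expect_true(all(diff(zs) > 0))
  # a flat (control) response transmits nothing
  flat <- capacity_small_noise(channel_model(fix_control(), 1), 10, 100)
  expect_identical(flat$capacity_rel, -Inf)
  expect_match(flat$note, "flat")
})

test_that("capacity maps are invariant to grid ordering", {
  tmpl <- hill_params(V = 2000, b = 50, Kd = 100, n = 2)
  Kd <- c(50, 150, 450); n <- c(1, 2, 3)
  m1 <- capacity_map(Kd, n, tmpl, 20, 600)
  m2 <- capacity_map(rev(Kd), rev(n), tmpl, 20, 600)
  expect_equal(m1, m2[rev(seq_along(Kd)), rev(seq_along(n))],
               ignore_attr = TRUE)
})

test_that("Blahut-Arimoto reproduces closed-form capacities", {
  # noiseless identity: 1 bit; useless channel: 0 bits
  expect_equal(blahut_arimoto(diag(2), tol = 1e-9)$capacity, 1,
               tolerance = 1e-7)
  expect_equal(blahut_arimoto(matrix(0.5, 2, 2), tol = 1e-9)$capacity, 0,
               tolerance = 1e-9)
  # binary symmetric channel, crossover 0.1: 1 - H2(0.1)
  bsc <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  h2 <- -(0.1 * log2(0.1) + 0.9 * log2(0.9))
  expect_equal(blahut_arimoto(bsc, tol = 1e-9)$capacity, 1 - h2,
               tolerance = 1e-6)
})

test_that("discretized channels are honest stochastic matrices", {
  ch <- discretize_channel(channel_model(fix_micF(), 1), 15, 60,
                           n_in = 40, n_out = 120)
  expect_equal(rowSums(ch$P), rep(1, 40), tolerance = 1e-9)
  expect_true(all(ch$P >= 0))
  expect_equal(range(ch$A), c(15, 60))
})

test_that("the MI estimator matches closed-form oracles", {
  set.seed(7)
  n <- 2e4
  # independence: MI near zero
  expect_lt(mutual_information(rnorm(n), rnorm(n)), 0.01)
  # deterministic identity over k equiprobable states: log2(k)
  k <- 8; x <- sample.int(k, n, replace = TRUE)
  expect_lt(abs(mutual_information(x, x) - log2(k)), 0.02)
  # bivariate Gaussian, rho = 0.5: -0.5*log2(1 - rho^2)
  x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  expect_lt(abs(mutual_information(x, y) + 0.5 * log2(1 - 0.25)), 0.03)
  # too few samples for the grid warns
  expect_warning(mutual_information(rnorm(30), rnorm(30)), "unreliable")
})

test_that("estimated MI respects the channel-capacity bound", {
  mod <- channel_model(fix_micF(), A0 = 1)
  cap <- blahut_arimoto(discretize_channel(mod, 15, 60))$capacity
  set.seed(23)
  for (A in list(runif(4000, 15, 60), runif(4000, 25, 35))) {
    ab <- push_through_channel(A, mod, seed = 3)
    expect_lte(mutual_information(ab$A, ab$B), cap + 0.05)
  }
})
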