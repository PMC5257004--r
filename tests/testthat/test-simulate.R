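test_that("noise-free cascade sits at the deterministic steady state", {
  pars <- ou_input_params(alpha_A = 50, beta = 0.5, sigma_I = 0)
  p <- fix_micF()
  ts <- integrate_cascade(pars, p, dt = 0.05, t_end = 50, seed = 1)
  expect_equal(ts$A, rep(50 / 0.5, nrow(ts)), tolerance = 1e-10)
  expect_equal(ts$B_micF, rep(hill_mean(100, p), nrow(ts)),
               tolerance = 1e-10)
})

test_that("the OU term reproduces its stationary SD and autocorrelation", {
  pars <- ou_input_params(alpha_A = 100, beta = 0.5, T_int = 5, sigma_I = 12)
  tau <- 5 / log(2)
  ts <- integrate_cascade(pars, fix_micF(), dt = 0.1, t_end = 4000, seed = 8)
  I <- ts$I[ts$time > 50]
  # stationary SD: ~550 effective samples => SE(sd) ~ sigma/sqrt(2*Neff)
  n_eff <- (max(ts$time) - 50) / tau
  expect_lt(abs(sd(I) - 12), 3 * 12 / sqrt(2 * n_eff))
  # exact-discretization update: lag-tau autocorrelation = exp(-1)
  lag <- round(tau / 0.1)
  rho <- cor(I[seq_len(length(I) - lag)], I[-seq_len(lag)])
  expect_lt(abs(rho - exp(-1)), 3 / sqrt(n_eff))
})

test_that("an unstable integration step is refused outright", {
  pars <- ou_input_params(alpha_A = 10, beta = 2, sigma_I = 1)
  expect_error(integrate_cascade(pars, fix_micF(), dt = 0.5, t_end = 10),
               "too large")
  expect_error(sweep_spec(c(1, 2), fix_micF(), beta = 5, dt = 1) |>
                 run_sweep(), "too large")
})

test_that("sweep specs validate their grid", {
  expect_error(sweep_spec(numeric(0), fix_micF()), "alpha_A_grid")
  expect_error(sweep_spec(c(2, 1), fix_micF()), "alpha_A_grid")
  expect_error(sweep_spec(c(-1, 2), fix_micF()), "alpha_A_grid")
})

test_that("ensemble sweeps cover grid x promoters and silence the control", {
  proms <- list(fix_micF(), fix_control())
  sw <- sweep_spec(log_spaced_alpha(50, 2000, 5, 8), proms,
                   n_replicates = 20, n_samples = 5, seed = 12)
  es <- run_sweep(sw, n_boot = 30)
  expect_equal(nrow(es), 8 * 2)
  expect_true(all(is.finite(es$cv_A)) && all(es$cv_A >= 0))
  # the control's output does not depend on the input at all
  expect_equal(max(abs(es$eta[es$promoter == "control"])), 0)
  # transmitted noise of the regulated promoter tracks the log-log slope
  reg <- es[es$promoter == "micF", ]
  eta_an <- transmitted_noise_analytic(reg$mean_A, proms[[1]])
  expect_true(mean(abs(reg$eta - eta_an) <= 3 * reg$eta_sd) >= 0.75)
})

test_that("sweeps are reproducible under their seed", {
  sw <- sweep_spec(c(100, 500), fix_micF(), n_replicates = 10,
                   n_samples = 3, seed = 33)
  expect_identical(run_sweep(sw, n_boot = 10), run_sweep(sw, n_boot = 10))
})

test_that("analytic noise peak grows with n and moves toward Kd", {
  # oracle: numerical maximization of the closed-form curve; with basal
  # expression the peak lies below Kd (where regulated output overtakes
  # basal, around Kd*(b/V)^(1/n)) and climbs toward Kd as n grows
  peak <- function(n) {
    p <- hill_params(V = 2000, b = 50, Kd = 100, n = n)
    opt <- optimize(function(A) -transmitted_noise_analytic(A, p),
                    interval = c(0.1, 1e4))
    c(A = opt$minimum, eta = -opt$objective)
  }
  pk <- sapply(c(1, 2, 3), peak)
  expect_true(all(diff(pk["eta", ]) > 0))      # higher n, higher peak
  expect_true(all(diff(pk["A", ]) > 0))        # peak approaches Kd
  expect_true(all(pk["A", ] < 100))
  expect_true(all(pk["A", ] > 100 * (50 / 2000)^(1 / c(1, 2, 3))))
})
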