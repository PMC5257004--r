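# shared fixtures for the test suite; everything is generated in code

fix_micF <- function() promoter_spec("micF", V = 2500, b = 50, Kd = 70,
                                     n = 2.4, klass = "amplifying")

fix_control <- function() promoter_spec("control", V = 800, b = 40, Kd = 1,
                                        n = 1, klass = "control")

quiet_cfg <- function(...) {
  # zero-noise configuration: every cell sits exactly on the Hill curve
  generator_config(extrinsic_cv = 0, reporter_intrinsic_cv = 0,
                   measurement_floor_sd = 0, ...)
}

# independent draw of the generative model used by generate_sweep, written
# without calling any package internals (Monte-Carlo oracle)
oracle_reporter_mean <- function(spec, mean_A, extrinsic_cv, intrinsic_cv,
                                 n_draw = 2e5) {
  sdlog <- sqrt(log(1 + extrinsic_cv^2))
  A <- exp(qnorm(runif(n_draw), log(mean_A) - sdlog^2 / 2, sdlog))
  x <- (A / spec$Kd)^spec$n
  mu <- spec$b + spec$V * x / (1 + x)
  if (intrinsic_cv > 0) {
    s <- sqrt(log(1 + intrinsic_cv^2))
    mu <- mu * exp(qnorm(runif(n_draw), -s^2 / 2, s))
  }
  list(mean = mean(mu), se = sd(mu) / sqrt(n_draw))
}

# group-by statistics oracle for bin_cells, via split() instead of tapply()
oracle_bin_stats <- function(A, B, edges) {
  idx <- findInterval(A, edges, rightmost.closed = TRUE, all.inside = TRUE)
  grp <- split(seq_along(A), idx)
  do.call(rbind, lapply(names(grp), function(g) {
    i <- grp[[g]]
    data.frame(bin = as.integer(g), count = length(i),
               mean_A = mean(A[i]), mean_B = mean(B[i]))
  }))
}
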