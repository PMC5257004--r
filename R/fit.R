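#' Differential evolution minimizer
#'
#' Global stochastic minimizer (DE/rand/1/bin): population of
#' `pop_factor * d` candidate vectors, mutation with a dithered scale
#' factor drawn uniformly from `F_range` each generation, binomial
#' crossover with rate `CR`, greedy selection. Bounds are enforced by
#' reflection. Terminates when the population's fitness spread falls below
#' `tol` (relative to the mean fitness) or after `max_gen` generations.
#' Deterministic under `seed`.
#'
#' @param fn objective function of a numeric vector; must return a finite
#'   scalar (non-finite values are treated as +Inf).
#' @param lower,upper bound vectors of equal length.
#' @param seed integer seed.
#' @param pop_factor population size per dimension (default 15).
#' @param CR crossover rate.
#' @param F_range range of the dithered mutation factor.
#' @param max_gen generation cap.
#' @param tol relative fitness-spread tolerance for early stopping.
#' @return List with `par`, `value`, `iterations`, `converged`.
#' @export
de_optimize <- function(fn, lower, upper, seed = 1L, pop_factor = 15,
                        CR = 0.9, F_range = c(0.5, 1), max_gen = 500,
                        tol = 1e-10) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  NP <- max(4L, as.integer(pop_factor * d))
  safe_fn <- function(x) {
    v <- fn(x)
    if (!is.finite(v)) Inf else v
  }
  with_seed(seed, {
    pop <- matrix(stats::runif(NP * d, lower, upper), NP, d, byrow = TRUE)
    fit <- apply(pop, 1L, safe_fn)
    gen <- 0L; converged <- FALSE
    while (gen < max_gen) {
      gen <- gen + 1L
      Fg <- stats::runif(1, F_range[1L], F_range[2L])
      for (i in seq_len(NP)) {
        idx <- sample.int(NP, 3L)
        while (any(idx == i)) idx <- sample.int(NP, 3L)
        v <- pop[idx[1L], ] + Fg * (pop[idx[2L], ] - pop[idx[3L], ])
        # reflect into bounds
        v <- ifelse(v < lower, pmin(2 * lower - v, upper), v)
        v <- ifelse(v > upper, pmax(2 * upper - v, lower), v)
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, v, pop[i, ])
        f_trial <- safe_fn(trial)
        if (f_trial <= fit[i]) {
          pop[i, ] <- trial
          fit[i] <- f_trial
        }
      }
      spread <- stats::sd(fit)
      if (is.finite(spread) &&
          spread <= tol * (abs(mean(fit)) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(fit)
    list(par = pop[best, ], value = fit[best], iterations = gen,
         converged = converged || gen < max_gen)
  })
}

#' Jointly fit the Hill activation and transmitted-noise curves
#'
#' Because the analytic transmitted noise is the log-log slope of the
#' activation curve, both curves share one parameter set `(V, b, Kd, n)`
#' plus the noise floor `S`. This routine fits all five simultaneously by
#' differential evolution, minimizing a combined objective:
#' standardized squared residuals of the bin means against the Hill curve
#' (inverse-variance weights from the per-bin standard errors) plus
#' `balance` times standardized squared residuals of the raw CV-ratio
#' noise curve against `eta_analytic(A) + S` (inverse-variance weights
#' from the bootstrap SDs). The `noise` curve must therefore be the raw
#' ratio (computed with `S = 0`); the floor is estimated, not subtracted
#' beforehand.
#'
#' Search bounds: `Kd` in `[min_A/10, max_A*10]` (searched on a log10
#' scale), `n` in `(0.3, 6]`, `V` and `b` within the observed output
#' range, `S` in `[0, max observed noise]`. A final derivative-based
#' polish (L-BFGS-B within the same bounds) refines the DE optimum.
#'
#' @param curve a [bin_cells()] result.
#' @param noise a [transmitted_noise_empirical()] result computed with
#'   `S = 0`, ideally carrying `eta_sd` from [bootstrap_eta()]. May be
#'   `NULL` to fit the activation curve alone.
#' @param seed integer seed for the stochastic optimizer.
#' @param balance relative weight of the noise-curve residuals (default 1,
#'   i.e. 1:1 after standardization).
#' @param max_gen,tol DE controls, see [de_optimize()].
#' @param polish refine the DE optimum with bounded L-BFGS-B.
#' @return An object of class `fit_result`: `params` ([hill_params()]),
#'   `S`, `fitness`, `n_bins_used`, `convergence` (list: `iterations`,
#'   `converged`, `seed`), and `flags` (character; `"flat"` marks a
#'   degenerate flat response, e.g. an unregulated control, whose `Kd`
#'   and `n` are not identifiable).
#' @export
fit_joint <- function(curve, noise = NULL, seed = 1L, balance = 1,
                      max_gen = 500, tol = 1e-10, polish = TRUE) {
  stopifnot(inherits(curve, "binned_curve"))
  use <- curve$usable & !is.na(curve$mean_A) & curve$mean_A > 0
  cb <- curve[use, , drop = FALSE]
  n_par <- if (is.null(noise)) 4L else 5L
  if (nrow(cb) < n_par)
    stop(sprintf("need at least %d usable bins to fit %d parameters",
                 n_par, n_par), call. = FALSE)
  se_B <- cb$sd_B / sqrt(cb$count)
  se_B <- pmax(se_B, 1e-9 * max(cb$mean_B, 1e-12))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_curve"))
    if (!isTRUE(all.equal(attr(noise, "S"), 0)))
      warning("`noise` was computed with a nonzero floor already subtracted; ",
              "fit_joint expects the raw CV ratio (S = 0)")
    eta_w <- if (!is.null(noise$eta_sd))
      pmax(noise$eta_sd, 1e-3) else rep(stats::sd(noise$eta) + 1e-3,
                                        nrow(noise))
  }
  rng_B <- range(cb$mean_B)
  lower <- c(V = 1e-9, b = 0, lKd = log10(min(cb$mean_A) / 10), n = 0.3)
  upper <- c(V = 2 * max(rng_B[2L] - rng_B[1L], rng_B[2L]),
             b = rng_B[2L], lKd = log10(max(cb$mean_A) * 10), n = 6)
  if (!is.null(noise)) {
    lower <- c(lower, S = 0)
    upper <- c(upper, S = max(noise$eta, 0) + 1e-6)
  }
  objective <- function(th) {
    p <- list(V = th[1L], b = th[2L], Kd = 10^th[3L], n = th[4L])
    r_act <- (cb$mean_B - hill_mean(cb$mean_A, p)) / se_B
    val <- mean(r_act^2)
    if (!is.null(noise)) {
      pred <- transmitted_noise_analytic(noise$mean_A, p) + th[5L]
      val <- val + balance * mean(((noise$eta - pred) / eta_w)^2)
    }
    val
  }
  de <- de_optimize(objective, lower, upper, seed = seed, max_gen = max_gen,
                    tol = tol)
  par <- de$par; value <- de$value
  if (polish) {
    pol <- try(stats::optim(par, objective, method = "L-BFGS-B",
                            lower = lower + 1e-12, upper = upper,
                            control = list(maxit = 500)), silent = TRUE)
    if (!inherits(pol, "try-error") && is.finite(pol$value) &&
        pol$value <= value) {
      par <- pol$par; value <- pol$value
    }
  }
  params <- hill_params(V = max(par[1L], 1e-12), b = par[2L],
                        Kd = 10^par[3L], n = par[4L])
  flags <- character(0)
  # flat-response degeneracy: dynamic range indistinguishable from bin noise
  # (the expected spread of ~20 independent bin means is about 4-5 SE)
  if ((rng_B[2L] - rng_B[1L]) < 6 * stats::median(se_B) ||
      par[4L] <= lower[["n"]] + 1e-6)
    flags <- c(flags, "flat")
  if (!de$converged) flags <- c(flags, "not_converged")
  structure(list(params = params,
                 S = if (n_par == 5L) par[5L] else NA_real_,
                 fitness = value, n_bins_used = nrow(cb),
                 convergence = list(iterations = de$iterations,
                                    converged = de$converged,
                                    seed = as.integer(seed)),
                 flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  cat(sprintf("  V = %.4g, b = %.4g, Kd = %.4g, n = %.3g, S = %.3g\n",
              x$params$V, x$params$b, x$params$Kd, x$params$n, x$S))
  cat(sprintf("  fitness = %.4g over %d bins; %d DE generations%s\n",
              x$fitness, x$n_bins_used, x$convergence$iterations,
              if (length(x$flags)) paste0(" [",
                                          paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}
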