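#' Analytic transmitted noise of a Hill transfer curve
#'
#' Transmitted noise is the local log-log slope of the transfer curve,
#' `eta(A) = (dB/dA) (A/B) = d ln B / d ln A`. For basal level `b = 0`
#' this reduces to `n / (1 + (A/Kd)^n)`: equal to `n` as `A -> 0`, `n/2`
#' at `A = Kd`, and 0 at saturation. With `b > 0` the curve is pulled down
#' at low `A` (the basal term dilutes relative fluctuations) and has an
#' interior maximum.
#'
#' @param A activator level(s), strictly positive.
#' @param params a [hill_params()] or [promoter_spec()].
#' @return Transmitted-noise values (dimensionless).
#' @export
transmitted_noise_analytic <- function(A, params) {
  stopifnot(all(A > 0))
  hill_slope(A, params) * A / hill_mean(A, params)
}

#' Empirical transmitted noise from binned data
#'
#' Per usable bin, the ratio of output to input coefficients of variation
#' minus the regulation-independent noise floor:
#' `eta = (sd_B/mean_B) / (sd_A/mean_A) - S`. `S` collects intrinsic and
#' extrinsic noise of the target that does not originate from the
#' activator; it is constant along the curve. Bins with `sd_A = 0` (the
#' ratio is undefined) are flagged and excluded.
#'
#' @param curve a [bin_cells()] result.
#' @param S noise floor to subtract (default 0, i.e. the raw CV ratio).
#' @param eta_sd optional per-bin bootstrap SDs (from [bootstrap_eta()]),
#'   aligned with the bins of `curve`.
#' @return A data frame of class `noise_curve` with one row per usable,
#'   defined bin: `bin`, `mean_A`, `eta`, `eta_sd`; attribute `S`.
#' @export
transmitted_noise_empirical <- function(curve, S = 0, eta_sd = NULL) {
  stopifnot(inherits(curve, "binned_curve"))
  assert_scalar_num(S, "S")
  ok <- curve$usable & curve$count >= 2
  defined <- ok & !is.na(curve$sd_A) & curve$sd_A > 0 &
    curve$mean_A > 0 & curve$mean_B > 0
  cv_A <- curve$sd_A / curve$mean_A
  cv_B <- curve$sd_B / curve$mean_B
  eta <- cv_B / cv_A - S
  out <- data.frame(bin = curve$bin, mean_A = curve$mean_A, eta = eta)
  if (!is.null(eta_sd)) {
    stopifnot(length(eta_sd) == nrow(curve))
    out$eta_sd <- eta_sd
  }
  out <- out[defined, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "S") <- S
  attr(out, "excluded_bins") <- curve$bin[ok & !defined]
  class(out) <- c("noise_curve", "data.frame")
  out
}

#' Bootstrap dispersion of the transmitted-noise curve
#'
#' Repeatedly subsamples a fraction of the pooled cell population (without
#' replacement within each draw; the default of one third of the cells,
#' 100 times, makes each replicate a genuine subsample), re-bins the
#' subsample on the *same* log-bin edges as the full data, recomputes the
#' raw CV-ratio transmitted noise per bin, and returns the per-bin SD
#' across replicates. Bins emptied (or left with a single cell) in a
#' replicate are dropped from that replicate.
#'
#' @param table a `snapshot_table`.
#' @param n_bins,min_count binning controls, as in [bin_cells()].
#' @param n_boot number of bootstrap draws (>= 2).
#' @param frac fraction of cells per draw, in (0, 1].
#' @param seed integer seed.
#' @param edges optional explicit bin edges (defaults to the edges
#'   [bin_cells()] derives from the full table).
#' @return Numeric vector of per-bin SDs, aligned with the `n_bins` bins of
#'   the full-table [bin_cells()] result (NA where a bin was never
#'   defined).
#' @export
bootstrap_eta <- function(table, n_bins = 20, min_count = 25, n_boot = 100,
                          frac = 1 / 3, seed = 1L, edges = NULL) {
  validate_snapshot_table(table)
  stopifnot(n_boot >= 2, frac > 0, frac <= 1)
  keep <- !is.na(table$A) & table$A > 0
  A <- table$A[keep]; B <- table$B[keep]
  if (is.null(edges))
    edges <- attr(bin_cells(table, n_bins, min_count), "edges")
  n_bins <- length(edges) - 1L
  n <- length(A)
  m <- max(2L, floor(frac * n))
  eta_rep <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      pick <- sample.int(n, m, replace = FALSE)
      eta_binned(A[pick], B[pick], edges)
    }, numeric(n_bins))
  })
  apply(eta_rep, 1L, stats::sd, na.rm = TRUE)
}

# raw CV-ratio transmitted noise per bin on fixed edges; NA where undefined
eta_binned <- function(A, B, edges) {
  n_bins <- length(edges) - 1L
  idx <- findInterval(A, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- rep(NA_real_, n_bins)
  for (b in unique(idx)) {
    sel <- idx == b
    if (sum(sel) < 2L) next
    sa <- stats::sd(A[sel]); ma <- mean(A[sel])
    sb <- stats::sd(B[sel]); mb <- mean(B[sel])
    if (sa > 0 && ma > 0 && mb > 0) out[b] <- (sb / mb) / (sa / ma)
  }
  out
}

#' Transmitted noise per known condition
#'
#' For synthetic or simulated data where the generating condition of each
#' cell is known, computes the CV-ratio transmitted noise per condition
#' (ensembles at fixed condition) instead of per log-bin. This sidesteps
#' the dependence of the per-bin input CV on the bin width.
#'
#' @inheritParams transmitted_noise_empirical
#' @param table a `snapshot_table`.
#' @param S noise floor to subtract.
#' @return A data frame with one row per condition: `condition_id`,
#'   `mean_A`, `eta`.
#' @export
transmitted_noise_by_condition <- function(table, S = 0) {
  validate_snapshot_table(table)
  parts <- lapply(split(table, table$condition_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    cv_A <- stats::sd(d$A) / mean(d$A)
    cv_B <- stats::sd(d$B) / mean(d$B)
    if (!is.finite(cv_A) || cv_A == 0) return(NULL)
    data.frame(condition_id = d$condition_id[1L], mean_A = mean(d$A),
               eta = cv_B / cv_A - S)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$mean_A), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Noise floor estimated from a reporter-only control table
#'
#' Alternative estimator of the regulation-independent floor `S`: the CV
#' of an unregulated (control-class) promoter's output, whose fluctuations
#' by construction contain no transmitted component.
#'
#' @param table a `snapshot_table` of a control promoter.
#' @return Scalar estimate of `S`.
#' @export
noise_floor_from_control <- function(table) {
  validate_snapshot_table(table)
  stats::sd(table$B) / mean(table$B)
}
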