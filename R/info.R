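#' Estimate the physiological input distribution by nearest-neighbour mapping
#'
#' Reporter-only measurements see only the output channel `B`; the latent
#' activator distribution that produced them is recovered by matching each
#' reporter-only cell to the cell in a paired activator/reporter sweep
#' table with the nearest `B` value and collecting that cell's `A`. The
#' collected `A` values are pooled across all included promoters' sweep
#' tables; promoters named in `exclude` are skipped (by default the
#' marRAB-like promoter, whose reporter does not track the activator
#' faithfully in the de-repressed background because the operon's own
#' repressor is overexpressed with it). Ties are broken by first
#' occurrence after a stable sort of the sweep table by `B`. If a
#' reporter-only value falls outside a sweep table's `B` range it is
#' matched to the nearest extreme cell, with a warning when the ranges do
#' not overlap at all.
#'
#' @param reporter_only a `snapshot_table` (or list of them, pooled) of
#'   reporter-only cells; only the `B` column is used.
#' @param sweeps named list of activator/reporter `snapshot_table`s, one
#'   per promoter.
#' @param exclude character vector of promoter names to skip.
#' @param label distribution label (`"wildtype"`, `"marAplus"`, or
#'   `"custom"`).
#' @return An object of class `input_distribution`: `samples` (pooled
#'   matched `A` values), `A_min`/`A_max` (5th and 95th percentiles), and
#'   `label`.
#' @export
estimate_input_distribution <- function(reporter_only, sweeps,
                                        exclude = "marRAB",
                                        label = c("custom", "wildtype",
                                                  "marAplus")) {
  label <- match.arg(label)
  if (inherits(reporter_only, "snapshot_table"))
    reporter_only <- list(reporter_only)
  B_obs <- unlist(lapply(reporter_only, function(t) t$B), use.names = FALSE)
  stopifnot(length(B_obs) >= 1L, is.list(sweeps), length(sweeps) >= 1L)
  use <- setdiff(names(sweeps), exclude)
  if (!length(use))
    stop("all sweep tables are excluded; nothing to match against",
         call. = FALSE)
  samples <- unlist(lapply(use, function(nm) {
    sw <- sweeps[[nm]]
    validate_snapshot_table(sw, context = sprintf("sweep table '%s'", nm))
    if (max(B_obs) < min(sw$B) || min(B_obs) > max(sw$B))
      warning(sprintf(paste0("reporter-only B range does not overlap the ",
                             "'%s' sweep; matches extrapolate to the ",
                             "nearest extreme cell"), nm), call. = FALSE)
    nearest_neighbour_A(B_obs, sw)
  }), use.names = FALSE)
  input_distribution(samples, label = label)
}

# for each query B, the A of the sweep cell with nearest B; stable ties
nearest_neighbour_A <- function(B_query, sweep) {
  ord <- order(sweep$B)                      # stable in R
  Bs <- sweep$B[ord]; As <- sweep$A[ord]
  pos <- findInterval(B_query, Bs, all.inside = FALSE)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(Bs))
  pick_hi <- (B_query - Bs[lo]) > (Bs[hi] - B_query)  # strict: ties -> lower
  pick_hi[pos == 0L] <- TRUE
  idx <- ifelse(pick_hi, hi, lo)
  As[idx]
}

#' Input-distribution container
#'
#' Wraps a sample of activator values with its 5th and 95th percentiles,
#' which bound the channel-capacity integral as the physiologically
#' relevant input range.
#'
#' @param samples positive activator values.
#' @param label distribution label.
#' @return An object of class `input_distribution`.
#' @export
input_distribution <- function(samples, label = "custom") {
  samples <- samples[is.finite(samples)]
  stopifnot(length(samples) >= 2L, all(samples > 0))
  q <- stats::quantile(samples, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[1L] >= q[2L])
    stop("degenerate input distribution: 5th and 95th percentiles coincide",
         call. = FALSE)
  structure(list(samples = samples, A_min = q[1L], A_max = q[2L],
                 label = label),
            class = "input_distribution")
}

#' @export
print.input_distribution <- function(x, ...) {
  cat(sprintf("<input_distribution> %s: %d samples, 5th-95th pct [%.4g, %.4g]\n",
              x$label, length(x$samples), x$A_min, x$A_max))
  invisible(x)
}

#' Small-noise channel model
#'
#' Gaussian channel in which the output conditional on input `A` has mean
#' `B(A)` (the Hill curve) and variance `B(A) + A0 * A * (dB/dA)^2`:
#' Poisson-like output noise plus propagated Poisson-like input noise,
#' with `A0` a scaling term for the activator concentration.
#'
#' @param params a [hill_params()] or [promoter_spec()].
#' @param A0 input-noise scaling term, >= 0; default 1 (generator units).
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(params, A0 = 1) {
  assert_scalar_num(A0, "A0", lower = 0)
  stopifnot(inherits(params, "hill_params"))
  structure(list(params = params, A0 = A0), class = "channel_model")
}

channel_sd <- function(A, model) {
  g <- hill_slope(A, model$params)
  sqrt(hill_mean(A, model$params) + model$A0 * A * g^2)
}

#' Bounded channel capacity under the small-noise approximation
#'
#' Computes
#' \deqn{Z = \int_{A_{min}}^{A_{max}}
#'   \sqrt{\frac{(dB/dA)^2}{B(A) + A_0 A (dB/dA)^2}} \, dA}
#' by adaptive quadrature and reports `capacity_rel = log2(Z)`. The
#' channel capacity is `log2(Z) + X` where `X` is a constant introduced by
#' the small-noise approximation, independent of the promoter parameters;
#' `X` is never evaluated here, so capacities are comparable only as
#' differences (which is exactly how they are used). A flat response over
#' the bounds gives `Z = 0` and a `-Inf` sentinel with an explanatory
#' note.
#'
#' @param model a [channel_model()].
#' @param A_min,A_max positive input bounds (typically the 5th and 95th
#'   percentiles of an [input_distribution()]); `A_min < A_max`.
#' @param abs_tol absolute quadrature tolerance on `Z`.
#' @return An object of class `capacity_result`: `Z`, `capacity_rel`
#'   (`log2(Z)`; `-Inf` when `Z = 0`), `A_min`, `A_max`, and `note`
#'   (records that the additive constant `X` is not evaluated, plus any
#'   degeneracy).
#' @export
capacity_small_noise <- function(model, A_min, A_max, abs_tol = 1e-8) {
  stopifnot(inherits(model, "channel_model"))
  assert_scalar_num(A_min, "A_min", lower = 0, strict_lower = TRUE)
  assert_scalar_num(A_max, "A_max", lower = 0, strict_lower = TRUE)
  note <- "capacity_rel = log2(Z); additive small-noise constant X not evaluated"
  if (A_min >= A_max) {
    if (A_min > A_max) stop("`A_min` must not exceed `A_max`", call. = FALSE)
    return(structure(list(Z = 0, capacity_rel = -Inf, A_min = A_min,
                          A_max = A_max,
                          note = paste(note, "; empty input interval",
                                       sep = "")),
                     class = "capacity_result"))
  }
  integrand <- function(A) hill_slope(A, model$params) / channel_sd(A, model)
  Z <- stats::integrate(integrand, A_min, A_max, abs.tol = abs_tol,
                        rel.tol = 1e-10, subdivisions = 500L)$value
  if (Z <= 0)
    return(structure(list(Z = 0, capacity_rel = -Inf, A_min = A_min,
                          A_max = A_max,
                          note = paste0(note, "; flat response over the ",
                                        "bounds, capacity undefined")),
                     class = "capacity_result"))
  structure(list(Z = Z, capacity_rel = log2(Z), A_min = A_min, A_max = A_max,
                 note = note),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> log2(Z) = %.4g over [%.4g, %.4g]\n",
              x$capacity_rel, x$A_min, x$A_max))
  cat(" ", x$note, "\n")
  invisible(x)
}

#' Relative channel capacity over a (Kd, n) parameter grid
#'
#' Evaluates [capacity_small_noise()] for every combination of `Kd` and
#' `n`, holding the template's amplitude, basal level, and `A0` fixed, as
#' used for capacity heat maps with promoters overlaid by their fitted
#' `(Kd, n)`.
#'
#' @param Kd_grid,n_grid positive parameter grids.
#' @param template a [hill_params()] or [promoter_spec()] supplying `V`
#'   and `b`.
#' @param A_min,A_max input bounds.
#' @param A0 input-noise scaling.
#' @return Matrix of `capacity_rel` values with `Kd_grid` on rows and
#'   `n_grid` on columns (dimnames carry the grid values).
#' @export
capacity_map <- function(Kd_grid, n_grid, template, A_min, A_max, A0 = 1) {
  stopifnot(all(Kd_grid > 0), all(n_grid > 0))
  out <- matrix(NA_real_, length(Kd_grid), length(n_grid),
                dimnames = list(Kd = signif(Kd_grid, 6),
                                n = signif(n_grid, 6)))
  for (i in seq_along(Kd_grid))
    for (j in seq_along(n_grid)) {
      p <- hill_params(V = template$V, b = template$b, Kd = Kd_grid[i],
                       n = n_grid[j])
      out[i, j] <- capacity_small_noise(channel_model(p, A0), A_min,
                                        A_max)$capacity_rel
    }
  out
}

#' Discretize a small-noise channel for the brute-force capacity oracle
#'
#' Builds the conditional probability matrix `P(B-bin | A-point)` of a
#' [channel_model()] on a uniform input grid over `[A_min, A_max]` and a
#' uniform output binning covering the conditional means plus/minus six
#' conditional SDs (outer bins extend to infinity, so rows sum to one
#' exactly).
#'
#' @param model a [channel_model()].
#' @param A_min,A_max input bounds.
#' @param n_in input grid points.
#' @param n_out output bins.
#' @return An object of class `discrete_channel`: `A` (input grid), `P`
#'   (`n_in` x `n_out` stochastic matrix), `B_edges`.
#' @export
discretize_channel <- function(model, A_min, A_max, n_in = 120L,
                               n_out = 400L) {
  stopifnot(inherits(model, "channel_model"), A_min > 0, A_max > A_min)
  A <- seq(A_min, A_max, length.out = n_in)
  mu <- hill_mean(A, model$params)
  sd <- channel_sd(A, model)
  lo <- min(mu - 6 * sd); hi <- max(mu + 6 * sd)
  inner <- seq(lo, hi, length.out = n_out - 1L)
  edges <- c(-Inf, inner, Inf)
  P <- t(vapply(seq_along(A), function(i) {
    diff(stats::pnorm(edges, mean = mu[i], sd = sd[i]))
  }, numeric(n_out)))
  stopifnot(all(abs(rowSums(P) - 1) < 1e-9), all(P >= 0))
  structure(list(A = A, P = P, B_edges = edges), class = "discrete_channel")
}

#' Blahut-Arimoto channel capacity
#'
#' Standard alternating maximization of mutual information over input
#' distributions for a discrete memoryless channel, returning the capacity
#' in bits. Serves as the brute-force oracle against which the small-noise
#' capacity integral is validated: across promoter parameters, the oracle
#' capacity minus `log2(Z)` must be a constant (the small-noise `X`).
#'
#' @param channel a `discrete_channel`, or a bare row-stochastic matrix
#'   `P(output | input)`.
#' @param tol convergence tolerance on the capacity (bits); iteration
#'   stops when the upper and lower capacity bounds differ by less than
#'   `tol`.
#' @param max_iter iteration cap.
#' @return List with `capacity` (bits), `p_input` (capacity-achieving
#'   input distribution), `iterations`.
#' @export
blahut_arimoto <- function(channel, tol = 1e-7, max_iter = 5000L) {
  P <- if (inherits(channel, "discrete_channel")) channel$P else channel
  stopifnot(is.matrix(P), all(P >= 0),
            all(abs(rowSums(P) - 1) < 1e-6))
  m <- nrow(P)
  p <- rep(1 / m, m)
  logP <- ifelse(P > 0, log(P), 0)
  rowH <- rowSums(P * logP)   # sum_j P_ij log P_ij, fixed across iterations
  it <- 0L
  repeat {
    it <- it + 1L
    q <- as.vector(p %*% P)
    logq <- ifelse(q > 0, log(q), 0)
    # D_i = KL(P_i || q) in nats; columns with q = 0 have P_ij = 0 too
    D <- rowH - as.vector(P %*% logq)
    IL <- sum(p * D)          # lower bound (current MI)
    IU <- max(D)              # upper bound
    if ((IU - IL) / log(2) < tol || it >= max_iter) break
    w <- p * exp(D)
    p <- w / sum(w)
  }
  list(capacity = IL / log(2), p_input = p, iterations = it)
}

#' Histogram mutual information between paired samples
#'
#' Plug-in estimator on a 2-D grid of equal-count (quantile) bins with
#' Miller-Madow bias correction. Continuous MI is estimated through its
#' discretized surrogate, so the estimate depends on the bin count; the
#' default 20 x 20 grid suits a few thousand samples. A warning is issued
#' when fewer than `n_bins^2 / 10` samples are supplied.
#'
#' @param x,y paired numeric samples.
#' @param n_bins marginal bin count.
#' @param correct apply the Miller-Madow correction.
#' @return Estimated mutual information in bits (truncated below at 0).
#' @export
mutual_information <- function(x, y, n_bins = 20L, correct = TRUE) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  n <- length(x)
  if (n < n_bins^2 / 10)
    warning(sprintf("only %d samples for a %dx%d grid; MI estimate is unreliable",
                    n, n_bins, n_bins), call. = FALSE)
  cut_q <- function(v) {
    ux <- sort(unique(v))
    if (length(ux) <= n_bins) return(match(v, ux))  # already discrete
    br <- unique(stats::quantile(v, seq(0, 1, length.out = n_bins + 1L),
                                 names = FALSE, type = 7))
    if (length(br) < 2L) return(rep(1L, length(v)))
    findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  ix <- cut_q(x); iy <- cut_q(y)
  joint <- table(ix, iy)
  pxy <- joint / n
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz])) / log(2)
  if (correct) {
    Kxy <- sum(nz); Kx <- sum(px > 0); Ky <- sum(py > 0)
    # entropy biases cancel into a positive MI bias; subtract it
    mi <- mi - ((Kxy - 1) - (Kx - 1) - (Ky - 1)) / (2 * n * log(2))
  }
  max(mi, 0)
}

#' Push an input distribution through a channel model
#'
#' Draws one output per input sample from the small-noise Gaussian
#' conditional (truncated at zero), giving paired `(A, B)` samples for
#' mutual-information estimation against the channel's capacity.
#'
#' @param inputs an [input_distribution()] or positive numeric vector.
#' @param model a [channel_model()].
#' @param seed integer seed.
#' @return Data frame with columns `A`, `B`.
#' @export
push_through_channel <- function(inputs, model, seed = 1L) {
  A <- if (inherits(inputs, "input_distribution")) inputs$samples else inputs
  stopifnot(all(A > 0), inherits(model, "channel_model"))
  with_seed(seed, {
    B <- stats::rnorm(length(A), hill_mean(A, model$params),
                      channel_sd(A, model))
    data.frame(A = A, B = pmax(B, 0))
  })
}
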