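#' Configuration for the synthetic snapshot generator
#'
#' Describes one induction-sweep / background experiment in the generator's
#' arbitrary fluorescence units. The default induction design emulates a
#' 12-point IPTG sweep (0, 10, ..., 100 and 500 uM) through an inducible
#' activator: condition means rise affinely with inducer from a basal level,
#' with the 500 uM point far above the rest, so pooling all conditions yields
#' the broad activator distribution the binned analysis assumes.
#'
#' Per cell, the activator `A` is drawn log-normally around its condition
#' mean with coefficient of variation `extrinsic_cv` (cell-to-cell extrinsic
#' variability); the reporter mean follows the Hill curve of the promoter;
#' multiplicative log-normal intrinsic noise (`reporter_intrinsic_cv`, mean
#' 1) and an additive zero-mean Gaussian measurement floor
#' (`measurement_floor_sd`, truncated so `B >= 0`) are then applied. The
#' additive floor is what gives the downstream gene a noise component that
#' does not come from the activator, i.e. it realizes the regulation-
#' independent noise floor `S` of the transmitted-noise analysis.
#'
#' @param induction_levels named or unnamed numeric vector of per-condition
#'   activator means (fluorescence units); all positive.
#' @param cells_per_condition cells per condition, >= 1.
#' @param extrinsic_cv coefficient of variation of the activator within a
#'   condition; >= 0.
#' @param reporter_intrinsic_cv CV of the multiplicative intrinsic reporter
#'   noise; >= 0.
#' @param measurement_floor_sd SD of the additive measurement floor
#'   (fluorescence units); >= 0.
#' @param wildtype_mean,marAplus_mean activator means of the two background
#'   (reporter-only) distributions; must satisfy
#'   `wildtype_mean < marAplus_mean`.
#' @param background_cv CV of the background activator distributions.
#' @param seed integer seed; the same `(spec, cfg)` pair with the same seed
#'   reproduces tables byte-identically.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(induction_levels = default_induction_levels(),
                             cells_per_condition = 100,
                             extrinsic_cv = 0.35,
                             reporter_intrinsic_cv = 0.15,
                             measurement_floor_sd = 20,
                             wildtype_mean = 30,
                             marAplus_mean = 600,
                             background_cv = 0.4,
                             seed = 1L) {
  if (!is.numeric(induction_levels) || length(induction_levels) < 1L ||
      !all(is.finite(induction_levels)) || any(induction_levels <= 0))
    stop("`induction_levels` must be positive finite activator means",
         call. = FALSE)
  assert_scalar_num(cells_per_condition, "cells_per_condition", lower = 1)
  assert_scalar_num(extrinsic_cv, "extrinsic_cv", lower = 0)
  assert_scalar_num(reporter_intrinsic_cv, "reporter_intrinsic_cv", lower = 0)
  assert_scalar_num(measurement_floor_sd, "measurement_floor_sd", lower = 0)
  assert_scalar_num(wildtype_mean, "wildtype_mean", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(marAplus_mean, "marAplus_mean", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(background_cv, "background_cv", lower = 0)
  assert_scalar_num(seed, "seed")
  if (wildtype_mean >= marAplus_mean)
    stop("`wildtype_mean` must be below `marAplus_mean`", call. = FALSE)
  if (is.null(names(induction_levels)))
    names(induction_levels) <- sprintf("cond_%02d",
                                       seq_along(induction_levels))
  structure(
    list(induction_levels = induction_levels,
         cells_per_condition = as.integer(cells_per_condition),
         extrinsic_cv = extrinsic_cv,
         reporter_intrinsic_cv = reporter_intrinsic_cv,
         measurement_floor_sd = measurement_floor_sd,
         wildtype_mean = wildtype_mean,
         marAplus_mean = marAplus_mean,
         background_cv = background_cv,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' @rdname generator_config
#' @param basal,gain affine map from inducer concentration (uM) to mean
#'   activator fluorescence.
#' @param iptg inducer concentrations (uM) of the sweep design.
#' @export
default_induction_levels <- function(basal = 15, gain = 4,
                                     iptg = c(0, 10, 20, 30, 40, 50, 60, 70,
                                              80, 90, 100, 500)) {
  stats::setNames(basal + gain * iptg, sprintf("iptg_%03d", iptg))
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d conditions x %d cells; extrinsic CV %.2f, intrinsic CV %.2f, floor SD %g\n",
              length(x$induction_levels), x$cells_per_condition,
              x$extrinsic_cv, x$reporter_intrinsic_cv,
              x$measurement_floor_sd))
  cat(sprintf("  backgrounds: wildtype mean %g, MarA+ mean %g (CV %.2f); seed %d\n",
              x$wildtype_mean, x$marAplus_mean, x$background_cv, x$seed))
  invisible(x)
}

# draw B given activator values and a promoter spec, applying intrinsic and
# measurement noise; truncation at zero keeps fluorescence non-negative
draw_reporter <- function(A, spec, cfg) {
  mu <- hill_mean(A, spec)
  n <- length(A)
  B <- mu
  if (cfg$reporter_intrinsic_cv > 0)
    B <- B * rlnorm_mean_cv(n, 1, cfg$reporter_intrinsic_cv)
  if (cfg$measurement_floor_sd > 0)
    B <- B + stats::rnorm(n, 0, cfg$measurement_floor_sd)
  pmax(B, 0)
}

as_snapshot_table <- function(df) {
  validate_snapshot_table(df)
  class(df) <- c("snapshot_table", "data.frame")
  df
}

validate_snapshot_table <- function(df, context = "snapshot table") {
  required <- c("cell_id", "condition_id", "strain", "promoter", "A", "B")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!is.na(df$A) & (!is.finite(df$A) | df$A < 0))
  bad <- union(bad, which(!is.finite(df$B) | df$B < 0))
  if (length(bad))
    stop(sprintf("%s has negative or non-finite fluorescence in row(s): %s",
                 context, paste(sort(utils::head(bad, 10)), collapse = ", ")),
         call. = FALSE)
  incomplete <- which(is.na(df$cell_id) | is.na(df$condition_id) |
                        is.na(df$strain) | is.na(df$promoter) | is.na(df$B))
  if (length(incomplete))
    stop(sprintf("%s has missing fields in row(s): %s", context,
                 paste(sort(utils::head(incomplete, 10)), collapse = ", ")),
         call. = FALSE)
  invisible(df)
}

#' Generate a synthetic induction-sweep snapshot table
#'
#' Simulates the two-plasmid activator/reporter experiment: for each
#' induction condition, `cells_per_condition` cells draw an activator level
#' `A` ("RFP") from a log-normal distribution with the condition mean and
#' `extrinsic_cv`, and a reporter level `B` ("GFP") from the promoter's Hill
#' curve with multiplicative intrinsic noise and an additive measurement
#' floor (see [generator_config()]). Output is one row per cell.
#'
#' @param spec a [promoter_spec()].
#' @param cfg a [generator_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return A `snapshot_table` data frame with columns `cell_id`,
#'   `condition_id`, `strain` (`"sweep"`), `promoter`, `A`, `B`.
#' @examples
#' cfg <- generator_config(cells_per_condition = 50)
#' tab <- generate_sweep(promoter_fixtures()[["micF"]], cfg)
#' table(tab$condition_id)
#' @export
generate_sweep <- function(spec, cfg, seed = NULL) {
  stopifnot(inherits(spec, "promoter_spec"), inherits(cfg, "generator_config"))
  with_seed(seed %||% cfg$seed, {
    k <- cfg$cells_per_condition
    parts <- lapply(names(cfg$induction_levels), function(cond) {
      m <- cfg$induction_levels[[cond]]
      A <- rlnorm_mean_cv(k, m, cfg$extrinsic_cv)
      data.frame(condition_id = cond, A = A,
                 B = draw_reporter(A, spec, cfg))
    })
    df <- do.call(rbind, parts)
    df <- data.frame(cell_id = sprintf("c%06d", seq_len(nrow(df))),
                     condition_id = df$condition_id,
                     strain = "sweep", promoter = spec$name,
                     A = df$A, B = df$B)
    as_snapshot_table(df)
  })
}

#' Generate a synthetic reporter-only background snapshot table
#'
#' Simulates the reporter-only experiment in one of two genetic backgrounds:
#' `"wildtype"` (basal activator; mean `cfg$wildtype_mean`) or `"marAplus"`
#' (de-repressed activator; mean `cfg$marAplus_mean`). The activator is
#' latent in the real experiment; here it is always drawn and recorded, and
#' `mask_activator = TRUE` replaces the `A` column with `NA` (mimicking
#' reporter-only data) while keeping the latent truth in attribute
#' `"A_latent"` for validation.
#'
#' @inheritParams generate_sweep
#' @param which `"wildtype"` or `"marAplus"`.
#' @param mask_activator mask the activator channel as in real
#'   reporter-only data.
#' @return A `snapshot_table` with `strain` and `condition_id` set to
#'   `which`.
#' @export
generate_background <- function(spec, which = c("wildtype", "marAplus"),
                                cfg, mask_activator = FALSE, seed = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(spec, "promoter_spec"), inherits(cfg, "generator_config"))
  mean_A <- switch(which, wildtype = cfg$wildtype_mean,
                   marAplus = cfg$marAplus_mean)
  with_seed(seed %||% cfg$seed, {
    k <- cfg$cells_per_condition
    A <- rlnorm_mean_cv(k, mean_A, cfg$background_cv)
    df <- data.frame(cell_id = sprintf("c%06d", seq_len(k)),
                     condition_id = which, strain = which,
                     promoter = spec$name, A = A,
                     B = draw_reporter(A, spec, cfg))
    out <- as_snapshot_table(df)
    if (mask_activator) {
      attr(out, "A_latent") <- out$A
      out$A <- NA_real_
    }
    out
  })
}
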