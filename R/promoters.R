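#' Promoter transfer-curve specification
#'
#' A promoter is described by the steady-state Hill transfer curve
#' \deqn{B(A) = b + V \frac{(A/K_d)^n}{1 + (A/K_d)^n}}
#' where `A` is the activator level and `B` the reporter level (both in
#' arbitrary fluorescence units). `V` and `b` are the amplitude and basal
#' level, i.e. the ratios of the maximal / basal production rates to the
#' degradation-and-dilution rate; steady-state snapshot data identify only
#' these ratios, never the rates themselves. `Kd` is the dissociation
#' constant (activator units at half-maximal activation) and `n` the Hill
#' coefficient. Promoters fall into qualitative classes: *amplifying*
#' (low `Kd`, high `n`: steep at low activator, saturating within the
#' physiological range) and *filtering* (high `Kd`, low `n`: flat at low
#' activator, responsive only at high input), plus *chimeric* promoters
#' with the activator-binding box swapped between classes, and unregulated
#' *control* promoters whose output is independent of the activator.
#'
#' @param name promoter label.
#' @param V amplitude, fluorescence units; must be positive.
#' @param b basal level, fluorescence units; non-negative.
#' @param Kd dissociation constant, activator fluorescence units; positive.
#' @param n Hill coefficient; positive.
#' @param klass one of `"amplifying"`, `"filtering"`, `"chimeric"`,
#'   `"control"`.
#' @param parents for chimeric promoters, character vector naming the two
#'   parent promoters (marbox donor and backbone); otherwise `NULL`.
#' @return An object of class `promoter_spec` (also a valid `hill_params`).
#' @seealso [hill_mean()], [promoter_fixtures()]
#' @export
promoter_spec <- function(name, V, b, Kd, n,
                          klass = c("amplifying", "filtering", "chimeric",
                                    "control"),
                          parents = NULL) {
  klass <- match.arg(klass)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_scalar_num(V, "V", lower = 0, strict_lower = TRUE)
  assert_scalar_num(b, "b", lower = 0)
  assert_scalar_num(Kd, "Kd", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n, "n", lower = 0, strict_lower = TRUE)
  structure(
    list(name = name, V = V, b = b, Kd = Kd, n = n, klass = klass,
         parents = parents),
    class = c("promoter_spec", "hill_params"))
}

#' Hill transfer-curve parameters
#'
#' Bare parameter container for the Hill curve `b + V x/(1+x)`,
#' `x = (A/Kd)^n`; used for fitted parameters when no promoter identity is
#' attached.
#'
#' @inheritParams promoter_spec
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(V, b, Kd, n) {
  assert_scalar_num(V, "V", lower = 0, strict_lower = TRUE)
  assert_scalar_num(b, "b", lower = 0)
  assert_scalar_num(Kd, "Kd", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n, "n", lower = 0, strict_lower = TRUE)
  structure(list(V = V, b = b, Kd = Kd, n = n), class = "hill_params")
}

#' @export
print.promoter_spec <- function(x, ...) {
  cat(sprintf("<promoter_spec> %s [%s]\n", x$name, x$klass))
  cat(sprintf("  V = %g, b = %g, Kd = %g, n = %g\n", x$V, x$b, x$Kd, x$n))
  if (!is.null(x$parents))
    cat("  parents:", paste(x$parents, collapse = " x "), "\n")
  invisible(x)
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> V = %g, b = %g, Kd = %g, n = %g\n",
              x$V, x$b, x$Kd, x$n))
  invisible(x)
}

#' Steady-state Hill response
#'
#' Mean reporter output at activator level `A`:
#' `b + V (A/Kd)^n / (1 + (A/Kd)^n)`. Control-class promoters are
#' constitutive and return `b + V` independent of `A`.
#'
#' @param A activator level(s), non-negative.
#' @param params a [hill_params()] or [promoter_spec()].
#' @return Numeric vector of reporter means.
#' @examples
#' hill_mean(c(0, 50, 1e6), hill_params(V = 1, b = 0.1, Kd = 50, n = 2))
#' @export
hill_mean <- function(A, params) {
  stopifnot(is.numeric(A), all(is.finite(A)), all(A >= 0))
  if (identical(params$klass, "control"))
    return(rep(params$b + params$V, length(A)))
  x <- (A / params$Kd)^params$n
  params$b + params$V * x / (1 + x)
}

#' Slope of the Hill response
#'
#' `dB/dA` of [hill_mean()] in closed form:
#' `V n (A/Kd)^n / (A (1 + (A/Kd)^n)^2)` for `A > 0`. Control promoters
#' have slope 0 everywhere.
#'
#' @inheritParams hill_mean
#' @return Numeric vector of slopes (reporter units per activator unit).
#' @export
hill_slope <- function(A, params) {
  stopifnot(is.numeric(A), all(is.finite(A)), all(A > 0))
  if (identical(params$klass, "control")) return(rep(0, length(A)))
  x <- (A / params$Kd)^params$n
  params$V * params$n * x / (A * (1 + x)^2)
}

#' Normalize a reporter response to the unit interval
#'
#' Subtracts the fitted basal level and divides by the amplitude,
#' `(B - b)/V`, so that activation curves of promoters with different
#' absolute expression can be overlaid on a common 0--1 scale.
#' `denormalize_response()` is the exact algebraic inverse.
#'
#' @param B reporter value(s).
#' @param params a [hill_params()] or [promoter_spec()].
#' @return Numeric vector on the normalized scale.
#' @export
normalize_response <- function(B, params) (B - params$b) / params$V

#' @rdname normalize_response
#' @param Bn normalized value(s).
#' @export
denormalize_response <- function(Bn, params) Bn * params$V + params$b

#' Shipped promoter fixtures
#'
#' Loads the packaged set of promoter parameter fixtures: two amplifying
#' promoters (micF-like and marRAB-like: low `Kd`, high `n`), four
#' filtering promoters (acrAB-, inaA-, sodA- and tolC-like: high `Kd`,
#' low `n`; the inaA-like `Kd` is ten times the micF-like `Kd`), two
#' chimeric promoters with the binding box swapped between the marRAB-like
#' and acrAB-like parents (intermediate `Kd`, `n`), and one unregulated
#' control. Parameter values are synthetic: chosen to realize these
#' qualitative classes in the generator's arbitrary fluorescence units,
#' not measured values.
#'
#' @param path optional path to a YAML fixture file with the same layout;
#'   defaults to the packaged file.
#' @return Named list of [promoter_spec()] objects.
#' @export
promoter_fixtures <- function(path = NULL) {
  path <- path %||% system.file("extdata", "promoters.yaml",
                                package = "hillnoise", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  specs <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    promoter_spec(name = nm, V = p$V, b = p$b, Kd = p$Kd, n = p$n,
                  klass = p$klass, parents = p$parents)
  })
  stats::setNames(specs, names(raw))
}
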