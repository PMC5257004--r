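#' Pipeline configuration
#'
#' Assembles the configuration for an end-to-end run: generate snapshot
#' data per promoter fixture, bin and jointly fit activation + noise,
#' estimate the two background input distributions by nearest-neighbour
#' mapping, and compute bounded channel capacity and mutual information
#' per promoter under both sets of bounds.
#'
#' @param promoters named list of [promoter_spec()]s; default the shipped
#'   fixture set.
#' @param out_dir output directory (created if absent).
#' @param seed master seed; per-stage seeds are derived deterministically
#'   from it and recorded in the manifest.
#' @param generator a [generator_config()] (its own seed is overridden by
#'   the derived stage seed).
#' @param stages character subset of
#'   `c("generate", "fit", "noise", "inputs", "capacity", "mi")`; later
#'   stages require earlier ones.
#' @param n_bins,min_count binning controls.
#' @param fit_max_gen DE generation cap for the joint fits.
#' @param A0 input-noise scaling for the channel model.
#' @param overwrite allow writing into a non-empty `out_dir`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(promoters = promoter_fixtures(),
                            out_dir = tempfile("hillnoise_run_"),
                            seed = 1L,
                            generator = generator_config(),
                            stages = c("generate", "fit", "noise", "inputs",
                                       "capacity", "mi"),
                            n_bins = 20, min_count = 25,
                            fit_max_gen = 200, A0 = 1,
                            overwrite = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(length(promoters) >= 1L,
            all(vapply(promoters, inherits, TRUE, "promoter_spec")))
  structure(list(promoters = promoters, out_dir = out_dir,
                 seed = as.integer(seed), generator = generator,
                 stages = stages, n_bins = n_bins, min_count = min_count,
                 fit_max_gen = fit_max_gen, A0 = A0, overwrite = overwrite),
            class = "pipeline_config")
}

# small deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, stage, k = 0L) {
  (seed * 7919L + utf8ToInt(substr(stage, 1L, 1L)) * 131L + k * 17L) %%
    2147480000L
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages for every promoter fixture and writes
#' all artifacts (CSV tables, JSON fits and capacities) plus a manifest
#' listing every file with its MD5 hash and the seeds used. Reruns with
#' the same configuration and seed reproduce byte-identical artifacts. A
#' stage failure aborts with an error attributed to the stage, after
#' writing a partial manifest of the artifacts completed so far.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly: a list with `seed`, `stage_seeds`,
#'   `files` (named MD5 hashes), `summary` (per-promoter data frame), and
#'   `timing` (seconds per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!config$overwrite && length(list.files(config$out_dir)))
    stop(sprintf("output directory '%s' is not empty (set overwrite = TRUE)",
                 config$out_dir), call. = FALSE)
  manifest <- list(seed = config$seed, stage_seeds = list(), files = list(),
                   timing = list())
  artifacts <- new.env(parent = emptyenv())
  register <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  path_of <- function(...) file.path(config$out_dir, paste0(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$partial <<- TRUE
      jsonlite::write_json(manifest, path_of("manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  proms <- config$promoters
  gen_cfg <- config$generator

  if ("generate" %in% config$stages) stage("generate", {
    sseed <- derive_seed(config$seed, "generate")
    manifest$stage_seeds$generate <- sseed
    artifacts$sweeps <- lapply(seq_along(proms), function(i)
      generate_sweep(proms[[i]], gen_cfg, seed = sseed + i))
    names(artifacts$sweeps) <- names(proms)
    artifacts$backgrounds <- lapply(c(wildtype = "wildtype",
                                      marAplus = "marAplus"), function(w)
      lapply(seq_along(proms), function(i)
        generate_background(proms[[i]], w, gen_cfg,
                            seed = derive_seed(config$seed, w, i))))
    for (w in names(artifacts$backgrounds))
      names(artifacts$backgrounds[[w]]) <- names(proms)
    for (nm in names(proms)) {
      p <- path_of("sweep_", nm, ".csv")
      write_snapshot_table(artifacts$sweeps[[nm]], p); register(p)
    }
  })

  if ("fit" %in% config$stages) stage("fit", {
    sseed <- derive_seed(config$seed, "fit")
    manifest$stage_seeds$fit <- sseed
    artifacts$binned <- lapply(artifacts$sweeps, bin_cells,
                               n_bins = config$n_bins,
                               min_count = config$min_count)
    artifacts$fits <- lapply(seq_along(proms), function(i) {
      tab <- artifacts$sweeps[[i]]
      bc <- artifacts$binned[[i]]
      esd <- bootstrap_eta(tab, config$n_bins, config$min_count,
                           seed = sseed + i, edges = attr(bc, "edges"))
      nc <- transmitted_noise_empirical(bc, S = 0,
                                        eta_sd = esd)
      fit_joint(bc, nc, seed = sseed + i, max_gen = config$fit_max_gen)
    })
    names(artifacts$fits) <- names(proms)
    for (nm in names(proms)) {
      p <- path_of("binned_", nm, ".csv")
      utils::write.csv(as.data.frame(artifacts$binned[[nm]]), p,
                       row.names = FALSE); register(p)
      f <- artifacts$fits[[nm]]
      pj <- path_of("fit_", nm, ".json")
      jsonlite::write_json(list(promoter = nm, V = f$params$V,
                                b = f$params$b, Kd = f$params$Kd,
                                n = f$params$n, S = f$S,
                                fitness = f$fitness,
                                n_bins_used = f$n_bins_used,
                                flags = f$flags,
                                convergence = f$convergence),
                           pj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      register(pj)
    }
  })

  if ("noise" %in% config$stages) stage("noise", {
    artifacts$noise <- lapply(names(proms), function(nm) {
      bc <- artifacts$binned[[nm]]
      S <- artifacts$fits[[nm]]$S
      transmitted_noise_empirical(bc, S = if (is.finite(S)) S else 0)
    })
    names(artifacts$noise) <- names(proms)
    for (nm in names(proms)) {
      p <- path_of("noise_", nm, ".csv")
      utils::write.csv(as.data.frame(artifacts$noise[[nm]]), p,
                       row.names = FALSE); register(p)
    }
  })

  if ("inputs" %in% config$stages) stage("inputs", {
    artifacts$inputs <- lapply(c(wildtype = "wildtype",
                                 marAplus = "marAplus"), function(w)
      estimate_input_distribution(
        unname(artifacts$backgrounds[[w]][
          setdiff(names(proms), c("marRAB", "control"))]),
        artifacts$sweeps, exclude = c("marRAB", "control"), label = w))
    for (w in names(artifacts$inputs)) {
      d <- artifacts$inputs[[w]]
      p <- path_of("input_", w, ".csv")
      utils::write.csv(data.frame(A = d$samples), p, row.names = FALSE)
      register(p)
    }
  })

  if ("capacity" %in% config$stages) stage("capacity", {
    artifacts$capacity <- lapply(names(proms), function(nm) {
      pars <- artifacts$fits[[nm]]$params
      mod <- channel_model(pars, A0 = config$A0)
      lapply(artifacts$inputs, function(d)
        capacity_small_noise(mod, d$A_min, d$A_max))
    })
    names(artifacts$capacity) <- names(proms)
    p <- path_of("capacity.json")
    jsonlite::write_json(
      lapply(artifacts$capacity, function(x)
        lapply(x, function(cr) list(capacity_rel = cr$capacity_rel,
                                    Z = cr$Z, A_min = cr$A_min,
                                    A_max = cr$A_max))),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    register(p)
  })

  if ("mi" %in% config$stages) stage("mi", {
    sseed <- derive_seed(config$seed, "mi")
    manifest$stage_seeds$mi <- sseed
    artifacts$mi <- lapply(seq_along(proms), function(i) {
      nm <- names(proms)[i]
      mod <- channel_model(artifacts$fits[[nm]]$params, A0 = config$A0)
      vapply(artifacts$inputs, function(d) {
        ab <- push_through_channel(d, mod, seed = sseed + i)
        mutual_information(ab$A, ab$B)
      }, numeric(1))
    })
    names(artifacts$mi) <- names(proms)
    p <- path_of("mutual_information.json")
    jsonlite::write_json(artifacts$mi, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    register(p)
  })

  manifest$summary <- pipeline_summary(artifacts, proms)
  if (!is.null(manifest$summary)) {
    p <- path_of("summary.csv")
    utils::write.csv(manifest$summary, p, row.names = FALSE); register(p)
  }
  jsonlite::write_json(manifest, path_of("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$out_dir <- config$out_dir
  class(manifest) <- "pipeline_manifest"
  invisible(manifest)
}

pipeline_summary <- function(artifacts, proms) {
  if (is.null(artifacts$fits)) return(NULL)
  rows <- lapply(names(proms), function(nm) {
    f <- artifacts$fits[[nm]]
    row <- data.frame(promoter = nm, klass = proms[[nm]]$klass,
                      Kd_true = proms[[nm]]$Kd, n_true = proms[[nm]]$n,
                      V = f$params$V, b = f$params$b, Kd = f$params$Kd,
                      n = f$params$n, S = f$S,
                      flat = "flat" %in% f$flags)
    if (!is.null(artifacts$capacity)) {
      row$capacity_rel_wildtype <-
        artifacts$capacity[[nm]]$wildtype$capacity_rel
      row$capacity_rel_marAplus <-
        artifacts$capacity[[nm]]$marAplus$capacity_rel
    }
    if (!is.null(artifacts$mi)) {
      row$mi_wildtype <- artifacts$mi[[nm]][["wildtype"]]
      row$mi_marAplus <- artifacts$mi[[nm]][["marAplus"]]
    }
    row
  })
  do.call(rbind, rows)
}

#' Summarize and plot a pipeline run
#'
#' Produces the run's tabular summary (fitted parameters, noise floor,
#' relative capacity under both input bounds, mutual information per
#' promoter) and, optionally, overview figures: normalized activation
#' overlays (basal subtracted, amplitude-normalized), transmitted-noise
#' overlays, and capacity bars under both bounds. Plots are diagnostic
#' artifacts written as PNG.
#'
#' @param manifest the result of [run_pipeline()].
#' @param plot also write `report.png` into the run directory.
#' @return The summary data frame, invisibly.
#' @export
pipeline_report <- function(manifest, plot = FALSE) {
  stopifnot(inherits(manifest, "pipeline_manifest"))
  s <- manifest$summary
  if (is.null(s)) stop("manifest has no summary (fit stage not run)",
                       call. = FALSE)
  if (plot) {
    png_path <- file.path(manifest$out_dir, "report.png")
    grDevices::png(png_path, width = 1500, height = 500, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    A <- exp(seq(log(5), log(5000), length.out = 200))
    cols <- grDevices::hcl.colors(nrow(s), "Dark 3")
    graphics::matplot(A, sapply(seq_len(nrow(s)), function(i) {
      p <- hill_params(s$V[i], s$b[i], s$Kd[i], s$n[i])
      normalize_response(hill_mean(A, p), p)
    }), type = "l", lty = 1, log = "x", col = cols,
    xlab = "activator (a.u.)", ylab = "normalized response",
    main = "activation")
    graphics::legend("topleft", legend = s$promoter, col = cols, lty = 1,
                     cex = 0.6, bty = "n")
    graphics::matplot(A, sapply(seq_len(nrow(s)), function(i)
      transmitted_noise_analytic(A, hill_params(s$V[i], s$b[i], s$Kd[i],
                                                s$n[i]))),
      type = "l", lty = 1, log = "x", col = cols,
      xlab = "activator (a.u.)", ylab = "transmitted noise",
      main = "noise")
    if (!is.null(s$capacity_rel_wildtype)) {
      m <- t(as.matrix(s[, c("capacity_rel_wildtype",
                             "capacity_rel_marAplus")]))
      m[!is.finite(m)] <- NA
      graphics::barplot(m, beside = TRUE, names.arg = s$promoter,
                        las = 2, col = c("grey40", "grey70"),
                        ylab = "log2(Z)", main = "relative capacity")
      graphics::legend("topright", c("wildtype bounds", "MarA+ bounds"),
                       fill = c("grey40", "grey70"), bty = "n", cex = 0.7)
    }
  }
  invisible(s)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest>\n")
  cat(sprintf("  seed %d; %d artifacts in %s\n", x$seed, length(x$files),
              x$out_dir %||% "?"))
  for (nm in names(x$timing))
    cat(sprintf("  stage %-9s %6.2fs\n", nm, x$timing[[nm]]))
  invisible(x)
}
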