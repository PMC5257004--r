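#' Log-bin pooled single-cell data by activator level
#'
#' Pools all cells in a snapshot table and bins them logarithmically along
#' the activator axis between the smallest positive and largest `A`. Per
#' bin it records the count and the mean and SD of both channels. Bins
#' whose count does not exceed `min_count` are flagged unusable and carry
#' no weight downstream (the default threshold of 25 cells follows common
#' practice for stable per-bin CV estimates). The fitting abscissa is the
#' per-bin *mean* of `A`, not the geometric bin center.
#'
#' @param table a `snapshot_table` with at least one `A > 0` row.
#' @param n_bins number of logarithmic bins.
#' @param min_count bins must have strictly more cells than this to be
#'   usable.
#' @return A data frame of class `binned_curve` with columns `bin`, `lo`,
#'   `hi` (edges), `count`, `mean_A`, `sd_A`, `mean_B`, `sd_B`, `usable`;
#'   attributes `edges` and `min_count`.
#' @export
bin_cells <- function(table, n_bins = 20, min_count = 25) {
  validate_snapshot_table(table)
  stopifnot(n_bins >= 1, min_count >= 0)
  A <- table$A[!is.na(table$A)]
  if (!length(A) || !any(A > 0))
    stop("table has no rows with A > 0", call. = FALSE)
  keep <- !is.na(table$A) & table$A > 0
  A <- table$A[keep]; B <- table$B[keep]
  lo <- min(A); hi <- max(A)
  if (lo == hi) { lo <- lo * 0.999; hi <- hi * 1.001 }
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  idx <- findInterval(A, edges, rightmost.closed = TRUE, all.inside = TRUE)
  stat <- function(f, x) {
    out <- rep(NA_real_, n_bins)
    agg <- tapply(x, idx, f)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  }
  count <- integer(n_bins)
  tab <- table(idx)
  count[as.integer(names(tab))] <- as.integer(tab)
  out <- data.frame(bin = seq_len(n_bins),
                    lo = edges[-(n_bins + 1L)], hi = edges[-1L],
                    count = count,
                    mean_A = stat(mean, A), sd_A = stat(stats::sd, A),
                    mean_B = stat(mean, B), sd_B = stat(stats::sd, B))
  out$sd_A[out$count == 1L] <- 0
  out$sd_B[out$count == 1L] <- 0
  out$usable <- out$count > min_count
  if (!any(out$usable))
    stop(sprintf(paste0("no bin has more than %d cells; supply more data ",
                        "or use fewer bins"), min_count), call. = FALSE)
  attr(out, "edges") <- edges
  attr(out, "min_count") <- min_count
  class(out) <- c("binned_curve", "data.frame")
  out
}
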