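#' Total-count normalization to the median library, then log1p
#'
#' Each spot's counts are rescaled so its library equals the median
#' library of the dataset, then log-transformed:
#' `normalized[i, ] = log(1 + counts[i, ] * median_library / library_i)`.
#' Raw counts are kept untouched alongside the normalized matrix.
#'
#' @param ds a `spatial_dataset`.
#' @return `ds` with the `normalized` field filled in.
#' @export
normalize_counts <- function(ds) {
  lib <- library_sizes(ds)
  zero <- which(lib == 0)
  if (length(zero) > 0) {
    stop(sprintf("zero-library spot(s): %s",
                 paste(ds$spot_ids[zero], collapse = ", ")))
  }
  med <- stats::median(lib)
  ds$normalized <- log1p(ds$counts * (med / lib))
  ds
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Classic dispersion-based ranking on log-normalized expression: genes
#' are binned by mean expression (20 bins), dispersion = variance/mean is
#' z-scored within each bin, and the top `n_top` genes by normalized
#' dispersion are kept. Gene order is preserved.
#'
#' @param ds a `spatial_dataset` with normalized expression (computed on
#'   the fly if absent).
#' @param n_top number of genes to keep (clipped to G), default 2000.
#' @param n_bins number of mean-expression bins.
#' @return `ds` restricted to the selected genes.
#' @export
select_hvg <- function(ds, n_top = 2000, n_bins = 20) {
  if (n_top <= 0) stop("n_top must be positive")
  if (is.null(ds$normalized)) ds <- normalize_counts(ds)
  g <- n_genes(ds)
  n_top <- min(n_top, g)
  x <- ds$normalized
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1, min(n_bins, floor(g / 4)))  # keep bins populated
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1))),
              include.lowest = TRUE)
  zdisp <- disp
  for (b in levels(bins)) {
    sel <- which(bins == b)
    if (length(sel) >= 2) {
      s <- stats::sd(disp[sel])
      zdisp[sel] <- if (s > 0) (disp[sel] - mean(disp[sel])) / s else 0
    } else if (length(sel) == 1) {
      zdisp[sel] <- 0
    }
  }
  keep <- sort(order(zdisp, decreasing = TRUE)[seq_len(n_top)])
  out <- ds
  out$counts <- ds$counts[, keep, drop = FALSE]
  out$normalized <- ds$normalized[, keep, drop = FALSE]
  out$gene_names <- ds$gene_names[keep]
  out
}

#' Size factors: library size over median library
#'
#' `factor_k = library_k / median_j(library_j)`; the median factor over
#' the full dataset is therefore 1, and factors are invariant to global
#' count rescaling.
#'
#' @param ds a `spatial_dataset`.
#' @return numeric vector of positive size factors, one per spot.
#' @export
compute_size_factors <- function(ds) {
  lib <- library_sizes(ds)
  zero <- which(lib == 0)
  if (length(zero) > 0) {
    stop(sprintf("zero-library spot(s): %s",
                 paste(ds$spot_ids[zero], collapse = ", ")))
  }
  lib / stats::median(lib)
}

#' Rescale coordinates to a target range, per slide
#'
#' Each axis is affinely mapped to `[0, range_max]` (min to 0, max to
#' range_max), independently for every slide so that multi-slide data
#' share a common spatial domain; a constant (degenerate) axis maps to 0.
#' The spatial kernel never couples spots across slides (slide identity
#' is carried by the `slide` factor), so per-slide rescaling is safe.
#'
#' @param ds a `spatial_dataset`.
#' @param range_max target range (default 20, the model's standard
#'   spatial domain).
#' @return `ds` with rescaled coordinates.
#' @export
rescale_coordinates <- function(ds, range_max = 20) {
  out <- ds
  for (sl in levels(ds$slide)) {
    idx <- which(ds$slide == sl)
    if (length(idx) == 0) next
    for (d in seq_len(ncol(ds$coords))) {
      v <- ds$coords[idx, d]
      rng <- range(v)
      out$coords[idx, d] <- if (rng[2] > rng[1]) {
        (v - rng[1]) / (rng[2] - rng[1]) * range_max
      } else rep(0, length(v))
    }
  }
  out
}
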