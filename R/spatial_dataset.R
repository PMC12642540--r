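#' Spatial perturbation dataset
#'
#' The universal input container: a raw UMI count matrix over spots and
#' genes, spot coordinates (2D or 3D), and per-spot attributes. The
#' perturbation label is mandatory (its first vocabulary level is the
#' unperturbed state); disease/region state, slide ID and continuous
#' covariates (e.g. day) are optional. Optional attributes default to a
#' single-level vocabulary so every spot shares one embedding row.
#'
#' @param counts integer-valued matrix, spots x genes, raw UMI counts.
#' @param coords numeric matrix, spots x D with D in \{2, 3\}.
#' @param perturbation factor or character per spot; first level of the
#'   factor is treated as the unperturbed reference state.
#' @param disease optional factor/character per spot (disease, region or
#'   spot-type annotation).
#' @param slide optional factor/character per spot identifying the slide.
#' @param continuous optional named list of numeric per-spot covariates.
#' @param normalized optional spots x genes matrix of log-normalized
#'   expression (filled in by [normalize_counts()]).
#' @param gene_names,spot_ids identifiers; default to dimnames or
#'   generated ids.
#'
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, coords, perturbation,
                            disease = NULL, slide = NULL,
                            continuous = NULL, normalized = NULL,
                            gene_names = NULL, spot_ids = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  storage.mode(counts) <- "double"
  storage.mode(coords) <- "double"
  n <- nrow(counts)
  if (is.null(spot_ids)) {
    spot_ids <- rownames(counts)
    if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(n))
  }
  if (is.null(gene_names)) {
    gene_names <- colnames(counts)
    if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(counts)))
  }
  as_attr_factor <- function(x, nm) {
    if (is.null(x)) return(factor(rep(paste0(substr(nm, 1, 1), "0"), n)))
    if (!is.factor(x)) x <- factor(x)
    if (length(x) != n) stop(sprintf("'%s' must have one value per spot", nm))
    x
  }
  ds <- structure(list(
    counts = counts,
    normalized = normalized,
    coords = coords,
    perturbation = as_attr_factor(perturbation, "perturbation"),
    disease = as_attr_factor(disease, "disease"),
    slide = as_attr_factor(slide, "slide"),
    continuous = continuous,
    gene_names = as.character(gene_names),
    spot_ids = as.character(spot_ids)
  ), class = "spatial_dataset")
  validate_spatial_dataset(ds)
  ds
}

#' Validate a spatial_dataset's invariants
#'
#' Checks non-negative integral counts, finite coordinates with D in
#' \{2,3\}, and dimension consistency across all fields. Errors name the
#' offending spots/entries.
#'
#' @param ds a `spatial_dataset`.
#' @return `ds`, invisibly.
#' @export
validate_spatial_dataset <- function(ds) {
  n <- nrow(ds$counts)
  g <- ncol(ds$counts)
  bad <- which(ds$counts < 0 | abs(ds$counts - round(ds$counts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("counts must be non-negative integers; offending entries (spot,gene): %s",
                 paste(utils::head(apply(bad, 1, paste, collapse = ","), 5),
                       collapse = "; ")))
  }
  if (!ncol(ds$coords) %in% c(2L, 3L))
    stop("coords must have 2 or 3 columns")
  if (nrow(ds$coords) != n)
    stop(sprintf("coords has %d rows but counts has %d spots",
                 nrow(ds$coords), n))
  nf <- which(!is.finite(ds$coords), arr.ind = TRUE)
  if (nrow(nf) > 0) {
    stop(sprintf("non-finite coordinates for spot(s): %s",
                 paste(unique(ds$spot_ids[nf[, 1]]), collapse = ", ")))
  }
  for (nm in c("perturbation", "disease", "slide")) {
    x <- ds[[nm]]
    if (length(x) != n) stop(sprintf("'%s' length mismatch", nm))
    if (anyNA(x)) {
      stop(sprintf("'%s' has missing labels for spot(s): %s", nm,
                   paste(ds$spot_ids[is.na(x)], collapse = ", ")))
    }
  }
  if (!is.null(ds$continuous)) {
    if (is.null(names(ds$continuous)) || any(names(ds$continuous) == ""))
      stop("continuous covariates must be named")
    for (nm in names(ds$continuous)) {
      v <- ds$continuous[[nm]]
      if (length(v) != n || !is.numeric(v) || anyNA(v))
        stop(sprintf("continuous covariate '%s' must be numeric per spot", nm))
    }
  }
  if (length(ds$gene_names) != g) stop("gene_names length mismatch")
  if (length(ds$spot_ids) != n) stop("spot_ids length mismatch")
  if (anyDuplicated(ds$spot_ids)) stop("duplicate spot_ids")
  invisible(ds)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes (%dD coordinates)\n",
              nrow(x$counts), ncol(x$counts), ncol(x$coords)))
  cat(sprintf("  perturbation states: %s\n",
              paste(levels(x$perturbation), collapse = ", ")))
  if (nlevels(x$disease) > 1)
    cat(sprintf("  disease states: %s\n", paste(levels(x$disease), collapse = ", ")))
  if (nlevels(x$slide) > 1)
    cat(sprintf("  slides: %s\n", paste(levels(x$slide), collapse = ", ")))
  if (!is.null(x$continuous))
    cat(sprintf("  continuous covariates: %s\n",
                paste(names(x$continuous), collapse = ", ")))
  cat(sprintf("  normalized: %s\n", !is.null(x$normalized)))
  invisible(x)
}

#' Subset spots of a spatial_dataset
#'
#' @param ds a `spatial_dataset`.
#' @param idx integer or logical index over spots.
#' @return a `spatial_dataset` restricted to the selected spots; factor
#'   vocabularies are preserved (levels are not dropped).
#' @export
subset_spots <- function(ds, idx) {
  if (is.logical(idx)) idx <- which(idx)
  out <- ds
  out$counts <- ds$counts[idx, , drop = FALSE]
  if (!is.null(ds$normalized)) out$normalized <- ds$normalized[idx, , drop = FALSE]
  out$coords <- ds$coords[idx, , drop = FALSE]
  out$perturbation <- ds$perturbation[idx]
  out$disease <- ds$disease[idx]
  out$slide <- ds$slide[idx]
  if (!is.null(ds$continuous))
    out$continuous <- lapply(ds$continuous, function(v) v[idx])
  out$spot_ids <- ds$spot_ids[idx]
  out
}

n_spots <- function(ds) nrow(ds$counts)
n_genes <- function(ds) ncol(ds$counts)

#' Per-spot library sizes
#' @param ds a `spatial_dataset`.
#' @return numeric vector of total counts per spot.
#' @export
library_sizes <- function(ds) rowSums(ds$counts)
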