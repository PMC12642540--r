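#' Initialize attribute codebooks
#'
#' Learnable embedding tables following the latent-optimization
#' (LORD-style) design: a basal table with one free row per training
#' spot, one row per perturbation state (including the unperturbed
#' reference), optional disease and slide tables when those attributes
#' have more than one level, and a small two-layer projector per
#' continuous covariate mapping a scalar to an embedding block. Rows are
#' initialized from a zero-mean normal with sd 0.01.
#'
#' Concatenation order of the blocks is fixed and recorded:
#' basal, disease, perturbation, continuous covariates (in order), slide.
#'
#' @param ds a `spatial_dataset` (vocabularies are taken from it).
#' @param dims named list/vector of block dimensions
#'   (`basal`, `disease`, `perturbation`, `continuous`, `slide`),
#'   each defaulting to `default_dim`.
#' @param seed RNG seed (initialization is deterministic under it).
#' @param default_dim default block dimensionality, 256.
#' @param noise_sigma sd of the Gaussian regularization noise added to
#'   the basal block during training, default 0.1.
#' @param l2_weight L2 penalty weight lambda on basal rows, default 1.
#' @param init_sd sd of the zero-mean normal initialization; the default
#'   0.1 gives attribute rows an initial norm comparable to the basal
#'   regularization noise, so attribute blocks are visible to the
#'   encoder from the start.
#' @return an object of class `attribute_codebooks`.
#' @export
init_codebooks <- function(ds, dims = list(), seed,
                           default_dim = 256, noise_sigma = 0.1,
                           l2_weight = 1, init_sd = 0.1) {
  if (missing(seed)) stop("a seed is required")
  dim_of <- function(nm) if (!is.null(dims[[nm]])) dims[[nm]] else default_dim
  for (nm in c("perturbation", "disease", "slide")) {
    if (anyDuplicated(levels(ds[[nm]]))) stop(sprintf("duplicate levels in '%s'", nm))
  }
  set.seed(seed)
  rinit <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = init_sd), nr, nc)
  n <- n_spots(ds)
  cb <- list(
    basal = rinit(n, dim_of("basal")),
    perturbation = rinit(nlevels(ds$perturbation), dim_of("perturbation")),
    disease = if (nlevels(ds$disease) > 1) rinit(nlevels(ds$disease), dim_of("disease")) else NULL,
    slide = if (nlevels(ds$slide) > 1) rinit(nlevels(ds$slide), dim_of("slide")) else NULL,
    continuous = NULL,
    vocab = list(perturbation = levels(ds$perturbation),
                 disease = levels(ds$disease),
                 slide = levels(ds$slide)),
    noise_sigma = noise_sigma, l2_weight = l2_weight
  )
  if (!is.null(ds$continuous)) {
    h <- 16
    m4 <- dim_of("continuous")
    cb$continuous <- lapply(ds$continuous, function(v) {
      list(W1 = rinit(1, h), b1 = rep(0, h),
           W2 = rinit(h, m4), b2 = rep(0, m4),
           center = mean(v), scale = max(stats::sd(v), 1e-8),
           range = range(v))
    })
    names(cb$continuous) <- names(ds$continuous)
  }
  blocks <- c("basal",
              if (!is.null(cb$disease)) "disease",
              "perturbation",
              if (!is.null(cb$continuous)) paste0("cont:", names(cb$continuous)),
              if (!is.null(cb$slide)) "slide")
  cb$block_order <- blocks
  structure(cb, class = "attribute_codebooks")
}

cont_project <- function(proj, values, warn_extrapolate = TRUE) {
  v <- (values - proj$center) / proj$scale
  if (warn_extrapolate &&
      (any(values < proj$range[1] - 1e-9) || any(values > proj$range[2] + 1e-9))) {
    warning("continuous attribute outside the trained range: extrapolating")
  }
  H <- tanh(outer(v, proj$W1[1, ]) +
              matrix(proj$b1, length(v), length(proj$b1), byrow = TRUE))
  E <- H %*% proj$W2 + matrix(proj$b2, length(v), length(proj$b2), byrow = TRUE)
  list(E = E, H = H, v = v)
}

#' Assemble spot embeddings from the codebooks
#'
#' Concatenates, in the recorded block order, the (optionally noisy)
#' basal rows with the attribute embeddings looked up for each spot.
#' Gaussian noise (sd `noise_sigma`) is added to the basal block only,
#' and only when `training = TRUE`; inference embeddings are
#' deterministic.
#'
#' @param cb an `attribute_codebooks` object.
#' @param spot_index integer indices into the basal table, or `NA` for
#'   unseen spots (then `basal_override` rows are used).
#' @param perturbation,disease,slide character or factor labels per spot
#'   (must be in the trained vocabularies).
#' @param continuous optional named list of numeric values per spot.
#' @param training logical; add basal noise?
#' @param basal_override optional matrix of basal rows for unseen spots.
#' @return list with the embedding matrix `e` (spots x total dim) and
#'   `blocks`, a named list of column index ranges per block.
#' @export
embed_spots <- function(cb, spot_index, perturbation,
                        disease = NULL, slide = NULL, continuous = NULL,
                        training = FALSE, basal_override = NULL) {
  n <- length(spot_index)
  lookup <- function(tbl, labels, vocab, nm) {
    i <- match(as.character(labels), vocab)
    if (anyNA(i)) {
      stop(sprintf("unknown %s label(s): %s", nm,
                   paste(unique(as.character(labels)[is.na(i)]), collapse = ", ")))
    }
    tbl[i, , drop = FALSE]
  }
  basal <- matrix(0, n, ncol(cb$basal))
  seen <- !is.na(spot_index)
  basal[seen, ] <- cb$basal[spot_index[seen], , drop = FALSE]
  if (any(!seen)) {
    if (is.null(basal_override)) stop("unseen spots require basal_override rows")
    basal[!seen, ] <- basal_override
  }
  if (training && cb$noise_sigma > 0) {
    basal <- basal + matrix(stats::rnorm(length(basal), sd = cb$noise_sigma),
                            nrow(basal), ncol(basal))
  }
  parts <- list(basal = basal)
  if (!is.null(cb$disease)) {
    if (is.null(disease)) stop("disease labels required")
    parts$disease <- lookup(cb$disease, disease, cb$vocab$disease, "disease")
  }
  parts$perturbation <- lookup(cb$perturbation, perturbation,
                               cb$vocab$perturbation, "perturbation")
  if (!is.null(cb$continuous)) {
    for (nm in names(cb$continuous)) {
      if (is.null(continuous[[nm]])) stop(sprintf("continuous covariate '%s' required", nm))
      parts[[paste0("cont:", nm)]] <-
        cont_project(cb$continuous[[nm]], continuous[[nm]])$E
    }
  }
  if (!is.null(cb$slide)) {
    if (is.null(slide)) stop("slide labels required")
    parts$slide <- lookup(cb$slide, slide, cb$vocab$slide, "slide")
  }
  parts <- parts[cb$block_order]
  e <- do.call(cbind, parts)
  ends <- cumsum(vapply(parts, ncol, integer(1)))
  starts <- c(1, utils::head(ends, -1) + 1)
  blocks <- Map(function(s, t) s:t, starts, ends)
  names(blocks) <- cb$block_order
  list(e = e, blocks = blocks)
}

#' L2 penalty on the basal codebook
#'
#' `lambda * sum of squared entries` over all basal rows; strictly
#' convex in the basal entries and invariant to row order.
#'
#' @param cb an `attribute_codebooks` object.
#' @param lambda penalty weight; defaults to the codebooks' `l2_weight`.
#' @return scalar penalty value.
#' @export
basal_l2_penalty <- function(cb, lambda = cb$l2_weight) {
  lambda * sum(cb$basal^2)
}
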