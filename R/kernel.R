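#' Kernel parameter set
#'
#' Anisotropic Cauchy kernel hyperparameters: one positive scale per
#' spatial axis (per perturbation state in `per_perturbation` mode, or a
#' single shared vector in `single_kernel` mode), an optional per-spot
#' cutoff in (0,1) driving a sigmoid mask, and the mask temperature tau.
#' Scales are stored through a softplus reparameterization so gradient
#' updates cannot leave the positive cone.
#'
#' @param scales numeric vector of length D (single_kernel) or matrix
#'   n_perturbations x D (per_perturbation); all entries > 0. Default 10
#'   per axis.
#' @param mode `"single_kernel"` or `"per_perturbation"`.
#' @param cutoffs optional per-spot cutoff values in (0,1); `NULL`
#'   disables the mask entirely (the raw kernel is used).
#' @param tau mask temperature (> 0), default 1.
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(scales, mode = c("single_kernel", "per_perturbation"),
                          cutoffs = NULL, tau = 1) {
  mode <- match.arg(mode)
  if (is.null(dim(scales))) scales <- matrix(scales, nrow = 1)
  if (any(scales <= 0)) stop("kernel scales must be positive")
  if (!is.null(cutoffs) && (any(cutoffs <= 0) || any(cutoffs >= 1)))
    stop("cutoffs must lie in (0,1)")
  if (tau <= 0) stop("tau must be positive")
  structure(list(scales = scales, mode = mode, cutoffs = cutoffs, tau = tau),
            class = "kernel_params")
}

#' Anisotropic Cauchy kernel between two locations
#'
#' `k(sa, sb) = 1 / (1 + sum_d (sa_d - sb_d)^2 / l_d)`; symmetric,
#' valued in (0, 1], equal to 1 iff the locations coincide, and strictly
#' decreasing in each squared coordinate difference.
#'
#' @param sa,sb numeric D-vectors.
#' @param scales positive numeric D-vector of per-axis scales.
#' @return kernel value in (0, 1].
#' @export
cauchy_kernel <- function(sa, sb, scales) {
  if (any(scales <= 0)) stop("kernel scales must be positive")
  1 / (1 + sum((sa - sb)^2 / scales))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Cutoff-masked Cauchy kernel
#'
#' The raw kernel value k is modulated by a learnable two-spot cutoff:
#' `c = (ca + cb)/2`, `mask = sigmoid(-tau * (k - c))`, value `k * mask`.
#' When cutoff mode is disabled (cutoffs absent, the "c = 0" branch) the
#' raw kernel is returned unmasked.
#'
#' @param sa,sb numeric D-vectors.
#' @param ca,cb per-spot cutoffs in (0,1), or `NULL` to disable masking.
#' @param params a [kernel_params()] object supplying scales and tau;
#'   scales taken from its first row.
#' @return masked kernel value.
#' @export
masked_kernel <- function(sa, sb, ca, cb, params) {
  k <- cauchy_kernel(sa, sb, params$scales[1, ])
  if (is.null(ca) || is.null(cb)) return(k)
  k * sigmoid(-params$tau * (k - (ca + cb) / 2))
}

#' Axis-aligned inducing-point grid
#'
#' `steps` equispaced points per axis spanning `[0, range_max]`
#' inclusive, in Cartesian product over D axes (steps^D points total),
#' sorted lexicographically.
#'
#' @param range_max upper end of the (rescaled) spatial domain, default 20.
#' @param steps points per axis (>= 2), default 6.
#' @param D spatial dimensionality, 2 or 3.
#' @return matrix steps^D x D of inducing locations.
#' @export
make_inducing_grid <- function(range_max = 20, steps = 6, D = 2) {
  if (steps < 2) stop("steps must be >= 2")
  axis <- seq(0, range_max, length.out = steps)
  g <- as.matrix(expand.grid(rep(list(axis), D)))
  colnames(g) <- c("x", "y", "z")[seq_len(D)]
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

#' Scales used for a pair of perturbation labels
#'
#' In `per_perturbation` mode, two spots with the same label use that
#' perturbation's scale vector; spots with different labels use the
#' element-wise mean of the two vectors (symmetric; reduces to the
#' shared case when scales agree). In `single_kernel` mode the shared
#' scales are returned regardless of labels.
#'
#' @param label_a,label_b integer perturbation indices (1-based rows of
#'   `params$scales`).
#' @param params a [kernel_params()].
#' @return numeric D-vector of scales.
#' @export
pair_kernel_scales <- function(label_a, label_b, params) {
  if (params$mode == "single_kernel") return(params$scales[1, ])
  (params$scales[label_a, ] + params$scales[label_b, ]) / 2
}

## Full cross-kernel matrix between two location sets with optional
## per-perturbation dispatch, slide blocking and cutoff masking.
## labels_*: integer perturbation indices (or NULL); slides_*: integer
## slide ids (or NULL -> single slide); cutoffs_*: per-location cutoffs.
kernel_matrix <- function(A, B, params,
                          labels_a = NULL, labels_b = NULL,
                          slides_a = NULL, slides_b = NULL,
                          cutoffs_a = NULL, cutoffs_b = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A); m <- nrow(B); D <- ncol(A)
  if (ncol(B) != D) stop("location sets have different dimensionality")
  plain <- function(ia, ib, sc) {
    q <- matrix(0, length(ia), length(ib))
    for (d in seq_len(D)) {
      q <- q + outer(A[ia, d], B[ib, d], "-")^2 / sc[d]
    }
    1 / (1 + q)
  }
  if (params$mode == "single_kernel") {
    K <- plain(seq_len(n), seq_len(m), params$scales[1, ])
  } else if (is.null(labels_a) && is.null(labels_b)) {
    ## label-free pair in per-perturbation mode: mean scale vector
    K <- plain(seq_len(n), seq_len(m), colMeans(params$scales))
  } else {
    ## a label-free side (e.g. inducing points) adopts the labelled
    ## side's scales; both-labelled pairs use pair_kernel_scales
    K <- matrix(0, n, m)
    ua <- if (is.null(labels_a)) 0L else unique(labels_a)
    ub <- if (is.null(labels_b)) 0L else unique(labels_b)
    for (la in ua) {
      ia <- if (is.null(labels_a)) seq_len(n) else which(labels_a == la)
      for (lb in ub) {
        ib <- if (is.null(labels_b)) seq_len(m) else which(labels_b == lb)
        sc <- if (la == 0L) params$scales[lb, ]
              else if (lb == 0L) params$scales[la, ]
              else pair_kernel_scales(la, lb, params)
        K[ia, ib] <- plain(ia, ib, sc)
      }
    }
  }
  if (!is.null(cutoffs_a) && !is.null(cutoffs_b)) {
    cbar <- outer(cutoffs_a, cutoffs_b, "+") / 2
    K <- K * sigmoid(-params$tau * (K - cbar))
  }
  if (!is.null(slides_a) && !is.null(slides_b)) {
    K <- K * outer(slides_a, slides_b, "==")
  }
  K
}
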