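#' Energy distance between two sets of expression profiles
#'
#' `E(X,Y) = 2/(NM) sum_ij ||x_i - y_j|| - 1/N^2 sum_ij ||x_i - x_j||
#'  - 1/M^2 sum_ij ||y_i - y_j||` with Euclidean norms; zero for
#' identical multisets, symmetric, non-negative in expectation. Any log
#' transform is applied only at reporting time.
#'
#' @param X,Y numeric matrices (rows = profiles) with equal column
#'   count; vectors are treated as single-column matrices.
#' @return scalar energy distance.
#' @export
e_distance <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty profile set")
  if (ncol(X) != ncol(Y)) stop("profile dimensionalities differ")
  n <- nrow(X); m <- nrow(Y)
  D <- as.matrix(stats::dist(rbind(X, Y)))
  xy <- D[seq_len(n), n + seq_len(m), drop = FALSE]
  xx <- D[seq_len(n), seq_len(n), drop = FALSE]
  yy <- D[n + seq_len(m), n + seq_len(m), drop = FALSE]
  2 * mean(xy) - mean(xx) - mean(yy)
}

check_pair <- function(x, y, min_len = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < min_len) stop(sprintf("need at least %d values", min_len))
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum (y - x)^2 / sum (y - mean(y))^2` of predictions `x`
#' against truth `y`.
#'
#' @param x predicted values; @param y true values.
#' @return scalar (at most 1; can be negative).
#' @export
score_r2 <- function(x, y) {
  check_pair(x, y)
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop("degenerate truth: zero variance in y")
  1 - sum((y - x)^2) / ss
}

#' Pearson correlation
#' @inheritParams score_r2
#' @return scalar in [-1, 1].
#' @export
score_pcc <- function(x, y) {
  check_pair(x, y, min_len = 3)
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("degenerate input: zero variance")
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' Mean absolute error
#' @inheritParams score_r2
#' @return non-negative scalar.
#' @export
score_mae <- function(x, y) {
  check_pair(x, y, min_len = 1)
  mean(abs(y - x))
}

#' Rank scores across methods and tests
#'
#' Per test, methods are ranked from worst to best (higher rank =
#' better; ties get average ranks; missing entries rank worst with a
#' warning). Returns both the mean rank per method and its reciprocal.
#'
#' @param table numeric matrix methods x tests of a metric.
#' @param higher_better does a larger metric value mean better?
#' @return data frame with `method`, `mean_rank`, `reciprocal_rank`.
#' @export
rank_score <- function(table, higher_better = TRUE) {
  table <- as.matrix(table)
  if (anyNA(table)) {
    warning("missing entries ranked worst")
    worst <- if (higher_better) min(table, na.rm = TRUE) - 1
             else max(table, na.rm = TRUE) + 1
    table[is.na(table)] <- worst
  }
  ranks <- apply(table, 2, function(col) {
    rank(if (higher_better) col else -col, ties.method = "average")
  })
  ranks <- matrix(ranks, nrow = nrow(table))
  mr <- rowMeans(ranks)
  data.frame(method = if (!is.null(rownames(table))) rownames(table)
             else paste0("method", seq_len(nrow(table))),
             mean_rank = mr, reciprocal_rank = 1 / mr,
             row.names = NULL)
}
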