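#' Participation ratio of a feature representation
#'
#' Effective number of feature dimensions carrying variance:
#' `PR = (sum(lambda))^2 / sum(lambda^2)` over the eigenvalues `lambda` of
#' the (mean-subtracted) feature covariance. `PR = 1` when all variance is
#' concentrated in a single feature; `PR = N` when the covariance is
#' isotropic in `N` dimensions.
#'
#' @param activations A `samples x N` numeric matrix (at least 2 rows).
#' @return A single number in `[1, N]`.
#' @examples
#' x <- matrix(rnorm(200), 100, 2) %*% diag(c(2, 1))
#' participation_ratio(x)
#' @export
participation_ratio <- function(activations) {
  x <- as.matrix(activations)
  stop_field(nrow(x) >= 2, "activations", "needs at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  d2 <- svd(xc, nu = 0, nv = 0)$d^2  # proportional to covariance eigenvalues
  tot <- sum(d2)
  if (tot <= 0) stop("zero total variance: participation ratio undefined",
                     call. = FALSE)
  tot^2 / sum(d2^2)
}

#' Number of dimensions needed to explain a variance fraction
#'
#' @param activations A `samples x N` numeric matrix.
#' @param fraction Target fraction of total variance, in `(0, 1)`.
#' @return Smallest integer `k` such that the top-`k` covariance eigenvalues
#'   sum to at least `fraction` of the total variance.
#' @export
explained_variance_dims <- function(activations, fraction = 0.9) {
  check_scalar(fraction, "fraction", 1e-12, 1 - 1e-12)
  x <- as.matrix(activations)
  stop_field(nrow(x) >= 2, "activations", "needs at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  d2 <- svd(xc, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) stop("zero total variance", call. = FALSE)
  cum <- cumsum(sort(d2, decreasing = TRUE)) / tot
  as.integer(which(cum >= fraction - 1e-12)[1])
}

#' Mean absolute pairwise correlation between manifold centers
#'
#' Manifold centers are the per-manifold means of the feature points with the
#' global mean (over all centers) subtracted. Returns the mean of
#' `|Pearson correlation|` over all `P(P-1)/2` center pairs; low values
#' indicate decorrelated, spread-out manifolds.
#'
#' @param manifolds A [manifold_set()].
#' @return A single number in `[0, 1]`.
#' @export
center_correlation <- function(manifolds) {
  stopifnot(inherits(manifolds, "manifold_set"))
  pts <- manifolds$points
  P <- dim(pts)[1]
  stop_field(P >= 2, "manifolds", "needs at least 2 manifolds")
  centers <- apply(pts, c(1, 3), mean)            # P x N
  centers <- sweep(centers, 2, colMeans(centers)) # subtract global mean
  sds <- apply(centers, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance center vector: correlation undefined", call. = FALSE)
  cc <- stats::cor(t(centers))
  mean(abs(cc[lower.tri(cc)]))
}

#' Construct a manifold set
#'
#' A manifold set holds `P` object manifolds of `M` examples each, embedded
#' in an `N`-dimensional feature space, as produced by [build_manifolds()] or
#' directly from an array.
#'
#' @param points A `P x M x N` numeric array.
#' @param task Character label of the generating task (e.g. `"translation"`).
#' @param layer_name Name of the network layer the features came from.
#' @param labels Optional length-`P` manifold identities.
#' @return An object of class `"manifold_set"`.
#' @export
manifold_set <- function(points, task = "generic", layer_name = "features",
                         labels = NULL) {
  stop_field(is.array(points) && length(dim(points)) == 3, "points",
             "must be a P x M x N array")
  d <- dim(points)
  stop_field(d[3] >= 2, "points", "needs N >= 2 features")
  if (is.null(labels)) labels <- seq_len(d[1])
  stop_field(length(labels) == d[1], "labels", "must have length P")
  structure(list(points = points, task = task, layer_name = layer_name,
                 labels = labels),
            class = "manifold_set")
}

#' @export
print.manifold_set <- function(x, ...) {
  d <- dim(x$points)
  cat(sprintf("<manifold_set> P=%d manifolds, M=%d examples, N=%d features (%s, layer %s)\n",
              d[1], d[2], d[3], x$task, x$layer_name))
  invisible(x)
}

# flatten a manifold set to (P*M) x N with a manifold index per row
manifold_flatten <- function(manifolds) {
  d <- dim(manifolds$points)
  X <- matrix(aperm(manifolds$points, c(2, 1, 3)), nrow = d[1] * d[2])
  list(X = X, manifold = rep(seq_len(d[1]), each = d[2]),
       P = d[1], M = d[2], N = d[3])
}
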