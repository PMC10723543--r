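# Linear separability of labeled points, decided by minimizing the convex
# squared-hinge loss sum(max(0, 1 - y*(Xw + b))^2) with L-BFGS. The loss is
# zero iff the data are separable with margin, and a labeling is declared
# separable iff the minimizer classifies every point correctly (strict
# margins > 0), i.e. a zero-misclassification linear separator was found.
linear_separable <- function(X, y, maxit = 1000L) {
  n <- nrow(X); N <- ncol(X)
  yx <- X * y  # row-scaled
  fn <- function(par) {
    m <- 1 - (drop(yx %*% par[seq_len(N)]) + y * par[N + 1])
    sum(pmax(m, 0)^2)
  }
  gr <- function(par) {
    m <- 1 - (drop(yx %*% par[seq_len(N)]) + y * par[N + 1])
    a <- -2 * pmax(m, 0)
    c(drop(crossprod(yx, a)), sum(a * y))
  }
  res <- stats::optim(numeric(N + 1), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  marg <- drop(yx %*% res$par[seq_len(N)]) + y * res$par[N + 1]
  all(marg > 0)
}

# balanced +/-1 labeling of P manifolds
balanced_dichotomy <- function(P) {
  y <- rep(-1, P)
  y[sample.int(P, floor(P / 2))] <- 1
  y
}

# Gaussian random projection of rows of X to n_dims (seeded by caller's RNG)
gaussian_project <- function(X, n_dims) {
  if (n_dims >= ncol(X)) return(X)
  G <- matrix(stats::rnorm(ncol(X) * n_dims, sd = 1 / sqrt(n_dims)),
              ncol(X), n_dims)
  X %*% G
}

# Fraction of random balanced manifold dichotomies separable at feature
# dimension n_dims. Reuses a fixed list of dichotomies; `early` stops as soon
# as the side of `target` is decided (used inside the bisection).
separable_fraction <- function(X, manifold, P, dichotomies, n_dims,
                               proj_seed, early = FALSE, target = 0.5) {
  Xp <- with_seed(proj_seed, gaussian_project(X, n_dims))
  n <- length(dichotomies)
  need <- floor(n * target) + 1L   # successes needed for frac > target
  succ <- 0L; fail <- 0L
  for (k in seq_len(n)) {
    y <- dichotomies[[k]][manifold]
    if (linear_separable(Xp, y)) succ <- succ + 1L else fail <- fail + 1L
    if (early && (succ >= need || fail > n - need)) break
  }
  if (early) return(list(decided_above = succ >= need, frac = succ / (succ + fail)))
  list(decided_above = succ / n > target, frac = succ / n)
}

#' Empirical (simulation) capacity of a manifold set
#'
#' Measures the ground-truth linear separability transition of `P` object
#' manifolds: for a candidate feature dimension `N`, the points are reduced
#' by a seeded Gaussian random projection to `N` dimensions and the fraction
#' of random balanced manifold-level dichotomies that are separable by a
#' zero-error linear hyperplane (with bias) is computed; the critical
#' dimension `N_c` where this fraction crosses 0.5 is located by bisection
#' and refined by linear interpolation between the bracketing dimensions.
#' The simulation capacity is `alpha_sim = P / N_c`.
#'
#' @param manifolds A [manifold_set()] (`P >= 4`).
#' @param n_dichotomies Number of random balanced dichotomies per candidate
#'   dimension (at least 20; default 50).
#' @param seed Integer seed controlling dichotomies and projections.
#' @param n_max Optional cap on the largest candidate dimension (defaults to
#'   the ambient feature dimension).
#' @return A list of class `"capacity_estimate"` with elements `alpha_sim`,
#'   `N_c`, `P`, `M`, `n_dichotomies` and `separability_curve` (a data frame
#'   of evaluated dimensions and separable fractions).
#' @examples
#' \donttest{
#' pts <- array(rnorm(20 * 1 * 60), c(20, 1, 60))
#' simulation_capacity(manifold_set(pts), n_dichotomies = 20, seed = 1)
#' }
#' @export
simulation_capacity <- function(manifolds, n_dichotomies = 50L, seed = 1L,
                                n_max = NULL) {
  stopifnot(inherits(manifolds, "manifold_set"))
  check_scalar(n_dichotomies, "n_dichotomies", 20, Inf, integer = TRUE)
  fl <- manifold_flatten(manifolds)
  stop_field(fl$P >= 4, "manifolds", "needs P >= 4 manifolds")
  if (is.null(n_max)) n_max <- fl$N
  n_max <- min(n_max, fl$N)
  dichotomies <- with_seed(derive_seed(seed, 1), {
    replicate(n_dichotomies, balanced_dichotomy(fl$P), simplify = FALSE)
  })
  frac_cache <- new.env(parent = emptyenv())
  eval_frac <- function(n_dims, early) {
    key <- as.character(n_dims)
    if (!early && !is.null(frac_cache[[key]]) && frac_cache[[key]]$full)
      return(frac_cache[[key]]$res)
    res <- separable_fraction(fl$X, fl$manifold, fl$P, dichotomies, n_dims,
                              proj_seed = derive_seed(seed, 100 + n_dims),
                              early = early)
    if (!early) frac_cache[[key]] <- list(res = res, full = TRUE)
    res
  }
  hi <- n_max
  res_hi <- eval_frac(hi, early = FALSE)
  if (!res_hi$decided_above)
    stop(sprintf(paste0("separable fraction at the ambient dimension N=%d is ",
                        "%.2f <= 0.5: no bracket for the 0.5 crossing"),
                 hi, res_hi$frac), call. = FALSE)
  lo <- 1L
  res_lo <- eval_frac(lo, early = FALSE)
  curve <- data.frame(n_dims = c(lo, hi), frac = c(res_lo$frac, res_hi$frac))
  if (res_lo$decided_above) {
    # even one dimension suffices more than half the time: N_c <= 1
    est <- structure(list(alpha_sim = fl$P / 1, N_c = 1, P = fl$P, M = fl$M,
                          n_dichotomies = n_dichotomies,
                          separability_curve = curve),
                     class = "capacity_estimate")
    return(est)
  }
  while (hi - lo > 1L) {
    mid <- as.integer(floor((lo + hi) / 2))
    r <- eval_frac(mid, early = TRUE)
    if (r$decided_above) hi <- mid else lo <- mid
  }
  # full evaluations at the bracketing dimensions for the interpolation
  r_lo <- eval_frac(lo, early = FALSE)
  r_hi <- eval_frac(hi, early = FALSE)
  # widen if the full evaluations disagree with the early-stopped decisions
  while (r_lo$frac > 0.5 && lo > 1L) {
    hi <- lo; r_hi <- r_lo
    lo <- max(1L, lo - max(1L, as.integer(0.05 * lo)))
    r_lo <- eval_frac(lo, early = FALSE)
  }
  while (r_hi$frac < 0.5 && hi < n_max) {
    lo <- hi; r_lo <- r_hi
    hi <- min(n_max, hi + max(1L, as.integer(0.05 * hi)))
    r_hi <- eval_frac(hi, early = FALSE)
  }
  curve <- unique(rbind(curve,
                        data.frame(n_dims = c(lo, hi),
                                   frac = c(r_lo$frac, r_hi$frac))))
  curve <- curve[order(curve$n_dims), , drop = FALSE]
  N_c <- if (abs(r_hi$frac - r_lo$frac) < 1e-12) (lo + hi) / 2
         else lo + (0.5 - r_lo$frac) * (hi - lo) / (r_hi$frac - r_lo$frac)
  structure(list(alpha_sim = fl$P / N_c, N_c = N_c, P = fl$P, M = fl$M,
                 n_dichotomies = n_dichotomies, separability_curve = curve),
            class = "capacity_estimate")
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat(sprintf("<capacity_estimate> alpha_sim = %.4f (P=%d, M=%d, N_c=%.1f, %d dichotomies)\n",
              x$alpha_sim, x$P, x$M, x$N_c, x$n_dichotomies))
  invisible(x)
}
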