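# Solve min_v ||v - t||^2  s.t.  t(S) %*% v <= -kappa  through its dual:
# min_{a >= 0} 1/2 a' G a - a' (S't + kappa), G = S'S, v = t - S a.
# Cyclic coordinate descent; after center normalization every point has unit
# last coordinate so G_ii >= 1 and the updates are well defined.
qp_anchor <- function(S, t, kappa = 0, tol = 1e-10, max_sweeps = 1000L) {
  m <- ncol(S)
  G <- crossprod(S)
  b <- drop(crossprod(S, t)) + kappa
  a <- numeric(m)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (i in seq_len(m)) {
      ai_new <- max(0, (b[i] - sum(G[i, ] * a) + G[i, i] * a[i]) / G[i, i])
      delta <- max(delta, abs(ai_new - a[i]))
      a[i] <- ai_new
    }
    if (delta < tol) break
  }
  v <- t - drop(S %*% a)
  list(alpha = a, v = v, lambda = sqrt(sum((t - v)^2)))
}

#' Mean-field manifold capacity, dimension and radius
#'
#' Implements the point-cloud mean-field analysis of linear manifold
#' classification. After subtracting the global mean, each manifold is
#' represented in the subspace spanned by its centered points plus its center
#' direction, with coordinates normalized by the center norm so the center
#' maps to the unit vector along the last axis. For each of
#' `n_gaussian_samples` Gaussian direction vectors `t` drawn in this
#' `(D+1)`-dimensional subspace, the convex program
#' `min ||v - t||^2 s.t. v's_j <= -kappa` yields the anchor point
#' `s_tilde = S a / sum(a)` — the convex-hull point entering the margin
#' constraint. The per-manifold quantities are:
#' \describe{
#'   \item{capacity `alpha_c`}{`1 / mean(lambda^2)` with
#'     `lambda = ||t - v||` (zero when all constraints hold at `v = t`);
#'     bounded between `2/M` and `2`;}
#'   \item{radius `R_M`}{root-mean-square norm of the anchor component
#'     orthogonal to the center, in center-normalized units;}
#'   \item{dimension `D_M`}{mean squared alignment `(t . s_hat)^2` of the
#'     Gaussian vector with the unit anchor direction in the manifold axes.}
#' }
#' The summary capacity over manifolds is the inverse of the mean inverse
#' capacity.
#'
#' @param manifolds A [manifold_set()].
#' @param n_gaussian_samples Number of Gaussian direction samples per
#'   manifold (default 200).
#' @param kappa Classification margin (default 0).
#' @param seed Integer seed for the Gaussian samples.
#' @return A list of class `"manifold_geometry"` with per-manifold vectors
#'   `alpha_c`, `D_M`, `R_M` and scalar summaries `alpha_c_mean` (inverse
#'   mean inverse), `D_M_mean`, `R_M_mean`.
#' @examples
#' pts <- array(rnorm(10 * 5 * 50), c(10, 5, 50))
#' meanfield_geometry(manifold_set(pts), n_gaussian_samples = 50, seed = 1)
#' @export
meanfield_geometry <- function(manifolds, n_gaussian_samples = 200L,
                               kappa = 0, seed = 1L) {
  stopifnot(inherits(manifolds, "manifold_set"))
  check_scalar(n_gaussian_samples, "n_gaussian_samples", 10, Inf,
               integer = TRUE)
  check_scalar(kappa, "kappa", 0, Inf)
  pts <- manifolds$points
  P <- dim(pts)[1]; M <- dim(pts)[2]; N <- dim(pts)[3]
  # center by the global mean over all points
  gmean <- apply(pts, 3, mean)
  alpha_inv <- numeric(P); D_M <- numeric(P); R_M <- numeric(P)
  fail <- character(0)
  for (p in seq_len(P)) {
    Xp <- matrix(pts[p, , ], nrow = M) # M x N
    Xp <- sweep(Xp, 2, gmean)
    cen <- colMeans(Xp)
    cn <- sqrt(sum(cen^2))
    Rres <- sweep(Xp, 2, cen)          # M x N residuals
    sv <- svd(Rres)
    rk <- sum(sv$d > max(sv$d[1], 1) * 1e-10)
    if (rk > 0) {
      coords <- sv$u[, seq_len(rk), drop = FALSE] %*%
        diag(sv$d[seq_len(rk)], rk)    # M x D coordinates in manifold axes
    } else {
      coords <- matrix(0, M, 0)
    }
    D <- ncol(coords)
    scale_cn <- max(cn, 1e-12)
    S <- t(cbind(coords / scale_cn, rep(1, M)))  # (D+1) x M, center -> e_{D+1}
    res <- with_seed(derive_seed(seed, p), {
      tvecs <- matrix(stats::rnorm((D + 1) * n_gaussian_samples),
                      D + 1, n_gaussian_samples)
      lam2 <- numeric(n_gaussian_samples)
      dsamp <- numeric(n_gaussian_samples)
      rsamp <- numeric(n_gaussian_samples)
      for (k in seq_len(n_gaussian_samples)) {
        tv <- tvecs[, k]
        proj <- drop(crossprod(S, tv))
        if (max(proj) + kappa <= 0) {
          # all margin constraints already satisfied at v = t
          lam2[k] <- 0
          anchor <- S[, which.max(proj)]
        } else {
          qp <- qp_anchor(S, tv, kappa = kappa)
          lam2[k] <- qp$lambda^2
          ssum <- sum(qp$alpha)
          anchor <- if (ssum > 1e-12) drop(S %*% qp$alpha) / ssum
                    else S[, which.max(proj)]
        }
        aperp <- anchor[seq_len(D)]
        an <- sqrt(sum(aperp^2))
        rsamp[k] <- an / abs(anchor[D + 1])
        dsamp[k] <- if (an > 1e-12)
          (sum(tv[seq_len(D)] * aperp) / an)^2 else 0
      }
      list(alpha_inv = mean(lam2), D_M = mean(dsamp),
           R_M = sqrt(mean(rsamp^2)))
    })
    alpha_inv[p] <- res$alpha_inv
    D_M[p] <- res$D_M
    R_M[p] <- res$R_M
  }
  alpha_c <- ifelse(alpha_inv > 0, 1 / alpha_inv, 2)
  structure(list(alpha_c = alpha_c, D_M = D_M, R_M = R_M,
                 alpha_c_mean = 1 / mean(alpha_inv[alpha_inv > 0], na.rm = TRUE),
                 D_M_mean = mean(D_M), R_M_mean = mean(R_M),
                 n_gaussian_samples = n_gaussian_samples, kappa = kappa,
                 seed = seed),
            class = "manifold_geometry")
}

#' @export
print.manifold_geometry <- function(x, ...) {
  cat(sprintf("<manifold_geometry> alpha_c = %.4f, D_M = %.3f, R_M = %.3f (%d manifolds)\n",
              x$alpha_c_mean, x$D_M_mean, x$R_M_mean, length(x$alpha_c)))
  invisible(x)
}
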