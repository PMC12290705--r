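# Phase-coupling optimization (PCO): in the whitened SSD space, find real
# spatial filters w whose projected analytic signal w'y_t is maximally
# phase-coupled to the audio z, as measured by the mean vector length
#   MVL(w) = | (1/Ns) * sum_t z_t * (w'y_t)/|w'y_t| |.
# The objective is scale-invariant in w and nonconvex; each component is the
# best of several seeded quasi-Newton ascents from random unit starts, and
# later components are restricted to the orthogonal complement of the ones
# already found (deflation).

#' Analytic signal (rowwise)
#'
#' Returns `x + i * Hilbert(x)` for a vector or for each row of a matrix.
#'
#' @param X real vector or channels x samples matrix; length at least 8.
#' @return complex data of the same shape.
#' @export
analytic_signal <- function(X) {
  if (is.null(dim(X))) return(analytic_vector(X))
  t(apply(X, 1, analytic_vector))
}

#' Mean vector length between a projected analytic signal and a target
#'
#' @param w real filter vector (length k).
#' @param Y k x samples complex analytic data.
#' @param z real target signal (z-scored by convention), same length.
#' @param eps guard added to the projection amplitude to avoid division by
#'   zero.
#' @return nonnegative scalar.
#' @export
mvl <- function(w, Y, z, eps = 1e-12) {
  stopifnot(length(w) == nrow(Y), ncol(Y) == length(z))
  p <- as.vector(w %*% Y)
  ap <- Mod(p)
  if (all(ap < eps)) stop("all-zero projection")
  u <- p / (ap + eps)
  Mod(mean(z * u))
}

# Analytic gradient of mvl() with respect to w.
mvl_grad <- function(w, Y, z, eps = 1e-12) {
  ns <- ncol(Y)
  p <- as.vector(w %*% Y)
  ap <- Mod(p) + eps
  u <- p / ap
  V <- mean(z * u)
  if (Mod(V) < 1e-300) return(numeric(length(w)))
  a1 <- Y %*% (z / ap)
  cc <- z * p / ap^3
  R <- Re(Y * matrix(Conj(p), nrow(Y), ns, byrow = TRUE))
  a2 <- R %*% cc
  dV <- (a1 - a2) / ns
  as.vector(Re(Conj(V) * dV) / Mod(V))
}

# Orthonormal basis of the columns of B after removing the direction w.
deflate_basis <- function(B, w) {
  P <- diag(length(w)) - tcrossprod(w)
  M <- P %*% B
  sv <- svd(M)
  keep <- sv$d > 1e-10 * max(sv$d, 1e-300)
  sv$u[, keep, drop = FALSE]
}

#' Fit a phase-coupling optimization model
#'
#' Whitens the real part of `Y_ssd` (PCA whitening, rank-truncated at
#' condition 1e8), then extracts components sequentially: each is the best
#' of `n_restarts` BFGS maximizations of the mean vector length from random
#' unit starts, with later searches confined to the orthogonal complement of
#' the filters already found. Filters are returned sorted by achieved MVL.
#'
#' @param Y_ssd k x samples complex analytic data in SSD space.
#' @param z z-scored target signal (the produced audio), same length.
#' @param n_restarts random restarts per component.
#' @param seed integer seed; the fit is deterministic given it.
#' @param maxit,reltol BFGS iteration cap and relative convergence tolerance.
#' @return an object of class `pco_model` with `W` (filters in columns, in
#'   the whitened space), `mvls` (sorted descending), `M_white` (whitening
#'   matrix, rank x k), `n_restarts`, `seed`.
#' @export
fit_pco <- function(Y_ssd, z, n_restarts = 10, seed = 1,
                    maxit = 500, reltol = 1e-10) {
  Y_ssd <- as.matrix(Y_ssd)
  k <- nrow(Y_ssd)
  ns <- ncol(Y_ssd)
  stopifnot(ns == length(z), k >= 1)
  Xr <- Re(Y_ssd)
  C <- tcrossprod(Xr) / ns
  ec <- eigen(C, symmetric = TRUE)
  keep <- ec$values > max(ec$values) * 1e-8
  r <- sum(keep)
  M <- diag(1 / sqrt(ec$values[keep]), r) %*%
    t(ec$vectors[, keep, drop = FALSE])
  Yw <- M %*% Y_ssd
  W <- matrix(0, r, r)
  mvls <- numeric(r)
  starts <- with_seed(seed, lapply(seq_len(r), function(i) {
    matrix(stats::rnorm(n_restarts * (r - i + 1)), ncol = n_restarts)
  }))
  B <- diag(r)
  for (i in seq_len(r)) {
    dim_i <- ncol(B)
    if (dim_i == 1) {
      w <- as.vector(B)
      best_val <- mvl(w, Yw, z)
    } else {
      best_val <- -Inf
      best_v <- NULL
      for (j in seq_len(n_restarts)) {
        v0 <- starts[[i]][seq_len(dim_i), j]
        v0 <- v0 / sqrt(sum(v0^2))
        fit <- stats::optim(
          v0,
          fn = function(v) mvl(as.vector(B %*% v), Yw, z),
          gr = function(v) as.vector(crossprod(B, mvl_grad(as.vector(B %*% v), Yw, z))),
          method = "BFGS",
          control = list(fnscale = -1, maxit = maxit, reltol = reltol)
        )
        if (!is.finite(fit$value)) stop("non-finite PCO objective")
        if (fit$value > best_val) {
          best_val <- fit$value
          best_v <- fit$par
        }
      }
      w <- as.vector(B %*% best_v)
      w <- w / sqrt(sum(w^2))
      best_val <- mvl(w, Yw, z)
    }
    W[, i] <- w
    mvls[i] <- best_val
    if (i < r) B <- deflate_basis(B, w)
  }
  ord <- order(mvls, decreasing = TRUE)
  structure(list(W = W[, ord, drop = FALSE], mvls = mvls[ord],
                 M_white = M, n_restarts = n_restarts,
                 seed = as.integer(seed)),
            class = "pco_model")
}

#' Select the number of artifactual components from the MVL trace
#'
#' The elbow is the point of maximum curvature of the descending MVL trace:
#' `m` is the index just before the largest discrete second difference,
#' clamped to `[1, k - 1]`; with two or fewer components, `m = 1`.
#'
#' @param mvls MVL values sorted descending.
#' @param method `"elbow"` (default) or `"fixed"`.
#' @param m fixed component count when `method = "fixed"`.
#' @return an object of class `artifact_selection` with fields `m`, `method`.
#' @export
select_artifact_components <- function(mvls, method = c("elbow", "fixed"),
                                       m = NULL) {
  method <- match.arg(method)
  k <- length(mvls)
  stopifnot(k >= 1)
  if (method == "fixed") {
    stopifnot(!is.null(m), m >= 1, m <= k)
    return(structure(list(m = as.integer(m), method = "fixed"),
                     class = "artifact_selection"))
  }
  if (k <= 2) {
    m_sel <- 1L
  } else {
    inner <- 2:(k - 1)
    d2 <- mvls[inner - 1] - 2 * mvls[inner] + mvls[inner + 1]
    m_sel <- inner[which.max(d2)] - 1L
    m_sel <- as.integer(min(max(m_sel, 1L), k - 1L))
  }
  structure(list(m = m_sel, method = "elbow"), class = "artifact_selection")
}

#' @export
print.pco_model <- function(x, ...) {
  cat(sprintf("<pco_model> %d components, %d restarts, seed %d\n",
              ncol(x$W), x$n_restarts, x$seed))
  cat("MVL:", paste(signif(x$mvls, 3), collapse = ", "), "\n")
  invisible(x)
}
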