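#' Photon-statistics correlation matrix O
#'
#' Under independent, identically blinking emitters the emitter-by-emitter
#' second-moment matrix of per-frame photon counts is
#' `O = sigma^2 I + mu^2 J` (J the all-ones matrix): diagonal entries
#' `sigma^2 + mu^2`, off-diagonal `mu^2`. Its eigenvalues are available in
#' closed form: `sigma^2 + M mu^2` (once, eigenvector proportional to the
#' all-ones vector) and `sigma^2` (multiplicity `M - 1`).
#'
#' @param M number of emitters (>= 1).
#' @param mu mean per-frame photon count.
#' @param sigma standard deviation of the per-frame photon count (> 0).
#' @return An object of class `o_matrix` with the realized matrix and
#'   closed-form eigenvalues.
#' @export
o_matrix <- function(M, mu, sigma) {
  if (M < 1) stop("'M' must be >= 1")
  if (sigma <= 0) stop("'sigma' must be > 0")
  O <- matrix(mu^2, M, M)
  diag(O) <- sigma^2 + mu^2
  structure(list(O = O, M = M, mu = mu, sigma = sigma,
                 eigenvalues = c(sigma^2 + M * mu^2,
                                 rep(sigma^2, M - 1))),
            class = "o_matrix")
}

#' Blinking-statistics weights of the component decomposition
#'
#' `c1 = K M (sigma^2 + M mu^2)` weights the mean-image component and
#' `c2 = K (M - 1) sigma^2` weights the fluctuation components. `c2/c1 < 1`
#' always, so the mean image dominates every stack; the closer `c2/c1` is to
#' 1 (small `mu^2/sigma^2`, few emitters), the more favourable the stack is
#' for super-resolution.
#'
#' @param K number of frames.
#' @param M number of emitters.
#' @param mu,sigma per-frame photon-count mean and standard deviation.
#' @return list with `c1`, `c2` and their ratio `c2/c1`.
#' @export
blink_coefficients <- function(K, M, mu, sigma) {
  if (K < 1 || M < 1) stop("'K' and 'M' must be >= 1")
  c1 <- K * M * (sigma^2 + M * mu^2)
  c2 <- K * (M - 1) * sigma^2
  list(c1 = c1, c2 = c2, ratio = c2 / c1)
}

#' Spatial component matrices C1, C2, C3
#'
#' Decomposes the spatial content of the stack correlation matrix:
#' \itemize{
#'   \item `C1 = G~ G~' / M^2` — the outer product of the mean image with
#'     itself (rank 1; contrast enhancement, no extra resolution),
#'   \item `C2 = sum_m g_m g_m' / M` — cross-pixel auto-emitter second
#'     moments (effective PSF is the squared optical PSF, sqrt(2) sharper),
#'   \item `C3 = sum_{m' != m} g_m' g_m' / (M (M-1))` — cross-pixel
#'     cross-emitter second moments (sharpening over both pixels and
#'     emitters).
#' }
#' They satisfy the exact identity `M C1 = C2 + (M - 1) C3`. For `M = 1`,
#' `C3` is undefined (its normalizer vanishes) and is returned as `NULL`.
#'
#' @param G a `system_matrix` or `N x M` matrix.
#' @param K number of frames used for the weights (metadata).
#' @param mu,sigma photon statistics used for the weights (metadata).
#' @return An object of class `component_set` with `C1`, `C2`, `C3`, the
#'   weights `c1`, `c2` (when `mu`, `sigma` are given) and metadata.
#' @export
compute_components <- function(G, K = NULL, mu = NULL, sigma = NULL) {
  Gm <- as_G(G)
  M <- ncol(Gm)
  gt <- rowSums(Gm)
  C1 <- tcrossprod(gt) / M^2
  C2 <- tcrossprod(Gm) / M
  C3 <- if (M >= 2) (tcrossprod(gt) - tcrossprod(Gm)) / (M * (M - 1)) else NULL
  co <- if (!is.null(K) && !is.null(mu) && !is.null(sigma))
    blink_coefficients(K, M, mu, sigma) else NULL
  structure(list(C1 = C1, C2 = C2, C3 = C3,
                 c1 = co$c1, c2 = co$c2,
                 M = M, K = K, mu = mu, sigma = sigma,
                 mean_image = gt, G = Gm),
            class = "component_set")
}

#' Reconstruct the stack correlation matrix from its components
#'
#' Returns `c1 C1 + c2 (C2 - C3)`, which equals `K G O G'` exactly.
#'
#' @param components a `component_set` built with `K`, `mu`, `sigma`.
#' @return `N x N` symmetric positive semi-definite matrix.
#' @export
reconstruct_J <- function(components) {
  stopifnot(inherits(components, "component_set"))
  if (is.null(components$C3))
    stop("C3 is undefined for a single emitter; J cannot be reconstructed")
  if (is.null(components$c1))
    stop("the component set carries no K/mu/sigma; rebuild with them")
  components$c1 * components$C1 +
    components$c2 * (components$C2 - components$C3)
}

#' Empirical stack correlation matrix
#'
#' The Gram matrix `J = I I'` of the measured (or simulated) stack.
#'
#' @param stack an `image_stack` or `N x K` matrix.
#' @return `N x N` matrix.
#' @export
empirical_J <- function(stack) {
  I <- if (inherits(stack, "image_stack")) stack$I else as.matrix(stack)
  tcrossprod(I)
}

#' Maximum entry of a matrix
#'
#' The "magnitude" used to compare the relative strengths of the component
#' matrices across emitter separations.
#'
#' @param A numeric matrix.
#' @export
matrix_magnitude <- function(A) max(A)

#' Numerical rank at a relative eigenvalue threshold
#'
#' Number of singular values at least `tol` times the largest (singular
#' values of the symmetrized matrix, i.e. absolute eigenvalues).
#'
#' @param A numeric matrix.
#' @param tol relative threshold (default 1e-10).
#' @export
numerical_rank <- function(A, tol = 1e-10) {
  s <- svd((A + t(A)) / 2, nu = 0, nv = 0)$d
  sum(s >= tol * s[1])
}

#' Summary report of a component decomposition
#'
#' Collects the weights, magnitudes, numerical ranks and the residual of the
#' identity `M C1 - C2 - (M - 1) C3` into a JSON-serializable list.
#'
#' @param components a `component_set`.
#' @param rank_tol relative rank threshold.
#' @export
component_report <- function(components, rank_tol = 1e-10) {
  x <- components
  res <- if (!is.null(x$C3))
    max(abs(x$M * x$C1 - x$C2 - (x$M - 1) * x$C3)) else NA_real_
  list(M = x$M, K = x$K, mu = x$mu, sigma = x$sigma,
       c1 = x$c1, c2 = x$c2,
       magnitudes = list(C1 = matrix_magnitude(x$C1),
                         C2 = matrix_magnitude(x$C2),
                         C3 = if (is.null(x$C3)) NA_real_
                              else matrix_magnitude(x$C3),
                         C2_minus_C3 = if (is.null(x$C3)) NA_real_
                              else matrix_magnitude(x$C2 - x$C3)),
       ranks = list(C1 = numerical_rank(x$C1, rank_tol),
                    C2 = numerical_rank(x$C2, rank_tol),
                    C3 = if (is.null(x$C3)) NA_integer_
                         else numerical_rank(x$C3, rank_tol)),
       rank_tol = rank_tol,
       identity_residual = res)
}

#' @export
print.component_set <- function(x, ...) {
  cat("Component set: M =", x$M, "emitters, N =", nrow(x$C1), "pixels\n")
  if (!is.null(x$c1))
    cat(sprintf("  c1 = %.4g, c2 = %.4g (c2/c1 = %.4g)\n",
                x$c1, x$c2, x$c2 / x$c1))
  cat(sprintf("  magnitudes: C1 %.4g, C2 %.4g%s\n",
              matrix_magnitude(x$C1), matrix_magnitude(x$C2),
              if (!is.null(x$C3))
                sprintf(", C3 %.4g", matrix_magnitude(x$C3)) else ""))
  invisible(x)
}
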