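#' Eigenimages of a stack-correlation or component matrix
#'
#' Eigen-decomposition of a symmetric matrix with the eigenvectors
#' interpreted as images. Singular values are the square roots of the
#' absolute eigenvalues (the cross-emitter component C3 is indefinite),
#' sorted descending.
#'
#' Forming a component matrix squares the conditioning of the underlying
#' emitter images, so for strongly sub-diffraction scenes the trailing
#' signal directions of e.g. `C2` fall below machine precision even though
#' they are well represented in `G` itself. Supplying `basis` (typically the
#' system matrix columns) computes the decomposition of `A` restricted to
#' that subspace via an orthonormal factor, which preserves those
#' directions; the orthogonal complement then has exactly zero singular
#' value.
#'
#' @param A symmetric `N x N` matrix. A non-symmetric input is symmetrized
#'   with a warning.
#' @param basis optional `N x m` matrix whose column space contains the
#'   signal subspace (e.g. `G`).
#' @return An object of class `subspaces` (pre-split): orthonormal
#'   eigenimages `u` (columns), singular values `s`, and the ambient
#'   dimension `N`.
#' @export
eigenimages <- function(A, basis = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("'A' must be a square matrix")
  if (max(abs(A - t(A))) > 1e-8 * max(abs(A))) {
    warning("'A' is not symmetric; symmetrizing")
  }
  As <- (A + t(A)) / 2
  if (is.null(basis)) {
    e <- eigen(As, symmetric = TRUE)
    s <- sqrt(abs(e$values))
    o <- order(-s)
    u <- e$vectors[, o, drop = FALSE]
    s <- s[o]
  } else {
    Q <- qr.Q(qr(basis))
    B <- crossprod(Q, As %*% Q)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    s <- sqrt(abs(e$values))
    o <- order(-s)
    u <- Q %*% e$vectors[, o, drop = FALSE]
    s <- s[o]
  }
  structure(list(u = u, s = s, N = nrow(As),
                 restricted = !is.null(basis)),
            class = "subspaces")
}

#' Split eigenimages into signal and null subspaces
#'
#' Partitions the eigenimages at a singular-value threshold `s0`: the signal
#' subspace S holds `s_j >= s0`, the null subspace N the rest (including,
#' implicitly, the orthogonal complement of a restricted decomposition,
#' whose singular values are zero). The leading eigenimage is always
#' assigned to S, whatever `s0`.
#'
#' Policies: `"eigengap"` places the split at the largest ratio
#' `s_j / s_{j+1}` among eligible indices (those with
#' `s_j >= floor_tol * s_1`, so gaps between numerically zero values are
#' ignored; singular values past the retained set count as zero);
#' `"rank"` keeps the leading `rank` eigenimages; `"threshold"` uses the
#' supplied `s0`.
#'
#' @param eig a `subspaces` object from [eigenimages()].
#' @param policy `"eigengap"`, `"rank"` or `"threshold"`.
#' @param rank signal rank for the `"rank"` policy.
#' @param s0 threshold for the `"threshold"` policy.
#' @param floor_tol relative floor below which singular values are treated
#'   as numerically zero (default 1e-10).
#' @return The input with `rank` (size of S) and `s0` filled in.
#' @export
split_subspaces <- function(eig, policy = c("eigengap", "rank", "threshold"),
                            rank = NULL, s0 = NULL, floor_tol = 1e-10) {
  stopifnot(inherits(eig, "subspaces"))
  policy <- match.arg(policy)
  s <- eig$s
  if (length(s) < 2 && eig$N <= length(s))
    stop("at least 2 eigenpairs are needed to split")
  r <- switch(policy,
    eigengap = {
      elig <- which(s >= floor_tol * s[1])
      # values beyond the retained set act as zeros, so the last eligible
      # index competes with a zero successor and wins unless an interior gap
      # is larger
      nxt <- c(s[-1], 0)
      ratios <- s[elig] / pmax(nxt[elig], .Machine$double.xmin)
      elig[which.max(ratios)]
    },
    rank = {
      if (is.null(rank)) stop("'rank' is required for the rank policy")
      min(rank, length(s))
    },
    threshold = {
      if (is.null(s0)) stop("'s0' is required for the threshold policy")
      max(1L, sum(s >= s0))   # leading eigenimage always in S
    })
  eig$rank <- as.integer(r)
  eig$s0 <- if (policy == "threshold") s0 else
    if (r < length(s)) mean(c(s[r], s[r + 1])) else s[r] / 2
  eig$policy <- policy
  eig
}

#' MUSIC pseudo-spectrum over a grid of test positions
#'
#' For every test position the image `g(r')` a hypothetical emitter would
#' produce is computed with the same pixel response as the system matrix,
#' and split into its projection onto the signal subspace,
#' `dPS = ||U_S' g||`, and the residual `dPN = ||g - U_S U_S' g||`
#' (the projection onto the null side, computed as an explicit residual so
#' that near-complete cancellation is resolved to machine precision). The
#' pseudo-spectrum is `f = (dPS / dPN)^alpha`; `dPN` is floored at `eps` to
#' keep `f` finite at exact emitter positions.
#'
#' @param sub a split `subspaces` object (see [split_subspaces()]).
#' @param grid the [pixel_grid()] the matrix lives on.
#' @param psf the [psf_model()] of the imaging system.
#' @param test numeric vector of test positions (nm).
#' @param alpha contrast exponent (the component-level studies use 1).
#' @param subsamples in-pixel subsamples for the test images.
#' @param eps floor for `dPN` (default 1e-12).
#' @return An object of class `pseudospectrum`: list with `test`, `f`,
#'   `dPS`, `dPN`, `alpha` and a flag for floored points.
#' @export
pseudospectrum <- function(sub, grid, psf = psf_model(), test,
                           alpha = 1, subsamples = 21, eps = 1e-12) {
  stopifnot(inherits(sub, "subspaces"))
  if (is.null(sub$rank)) stop("subspaces are not split; call split_subspaces()")
  if (alpha <= 0) stop("'alpha' must be positive")
  if (sub$rank >= sub$N)
    stop("the null subspace is empty; the pseudo-spectrum is undefined")
  Gtst <- emitter_image(test, grid, psf, subsamples)
  Us <- sub$u[, seq_len(sub$rank), drop = FALSE]
  proj <- crossprod(Us, Gtst)
  resid <- Gtst - Us %*% proj
  dPS <- sqrt(colSums(proj^2))
  dPN <- sqrt(colSums(resid^2))
  floored <- dPN < eps
  f <- (dPS / pmax(dPN, eps))^alpha
  structure(list(test = test, f = f, dPS = dPS, dPN = dPN,
                 alpha = alpha, rank = sub$rank, floored = floored),
            class = "pseudospectrum")
}

#' Count peaks of a pseudo-spectrum
#'
#' Strict local maxima of `f` within a window, retained when at least
#' `min_rel_height` times the window maximum AND prominent enough: the drop
#' from the peak to the highest saddle separating it from higher terrain
#' must reach `min_prominence` times the window maximum (ripples riding on a
#' broad hump are not peaks). Optionally, maxima closer than `min_sep` are
#' merged keeping the highest.
#'
#' @param ps a `pseudospectrum` (or numeric vector with `test` supplied).
#' @param window length-2 numeric range of positions to scan (default: all).
#' @param min_rel_height fraction of the window maximum a peak must reach.
#' @param min_prominence fraction of the window maximum a peak must rise
#'   above its surrounding saddles.
#' @param min_sep minimum separation between reported peaks (nm, 0 for no
#'   merging).
#' @param test test positions when `ps` is a plain vector.
#' @return list with `n` and the peak `positions`.
#' @export
count_peaks <- function(ps, window = NULL, min_rel_height = 0.05,
                        min_prominence = 0.05, min_sep = 0, test = NULL) {
  if (inherits(ps, "pseudospectrum")) {
    f <- ps$f; test <- ps$test
  } else {
    f <- as.numeric(ps)
    if (is.null(test)) stop("'test' is required for a plain vector")
  }
  if (any(!is.finite(f))) stop("'f' must be finite on the grid")
  if (is.null(window)) window <- range(test)
  w <- which(test >= window[1] & test <= window[2])
  fv <- f[w]; tv <- test[w]
  if (length(fv) < 3) return(list(n = 0L, positions = numeric(0)))
  loc <- which(diff(sign(diff(fv))) == -2) + 1
  fmax <- max(fv)
  prom <- vapply(loc, function(i) {
    h <- fv[i]
    hi_l <- which(fv[seq_len(i)] > h)
    pl <- if (length(hi_l)) h - min(fv[max(hi_l):i]) else h - min(fv[seq_len(i)])
    rest <- fv[i:length(fv)]
    hi_r <- which(rest > h)
    pr <- if (length(hi_r)) h - min(rest[seq_len(min(hi_r))]) else h - min(rest)
    min(pl, pr)
  }, numeric(1))
  keep <- fv[loc] >= min_rel_height * fmax & prom >= min_prominence * fmax
  pk <- tv[loc][keep]; hh <- fv[loc][keep]
  if (min_sep > 0 && length(pk) > 1) {
    o <- order(-hh); acc <- integer(0)
    for (i in o)
      if (!length(acc) || all(abs(pk[i] - pk[acc]) >= min_sep))
        acc <- c(acc, i)
    pk <- sort(pk[acc])
  }
  list(n = length(pk), positions = pk)
}

#' MUSIC analysis of one component matrix
#'
#' Convenience pipeline: eigenimages (optionally basis-stabilized), subspace
#' split, pseudo-spectrum on a test grid. For noiseless strongly
#' sub-diffraction scenes pass `basis = G` to keep the trailing signal
#' directions (see [eigenimages()]).
#'
#' @param A component matrix (`C1`, `C2`, `C3`, or `J`).
#' @param grid,psf imaging geometry.
#' @param test test positions (default 1-nm grid over the pixel span).
#' @param basis optional basis for the decomposition.
#' @param policy,rank,s0 subspace split controls (see [split_subspaces()]).
#' @param alpha contrast exponent.
#' @return A `pseudospectrum`.
#' @export
musical_component <- function(A, grid, psf = psf_model(), test = NULL,
                              basis = NULL,
                              policy = "eigengap", rank = NULL, s0 = NULL,
                              alpha = 1) {
  if (is.null(test))
    test <- seq(min(grid$centers), max(grid$centers), by = 1)
  eig <- eigenimages(A, basis = basis)
  sub <- split_subspaces(eig, policy = policy, rank = rank, s0 = s0)
  pseudospectrum(sub, grid, psf, test, alpha = alpha)
}

#' Dominant spatial frequency of an eigenimage
#'
#' Index (in cycles over the grid span) of the largest non-DC Fourier
#' coefficient. Used to verify that eigenimage spatial frequency rises as
#' the singular value falls.
#'
#' @param u numeric vector (an eigenimage).
#' @export
dominant_frequency <- function(u) {
  a <- Mod(stats::fft(u))[seq_len(floor(length(u) / 2) + 1)]
  which.max(a[-1])          # skip the DC term; index 1 = one cycle
}

#' @export
print.subspaces <- function(x, ...) {
  cat("Eigenimages: N =", x$N, if (x$restricted) "(restricted basis)", "\n")
  cat("  leading singular values:",
      paste(signif(utils::head(x$s, 5), 4), collapse = ", "), "...\n")
  if (!is.null(x$rank))
    cat("  signal rank:", x$rank, "(policy:", x$policy, ")\n")
  invisible(x)
}

#' @export
print.pseudospectrum <- function(x, ...) {
  cat("MUSIC pseudo-spectrum:", length(x$test), "test points, alpha =",
      x$alpha, ", signal rank", x$rank, "\n")
  invisible(x)
}
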