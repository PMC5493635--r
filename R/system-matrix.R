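#' Build the emitter-to-pixel system matrix G
#'
#' Column `m` of G is the noiseless pixel image of emitter `m`: the PSF
#' centered at the emitter position, point-sampled at the pixel centers for an
#' ideal camera, or averaged over `subsamples` equispaced evaluations across
#' the pixel extent for a finite-pixel camera. The sum of the columns is
#' proportional to the mean image of the stack.
#'
#' @param emitters an [emitter_set()].
#' @param grid a [pixel_grid()].
#' @param psf a [psf_model()].
#' @param subsamples number of equispaced in-pixel evaluations used for the
#'   finite-pixel response (ignored for an ideal grid).
#' @return An object of class `system_matrix`: a list with the `N x M` matrix
#'   `G`, the generating geometry and the PSF.
#' @examples
#' G <- build_system_matrix(emitter_pair(100), camera_grid(10, 100))
#' dim(G$G)   # 10 x 2
#' @export
build_system_matrix <- function(emitters, grid, psf = psf_model(),
                                subsamples = 21) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(grid, "pixel_grid"),
            inherits(psf, "psf_model"))
  if (subsamples < 1) stop("'subsamples' must be >= 1")
  # offsets matrix: N x M of (pixel center - emitter position)
  off <- outer(grid$centers, emitters$positions, "-")
  if (grid$pixel_size == 0 || subsamples == 1) {
    G <- matrix(psf_profile(off, psf), nrow = grid$N)
  } else {
    half <- grid$pixel_size / 2
    sub <- seq(-half + half / subsamples, half - half / subsamples,
               length.out = subsamples)   # midpoint rule
    G <- matrix(0, grid$N, emitters$M)
    for (s in sub) G <- G + matrix(psf_profile(off + s, psf), nrow = grid$N)
    G <- G / subsamples
  }
  structure(list(G = G, emitters = emitters, grid = grid, psf = psf,
                 N = grid$N, M = emitters$M),
            class = "system_matrix")
}

#' Mean image of the stack (up to the photon-count scale)
#'
#' The row sums of G, i.e. the superposition of all emitter images. This is
#' what the time-averaged stack converges to, scaled by the mean per-frame
#' photon count.
#'
#' @param G a `system_matrix` or a plain numeric matrix.
#' @return numeric vector of length N.
#' @export
mean_image <- function(G) {
  rowSums(as_G(G))
}

#' Normalize each emitter image to unit peak
#'
#' Rescales every column of G so its maximum entry is 1. The component
#' magnitude studies (with their 0.5/0.25 asymptotes) are defined on
#' peak-normalized emitter images, which makes magnitudes comparable across
#' pixel sizes and separations.
#'
#' @param G a `system_matrix` or a plain numeric matrix.
#' @return Same type as the input, with unit-peak columns.
#' @export
normalize_columns <- function(G) {
  if (inherits(G, "system_matrix")) {
    G$G <- sweep(G$G, 2, apply(G$G, 2, max), "/")
    G
  } else {
    sweep(G, 2, apply(G, 2, max), "/")
  }
}

# Accept either a system_matrix or a bare matrix wherever only the numbers
# are needed.
as_G <- function(G) {
  if (inherits(G, "system_matrix")) G$G
  else if (is.matrix(G)) G
  else stop("expected a 'system_matrix' or a numeric matrix")
}

#' Pixel image of a hypothetical emitter at arbitrary test positions
#'
#' Evaluates the same pixel response as [build_system_matrix()] for emitters
#' at `positions`, returning an `N x length(positions)` matrix. Used by the
#' MUSIC pseudo-spectrum, where each test point needs the image the camera
#' would record of an emitter placed there.
#'
#' @param positions numeric vector of test positions in nm.
#' @inheritParams build_system_matrix
#' @export
emitter_image <- function(positions, grid, psf = psf_model(),
                          subsamples = 21) {
  es <- structure(list(positions = as.numeric(positions),
                       M = length(positions)), class = "emitter_set")
  off <- outer(grid$centers, es$positions, "-")
  if (grid$pixel_size == 0 || subsamples == 1)
    return(matrix(psf_profile(off, psf), nrow = grid$N))
  half <- grid$pixel_size / 2
  sub <- seq(-half + half / subsamples, half - half / subsamples,
             length.out = subsamples)   # midpoint rule
  G <- matrix(0, grid$N, es$M)
  for (s in sub) G <- G + matrix(psf_profile(off + s, psf), nrow = grid$N)
  G / subsamples
}

#' @export
print.system_matrix <- function(x, ...) {
  cat("System matrix G:", x$N, "pixels x", x$M, "emitters\n")
  cat("  column peaks:", paste(signif(apply(x$G, 2, max), 4), collapse = ", "),
      "\n")
  invisible(x)
}
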