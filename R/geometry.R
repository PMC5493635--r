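#' Emitter positions along the optical axis transverse coordinate
#'
#' A set of point emitters on the 1-D object line, positions in nm, strictly
#' increasing. The two-emitter scenes used throughout place the pair
#' symmetrically about 0 at separation `delta_y`.
#'
#' @param positions numeric vector of emitter positions in nm (strictly
#'   increasing).
#' @return An object of class `emitter_set`.
#' @seealso [emitter_pair()], [emitter_chain()]
#' @export
emitter_set <- function(positions) {
  if (length(positions) < 1) stop("at least one emitter is required")
  if (is.unsorted(positions, strictly = TRUE))
    stop("emitter positions must be strictly increasing")
  structure(list(positions = as.numeric(positions),
                 M = length(positions)),
            class = "emitter_set")
}

#' Symmetric emitter pair at a given separation
#' @param delta_y separation in nm (>= 0); the emitters sit at `+/- delta_y/2`.
#' @export
emitter_pair <- function(delta_y) {
  if (delta_y < 0) stop("'delta_y' must be non-negative")
  if (delta_y == 0) {
    # coincident pair: represented as two emitters at the same point is not a
    # valid strictly-increasing set, so nudge by an infinitesimal amount
    return(emitter_set(c(-1e-9, 1e-9)))
  }
  emitter_set(c(-delta_y / 2, delta_y / 2))
}

#' Uniformly spaced chain of emitters symmetric about 0
#' @param n number of emitters.
#' @param delta_y spacing between neighbours in nm.
#' @export
emitter_chain <- function(n, delta_y) {
  emitter_set((seq_len(n) - (n + 1) / 2) * delta_y)
}

#' Detector pixel grid
#'
#' Uniformly spaced pixel centers in nm. `pixel_size = 0` denotes an ideal
#' (infinitesimal-pixel) camera for which the PSF is point-sampled at the
#' centers; a positive `pixel_size` models a finite pixel over which the PSF
#' is integrated.
#'
#' @param centers numeric vector of pixel centers in nm (uniformly spaced,
#'   length >= 2).
#' @param pixel_size pixel extent in nm (0 for an ideal camera).
#' @return An object of class `pixel_grid`.
#' @seealso [ideal_grid()], [camera_grid()]
#' @export
pixel_grid <- function(centers, pixel_size = 0) {
  if (length(centers) < 2) stop("a pixel grid needs at least 2 pixels")
  d <- diff(centers)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * abs(d[1]))
    stop("pixel centers must be uniformly spaced and increasing")
  if (pixel_size < 0) stop("'pixel_size' must be non-negative")
  structure(list(centers = as.numeric(centers),
                 pixel_size = pixel_size,
                 N = length(centers)),
            class = "pixel_grid")
}

#' Ideal (infinitesimal-pixel) camera grid
#'
#' Dense point-sampling grid spanning `+/- half_span`, default 1-nm spacing.
#' The default span is wide enough (>= 6 Rayleigh radii for the default PSF)
#' that profile metrics are grid-converged.
#'
#' @param half_span half-width of the grid in nm.
#' @param step sampling step in nm.
#' @export
ideal_grid <- function(half_span = 1000, step = 1) {
  pixel_grid(seq(-half_span, half_span, by = step), pixel_size = 0)
}

#' Finite-pixel camera grid symmetric about 0
#'
#' `n_pixels` contiguous pixels of size `pixel_size`; for an even count the
#' grid boundary (not a center) sits at 0, as for a camera placed symmetric
#' to the scene.
#'
#' @param n_pixels number of pixels.
#' @param pixel_size pixel size in nm.
#' @export
camera_grid <- function(n_pixels = 10, pixel_size = 100) {
  centers <- (seq_len(n_pixels) - (n_pixels + 1) / 2) * pixel_size
  pixel_grid(centers, pixel_size = pixel_size)
}

#' @export
print.emitter_set <- function(x, ...) {
  cat("Emitter set: M =", x$M, "\n  positions (nm):",
      paste(signif(x$positions, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat("Pixel grid: N =", x$N, "pixels, pixel size",
      if (x$pixel_size == 0) "0 (ideal camera)" else paste(x$pixel_size, "nm"),
      "\n  span:", min(x$centers), "to", max(x$centers), "nm\n")
  invisible(x)
}
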