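#' Diagonal profile of a component matrix
#'
#' The vector of diagonal entries `C(n, n)`, i.e. the per-pixel
#' autocorrelation image.
#'
#' @param C square numeric matrix.
#' @export
diagonal_profile <- function(C) {
  if (nrow(C) != ncol(C)) stop("'C' must be square")
  diag(C)
}

#' Cross profile of a component matrix at a fixed position
#'
#' The row of `C` at the pixel nearest `r_fixed`.
#'
#' @param C square numeric matrix.
#' @param grid the [pixel_grid()] the matrix lives on.
#' @param r_fixed position in nm; must lie within the grid span.
#' @export
cross_profile <- function(C, grid, r_fixed) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (r_fixed < min(grid$centers) - grid$pixel_size / 2 ||
      r_fixed > max(grid$centers) + grid$pixel_size / 2)
    stop("'r_fixed' lies outside the pixel grid")
  C[which.min(abs(grid$centers - r_fixed)), ]
}

#' Full width at half maximum of a sampled profile
#'
#' Width between the two half-maximum crossings nearest the global maximum,
#' linearly interpolated between samples. Errors if the profile does not
#' cross half maximum on both sides.
#'
#' @param profile numeric vector.
#' @param coords coordinates (nm) of the samples, increasing.
#' @return width in nm.
#' @export
profile_fwhm <- function(profile, coords) {
  if (length(profile) != length(coords)) stop("length mismatch")
  i <- which.max(profile)
  h <- profile[i] / 2
  left <- which(profile[seq_len(i)] < h)
  right <- which(profile[i:length(profile)] < h)
  if (!length(left) || !length(right))
    stop("profile does not fall below half maximum on both sides")
  l <- max(left)                       # last sample below h on the left
  r <- i - 1 + min(right)              # first sample below h on the right
  xl <- coords[l] + (h - profile[l]) / (profile[l + 1] - profile[l]) *
    (coords[l + 1] - coords[l])
  xr <- coords[r - 1] + (h - profile[r - 1]) / (profile[r] - profile[r - 1]) *
    (coords[r] - coords[r - 1])
  xr - xl
}

#' Minima-to-maxima intensity ratio R of a two-emitter profile
#'
#' For a profile symmetric about 0, `R` is the value at the central dip
#' divided by the global maximum; `R = 1` when the center is the global
#' maximum (the two emitters are unresolved by this profile), and `R < 1`
#' signals a resolved pair.
#'
#' @param profile numeric vector.
#' @param coords sample coordinates in nm.
#' @return unitless ratio in `(0, 1]`.
#' @export
min_max_ratio <- function(profile, coords) {
  if (length(profile) != length(coords)) stop("length mismatch")
  flipped <- rev(profile)
  if (max(abs(profile - flipped)) > 1e-6 * max(abs(profile))) {
    warning("profile is not symmetric about 0; using the center value")
  }
  center <- profile[which.min(abs(coords))]
  mx <- max(profile)
  if (center >= mx) 1 else center / mx
}

#' First separation at which a two-emitter profile resolves
#'
#' Sweeps the pair separation on a uniform grid and returns the first
#' separation at which `R < 1` for the requested profile of the requested
#' matrix.
#'
#' @param matrix_id one of `"meanimg"`, `"C1"`, `"C2"`, `"C3"`.
#' @param grid a [pixel_grid()] (ideal recommended).
#' @param psf a [psf_model()].
#' @param delta_y separations to scan (nm, increasing).
#' @return list with the threshold (nm) and the full `R(delta_y)` curve.
#' @export
resolution_threshold <- function(matrix_id = c("C2", "meanimg", "C1", "C3"),
                                 grid = ideal_grid(), psf = psf_model(),
                                 delta_y = seq(80, 260, by = 2)) {
  matrix_id <- match.arg(matrix_id)
  rs <- vapply(delta_y, function(d) {
    G <- build_system_matrix(emitter_pair(d), grid, psf)
    prof <- switch(matrix_id,
                   meanimg = mean_image(G),
                   C1 = diagonal_profile(compute_components(G)$C1),
                   C2 = diagonal_profile(compute_components(G)$C2),
                   C3 = diagonal_profile(compute_components(G)$C3))
    min_max_ratio(prof, grid$centers)
  }, numeric(1))
  idx <- which(rs < 1)
  list(threshold = if (length(idx)) delta_y[idx[1]] else NA_real_,
       delta_y = delta_y, R = rs)
}

#' Magnitude of component matrices as a function of emitter separation
#'
#' For each separation the two-emitter system matrix is built, its columns
#' peak-normalized (see [normalize_columns()]) so magnitudes are comparable,
#' optionally degraded with Poisson noise, and the maximum entry of the
#' requested matrices recorded. With noise, `n_realizations` independent
#' executions are averaged and the standard deviation returned alongside.
#'
#' @param delta_y separations in nm (increasing).
#' @param matrix_id character vector among `"meanimg"`, `"C1"`, `"C2"`,
#'   `"C3"`, `"C2minusC3"`.
#' @param grid a [pixel_grid()].
#' @param psf a [psf_model()].
#' @param peak_snr peak SNR of Poisson noise applied to G (`NULL` for
#'   noiseless).
#' @param n_realizations number of independent noise executions.
#' @param seed master seed for the noise.
#' @return An object of class `resolution_curve`: list with `delta_y`, the
#'   value matrix (one column per `matrix_id`) and, for noisy sweeps, the
#'   per-curve standard deviations.
#' @export
magnitude_curve <- function(delta_y, matrix_id = c("C1", "C2", "C3"),
                            grid = ideal_grid(half_span = 400, step = 2),
                            psf = psf_model(), peak_snr = NULL,
                            n_realizations = 100, seed = 1) {
  if (is.unsorted(delta_y, strictly = TRUE))
    stop("'delta_y' must be strictly increasing")
  ids <- match.arg(matrix_id, c("meanimg", "C1", "C2", "C3", "C2minusC3"),
                   several.ok = TRUE)
  one_pass <- function(noise_seed) {
    t(vapply(delta_y, function(d) {
      G <- normalize_columns(build_system_matrix(emitter_pair(d), grid, psf))
      if (!is.null(peak_snr))
        G <- add_poisson_noise(G, peak_snr, seed = noise_seed + round(d * 7))
      cs <- compute_components(G)
      vapply(ids, function(id)
        switch(id,
               meanimg = max(mean_image(G)),
               C1 = max(cs$C1), C2 = max(cs$C2), C3 = max(cs$C3),
               C2minusC3 = max(cs$C2 - cs$C3)),
        numeric(1))
    }, numeric(length(ids))))
  }
  if (is.null(peak_snr)) {
    vals <- one_pass(0)
    sds <- NULL
  } else {
    acc <- 0; acc2 <- 0
    for (r in seq_len(n_realizations)) {
      v <- one_pass(seed + 100003L * r)
      acc <- acc + v; acc2 <- acc2 + v^2
    }
    vals <- acc / n_realizations
    sds <- sqrt(pmax(acc2 / n_realizations - vals^2, 0))
  }
  colnames(vals) <- ids
  structure(list(delta_y = delta_y, values = vals, sd = sds,
                 matrix_id = ids, metric = "magnitude",
                 peak_snr = peak_snr,
                 n_realizations = if (is.null(peak_snr)) 1 else n_realizations),
            class = "resolution_curve")
}

#' Inflection point of a magnitude-versus-separation curve
#'
#' Locates the separation at which the curve's curvature changes sign. The
#' curve is smoothed with a Savitzky-Golay filter (local quadratic,
#' `window` samples) and analyzed on the log scale by default, where the
#' component magnitude transitions of the two-emitter sweeps appear as clean
#' curvature sign changes; the linear scale is used automatically when the
#' curve has non-positive values.
#'
#' Two detection rules are available: `"crossing"` (the first sign change of
#' the smoothed second difference above `min_delta`, for noiseless curves)
#' and `"steepest"` (the location of the most negative smoothed first
#' derivative, robust for noise-averaged curves whose plateaus retain
#' realization jitter).
#'
#' @param curve a `resolution_curve` or a numeric vector of values.
#' @param delta_y separations (needed when `curve` is a plain vector).
#' @param matrix_id which column of a `resolution_curve` to analyze.
#' @param method `"crossing"` or `"steepest"`.
#' @param log_scale analyze `log(value)` (default) or the raw values.
#' @param min_delta ignore structure below this separation (nm).
#' @param window Savitzky-Golay window length (odd, default 5).
#' @return separation in nm, or `NA` if no inflection is found.
#' @export
inflection_point <- function(curve, delta_y = NULL, matrix_id = NULL,
                             method = c("crossing", "steepest"),
                             log_scale = TRUE, min_delta = 50, window = 5) {
  method <- match.arg(method)
  if (inherits(curve, "resolution_curve")) {
    delta_y <- curve$delta_y
    v <- if (is.null(matrix_id)) curve$values[, 1]
         else curve$values[, matrix_id]
  } else v <- as.numeric(curve)
  if (is.null(delta_y)) stop("'delta_y' is required")
  if (log_scale && any(v <= 0)) log_scale <- FALSE
  y <- if (log_scale) log(v) else v
  if (method == "crossing") {
    sm <- signal::sgolayfilt(y, p = 2, n = window)
    d2 <- diff(sm, differences = 2)
    dd <- delta_y[seq_along(d2) + 1]
    ix <- which(dd > min_delta & d2 > 0 & c(NA, d2[-length(d2)]) <= 0)
    if (!length(ix)) return(NA_real_)
    dd[ix[1]]
  } else {
    d1 <- signal::sgolayfilt(y, p = 2, n = window, m = 1)
    ok <- delta_y > min_delta
    delta_y[ok][which.min(d1[ok])]
  }
}

#' Ratio of the mean-image magnitude to the fluctuation magnitude
#'
#' `max(C1) / max(C2 - C3)` as a function of separation, with the slope and
#' R^2 of a log-log linear fit over a specified range. The ratio quantifies
#' how deeply the resolution-carrying content is buried under the mean
#' image.
#'
#' @inheritParams magnitude_curve
#' @param fit_range range of separations (nm) for the log-log fit.
#' @return An object of class `resolution_curve` with extra fields `slope`
#'   and `r_squared`.
#' @export
magnitude_ratio_curve <- function(delta_y,
                                  grid = ideal_grid(half_span = 400, step = 2),
                                  psf = psf_model(), peak_snr = NULL,
                                  n_realizations = 100, seed = 1,
                                  fit_range = c(10, 150)) {
  if (any(delta_y <= 0)) stop("'delta_y' must be positive (ratio diverges at 0)")
  mc <- magnitude_curve(delta_y, c("C1", "C2minusC3"), grid, psf,
                        peak_snr, n_realizations, seed)
  ratio <- mc$values[, "C1"] / mc$values[, "C2minusC3"]
  keep <- is.finite(ratio) & ratio > 0
  fitsel <- keep & delta_y >= fit_range[1] & delta_y <= fit_range[2]
  fit <- stats::lm(log(ratio[fitsel]) ~ log(delta_y[fitsel]))
  structure(list(delta_y = delta_y[keep], values = cbind(ratio = ratio[keep]),
                 matrix_id = "magnitude_ratio", metric = "magnitude_ratio",
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 fit_range = fit_range, peak_snr = peak_snr),
            class = "resolution_curve")
}

#' FWHM of component diagonal profiles versus separation
#'
#' @inheritParams magnitude_curve
#' @return A `resolution_curve` of FWHM values (nm).
#' @export
fwhm_curve <- function(delta_y,
                       matrix_id = c("meanimg", "C1", "C2", "C3"),
                       grid = ideal_grid(), psf = psf_model()) {
  ids <- match.arg(matrix_id, c("meanimg", "C1", "C2", "C3", "C2minusC3"),
                   several.ok = TRUE)
  vals <- t(vapply(delta_y, function(d) {
    G <- build_system_matrix(emitter_pair(d), grid, psf)
    cs <- compute_components(G)
    vapply(ids, function(id) {
      prof <- switch(id,
                     meanimg = mean_image(G),
                     C1 = diagonal_profile(cs$C1),
                     C2 = diagonal_profile(cs$C2),
                     C3 = diagonal_profile(cs$C3),
                     C2minusC3 = diagonal_profile(cs$C2 - cs$C3))
      profile_fwhm(prof, grid$centers)
    }, numeric(1))
  }, numeric(length(ids))))
  colnames(vals) <- ids
  structure(list(delta_y = delta_y, values = vals, sd = NULL,
                 matrix_id = ids, metric = "fwhm"),
            class = "resolution_curve")
}

#' @export
print.resolution_curve <- function(x, ...) {
  cat("Resolution curve (", x$metric, "): ", length(x$delta_y),
      " separations in [", min(x$delta_y), ", ", max(x$delta_y), "] nm\n",
      sep = "")
  if (!is.null(x$slope))
    cat(sprintf("  log-log slope %.3f (R^2 = %.4f)\n", x$slope, x$r_squared))
  invisible(x)
}

#' Export a resolution curve as a data frame
#' @param x a `resolution_curve`.
#' @param ... unused.
#' @export
as.data.frame.resolution_curve <- function(x, ...) {
  df <- data.frame(delta_y_nm = x$delta_y, x$values, check.names = FALSE)
  if (!is.null(x$sd)) {
    sd <- x$sd; colnames(sd) <- paste0("sd_", colnames(x$values))
    df <- cbind(df, sd)
  }
  df
}
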