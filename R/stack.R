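#' Assemble a synthetic image stack
#'
#' The stack is the matrix product `I = G S`: frame k is the superposition of
#' the emitter images weighted by that frame's photon counts.
#'
#' @param G a `system_matrix` (or `N x M` matrix).
#' @param S a `photon_count_matrix` (or `M x K` matrix).
#' @return An object of class `image_stack` with the `N x K` matrix `I`.
#' @export
simulate_stack <- function(G, S) {
  Gm <- as_G(G)
  Sm <- if (inherits(S, "photon_count_matrix")) S$S else as.matrix(S)
  if (ncol(Gm) != nrow(Sm))
    stop("dimension mismatch: G has ", ncol(Gm), " emitters but S has ",
         nrow(Sm))
  frame_time <- if (inherits(S, "photon_count_matrix"))
    S$params$frame_time else NA_real_
  structure(list(I = Gm %*% Sm, N = nrow(Gm), K = ncol(Sm),
                 frame_time = frame_time, provenance = "simulated"),
            class = "image_stack")
}

#' Inject Poisson noise at a prescribed peak signal-to-noise ratio
#'
#' The input is scaled so that its maximum expected value equals
#' `peak_snr^2` counts (peak SNR of a Poisson variate with mean n is
#' sqrt(n)), every entry is replaced by a Poisson draw, and the result is
#' scaled back. The expectation is preserved entrywise.
#'
#' @param X non-negative numeric matrix (or `system_matrix`/`image_stack`).
#' @param peak_snr peak signal-to-noise ratio (> 0); values above 1e6 are
#'   treated as noiseless.
#' @param seed integer seed (optional).
#' @return Same type as the input, with noisy values.
#' @export
add_poisson_noise <- function(X, peak_snr, seed = NULL) {
  if (!is.numeric(peak_snr) || peak_snr <= 0) stop("'peak_snr' must be > 0")
  wrap <- NULL
  if (inherits(X, "system_matrix")) { wrap <- X; Xm <- X$G }
  else if (inherits(X, "image_stack")) { wrap <- X; Xm <- X$I }
  else Xm <- as.matrix(X)
  if (any(Xm < 0)) stop("'X' must be non-negative")
  mx <- max(Xm)
  if (mx == 0) return(X)
  if (peak_snr >= 1e6) return(X)
  if (!is.null(seed)) set.seed(seed)
  sc <- peak_snr^2 / mx
  noisy <- matrix(stats::rpois(length(Xm), Xm * sc), nrow(Xm)) / sc
  if (is.null(wrap)) return(noisy)
  if (inherits(wrap, "system_matrix")) wrap$G <- noisy else wrap$I <- noisy
  wrap
}

#' Write an image stack to a multi-page 32-bit float TIFF
#'
#' One page per frame. TIFF float samples are stored in `[0, 1]`, so the
#' stack is divided by its maximum on write and the scale (plus frame time)
#' is recorded in a JSON sidecar `<path>.json`; [read_stack_tiff()] restores
#' the original values. The round trip is exact to float32 quantization.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  sc <- max(stack$I)
  if (sc == 0) sc <- 1
  pages <- lapply(seq_len(stack$K), function(k)
    matrix(stack$I[, k] / sc, nrow = 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = sc, frame_time = stack$frame_time,
                            N = stack$N, K = stack$K),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' @param path TIFF path (one page per frame; pages are flattened to the
#'   pixel vector). A JSON sidecar written by [write_stack_tiff()] restores
#'   the intensity scale and frame time.
#' @param frame_time frame time in ms; overrides the sidecar value.
#' @export
read_stack_tiff <- function(path, frame_time = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  I <- vapply(pages, function(p) as.numeric(t(p)), numeric(length(pages[[1]])))
  sc <- 1; ft <- NA_real_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    sc <- meta$scale %||% 1
    ft <- meta$frame_time %||% NA_real_
  }
  if (!is.null(frame_time)) ft <- frame_time
  structure(list(I = I * sc, N = nrow(I), K = ncol(I),
                 frame_time = ft, provenance = "loaded"),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("Image stack:", x$N, "pixels x", x$K, "frames (", x$provenance, ")\n")
  invisible(x)
}
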