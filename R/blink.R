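#' Blinking kinetics and acquisition parameters
#'
#' Two-state (bright/dark) renewal model of fluorophore intermittency with
#' truncated power-law sojourn times, the standard phenomenology of
#' quantum-dot blinking: interval durations are drawn from
#' \eqn{p(\tau) \propto \tau^{-a}} on `(tau_min, tau_max)` with separate
#' maximum time scales for the bright (`tau_max_b`) and dark (`tau_max_d`)
#' states. Photons are emitted at a constant rate while bright and counted
#' per camera frame of duration `frame_time`.
#'
#' @param tau_max_b maximum bright-state duration scale (ms).
#' @param tau_max_d maximum dark-state duration scale (ms).
#' @param exponent power-law exponent `a` (> 1, default 1.5).
#' @param tau_min_frac lower truncation as a fraction of the respective
#'   `tau_max` (default 0.01).
#' @param emission_rate photons per ms while bright (default 40, giving a
#'   peak per-frame mean of about 400 photons at `frame_time = 10`).
#' @param frame_time camera frame acquisition time T (ms).
#' @param n_frames number of frames K (>= 2).
#' @return An object of class `blink_params`.
#' @export
blink_params <- function(tau_max_b = 10, tau_max_d = 10, exponent = 1.5,
                         tau_min_frac = 0.01, emission_rate = 40,
                         frame_time = 10, n_frames = 1000) {
  vals <- c(tau_max_b, tau_max_d, exponent, tau_min_frac, emission_rate,
            frame_time, n_frames)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all blink parameters must be positive")
  if (exponent <= 1) stop("'exponent' must be > 1")
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  structure(list(tau_max_b = tau_max_b, tau_max_d = tau_max_d,
                 exponent = exponent, tau_min_frac = tau_min_frac,
                 emission_rate = emission_rate, frame_time = frame_time,
                 n_frames = as.integer(n_frames)),
            class = "blink_params")
}

# Inverse-CDF sampler for the truncated power law p(tau) ~ tau^(-a) on
# (tmin, tmax).
rpowerlaw <- function(n, tmax, a, tmin) {
  u <- stats::runif(n)
  e <- 1 - a
  (tmin^e - u * (tmin^e - tmax^e))^(1 / e)
}

# Mean of the truncated power law (closed form, a != 1, a != 2).
powerlaw_mean <- function(tmax, a, tmin) {
  e <- 1 - a
  C <- e / (tmax^e - tmin^e)
  C * (tmax^(2 - a) - tmin^(2 - a)) / (2 - a)
}

#' Sample an alternating bright/dark blinking trace
#'
#' Draws alternating bright and dark sojourns from the truncated power laws
#' until `duration` is covered; the final interval is clipped so the
#' intervals tile `[0, duration]` exactly. The initial state is bright or
#' dark with probability proportional to the respective mean sojourn
#' (stationary start).
#'
#' @param params a [blink_params()].
#' @param duration total trace duration in ms.
#' @param seed integer seed for reproducibility (optional).
#' @return A data frame with columns `start`, `end`, `state` (`"bright"` or
#'   `"dark"`), of class `blink_trace`.
#' @export
sample_blink_trace <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "blink_params"))
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive")
  if (!is.null(seed)) set.seed(seed)
  a <- params$exponent
  tb <- params$tau_max_b; td <- params$tau_max_d
  mb <- powerlaw_mean(tb, a, params$tau_min_frac * tb)
  md <- powerlaw_mean(td, a, params$tau_min_frac * td)
  start_bright <- stats::runif(1) < mb / (mb + md)
  ncyc <- ceiling(1.3 * duration / (mb + md)) + 16
  draw <- function(n) {
    b <- rpowerlaw(n, tb, a, params$tau_min_frac * tb)
    d <- rpowerlaw(n, td, a, params$tau_min_frac * td)
    if (start_bright) as.vector(rbind(b, d)) else as.vector(rbind(d, b))
  }
  iv <- draw(ncyc)
  cum <- cumsum(iv)
  while (cum[length(cum)] < duration) {
    iv2 <- draw(max(16, ncyc %/% 4))
    cum <- c(cum, cum[length(cum)] + cumsum(iv2))
  }
  n <- which(cum >= duration)[1]
  ends <- pmin(cum[seq_len(n)], duration)
  starts <- c(0, ends[-n])
  state <- rep(c("bright", "dark"), length.out = n)
  if (!start_bright) state <- rep(c("dark", "bright"), length.out = n)
  structure(data.frame(start = starts, end = ends, state = state,
                       stringsAsFactors = FALSE),
            class = c("blink_trace", "data.frame"))
}

# Bright time inside each of K frames of length T, for a trace tiling
# [0, K*T].
frame_bright_time <- function(trace, frame_time, n_frames) {
  fb <- numeric(n_frames)
  br <- trace[trace$state == "bright", , drop = FALSE]
  for (i in seq_len(nrow(br))) {
    lo <- max(1L, floor(br$start[i] / frame_time) + 1L)
    hi <- min(n_frames, ceiling(br$end[i] / frame_time))
    if (lo > hi) next
    ks <- lo:hi
    fb[ks] <- fb[ks] +
      pmax(0, pmin(br$end[i], ks * frame_time) -
              pmax(br$start[i], (ks - 1) * frame_time))
  }
  fb
}

#' Per-frame photon counts from a blinking trace
#'
#' For each frame the count is a Poisson draw with mean
#' `emission_rate * (bright time inside the frame)`.
#'
#' @param trace a `blink_trace` covering at least `n_frames * frame_time`.
#' @param params a [blink_params()].
#' @param seed integer seed (optional).
#' @return integer vector of `n_frames` photon counts.
#' @export
photon_counts <- function(trace, params, seed = NULL) {
  stopifnot(inherits(trace, "blink_trace"), inherits(params, "blink_params"))
  need <- params$n_frames * params$frame_time
  if (max(trace$end) < need - 1e-9)
    stop("trace is shorter than n_frames * frame_time")
  if (!is.null(seed)) set.seed(seed)
  fb <- frame_bright_time(trace, params$frame_time, params$n_frames)
  stats::rpois(params$n_frames, params$emission_rate * fb)
}

#' Simulate the emitter-by-frame photon-count matrix S
#'
#' Simulates `M` independent emitters with identical kinetics. Each emitter's
#' trace and counts use a sub-seed derived from `seed` by a fixed offset, so
#' a master seed reproduces the full matrix.
#'
#' @param M number of emitters.
#' @param params a [blink_params()].
#' @param seed master integer seed.
#' @return An object of class `photon_count_matrix`: list with the `M x K`
#'   integer matrix `S` and the parameters.
#' @export
simulate_photon_counts <- function(M, params, seed = 1) {
  stopifnot(inherits(params, "blink_params"))
  K <- params$n_frames
  S <- matrix(0L, M, K)
  for (m in seq_len(M)) {
    tr <- sample_blink_trace(params, K * params$frame_time,
                             seed = seed + 1000L * m)
    S[m, ] <- photon_counts(tr, params, seed = seed + 1000L * m + 1L)
  }
  structure(list(S = S, M = M, K = K, params = params, seed = seed),
            class = "photon_count_matrix")
}

#' Pooled emission statistics of a photon-count matrix
#'
#' Per-emitter frame-wise mean and variance, pooled across emitters (the
#' emitters are i.i.d.), and the ratio mu^2/sigma^2 that governs how strongly
#' the stack is biased towards the mean image: small values leave more
#' relative weight on the resolution-carrying fluctuation components.
#'
#' @param S a `photon_count_matrix` or a plain `M x K` matrix.
#' @return list with `mu`, `sigma`, `ratio` (= mu^2/sigma^2) and `degenerate`
#'   (`TRUE` when sigma is 0, in which case `ratio` is `Inf`).
#' @export
emission_stats <- function(S) {
  Sm <- if (inherits(S, "photon_count_matrix")) S$S else as.matrix(S)
  if (ncol(Sm) < 2) stop("at least 2 frames are needed")
  mu <- mean(rowMeans(Sm))
  v <- mean(apply(Sm, 1, stats::var))
  if (v == 0)
    return(list(mu = mu, sigma = 0, ratio = Inf, degenerate = TRUE))
  list(mu = mu, sigma = sqrt(v), ratio = mu^2 / v, degenerate = FALSE)
}

#' Fraction of time spent bright in a trace
#' @param trace a `blink_trace`.
#' @export
on_fraction <- function(trace) {
  sum(trace$end[trace$state == "bright"] -
        trace$start[trace$state == "bright"]) / max(trace$end)
}

#' @export
print.photon_count_matrix <- function(x, ...) {
  st <- emission_stats(x)
  cat("Photon counts: M =", x$M, "emitters x K =", x$K, "frames\n")
  cat(sprintf("  mu = %.2f, sigma = %.2f, mu^2/sigma^2 = %.4g\n",
              st$mu, st$sigma, st$ratio))
  invisible(x)
}
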