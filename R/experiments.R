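#' Built-in experiment presets
#'
#' Named configurations reproducing the desk-scale studies: the ideal-camera
#' two-emitter scene, the 100-nm-pixel camera scene, the eight-emitter MUSIC
#' scenes, and the quantum-dot blinking-statistics sweep.
#'
#' @return named list of configuration lists (see [run_experiment()]).
#' @export
experiment_presets <- function() {
  psf <- list(kind = "airy1d", rayleigh_radius_nm = 222)
  list(
    example1 = list(
      name = "example1", analysis = "components",
      psf = psf,
      grid = list(n_pixels = NULL, pixel_size_nm = 0, half_span_nm = 1000,
                  step_nm = 1),
      emitters = list(count = 2, delta_y_nm = 100)),
    example2 = list(
      name = "example2", analysis = "components",
      psf = psf,
      grid = list(n_pixels = 10, pixel_size_nm = 100),
      emitters = list(count = 2, delta_y_nm = 100)),
    metrics_sweep = list(
      name = "metrics_sweep", analysis = "metrics",
      psf = psf,
      grid = list(n_pixels = NULL, pixel_size_nm = 0, half_span_nm = 400,
                  step_nm = 2),
      sweep = list(delta_y_min = 10, delta_y_max = 400, step = 2)),
    eight_emitters_10nm = list(
      name = "eight_emitters_10nm", analysis = "musical",
      psf = psf,
      grid = list(n_pixels = 40, pixel_size_nm = 100),
      emitters = list(count = 8, delta_y_nm = 10),
      musical = list(alpha = 1, s0_policy = "eigengap", test_step_nm = 1,
                     min_rel_height = 0.05, use_basis = TRUE)),
    eight_emitters_100nm_snr20 = list(
      name = "eight_emitters_100nm_snr20", analysis = "musical",
      psf = psf,
      grid = list(n_pixels = 40, pixel_size_nm = 100),
      emitters = list(count = 8, delta_y_nm = 100),
      noise = list(peak_snr = 20, apply_to = "G", n_realizations = 20),
      musical = list(alpha = 1, s0_policy = "eigengap", test_step_nm = 2,
                     min_rel_height = 0.05, use_basis = FALSE)),
    qd_blink_T10 = list(
      name = "qd_blink_T10", analysis = "blinkstats",
      blink = list(tau_max_b_ms = 10, ratios = c(1e-2, 1, 100),
                   exponent = 1.5, emission_rate_per_ms = 40,
                   frame_time_ms = 10, n_frames = 10000)),
    two_emitters_100nm = list(
      name = "two_emitters_100nm", analysis = "simulate",
      psf = psf,
      grid = list(n_pixels = 10, pixel_size_nm = 100),
      emitters = list(count = 2, delta_y_nm = 100),
      blink = list(tau_max_b_ms = 10, tau_max_d_ms = 10, exponent = 1.5,
                   emission_rate_per_ms = 40, frame_time_ms = 10,
                   n_frames = 500))
  )
}

config_psf <- function(cfg) {
  p <- cfg$psf
  if (is.null(p)) return(psf_model())
  psf_model(kind = p$kind %||% "airy1d",
            rayleigh_radius = p$rayleigh_radius_nm %||% 222,
            fwhm = p$fwhm_nm)
}

config_grid <- function(cfg) {
  g <- cfg$grid
  if (is.null(g)) return(ideal_grid())
  if (!is.null(g$pixel_size_nm) && g$pixel_size_nm > 0)
    camera_grid(g$n_pixels %||% 10, g$pixel_size_nm)
  else
    ideal_grid(g$half_span_nm %||% 1000, g$step_nm %||% 1)
}

config_emitters <- function(cfg) {
  e <- cfg$emitters
  if (!is.null(e$positions_nm)) return(emitter_set(e$positions_nm))
  n <- e$count %||% 2
  if (n == 2) emitter_pair(e$delta_y_nm) else emitter_chain(n, e$delta_y_nm)
}

config_blink <- function(cfg, ratio = NULL) {
  b <- cfg$blink
  tb <- b$tau_max_b_ms %||% 10
  td <- if (!is.null(ratio)) tb / ratio else b$tau_max_d_ms %||% 10
  blink_params(tau_max_b = tb, tau_max_d = td,
               exponent = b$exponent %||% 1.5,
               emission_rate = b$emission_rate_per_ms %||% 40,
               frame_time = b$frame_time_ms %||% 10,
               n_frames = b$n_frames %||% 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  if (is.null(config$analysis) ||
      !config$analysis %in% c("components", "metrics", "musical", "sofi",
                              "blinkstats", "simulate"))
    stop("invalid config: 'analysis' must be one of components, metrics, ",
         "musical, sofi, blinkstats, simulate")
  needs_scene <- config$analysis %in% c("components", "musical", "sofi",
                                        "simulate")
  if (needs_scene && is.null(config$emitters))
    stop("invalid config: missing key 'emitters'")
  if (config$analysis == "blinkstats" && is.null(config$blink))
    stop("invalid config: missing key 'blink'")
  invisible(TRUE)
}

#' Run a configured experiment and write its outputs
#'
#' Dispatches on `config$analysis`; writes CSV curves/matrices, a JSON
#' summary and (for simulated stacks) a float TIFF into `out_dir`. The same
#' config and seed reproduce all outputs bit-for-bit on deterministic paths.
#'
#' @param config a configuration list (see [experiment_presets()]) or a
#'   preset name.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param seed master seed for all stochastic steps.
#' @return the summary list, invisibly when files are written.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = 1) {
  if (is.character(config)) {
    presets <- experiment_presets()
    if (!config %in% names(presets))
      stop("unknown preset; available: ",
           paste(names(presets), collapse = ", "))
    config <- presets[[config]]
  }
  validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  summary <- switch(config$analysis,
    components = run_components(config, out_dir),
    metrics = run_metrics(config, out_dir),
    musical = run_musical_exp(config, out_dir, seed),
    sofi = run_sofi_exp(config, out_dir, seed),
    blinkstats = run_blinkstats(config, out_dir, seed),
    simulate = run_simulate(config, out_dir, seed))
  summary$config <- config
  summary$seed <- seed
  summary$config_hash <- config_hash(config)
  summary$r_version <- as.character(getRversion())
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(summary)
  } else summary
}

config_hash <- function(config) {
  # stable content hash without extra dependencies
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

run_components <- function(config, out_dir) {
  psf <- config_psf(config); grid <- config_grid(config)
  G <- build_system_matrix(config_emitters(config), grid, psf)
  cs <- compute_components(G)
  if (!is.null(out_dir)) {
    if (grid$N <= 256) {   # full matrices only at camera-scale N
      utils::write.csv(cs$C1, file.path(out_dir, "C1.csv"), row.names = FALSE)
      utils::write.csv(cs$C2, file.path(out_dir, "C2.csv"), row.names = FALSE)
      if (!is.null(cs$C3))
        utils::write.csv(cs$C3, file.path(out_dir, "C3.csv"),
                         row.names = FALSE)
    }
    prof <- data.frame(r_nm = grid$centers,
                       mean_image = mean_image(G),
                       C1 = diagonal_profile(cs$C1),
                       C2 = diagonal_profile(cs$C2),
                       C3 = if (!is.null(cs$C3)) diagonal_profile(cs$C3) else NA,
                       C2minusC3 = if (!is.null(cs$C3))
                         diagonal_profile(cs$C2 - cs$C3) else NA)
    utils::write.csv(prof, file.path(out_dir, "diagonal_profiles.csv"),
                     row.names = FALSE)
  }
  component_report(cs)
}

run_metrics <- function(config, out_dir) {
  psf <- config_psf(config); grid <- config_grid(config)
  sw <- config$sweep %||% list(delta_y_min = 10, delta_y_max = 400, step = 2)
  ds <- seq(sw$delta_y_min, sw$delta_y_max, by = sw$step)
  mc <- magnitude_curve(ds, c("C1", "C2", "C3", "C2minusC3"), grid, psf)
  infl <- lapply(c(C1 = "C1", C2 = "C2", C3 = "C3"), function(id)
    inflection_point(mc, matrix_id = id))
  thr <- list(C2 = resolution_threshold("C2", grid, psf)$threshold,
              meanimg = resolution_threshold("meanimg", grid, psf)$threshold)
  if (!is.null(out_dir))
    utils::write.csv(as.data.frame(mc),
                     file.path(out_dir, "magnitude_curves.csv"),
                     row.names = FALSE)
  list(inflection_points_nm = infl, R_thresholds_nm = thr)
}

run_musical_exp <- function(config, out_dir, seed) {
  psf <- config_psf(config); grid <- config_grid(config)
  em <- config_emitters(config)
  mu <- config$musical %||% list()
  step <- mu$test_step_nm %||% 1
  test <- seq(min(grid$centers), max(grid$centers), by = step)
  dy <- config$emitters$delta_y_nm %||% diff(em$positions[1:2])
  win <- range(em$positions) + c(-dy / 2, dy / 2)
  G0 <- normalize_columns(build_system_matrix(em, grid, psf))
  noise <- config$noise
  analyze <- function(G, use_basis) {
    cs <- compute_components(G)
    sapply(c("C1", "C2", "C3"), function(wh) {
      # each component's natural basis is its own defining factor: the mean
      # image for C1, the emitter columns for C2/C3
      basis <- if (!use_basis) NULL
               else if (wh == "C1") cbind(mean_image(G)) else as_G(G)
      log(musical_component(cs[[wh]], grid, psf, test, basis = basis,
                            alpha = mu$alpha %||% 1)$f)
    })
  }
  if (is.null(noise)) {
    logf <- analyze(G0, use_basis = isTRUE(mu$use_basis))
  } else {
    nr <- noise$n_realizations %||% 20
    logf <- 0
    for (r in seq_len(nr)) {
      Gn <- add_poisson_noise(G0, noise$peak_snr, seed = seed + 7919L * r)
      logf <- logf + analyze(Gn, use_basis = FALSE)
    }
    logf <- logf / nr
  }
  peaks <- lapply(c(C1 = 1, C2 = 2, C3 = 3), function(j)
    count_peaks(exp(logf[, j]), window = win,
                min_rel_height = mu$min_rel_height %||% 0.05, test = test))
  if (!is.null(out_dir)) {
    df <- data.frame(r_nm = test, f_C1 = exp(logf[, 1]),
                     f_C2 = exp(logf[, 2]), f_C3 = exp(logf[, 3]))
    utils::write.csv(df, file.path(out_dir, "pseudospectra.csv"),
                     row.names = FALSE)
  }
  list(peak_counts = lapply(peaks, `[[`, "n"),
       peak_positions_nm = lapply(peaks, `[[`, "positions"),
       window_nm = win,
       n_realizations = if (is.null(noise)) 1
                        else noise$n_realizations %||% 20)
}

run_sofi_exp <- function(config, out_dir, seed) {
  psf <- config_psf(config); grid <- config_grid(config)
  G <- build_system_matrix(config_emitters(config), grid, psf)
  bp <- config_blink(config)
  S <- simulate_photon_counts(G$M, bp, seed = seed)
  stack <- simulate_stack(G, S)
  st <- emission_stats(S)
  chk <- sofi_component_check(G, st$mu, st$sigma, stack)
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(r_nm = grid$centers,
                                sofi = chk$empirical,
                                component_expression = chk$component_expression,
                                variance_expectation = chk$variance_expectation),
                     file.path(out_dir, "sofi.csv"), row.names = FALSE)
  }
  list(distances = chk$distances, mu = st$mu, sigma = st$sigma)
}

run_blinkstats <- function(config, out_dir, seed) {
  b <- config$blink
  ratios <- b$ratios %||% c(1e-2, 1, 100)
  rows <- lapply(ratios, function(r) {
    bp <- config_blink(config, ratio = r)
    S <- simulate_photon_counts(1, bp, seed = seed + round(1000 * log10(r)))
    st <- emission_stats(S)
    data.frame(tau_ratio = r, mu = st$mu, sigma = st$sigma,
               mu2_over_sigma2 = st$ratio)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(tab, file.path(out_dir, "blinkstats.csv"),
                     row.names = FALSE)
  list(table = tab)
}

run_simulate <- function(config, out_dir, seed) {
  psf <- config_psf(config); grid <- config_grid(config)
  G <- build_system_matrix(config_emitters(config), grid, psf)
  bp <- config_blink(config)
  S <- simulate_photon_counts(G$M, bp, seed = seed)
  stack <- simulate_stack(G, S)
  if (!is.null(config$noise))
    stack <- add_poisson_noise(stack, config$noise$peak_snr,
                               seed = seed + 31L)
  if (!is.null(out_dir)) {
    write_stack_tiff(stack, file.path(out_dir, "stack.tif"))
    utils::write.csv(S$S, file.path(out_dir, "photon_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(r_nm = grid$centers, G = G$G),
                     file.path(out_dir, "system_matrix.csv"),
                     row.names = FALSE)
  }
  st <- emission_stats(S)
  list(N = stack$N, K = stack$K, mu = st$mu, sigma = st$sigma)
}

#' Generate a small on-disk fixture for a preset
#'
#' Simulates the preset scene at reduced size and writes the stack (TIFF),
#' counts (CSV) and scene description (JSON) into `dir`. Regeneration with
#' the same seed is bitwise identical.
#'
#' @param preset preset name (see [experiment_presets()]).
#' @param dir output directory.
#' @param seed master seed.
#' @export
generate_fixture <- function(preset, dir, seed = 1) {
  presets <- experiment_presets()
  if (!preset %in% names(presets))
    stop("unknown preset; available: ", paste(names(presets), collapse = ", "))
  cfg <- presets[[preset]]
  cfg$analysis <- "simulate"
  if (is.null(cfg$blink))
    cfg$blink <- list(tau_max_b_ms = 10, tau_max_d_ms = 10,
                      emission_rate_per_ms = 40, frame_time_ms = 10,
                      n_frames = 500)
  cfg$blink$n_frames <- min(cfg$blink$n_frames %||% 500, 1000)
  run_experiment(cfg, out_dir = dir, seed = seed)
}

#' Read an experiment configuration from a YAML file
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
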