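test_that("O has the stated structure and closed-form eigenvalues", {
  O <- o_matrix(3, 1, 2)
  expect_equal(diag(O$O), rep(5, 3))
  expect_equal(O$O[1, 2], 1)
  expect_equal(sort(O$eigenvalues), sort(c(7, 4, 4)))
  # against a generic eigensolver for random parameters
  set.seed(4)
  for (i in 1:5) {
    mu <- runif(1, 0.5, 5); sg <- runif(1, 0.5, 5)
    O5 <- o_matrix(5, mu, sg)
    expect_lt(max(abs(sort(eigen(O5$O, symmetric = TRUE)$values) -
                        sort(O5$eigenvalues))), 1e-10)
  }
  expect_equal(o_matrix(2, 0, 3)$O, diag(9, 2))
  expect_error(o_matrix(0, 1, 1))
})

test_that("M C1 = C2 + (M-1) C3 holds to machine precision for arbitrary G", {
  set.seed(10)
  for (M in c(2, 3, 8)) {
    G <- matrix(runif(12 * M), 12, M)
    cs <- compute_components(G)
    expect_lt(max(abs(M * cs$C1 - cs$C2 - (M - 1) * cs$C3)), 1e-12)
  }
})

test_that("coincident emitters collapse the three components onto each other", {
  G <- build_system_matrix(emitter_pair(0), ideal_grid(500, 2))
  cs <- compute_components(G)
  expect_lt(max(abs(cs$C1 - cs$C2)), 1e-9)
  expect_lt(max(abs(cs$C1 - cs$C3)), 1e-9)
})

test_that("C3 is an explicit absence for a single emitter", {
  cs <- compute_components(matrix(runif(6), 6, 1))
  expect_null(cs$C3)
  expect_false(is.null(cs$C1))
})

test_that("well-separated emitters push max(C2) to 0.5 and max(C1) to 0.25", {
  G <- normalize_columns(
    build_system_matrix(emitter_pair(400), camera_grid(10, 100)))
  cs <- compute_components(G)
  expect_lt(abs(matrix_magnitude(cs$C2) - 0.5), 0.01)
  expect_lt(abs(matrix_magnitude(cs$C1) - 0.25), 0.01)
})

test_that("the blinking weights follow their closed forms and c2/c1 < 1 always", {
  co <- blink_coefficients(1000, 2, 1, 2)
  expect_equal(co$c1, 12000)
  expect_equal(co$c2, 4000)
  expect_equal(blink_coefficients(10, 1, 3, 2)$c2, 0)
  for (M in c(1, 2, 5, 50)) for (r in c(0.01, 0.5, 1, 10, 100)) {
    co <- blink_coefficients(100, M, r, 1)
    expect_lt(co$ratio, 1)
    expect_true(co$c1 > 0 && co$c2 >= 0)
  }
})

test_that("the component reconstruction reproduces K G O G' exactly", {
  set.seed(6)
  G <- matrix(runif(18), 6, 3)
  K <- 500; mu <- 1.7; sg <- 2.4
  cs <- compute_components(G, K = K, mu = mu, sigma = sg)
  J <- reconstruct_J(cs)
  Jref <- K * G %*% o_matrix(3, mu, sg)$O %*% t(G)
  expect_lt(max(abs(J - Jref)), 1e-9)
  expect_lt(max(abs(J - t(J))), 1e-12)
  expect_true(all(eigen(J, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-9 * max(J)))
})

test_that("without photon-count variance the stack is pure mean image", {
  set.seed(7)
  G <- matrix(runif(10), 5, 2)
  cs <- compute_components(G, K = 100, mu = 2, sigma = 1e-9)
  expect_lt(max(abs(reconstruct_J(cs) - 100 * 4 * 4 * cs$C1)) /
              max(abs(reconstruct_J(cs))), 1e-6)
})

test_that("the empirical Gram matrix converges to the model correlation", {
  psf <- psf_model()
  G <- build_system_matrix(emitter_pair(100), camera_grid(10, 100), psf)
  err <- vapply(c(1e3, 1e5), function(K) {
    bp <- blink_params(tau_max_b = 10, tau_max_d = 10, n_frames = K)
    S <- simulate_photon_counts(2, bp, seed = 12)
    st <- emission_stats(S)
    cs <- compute_components(G, K = K, mu = st$mu, sigma = st$sigma)
    Jm <- reconstruct_J(cs)
    Je <- empirical_J(simulate_stack(G, S))
    sqrt(sum((Je - Jm)^2)) / sqrt(sum(Jm^2))
  }, numeric(1))
  expect_lt(err[2], err[1])   # error shrinks with K
  expect_lt(err[2], 0.05)
  # single frame: rank-1 Gram matrix
  J1 <- empirical_J(matrix(c(1, 2, 3), 3, 1))
  expect_equal(numerical_rank(J1), 1L)
  expect_equal(empirical_J(matrix(0, 3, 4)), matrix(0, 3, 3))
})

test_that("C1 is rank one with the mean image as its only eigenvector", {
  G <- build_system_matrix(emitter_pair(100), camera_grid(10, 100))
  cs <- compute_components(G)
  expect_equal(numerical_rank(cs$C1), 1L)
  e <- eigen(cs$C1, symmetric = TRUE)
  gt <- mean_image(G) / sqrt(sum(mean_image(G)^2))
  expect_gt(abs(sum(e$vectors[, 1] * gt)), 1 - 1e-10)
})

test_that("the component report carries magnitudes, ranks and the identity residual", {
  G <- normalize_columns(
    build_system_matrix(emitter_pair(100), camera_grid(10, 100)))
  rep <- component_report(compute_components(G, K = 100, mu = 2, sigma = 3))
  expect_lt(rep$identity_residual, 1e-12)
  expect_equal(rep$ranks$C1, 1L)
  expect_equal(rep$ranks$C2, 2L)
  expect_true(rep$c2 / rep$c1 < 1)
})
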