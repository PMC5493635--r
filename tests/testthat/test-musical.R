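grid40 <- camera_grid(40, 100)
psf0 <- psf_model()

test_that("eigenimages are orthonormal with descending singular values", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  eg <- eigenimages(compute_components(G)$C2)
  expect_lt(max(abs(crossprod(eg$u) - diag(eg$N))), 1e-10)
  expect_true(all(diff(eg$s) <= 1e-12))
  expect_equal(eigenimages(diag(4))$s, rep(1, 4))
})

test_that("C1 has exactly one significant eigenimage, aligned with the mean image", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  cs <- compute_components(G)
  eg <- eigenimages(cs$C1)
  # on the eigenvalue scale (s^2), one direction survives the 1e-10 threshold
  expect_equal(sum(eg$s^2 >= 1e-10 * eg$s[1]^2), 1L)
  expect_equal(numerical_rank(cs$C1), 1L)
  gt <- mean_image(G) / sqrt(sum(mean_image(G)^2))
  expect_gt(abs(sum(eg$u[, 1] * gt)), 1 - 1e-10)
})

test_that("the leading eigenimage of C2 and C3 follows the mean image", {
  G <- build_system_matrix(emitter_pair(100), camera_grid(10, 100), psf0)
  cs <- compute_components(G)
  gt <- mean_image(G) / sqrt(sum(mean_image(G)^2))
  for (A in list(cs$C2, cs$C3)) {
    u1 <- eigenimages(A)$u[, 1]
    expect_gt(abs(sum(u1 * gt)), 0.99)
  }
})

test_that("noiseless C2 of eight well-separated emitters has signal rank 8", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  C2 <- compute_components(G)$C2
  # independent rank oracle
  expect_equal(numerical_rank(C2), 8L)
  sub <- split_subspaces(eigenimages(C2), policy = "eigengap")
  expect_equal(sub$rank, 8L)
})

test_that("subspace split policies honour their contracts", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  eg <- eigenimages(compute_components(G)$C2)
  expect_equal(split_subspaces(eg, "rank", rank = 1)$rank, 1L)
  # s0 below the smallest singular value: the null set is empty
  sub <- split_subspaces(eg, "threshold", s0 = 0)
  expect_equal(sub$rank, eg$N)
  # s0 above the largest: the leading eigenimage is still relegated to S
  sub <- split_subspaces(eg, "threshold", s0 = 2 * eg$s[1])
  expect_equal(sub$rank, 1L)
})

test_that("signal and null projections satisfy the Pythagoras identity", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  sub <- split_subspaces(eigenimages(compute_components(G)$C2), "eigengap")
  test <- seq(-500, 500, by = 25)
  ps <- pseudospectrum(sub, grid40, psf0, test)
  nrm2 <- colSums(emitter_image(test, grid40, psf0)^2)
  expect_lt(max(abs(ps$dPS^2 + ps$dPN^2 - nrm2) / nrm2), 1e-9)
})

test_that("a test point optically isolated from all emitters projects onto the null side", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  sub <- split_subspaces(eigenimages(compute_components(G)$C2), "eigengap")
  ps <- pseudospectrum(sub, grid40, psf0, c(-1900, 0, 1900))
  expect_lt(ps$dPS[1] / ps$dPN[1], 0.05)
  expect_lt(ps$dPS[3] / ps$dPN[3], 0.05)
  expect_gt(ps$dPS[2] / ps$dPN[2], 10)
})

test_that("an empty null subspace is rejected", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  eg <- eigenimages(compute_components(G)$C2)
  sub <- split_subspaces(eg, "threshold", s0 = 0)
  expect_error(pseudospectrum(sub, grid40, psf0, 0), "null subspace")
})

test_that("eigenimage spatial frequency rises as the singular value falls", {
  G <- build_system_matrix(emitter_chain(8, 100), grid40, psf0)
  eg <- eigenimages(compute_components(G)$C2)
  freqs <- vapply(1:8, function(j) dominant_frequency(eg$u[, j]), numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("C2- and C3-based pseudo-spectra resolve eight 10-nm-spaced emitters; C1 cannot", {
  em <- emitter_chain(8, 10)
  G <- normalize_columns(build_system_matrix(em, grid40, psf0))
  cs <- compute_components(G)
  test <- seq(-100, 100, by = 1)
  win <- c(-40, 40)
  for (A in list(cs$C2, cs$C3)) {
    ps <- musical_component(A, grid40, psf0, test, basis = G$G)
    pk <- count_peaks(ps, window = win)
    expect_equal(pk$n, 8L)
    expect_equal(pk$positions, em$positions, tolerance = 1e-8)
    # pseudo-spectrum is higher at emitters than between them
    f_at <- ps$f[match(em$positions, test)]
    f_mid <- ps$f[match(seq(-30, 30, by = 10), test)]
    expect_gt(min(f_at), max(f_mid))
  }
  # C1's defining factor is the mean image, so its signal space is rank one
  ps1 <- musical_component(cs$C1, grid40, psf0, test,
                           basis = cbind(mean_image(G)))
  expect_lt(count_peaks(ps1, window = win)$n, 8L)
})

test_that("peak counting handles monotone and two-bump profiles", {
  x <- seq(-100, 100, by = 1)
  expect_equal(count_peaks(seq_along(x), test = x)$n, 0L)
  two <- exp(-(x - 40)^2 / 100) + 0.8 * exp(-(x + 40)^2 / 100)
  pk <- count_peaks(two, test = x)
  expect_equal(pk$n, 2L)
  expect_equal(sort(pk$positions), c(-40, 40))
  # relative-height filter removes a tiny bump
  three <- two + 1e-3 * exp(-x^2 / 50)
  expect_equal(count_peaks(three, test = x, min_rel_height = 0.05)$n, 2L)
})

test_that("a basis-restricted decomposition preserves deep sub-diffraction signal rank", {
  em <- emitter_chain(8, 10)
  G <- normalize_columns(build_system_matrix(em, grid40, psf0))
  C2 <- compute_components(G)$C2
  plain <- eigenimages(C2)
  restr <- eigenimages(C2, basis = G$G)
  # squaring the conditioning leaves the 8th eigenvalue at machine noise in
  # the plain route
  expect_lt((plain$s[8] / plain$s[1])^2, 1e-14)
  # the restricted route retains exactly the 8-dimensional signal span and
  # reproduces every emitter image within it
  expect_equal(ncol(restr$u), 8L)
  resid <- G$G - restr$u %*% crossprod(restr$u, G$G)
  expect_lt(max(abs(resid)), 1e-8)
  expect_equal(split_subspaces(restr, "eigengap")$rank, 8L)
})
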