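kernel3 <- build_kernel(3)

test_that("memberships form an exact partition of unity", {
  set.seed(21)
  phi <- matrix(rnorm(100, sd = 5), 10, 10)
  u2 <- memberships_two_phase(phi, 1.3)
  expect_lt(max(abs(u2[[1]] + u2[[2]] - 1)), 1e-12)
  phi2 <- matrix(rnorm(100, sd = 5), 10, 10)
  u3 <- memberships_three_phase(phi, phi2, 0.8)
  expect_lt(max(abs(Reduce(`+`, u3) - 1)), 1e-12)
  expect_true(all(vapply(u3, function(m) all(m >= 0 & m <= 1), logical(1))))
})

test_that("cluster mean update reduces to constants and scales linearly", {
  h <- 10; w <- 12
  b <- matrix(1, h, w)
  d <- matrix(0, h, w)
  u <- random_partition(h, w, 2L)
  I <- matrix(7.5, h, w)
  expect_equal(update_c(I, b, d, u, kernel3), c(7.5, 7.5),
               tolerance = 1e-12)
  # scaling (I, d) by t scales every mean by t
  set.seed(3)
  inst <- random_instance(h, w, 2L, kernel3)
  c1 <- update_c(inst$I, inst$b, inst$d, inst$u, kernel3)
  c2 <- update_c(3 * inst$I, inst$b, 3 * inst$d, inst$u, kernel3)
  expect_equal(c2, 3 * c1, tolerance = 1e-12)
})

test_that("cluster mean update errors on a vanished class unless a fallback is given", {
  h <- 8; w <- 8
  empty <- matrix(0, h, w)
  u <- list(matrix(1, h, w), empty)
  I <- matrix(runif(h * w), h, w)
  b <- matrix(1, h, w)
  expect_error(update_c(I, b, empty, u, kernel3), "degenerate class 2")
  got <- update_c(I, b, empty, u, kernel3, fallback = c(-1, 99))
  expect_equal(got[2], 99)
})

test_that("bias update passes constants through and recovers a linear ramp", {
  h <- 20; w <- 20
  u <- list(matrix(1, h, w), matrix(0, h, w))
  d <- matrix(0, h, w)
  I <- matrix(0.9 * 5, h, w)
  b <- update_b(I, d, c(5, 100), u, kernel3)
  expect_equal(b, matrix(0.9, h, w), tolerance = 1e-12)
  # smooth true bias: linear ramp is invariant under the symmetric kernel
  h <- 40; w <- 40
  ramp <- matrix(rep(seq(0.8, 1.2, length.out = w), each = h), h, w)
  u <- list(matrix(1, h, w), matrix(0, h, w))
  I <- ramp * 130
  b <- update_b(I, matrix(0, h, w), c(130, 10), u, build_kernel(3))
  sel <- 10:31
  expect_lt(max(abs(b[sel, sel] - ramp[sel, sel]) / ramp[sel, sel]), 0.02)
})

test_that("difference update vanishes on perfect fits and smooths I when b = 0", {
  h <- 12; w <- 12
  set.seed(9)
  u <- random_partition(h, w, 2L)
  cvec <- c(40, 190)
  b <- random_smooth_field(h, w, 0.8, 1.2, kernel3)
  I <- b * (cvec[1] * u[[1]] + cvec[2] * u[[2]])
  d <- update_d(I, b, cvec, u, kernel3)
  expect_lt(max(abs(d)), 1e-9)
  I2 <- matrix(runif(h * w, 0, 255), h, w)
  d2 <- update_d(I2, matrix(0, h, w), cvec, u, kernel3)
  expect_equal(d2, local_convolve(I2, kernel3), tolerance = 1e-12)
})

test_that("closed-form updates match the literal loop transcriptions", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(c(2L, 3L), 1)
    h <- sample(8:12, 1)
    w <- sample(8:12, 1)
    inst <- random_instance(h, w, n, kernel3)
    expect_lt(max_rel_err(
      update_c(inst$I, inst$b, inst$d, inst$u, kernel3),
      oracle_update_c(inst$I, inst$b, inst$d, inst$u, kernel3)
    ), 1e-10)
    expect_lt(max_rel_err(
      update_b(inst$I, inst$d, inst$cvec, inst$u, kernel3),
      oracle_update_b(inst$I, inst$d, inst$cvec, inst$u, kernel3)
    ), 1e-10)
    expect_lt(max_rel_err(
      update_d(inst$I, inst$b, inst$cvec, inst$u, kernel3),
      oracle_update_d(inst$I, inst$b, inst$cvec, inst$u, kernel3)
    ), 1e-10)
  }
})

test_that("fit maps are non-negative, vanish on perfect fits, and match the literal definition", {
  h <- 9; w <- 9
  # perfect fit with constant fields
  b <- matrix(1.1, h, w)
  d <- matrix(4, h, w)
  I <- matrix(1.1 * 55 + 4, h, w)
  f <- fit_maps(I, b, d, c(55, 200), kernel3)
  expect_lt(max(abs(f[[1]])), 1e-9)
  set.seed(17)
  inst <- random_instance(6, 6, 2L, kernel3)
  got <- fit_maps(inst$I, inst$b, inst$d, inst$cvec, kernel3)
  want <- oracle_fit_maps(inst$I, inst$b, inst$d, inst$cvec, kernel3)
  for (i in 1:2) {
    expect_lt(max_rel_err(got[[i]], want[[i]]), 1e-10)
    expect_true(all(got[[i]] > -1e-8))
  }
})

test_that("total energy matches the literal quadruple-loop evaluation", {
  set.seed(41)
  params <- ls_params()
  for (rep in 1:3) {
    h <- sample(8:12, 1)
    w <- sample(8:12, 1)
    inst <- random_instance(h, w, 2L, kernel3)
    phi <- random_smooth_field(h, w, -6, 6, kernel3)
    got <- total_energy(inst$I, inst$b, inst$d, inst$cvec, list(phi),
                        params, kernel3)
    want <- oracle_total_energy(inst$I, inst$b, inst$d, inst$cvec,
                                list(phi), params, kernel3)
    expect_lt(abs(got - want) / (1 + abs(want)), 1e-10)
    expect_gt(got, 0)
  }
  # three-phase energy too
  inst <- random_instance(8, 8, 3L, kernel3)
  phis <- list(random_smooth_field(8, 8, -4, 4, kernel3),
               random_smooth_field(8, 8, -4, 4, kernel3))
  p3 <- ls_params(n_classes = 3L)
  got <- total_energy(inst$I, inst$b, inst$d, inst$cvec, phis, p3, kernel3)
  want <- oracle_total_energy(inst$I, inst$b, inst$d, inst$cvec, phis, p3,
                              kernel3)
  expect_lt(abs(got - want) / (1 + abs(want)), 1e-10)
})

test_that("energy reduces to the regularization terms when every class fits exactly", {
  h <- 30; w <- 30
  phi <- matrix(rep(seq_len(h) - 15.5, w), h, w)  # signed distance, straight edge
  params <- ls_params()
  # both class means equal the (constant) true intensity: f1 = f2 = 0
  v <- 120
  b <- matrix(1, h, w)
  d <- matrix(0, h, w)
  e <- total_energy(b * v, b, d, c(v, v), list(phi), params, kernel3)
  g <- oracle_grad(phi)
  gm <- sqrt(g$fx^2 + g$fy^2)
  reg <- params$alpha * 0.5 * sum((gm - 1)^2) +
    params$beta * sum(dirac(phi, params$epsilon) * gm)
  expect_equal(e, reg, tolerance = 1e-10)
  # interior level lines are unit-speed, so the length term dominates and
  # equals beta times the smoothed contour measure there
  expect_gt(e, 0)
})

test_that("each closed-form update does not increase the energy", {
  # each update is applied to the same starting configuration with the
  # other unknowns held fixed; instances follow the model's assumptions
  # (forward-model image, slowly varying fields)
  set.seed(53)
  params <- ls_params()
  for (rep in 1:10) {
    inst <- random_forward_instance(16, 16)
    u <- memberships_two_phase(inst$phi, params$epsilon)
    ener <- function(b, d, cvec) {
      total_energy(inst$I, b, d, cvec, list(inst$phi), params, kernel3)
    }
    b0 <- inst$b; d0 <- inst$d; c0 <- inst$cvec
    e0 <- ener(b0, d0, c0)
    tol <- 1e-9 * (1 + abs(e0))
    expect_lte(ener(b0, d0, update_c(inst$I, b0, d0, u, kernel3)),
               e0 + tol)
    expect_lte(ener(update_b(inst$I, d0, c0, u, kernel3), d0, c0),
               e0 + tol)
    expect_lte(ener(b0, update_d(inst$I, b0, c0, u, kernel3), c0),
               e0 + tol)
  }
})

test_that("with the difference field clamped to zero the updates equal the baseline forms bit for bit", {
  set.seed(61)
  h <- 11; w <- 13
  inst <- random_instance(h, w, 2L, kernel3)
  zero <- matrix(0, h, w)
  expect_identical(update_b(inst$I, zero, inst$cvec, inst$u, kernel3),
                   li_update_b(inst$I, inst$cvec, inst$u, kernel3))
  expect_identical(update_c(inst$I, inst$b, zero, inst$u, kernel3),
                   li_update_c(inst$I, inst$b, inst$u, kernel3))
  expect_identical(fit_maps(inst$I, inst$b, zero, inst$cvec, kernel3),
                   li_fit_maps(inst$I, inst$b, inst$cvec, kernel3))
})

test_that("a local artifact lands in the difference field, growing with its amplitude", {
  suite <- default_phantom_suite()
  ph <- generate_phantom(suite$tshape_clean)
  h <- nrow(ph$image); w <- ncol(ph$image)
  u <- lapply(1:2, function(i) {
    m <- matrix(0, h, w); m[ph$true_labels == i] <- 1; m
  })
  patch <- matrix(FALSE, h, w)
  patch[91:100, 91:100] <- TRUE
  # well-fit image: d stays at noise level (zero here)
  d0 <- update_d(ph$image, ph$true_bias, ph$true_means, u, kernel3)
  expect_lt(max(abs(d0)), 1e-9)
  peaks <- vapply(c(10, 20, 40), function(A) {
    I <- ph$image
    I[patch] <- I[patch] + A
    d <- update_d(I, ph$true_bias, ph$true_means, u, kernel3)
    max(abs(d[patch]))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_gt(peaks[1], 5)
})

test_that("corrected image inverts the forward model", {
  set.seed(71)
  b <- random_smooth_field(10, 10, 0.8, 1.2, kernel3)
  d <- random_smooth_field(10, 10, -3, 3, kernel3)
  J <- matrix(sample(c(60, 160), 100, replace = TRUE), 10, 10)
  I <- b * J + d
  expect_equal(corrected_image(I, b, d), J, tolerance = 1e-12)
})
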