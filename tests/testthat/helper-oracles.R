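# Independent brute-force oracles: literal loop transcriptions of the
# closed-form updates, fit maps, energy, and evolution steps, plus an
# independently coded baseline (difference field absent) evolution.
# These share only the kernel weights with the package; every sum is an
# explicit loop over pixels and window offsets.

clamp <- function(i, n) pmin(pmax(i, 1L), n)

# Replicate-padded correlation with the (symmetric) kernel weights.
conv_brute <- function(f, kernel) {
  w <- kernel$weights
  k <- kernel$half_width * 2L
  h <- nrow(f)
  wd <- ncol(f)
  out <- matrix(0, h, wd)
  for (i in seq_len(h)) {
    for (j in seq_len(wd)) {
      s <- 0
      for (a in -k:k) {
        for (b in -k:k) {
          s <- s + w[a + k + 1L, b + k + 1L] *
            f[clamp(i + a, h), clamp(j + b, wd)]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

oracle_update_c <- function(I, b, d, u, kernel) {
  kb <- conv_brute(b, kernel)
  kb2 <- conv_brute(b * b, kernel)
  vapply(u, function(ui) sum(kb * (I - d) * ui) / sum(kb2 * ui), numeric(1))
}

oracle_update_b <- function(I, d, cvec, u, kernel) {
  j1 <- 0
  j2 <- 0
  for (i in seq_along(u)) {
    j1 <- j1 + cvec[i] * u[[i]]
    j2 <- j2 + cvec[i]^2 * u[[i]]
  }
  conv_brute((I - d) * j1, kernel) / conv_brute(j2, kernel)
}

oracle_update_d <- function(I, b, cvec, u, kernel) {
  m1 <- 0
  m2 <- 0
  for (i in seq_along(u)) {
    m1 <- m1 + I * u[[i]] - b * cvec[i] * u[[i]]
    m2 <- m2 + u[[i]]
  }
  conv_brute(m1, kernel) / conv_brute(m2, kernel)
}

# f_i(x) = sum_y K(y - x) (I(x) - b(y) c_i - d(y))^2, literal double loop.
oracle_fit_maps <- function(I, b, d, cvec, kernel) {
  w <- kernel$weights
  k <- kernel$half_width * 2L
  h <- nrow(I)
  wd <- ncol(I)
  lapply(cvec, function(ci) {
    out <- matrix(0, h, wd)
    for (i in seq_len(h)) {
      for (j in seq_len(wd)) {
        s <- 0
        for (a in -k:k) {
          for (b_ in -k:k) {
            yi <- clamp(i + a, h)
            yj <- clamp(j + b_, wd)
            s <- s + w[a + k + 1L, b_ + k + 1L] *
              (I[i, j] - b[yi, yj] * ci - d[yi, yj])^2
          }
        }
        out[i, j] <- s
      }
    }
    out
  })
}

# Central differences with clamped (replicated) edge indices.
oracle_grad <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  fx <- matrix(0, h, w)
  fy <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      fx[i, j] <- (m[clamp(i + 1L, h), j] - m[clamp(i - 1L, h), j]) / 2
      fy[i, j] <- (m[i, clamp(j + 1L, w)] - m[i, clamp(j - 1L, w)]) / 2
    }
  }
  list(fx = fx, fy = fy)
}

oracle_total_energy <- function(I, b, d, cvec, phis, params, kernel) {
  u <- if (length(phis) == 1L) {
    hh <- heaviside(phis[[1]], params$epsilon)
    list(hh, 1 - hh)
  } else {
    h1 <- heaviside(phis[[1]], params$epsilon)
    h2 <- heaviside(phis[[2]], params$epsilon)
    list(h1 * h2, h1 * (1 - h2), 1 - h1)
  }
  f <- oracle_fit_maps(I, b, d, cvec, kernel)
  e <- 0
  for (i in seq_along(u)) e <- e + sum(f[[i]] * u[[i]])
  for (phi in phis) {
    g <- oracle_grad(phi)
    gm <- sqrt(g$fx^2 + g$fy^2)
    e <- e + params$alpha * 0.5 * sum((gm - 1)^2) +
      params$beta * sum(dirac(phi, params$epsilon) * gm)
  }
  e
}

# Literal transcription of the two-phase explicit step.
oracle_step_2p <- function(phi, f1, f2, params) {
  g <- oracle_grad(phi)
  nm <- sqrt(g$fx^2 + g$fy^2 + 1e-10)
  nxy <- oracle_grad(g$fx / nm)
  nyy <- oracle_grad(g$fy / nm)
  kap <- nxy$fx + nyy$fy
  h <- nrow(phi)
  w <- ncol(phi)
  lap <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      lap[i, j] <- phi[clamp(i + 1L, h), j] + phi[clamp(i - 1L, h), j] +
        phi[i, clamp(j + 1L, w)] + phi[i, clamp(j - 1L, w)] - 4 * phi[i, j]
    }
  }
  del <- dirac(phi, params$epsilon)
  phi + params$dt * (del * (f2 - f1) + params$alpha * (lap - kap) +
                       params$beta * del * kap)
}

# Literal transcription of the coupled three-phase step (both updates from
# the incoming state).
oracle_step_3p <- function(phi1, phi2, f1, f2, f3, params) {
  step_one <- function(phi, force) {
    g <- oracle_grad(phi)
    nm <- sqrt(g$fx^2 + g$fy^2 + 1e-10)
    nxy <- oracle_grad(g$fx / nm)
    nyy <- oracle_grad(g$fy / nm)
    kap <- nxy$fx + nyy$fy
    h <- nrow(phi)
    w <- ncol(phi)
    lap <- matrix(0, h, w)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        lap[i, j] <- phi[clamp(i + 1L, h), j] + phi[clamp(i - 1L, h), j] +
          phi[i, clamp(j + 1L, w)] + phi[i, clamp(j - 1L, w)] -
          4 * phi[i, j]
      }
    }
    del <- dirac(phi, params$epsilon)
    phi + params$dt * (del * force + params$alpha * (lap - kap) +
                         params$beta * del * kap)
  }
  del_free_force1 <- (f2 - f1) * heaviside(phi2, params$epsilon) + f3 - f2
  del_free_force2 <- (f2 - f1) * heaviside(phi1, params$epsilon)
  list(phi1 = step_one(phi1, del_free_force1),
       phi2 = step_one(phi2, del_free_force2))
}

# Independently coded baseline evolution (Li's model: bias and means only,
# no difference field), mirroring the two-phase driver's loop structure.
li_update_b <- function(I, cvec, u, kernel) {
  j1 <- Reduce(`+`, Map(function(ci, ui) ci * ui, cvec, u))
  j2 <- Reduce(`+`, Map(function(ci, ui) ci^2 * ui, cvec, u))
  local_convolve(I * j1, kernel) / local_convolve(j2, kernel)
}

li_update_c <- function(I, b, u, kernel) {
  kb <- local_convolve(b, kernel)
  kb2 <- local_convolve(b * b, kernel)
  vapply(u, function(ui) sum(kb * I * ui) / sum(kb2 * ui), numeric(1))
}

li_fit_maps <- function(I, b, cvec, kernel) {
  k1 <- local_convolve(matrix(1, nrow(I), ncol(I)), kernel)
  kb <- local_convolve(b, kernel)
  kb2 <- local_convolve(b * b, kernel)
  zero <- matrix(0, nrow(I), ncol(I))
  kd <- local_convolve(zero, kernel)
  kd2 <- local_convolve(zero, kernel)
  kbd <- local_convolve(zero, kernel)
  i2 <- I * I
  lapply(cvec, function(ci) {
    i2 * k1 - 2 * I * (ci * kb + kd) + (ci^2 * kb2 + 2 * ci * kbd + kd2)
  })
}

li_evolve <- function(I, init_mask, params, n_iters) {
  phi <- init_level_set(dim(I), init_mask, params$c0, params$seed_positive)
  b <- matrix(1, nrow(I), ncol(I))
  u <- memberships_two_phase(phi, params$epsilon)
  kernel <- build_kernel(params$sigma)
  cvec <- li_update_c(I, b, u, kernel)
  for (k in seq_len(n_iters)) {
    u <- memberships_two_phase(phi, params$epsilon)
    cvec <- li_update_c(I, b, u, kernel)
    b <- li_update_b(I, cvec, u, kernel)
    f <- li_fit_maps(I, b, cvec, kernel)
    del <- dirac(phi, params$epsilon)
    kap <- curvature(phi)
    phi <- phi + params$dt * (
      del * (f[[2]] - f[[1]]) + params$alpha * (laplacian(phi) - kap) +
        params$beta * del * kap
    )
  }
  list(phi = phi, b = b, cvec = cvec)
}

# Random test-instance builders ------------------------------------------

# Smooth random field in [lo, hi]: kernel-smoothed white noise, rescaled.
random_smooth_field <- function(h, w, lo, hi, kernel) {
  f <- local_convolve(matrix(rnorm(h * w), h, w), kernel)
  if (max(f) > min(f)) {
    f <- (f - min(f)) / (max(f) - min(f))
  } else {
    f <- matrix(0.5, h, w)
  }
  lo + (hi - lo) * f
}

# Crisp random partition into n classes, each guaranteed non-empty.
random_partition <- function(h, w, n) {
  repeat {
    lab <- matrix(sample.int(n, h * w, replace = TRUE), h, w)
    if (all(tabulate(lab, n) > 0)) break
  }
  lapply(seq_len(n), function(i) {
    m <- matrix(0, h, w)
    m[lab == i] <- 1
    m
  })
}

random_instance <- function(h, w, n_classes = 2L, kernel) {
  list(
    I = matrix(runif(h * w, 0, 255), h, w),
    b = random_smooth_field(h, w, 0.7, 1.3, kernel),
    d = random_smooth_field(h, w, -8, 8, kernel),
    u = random_partition(h, w, n_classes),
    cvec = runif(n_classes, 20, 230)
  )
}

# Instance drawn from the model's own regime: a blobby two-class scene,
# a slowly varying (low-order polynomial) true bias, forward-model image
# I = b.J + noise, and slowly varying starting fields.  The closed-form
# updates are descent steps of the clustering energy in this regime.
random_forward_instance <- function(h, w) {
  x <- matrix(seq_len(h) / h, h, w)
  y <- matrix(rep(seq_len(w) / w, each = h), h, w)
  poly <- function(scale) {
    a <- runif(4, -1, 1)
    scale * (a[1] * x + a[2] * y + a[3] * x * y +
               a[4] * (x - 0.5)^2) / 2
  }
  repeat {
    phi <- 3 * (sin(2 * pi * runif(1, 0.6, 1.4) * x + runif(1, 0, 6)) +
                  sin(2 * pi * runif(1, 0.6, 1.4) * y + runif(1, 0, 6)))
    if (sum(phi > 0) > 20 && sum(phi <= 0) > 20) break
  }
  labels <- (phi <= 0) + 1
  cvec_true <- c(runif(1, 40, 90), runif(1, 140, 220))
  b_true <- 0.95 + poly(0.3)
  I <- b_true * matrix(cvec_true[labels], h, w) +
    matrix(rnorm(h * w, 0, 5), h, w)
  list(
    I = I, phi = phi,
    b = 0.95 + poly(0.3),      # starting bias, distinct from b_true
    d = poly(8),
    cvec = cvec_true * runif(2, 0.7, 1.3)
  )
}

# Relative-to-magnitude closeness check.
max_rel_err <- function(got, want) {
  max(abs(got - want)) / (1 + max(abs(want)))
}
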