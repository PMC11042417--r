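test_that("null initial data stays null", {
  med <- medium(array(1, c(16, 16)), spacing = 1 / 16)
  wf <- simulate_wave_field(med, array(0, c(16, 16)), dt = 0.05,
                            n_steps = 10)
  expect_equal(max(abs(wf$phi)), 0)
})

test_that("homogeneous medium damps a plane wave at rate Sigma", {
  n <- 32; h <- 1 / n
  x <- (0:(n - 1)) * h
  g <- 1.3
  med <- medium(array(g, c(n, n)), spacing = h)
  phi0 <- matrix(rep(cos(2 * pi * 4 * x), n), n, n)
  wf <- simulate_wave_field(med, phi0, dt = 0.05, n_steps = 20)
  amp <- apply(wf$phi, 3, function(p) max(abs(p)))
  fit <- stats::lm(log(amp) ~ wf$times)
  expect_equal(unname(stats::coef(fit)[2]), -g, tolerance = 0.02)
  # no measurable oscillation: the projection phase stays fixed
  pr <- apply(wf$phi, 3, function(p) sum(p * phi0))
  expect_true(all(pr > 0))
})

test_that("the simulator conserves the zero mean of the Laplacian", {
  n <- 24; h <- 1 / n
  x <- (0:(n - 1)) * h
  sig <- 1 + 0.5 * outer(sin(2 * pi * x), cos(2 * pi * x))
  med <- medium(sig, spacing = h)
  set.seed(5)
  phi0 <- matrix(rnorm(n * n), n, n)
  wf <- simulate_wave_field(med, phi0, dt = 0.05, n_steps = 15)
  for (i in seq_len(dim(wf$phi)[3])) {
    expect_lt(abs(mean(laplacian(wf$phi[, , i], spacing = h))),
              1e-10 * max(abs(wf$phi[, , 1])))
    expect_lt(abs(mean(wf$phi[, , i])), 1e-10)
  }
})

test_that("the stability guard rejects oversized steps by name", {
  med <- medium(array(100, c(16, 16)), spacing = 1 / 16)
  expect_error(simulate_wave_field(med, array(1, c(16, 16)),
                                   dt = 0.01, n_steps = 5),
               "stability guard")
})

test_that("a plane-wave packet obeys the local dispersion relation", {
  # 2D periodic domain with a sinusoidal conductivity profile; the
  # packet sits at the zero crossing where the gradient is maximal and
  # locally linear.  Complex initial data isolates one wave branch.
  n <- 96; L <- 1; h <- L / n
  x <- (0:(n - 1)) * h
  s0 <- 1; s1 <- 0.5; K <- 2 * pi / L
  med <- medium(matrix(rep(s0 + s1 * sin(K * x), n), n, n), spacing = h)
  m <- 18; k <- 2 * pi * m / L
  sw <- 5 * h
  w <- exp(-0.5 * (x / sw)^2) + exp(-0.5 * ((x - L) / sw)^2)
  phi0 <- matrix(rep(w * exp(1i * k * x), n), n, n)
  wf <- simulate_wave_field(med, phi0, dt = 0.05, n_steps = 30)
  W <- matrix(rep(w, n), n, n)
  A <- sapply(seq_len(dim(wf$phi)[3]),
              function(i) sum(W * wf$phi[, , i] * exp(-1i * k * x)))
  tt <- wf$times
  sl <- sum((tt - mean(tt)) * (log(A) - mean(log(A)))) /
    sum((tt - mean(tt))^2)
  oracle <- dispersion(c(k, 0), Sigma = s0, div_Sigma = c(s1 * K, 0))
  expect_equal(-Re(sl), oracle$gamma, tolerance = 0.05)
  expect_equal(abs(Im(sl)), abs(oracle$omega), tolerance = 0.05)
})

test_that("transverse boundary-layer mode conserves energy; parallel decays", {
  n <- 64
  y <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi0 <- cos(4 * y)
  # transverse: Omega = -b/k is real; RK4 drift stays tiny
  wf <- simulate_boundary_layer(a = 0, b = 1, branch = "transverse",
                                phi0 = phi0, dt = 0.2, n_steps = 150)
  E <- colSums(wf$phi^2)
  period <- 2 * pi / abs(-1 / 4)
  drift_per_period <- abs(E[length(E)] / E[1] - 1) /
    (wf$times[length(wf$times)] / period)
  expect_lt(drift_per_period, 1e-6)
  # phase rotates at the transverse eigenfrequency
  z <- apply(wf$phi, 2, function(p) sum(p * exp(-1i * 4 * y)))
  om_fit <- mean(Arg(z[-1] / z[-length(z)])) / wf$dt
  expect_equal(abs(om_fit), 1 / 4, tolerance = 0.01)

  # parallel: decay at |a| k^2
  wf2 <- simulate_boundary_layer(a = -0.01, b = 0.3, branch = "parallel",
                                 phi0 = phi0, dt = 0.02, n_steps = 500)
  amp <- apply(wf2$phi, 2, function(p) Mod(sum(p * exp(-1i * 4 * y))))
  dec <- -stats::coef(stats::lm(log(amp) ~ wf2$times))[2]
  expect_equal(unname(dec), 0.01 * 16, tolerance = 0.02)
})

test_that("harmonic steady state equals the long-time driven simulation", {
  # non-stiff two-tissue medium with constant permittivity, driven at a
  # fixed frequency: after the transients die out the RK4 solution must
  # oscillate with the complex amplitude of the frequency-domain solve.
  n <- 16
  labs <- array(5L, c(n, n, n))
  labs[1:(n / 2), , ] <- 4L
  g <- tissue_grid(labs, voxel_size = 50)   # large voxels -> small k
  eps <- 1e7
  sig1 <- 1.0 * eps * 8.854187817e-12       # scaled rates 1.0 and 1.6
  sig2 <- 1.6 * eps * 8.854187817e-12
  tab <- tissue_properties(sigma = c(background = sig1, scalp = sig1,
                                     skull = sig1, csf = sig1,
                                     gm = sig1, wm = sig2),
                           eps_rel = c(background = eps, scalp = eps,
                                       skull = eps, csf = eps,
                                       gm = eps, wm = eps))
  pf <- property_fields(g, table = tab, smooth_width = 100)
  freq <- 0.16
  blob <- array(0, c(n, n, n))
  blob[n / 2, n / 2, n / 2] <- 1
  blob <- invert_laplacian(blob, spacing = 1)  # smooth-ish source
  blob <- blob / max(abs(blob))
  omega <- 2 * pi * freq
  truth <- harmonic_response(pf, blob / (pf$sigma_bar_scaled - 1i * omega),
                             freq)
  dt <- 0.05
  n_per <- round(1 / (freq * dt))
  n_steps <- round(12 / dt)                  # ~19 damping times
  wf <- simulate_wave_field(pf, array(0, c(n, n, n)), dt = dt,
                            n_steps = n_steps,
                            forcing = list(amplitude = blob, freq = freq),
                            apodize = FALSE)
  nt <- dim(wf$phi)[4]
  win <- (nt - n_per + 1):nt
  osc <- exp(1i * omega * wf$times[win])
  probes <- rbind(c(5, 8, 8), c(12, 8, 8), c(8, 5, 11))
  for (p in seq_len(nrow(probes))) {
    ts <- wf$phi[probes[p, 1], probes[p, 2], probes[p, 3], win]
    ahat <- 2 * mean(ts * osc)
    expect_equal(ahat, truth[probes[p, 1], probes[p, 2], probes[p, 3]],
                 tolerance = 0.05)
  }
})
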