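test_that("band transform recovers on-bin sinusoids and Parseval", {
  fs <- 64; n <- 64
  tt <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 10 * tt)
  rec <- eeg_recording(rbind(x, 2 * x), fs)
  bt <- band_transform(rec, c(8, 12))
  expect_equal(bt$bins, 8:11)
  expect_equal(unname(Mod(bt$coef[1, bt$bins == 10])), 1,
               tolerance = 1e-10)
  expect_equal(unname(Mod(bt$coef[2, bt$bins == 10])), 2,
               tolerance = 1e-10)
  # the synthesis convention: x(t) = sum Re[d exp(-2i pi f t)]
  d <- bt$coef[1, bt$bins == 10]
  expect_equal(Re(d * exp(-2i * pi * 10 * tt)), x, tolerance = 1e-10)
  # off-band energy of an on-bin sinusoid is negligible
  bt2 <- band_transform(rec, c(20, 30))
  expect_lt(max(Mod(bt2$coef[1, ])), 0.01)
  # Parseval: sum of |d|^2/2 over all positive bins = signal power
  y <- 0.7 * sin(2 * pi * 5 * tt + 0.3) + 0.2 * cos(2 * pi * 13 * tt)
  bty <- band_transform(eeg_recording(rbind(y), fs), c(0, fs / 2))
  expect_equal(sum(Mod(bty$coef)^2) / 2, mean(y^2), tolerance = 1e-10)
  expect_error(band_transform(rec, c(8.2, 8.4)), "no DFT bins")
  expect_error(band_transform(rec, c(12, 8)), "band")
})

test_that("Laplacian inversion is the spectral inverse with zero gauge", {
  n <- 32; h <- 1 / n
  x <- (0:(n - 1)) * h
  f <- sin(2 * pi * x)
  u <- invert_laplacian(f, spacing = h)
  expect_equal(u, -(1 / (2 * pi))^2 * f, tolerance = 1e-12)
  expect_equal(invert_laplacian(rep(3, n)), rep(0, n))
  set.seed(2)
  g3 <- array(rnorm(16^3), c(16, 16, 16))
  round_trip <- laplacian(invert_laplacian(g3, h), h)
  expect_equal(round_trip, g3 - mean(g3), tolerance = 1e-10)
})

test_that("the tissue operator vanishes on homogeneous media", {
  labs <- array(4L, c(16, 16, 16))
  pf <- property_fields(tissue_grid(labs, 2), smooth_width = 0)
  set.seed(3)
  phi <- array(complex(real = rnorm(16^3), imaginary = rnorm(16^3)),
               c(16, 16, 16))
  out <- apply_R(phi, pf, omega = 2 * pi * 10)
  expect_lt(max(Mod(out)), 1e-10 * max(Mod(phi)))
})

test_that("the gradient term matches its closed form", {
  # eps constant, sigma sinusoidal along x, plane-wave phi: the only
  # surviving term is -P (d sigma/dx)(d phi/dx), all factors analytic
  n <- 32
  vx <- 4                                   # mm
  labs <- array(4L, c(n, n, n))
  g <- tissue_grid(labs, vx)
  pf <- property_fields(g, smooth_width = 0)
  L <- n * vx * 1e-3                        # meters
  xm <- (0:(n - 1)) * vx * 1e-3
  s0 <- 2.75e-2; s1 <- 0.3 * s0; K <- 2 * pi / L
  sig1 <- s0 + s1 * sin(K * xm)
  pf$sigma <- array(rep(sig1, n * n), c(n, n, n))
  pf$sigma_bar <- pf$sigma
  pf$div_sigma <- list(array(rep(s1 * K * cos(K * xm), n * n), c(n, n, n)),
                       array(0, c(n, n, n)), array(0, c(n, n, n)))
  k <- 2 * pi * 3 / L
  phi <- array(rep(exp(1i * k * xm), n * n), c(n, n, n))
  omega <- 2 * pi * 10
  got <- apply_R(phi, pf, omega)
  P <- (pf$sigma_bar + 1i * omega * pf$eps_abs) /
    (pf$sigma_bar^2 + omega^2 * pf$eps_abs^2)
  want <- -P * pf$div_sigma[[1]] * 1i * k * phi
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("the spectral operator agrees with a finite-difference oracle", {
  pf <- property_fields(tiny_phantom(), smooth_width = 8)
  n <- pf$grid$shape[1]
  h <- pf$grid$voxel_size[1] * 1e-3
  # smooth band-limited test potential
  xm <- (0:(n - 1)) / n
  phi <- outer(outer(sin(2 * pi * xm), cos(2 * pi * xm), `+`),
               sin(2 * pi * xm) + 1, `*`)
  omega <- 2 * pi * 10
  got <- apply_R(phi, pf, omega)
  # independent discretization: 2nd-order central differences of the
  # same expression (periodic shifts)
  shp <- function(a, d, s) {
    idx <- rep(list(quote(expr =)), 3)
    nn <- dim(a)[d]
    idx[[d]] <- c((1 + s):nn, seq_len(s))
    do.call(`[`, c(list(a), idx))
  }
  cdiff <- function(a, d) (shp(a, d, 1) - shp(a, d, nn <- dim(a)[d] - 1)) /
    (2 * h)
  P <- (pf$sigma_bar + 1i * omega * pf$eps_abs) /
    (pf$sigma_bar^2 + omega^2 * pf$eps_abs^2)
  want <- array(0i, dim(phi))
  for (i in 1:3)
    want <- want + 1i * omega * pf$grad_eps[[i]] * cdiff(phi, i) -
      pf$div_sigma[[i]] * cdiff(phi, i)
  want <- P * want
  relerr <- max(Mod(got - want)) / max(Mod(got))
  expect_lt(relerr, 0.05)
})

test_that("reconstruction is linear and vanishes on zero data", {
  s32 <- study32()
  rec0 <- eeg_recording(matrix(0, 48, 64), 64, sensors = s32$sen)
  fit0 <- spectre(rec0, s32$pf, band = c(8, 12))
  expect_true(all(vapply(fit0$phi, function(p) max(Mod(p)), 0) == 0))

  fit1 <- fit32()
  rec3 <- s32$st$recording
  rec3$data <- 3 * rec3$data
  fit3 <- spectre(rec3, s32$pf, band = c(8, 12))
  for (b in seq_along(fit1$bins))
    expect_equal(fit3$phi[[b]], 3 * fit1$phi[[b]], tolerance = 1e-6)
})

test_that("deep-source recovery on the scaled fixture", {
  s32 <- study32()
  fit <- fit32()
  bp <- band_power(fit)
  tp <- Mod(s32$st$phi_hat[[1]])^2
  r <- stats::cor(bp[s32$brain], tp[s32$brain])
  expect_gt(r, 0.7)
  pk <- arrayInd(which.max(bp * s32$brain), dim(bp))
  tpk <- arrayInd(which.max(tp * s32$brain), dim(tp))
  expect_lt(sqrt(sum((pk - tpk)^2)), 5)
  # sensor fit is tight and the scale factor is near unity
  expect_true(all(fit$misfit < 0.05))
  expect_true(all(abs(Mod(fit$alpha) - 1) < 0.2))
})

test_that("recovery degrades gracefully under 10 dB sensor noise", {
  s32 <- study32()
  stN <- synthesize_study(s32$g, s32$pf, s32$src, duration = 1, fs = 64,
                          sensors = s32$sen, snr_db = 10, seed = 7)
  fitN <- spectre(stN$recording, s32$pf, band = c(8, 12))
  tp <- Mod(s32$st$phi_hat[[1]])^2
  r0 <- stats::cor(band_power(fit32())[s32$brain], tp[s32$brain])
  rN <- stats::cor(band_power(fitN)[s32$brain], tp[s32$brain])
  expect_gt(rN, 0.9 * r0)
})

test_that("more relaxation iterations never worsen the sensor fit", {
  s32 <- study32()
  # max_iter = 2 is deliberately too few iterations; the solver warns
  fit_few <- suppressWarnings(
    spectre(s32$st$recording, s32$pf, band = c(9.5, 10.5), max_iter = 2))
  fit_many <- spectre(s32$st$recording, s32$pf, band = c(9.5, 10.5),
                      max_iter = 40)
  expect_lte(fit_many$misfit[1], fit_few$misfit[1] + 1e-9)
})

test_that("time-domain conversion is the inverse transform", {
  fit <- fit32()
  wf <- to_time_domain(fit)
  expect_false(is.complex(wf$phi))
  # per-voxel DFT of the synthesized series returns the bin volumes
  v <- c(17, 17, 17)
  ts <- wf$phi[v[1], v[2], v[3], ]
  dhat <- Conj(stats::fft(ts)) * 2 / length(ts)
  for (b in seq_along(fit$bins)) {
    bin <- fit$bins[b] + 1           # 1 Hz spacing, DC at index 1
    expect_equal(dhat[bin], fit$phi[[b]][v[1], v[2], v[3]],
                 tolerance = 1e-8)
  }
  # band power equals twice the time-domain variance (Parseval)
  bp <- band_power(fit)
  vars <- apply(wf$phi[15:19, 17, 17, , drop = FALSE], 1:3, stats::var)
  expect_equal(2 * as.vector(vars) * (63 / 64),
               bp[15:19, 17, 17], tolerance = 1e-6)
})

test_that("band power is the squared magnitude summed over bins", {
  fit <- fit32()
  bp <- band_power(fit)
  expect_equal(band_power(lapply(fit$phi, function(p) 2 * p)), 4 * bp)
  byhand <- Reduce(`+`, lapply(fit$phi, function(p) Re(p)^2 + Im(p)^2))
  expect_equal(bp, byhand)
})

test_that("model methods are mutually consistent", {
  fit <- fit32()
  f <- fitted(fit)
  r <- residuals(fit)
  expect_equal(f + r, fit$coef, tolerance = 1e-12)
  expect_equal(unname(Mod(coef(fit))), Mod(fit$alpha))
  p <- predict(fit, as.matrix(fit$sensors[1:3, c("x", "y", "z")]))
  expect_equal(p, unname(f[1:3, ]), tolerance = 1e-12)
  s <- summary(fit)
  expect_equal(s$rel_misfit, fit$misfit)
})
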