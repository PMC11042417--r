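test_that("coupling matrix reproduces hand-set correlations", {
  T <- 64
  tt <- seq_len(T)
  u <- sin(2 * pi * tt / T); u <- (u - mean(u)) / stats::sd(u)
  v <- cos(2 * pi * tt / T); v <- (v - mean(v)) / stats::sd(v)
  w <- sin(4 * pi * tt / T); w <- (w - mean(w)) / stats::sd(w)
  x1 <- u
  x2 <- 0.5 * u + sqrt(0.75) * v
  x3 <- w
  field <- array(t(cbind(x1, x2, x3)), c(3, 1, T))
  Q <- coupling_matrix(field)$Q
  expect_equal(Q[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(Q[1, 3], 0, tolerance = 1e-12)
  expect_equal(diag(Q), rep(1, 3))
  # identical time courses couple at exactly 1
  f2 <- array(rbind(x1, x1), c(2, 1, T))
  expect_equal(coupling_matrix(f2)$Q[1, 2], 1)
})

test_that("white-noise couplings concentrate near zero", {
  set.seed(10)
  nv <- 40; T <- 1000
  field <- array(rnorm(nv * T), c(nv, 1, T))
  Q <- coupling_matrix(field)$Q
  off <- Q[upper.tri(Q)]
  expect_gt(mean(off < 0.1), 0.95)
})

test_that("constant voxels are dropped with a warning", {
  T <- 32
  field <- array(rnorm(3 * T), c(3, 1, T))
  field[2, 1, ] <- 5
  expect_warning(cm <- coupling_matrix(field), "constant")
  expect_equal(nrow(cm$Q), 2L)
})

test_that("subsampling is deterministic and bounded", {
  set.seed(1)
  field <- array(rnorm(100 * 32), c(100, 1, 32))
  c1 <- coupling_matrix(field, max_voxels = 30, seed = 5)
  c2 <- coupling_matrix(field, max_voxels = 30, seed = 5)
  expect_identical(c1$voxels, c2$voxels)
  expect_lte(nrow(c1$Q), 30)
})

test_that("equilibrium distribution follows the coupling spectrum", {
  Q <- rbind(c(1, .5, 0), c(.5, 1, 0), c(0, 0, 1))
  es <- esp_equilibrium(Q)
  expect_equal(max(es$values), 1.5)
  expect_equal(es$mu_star, c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(sum(es$mu_star), 1)
  # exchangeable voxels get equal equilibrium mass
  Qs <- rbind(c(1, .3, .6), c(.3, 1, .6), c(.6, .6, 1))
  ess <- esp_equilibrium(Qs)
  expect_equal(ess$mu_star[1], ess$mu_star[2], tolerance = 1e-12)
  # degenerate spectrum: all eigenvalues 1
  expect_equal(esp_equilibrium(diag(4))$values, rep(1, 4))
  expect_error(esp_equilibrium(matrix(c(1, NA, NA, 1), 2)), "finite")
})

test_that("mu_star is permutation-equivariant", {
  set.seed(8)
  X <- matrix(rnorm(6 * 50), 6, 50)
  Q <- abs(stats::cor(t(X)))
  perm <- c(4, 1, 6, 2, 5, 3)
  mu <- esp_equilibrium(Q)$mu_star
  mu_p <- esp_equilibrium(Q[perm, perm])$mu_star
  expect_equal(mu_p, mu[perm], tolerance = 1e-10)
})

test_that("a rank-1 field concentrates in the first mode", {
  nv <- 25; T <- 48
  set.seed(2)
  # correlation coupling is amplitude-blind, so keep the spatial
  # profile near-uniform for a truly rank-1 mode structure
  pattern <- 1 + 0.1 * runif(nv)
  ts <- sin(2 * pi * seq_len(T) / 16)
  field <- array(outer(pattern, ts) + 1e-4 * rnorm(nv * T), c(5, 5, T))
  fit <- efd(field, n = 2)
  s <- summary(fit)
  expect_gt(s$variance_share[1], 0.99)
})

test_that("an orthonormal decomposition conserves energy and completes", {
  set.seed(4)
  nv <- 30; T <- 64
  field <- array(rnorm(nv * T), c(nv, 1, T))
  fit <- efd(field, n = nv)
  # unweighted summed power over all modes = voxelwise total variance
  total <- sum(mode_power_map(fit, weights = "unit"))
  expect_equal(total, fit$total_variance, tolerance = 1e-10)
  # completeness: psi tau reconstructs the centred data exactly
  X <- matrix(field, nv, T)
  Xc <- X - rowMeans(X)
  expect_equal(fit$maps %*% fit$timecourses, Xc, tolerance = 1e-10)
  expect_error(efd(field, n = nv + 1), "exceeds")
})

test_that("two orthogonal patterns give two clean modes", {
  nv <- 60; T <- 128
  tt <- seq_len(T)
  a <- sin(2 * pi * tt / 16)
  b <- cos(2 * pi * tt / 16)        # exactly orthogonal to a
  # unequal supports keep the two coupling eigenvalues distinct
  p1 <- c(rep(1, 35), rep(0, 25))
  p2 <- c(rep(0, 35), rep(1, 25))
  field <- array(outer(p1, a) + outer(p2, b), c(nv, 1, T))
  fit <- efd(field, n = 2)
  # eigenvalues 35 > 25 order the modes: mode 1 belongs to p1
  cors <- abs(stats::cor(fit$maps, cbind(p1, p2)))
  expect_gt(cors[1, 1], 0.95)
  expect_gt(cors[2, 2], 0.95)
  # the two modes carry all the variance
  expect_equal(sum(mode_power_map(fit, weights = "unit")),
               fit$total_variance, tolerance = 1e-6)
})

test_that("contrast maps subtract and anticommute", {
  set.seed(6)
  A <- array(runif(27), c(3, 3, 3)); B <- array(runif(27), c(3, 3, 3))
  expect_equal(contrast_power(A, A), array(0, c(3, 3, 3)))
  expect_equal(contrast_power(A, B), -contrast_power(B, A))
  C1 <- A; C1[2, 2, 2] <- C1[2, 2, 2] + 2
  d <- contrast_power(C1, A)
  expect_equal(d[2, 2, 2], 2)
  expect_equal(sum(abs(d)), 2)
  expect_error(contrast_power(A, array(0, c(2, 2, 2))), "grids")
})

test_that("ROI power tables aggregate by region", {
  map <- array(0, c(4, 4, 1))
  atlas <- array(0L, c(4, 4, 1))
  atlas[1:2, 1, 1] <- 1L; atlas[3, 1, 1] <- 2L; atlas[4, 4, 1] <- 3L
  map[1:2, 1, 1] <- 1; map[3, 1, 1] <- 3
  tab <- roi_power_table(map, atlas)
  expect_equal(tab$mean_power[tab$region == 1], 1)
  expect_equal(tab$mean_power[tab$region == 2], 3)
  expect_equal(tab$region[1], 2)          # sorted by decreasing mean
  # uniform map: all regions equal
  tab2 <- roi_power_table(array(7, c(4, 4, 1)), atlas)
  expect_true(all(tab2$mean_power == 7))
  # impulse inside one region: only that region nonzero
  imp <- array(0, c(4, 4, 1)); imp[3, 1, 1] <- 5
  tab3 <- roi_power_table(imp, atlas)
  expect_equal(sum(tab3$mean_power > 0), 1L)
})

test_that("thresholded map correlation matches the hand formula", {
  A <- array(c(.2, .4, .6, .8), c(4, 1, 1))
  B <- array(c(.3, .5, .5, .9), c(4, 1, 1))
  r <- map_correlation(A, B, threshold = 0.1)
  a <- c(.2, .4, .6, .8); b <- c(.3, .5, .5, .9)
  by_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, by_hand, tolerance = 1e-12)
  expect_equal(map_correlation(A, A), 1)
  expect_equal(map_correlation(A, -A), -1)
  expect_error(map_correlation(A, B, threshold = 0.7), "fewer than 3")
  # affine rescaling with matching threshold leaves r unchanged
  expect_equal(map_correlation(5 * A, B, threshold = c(0.5, 0.1)), r)
})

test_that("slice-wise correlations flag constant slices", {
  set.seed(9)
  A <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  expect_equal(slicewise_correlation(A, A), rep(1, 5))
  B <- A; B[, , 3] <- -A[, , 3]
  sw <- slicewise_correlation(A, B)
  expect_equal(sw, c(1, 1, -1, 1, 1))
  # independent noise: small slice correlations on average
  C <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  expect_lt(mean(abs(slicewise_correlation(A, C))), 0.1)
  A2 <- A; A2[, , 2] <- 0
  expect_true(is.na(slicewise_correlation(A2, C)[2]))
})

test_that("Fisher z is the inverse hyperbolic tangent", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.74), atanh(0.74))
  expect_equal(fisher_z(0.74), 0.9505, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "< 1")
})
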