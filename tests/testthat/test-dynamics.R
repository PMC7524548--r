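test_that("lattice Laplacian is exact on polynomials of degree <= 2", {
  lat <- fix_ellipse$lattice
  interior <- interior_hexes(lat)
  x <- lat$centres[, 1L]
  y <- lat$centres[, 2L]
  expect_equal(hex_laplacian(rep(3.7, lat$n_hex), lat), rep(0, lat$n_hex))
  L <- hex_laplacian(x^2 + y^2, lat)
  expect_equal(L[interior], rep(4, sum(interior)), tolerance = 1e-10)
  L2 <- hex_laplacian(x^2 - y^2 + 2 * x * y + x - 3, lat)
  expect_equal(L2[interior], rep(0, sum(interior)), tolerance = 1e-10)
})

test_that("Laplacian telescopes to exactly zero total flux for any field", {
  lat <- fix_ellipse$lattice
  set.seed(11)
  for (rep in 1:3) {
    f <- runif(lat$n_hex)
    tot <- sum(hex_laplacian(f, lat)) * lat$omega
    expect_lt(abs(tot), 1e-12 * sum(abs(f)))
  }
})

test_that("lattice gradient is exact on linear fields and rotation-equivariant", {
  lat <- fix_ellipse$lattice
  interior <- interior_hexes(lat)
  g <- hex_gradient(2 * lat$centres[, 1L], lat)
  expect_equal(g[interior, 1L], rep(2, sum(interior)), tolerance = 1e-10)
  expect_equal(g[interior, 2L], rep(0, sum(interior)), tolerance = 1e-10)
  expect_equal(hex_gradient(rep(1, lat$n_hex), lat),
               cbind(x = rep(0, lat$n_hex), y = rep(0, lat$n_hex)))
  # rotating a linear field rotates its gradient
  for (theta in c(0.4, 1.2, 2.9)) {
    dir <- c(cos(theta), sin(theta))
    grot <- hex_gradient(lat$centres %*% dir, lat)
    expect_equal(grot[interior, 1L], rep(dir[1L], sum(interior)),
                 tolerance = 1e-10)
    expect_equal(grot[interior, 2L], rep(dir[2L], sum(interior)),
                 tolerance = 1e-10)
  }
})

test_that("flux-sum divergence term recovers analytic divergences", {
  lat <- fix_ellipse$lattice
  interior <- interior_hexes(lat)
  H <- lat$n_hex
  const_g <- cbind(rep(0.7, H), rep(-0.3, H))
  expect_equal(a_divg(rep(1, H), const_g, lat)[interior],
               rep(0, sum(interior)), tolerance = 1e-10)
  expect_equal(a_divg(rep(0, H), lat$centres, lat), rep(0, H))
  # g = (x, y) has divergence 2
  expect_equal(a_divg(rep(1, H), lat$centres, lat)[interior],
               rep(2, sum(interior)), tolerance = 1e-9)
})

test_that("divJ reduces to pure diffusion and vanishes on uniform states", {
  lat <- fix_ellipse$lattice
  H <- lat$n_hex
  p0 <- model_params(N = 3, epsilon = 0)
  set.seed(4)
  a <- runif(H)
  zero_g <- cbind(rep(0, H), rep(0, H))
  dJ <- compute_divJ(a, runif(H), zero_g, rep(0, H), p0, lat)
  expect_equal(dJ, p0$D * hex_laplacian(a, lat))
  # uniform a and a_hat, zero g
  p1 <- model_params(N = 3, epsilon = 1.2)
  dJu <- compute_divJ(rep(0.3, H), rep(0.6, H), zero_g, rep(0, H), p1, lat)
  expect_equal(dJu, rep(0, H))
  expect_error(compute_divJ(a, a, zero_g, rep(0, H),
                            structure(list(N = 1L, epsilon = 1, D = 1,
                                           trim = 1), class = "model_params"),
                            lat), "N >= 2")
})

test_that("global no-flux balance: exact for guided diffusion, small for competition", {
  lat <- fix_ellipse$lattice
  gd <- fix_guidance5$guidance
  p0 <- model_params(N = 5, epsilon = 0)
  st <- init_state(lat, p0, seed = 2)
  der <- da_dt(st, gd, p0, lat)
  divJ <- der$da + der$dc
  expect_lt(abs(sum(divJ)), 1e-6 * sum(abs(divJ)))
  # the five-term expansion of the competition flux couples centred
  # gradients that do not telescope pairwise, so its global balance is
  # approximate on rough states (it tightens as the state smooths)
  p1 <- model_params(N = 5, epsilon = 1.2)
  der1 <- da_dt(st, gd, p1, lat)
  divJ1 <- der1$da + der1$dc
  expect_lt(abs(sum(divJ1)), 2e-2 * sum(abs(divJ1)))
})

test_that("connection dynamics have the closed-form fixed point", {
  lat <- fix_ellipse$lattice
  H <- lat$n_hex
  p <- model_params(N = 1, epsilon = 0)  # alpha 3.6, beta 16.67, k 3
  a0 <- 0.3
  cstar <- p$beta * a0^p$k / (p$alpha + p$beta * a0^p$k)
  expect_equal(cstar, 0.11113, tolerance = 1e-4)
  expect_equal(dc_dt(rep(a0, H), rep(cstar, H), rep(cstar, H), p),
               rep(0, H), tolerance = 1e-14)
  # symmetric N-projection fixed point c* = beta a^k / (alpha + N beta a^k)
  pN <- model_params(N = 4, epsilon = 0)
  cN <- pN$beta * a0^pN$k / (pN$alpha + 4 * pN$beta * a0^pN$k)
  expect_equal(dc_dt(rep(a0, H), rep(cN, H), rep(4 * cN, H), pN),
               rep(0, H), tolerance = 1e-14)
  # saturation: when total connections reach 1, only decay remains
  expect_equal(dc_dt(rep(a0, H), rep(0.2, H), rep(1, H), p),
               rep(-p$alpha * 0.2, H))
  expect_equal(dc_dt(rep(0, H), rep(0, H), rep(0, H), p), rep(0, H))
})

test_that("compiled engine matches the R reference derivative and one RK4 step", {
  lat <- fix_ellipse$lattice
  gd <- fix_guidance5$guidance
  p <- model_params(N = 5)
  st <- init_state(lat, p, seed = 9)
  der <- da_dt(st, gd, p, lat)
  # R-composed classical RK4
  dt <- p$dt
  k1 <- der
  s2 <- st; s2$a <- st$a + dt / 2 * k1$da; s2$c <- st$c + dt / 2 * k1$dc
  k2 <- da_dt(s2, gd, p, lat)
  s3 <- st; s3$a <- st$a + dt / 2 * k2$da; s3$c <- st$c + dt / 2 * k2$dc
  k3 <- da_dt(s3, gd, p, lat)
  s4 <- st; s4$a <- st$a + dt * k3$da; s4$c <- st$c + dt * k3$dc
  k4 <- da_dt(s4, gd, p, lat)
  a_ref <- st$a + dt / 6 * (k1$da + 2 * k2$da + 2 * k3$da + k4$da)
  c_ref <- st$c + dt / 6 * (k1$dc + 2 * k2$dc + 2 * k3$dc + k4$dc)
  stepped <- rk4_step(st, gd, p, lat)
  expect_equal(stepped$a, a_ref, tolerance = 1e-12)
  expect_equal(stepped$c, c_ref, tolerance = 1e-12)
  expect_equal(stepped$step, 1L)
})

test_that("RK4 reproduces exponential decay to fifth-order accuracy", {
  lat <- build_lattice(make_ellipse_boundary(0.3, 0.3, 64), 0.08)
  H <- lat$n_hex
  p <- model_params(N = 1, alpha = 3.6, beta = 0, D = 0, epsilon = 0, dt = 0.05)
  st <- structure(list(a = matrix(0, H, 1L), c = matrix(1, H, 1L),
                       step = 0L, seed = 1L), class = "sim_state")
  gd <- zero_guidance(lat, 1L)
  s1 <- rk4_step(st, gd, p, lat)
  lam <- p$alpha * p$dt
  rk4_poly <- 1 - lam + lam^2 / 2 - lam^3 / 6 + lam^4 / 24
  expect_equal(s1$c[1L, 1L], rk4_poly, tolerance = 1e-14)
  expect_lt(abs(s1$c[1L, 1L] - exp(-lam)), lam^5 / 100)
  # zero-rate state is a fixed point
  st0 <- structure(list(a = matrix(0, H, 1L), c = matrix(0, H, 1L),
                        step = 0L, seed = 1L), class = "sim_state")
  s0 <- rk4_step(st0, gd, p, lat)
  expect_identical(s0$a, st0$a)
  expect_identical(s0$c, st0$c)
})

test_that("halving the step shows fourth-order convergence on the full model", {
  lat <- build_lattice(make_ellipse_boundary(0.5, 0.3, 64), 0.07)
  co <- data.frame(label = c("L", "R"), p = c(0, 1), q = c(0, 1))
  im <- scale_interactions(co)
  f1 <- make_linear_field(lat, 0, 1)
  f2 <- make_linear_field(lat, 90, 1)
  gd <- compute_projection_guidance(im, list(f1, f2), lat)
  run_T <- function(dt, n) {
    p <- model_params(N = 2, dt = dt)
    st <- init_state(lat, p, seed = 5)
    rk4_step(st, gd, p, lat, n)$a
  }
  a_ref <- run_T(2.5e-4, 160L)   # fine reference
  e1 <- max(abs(run_T(2e-3, 20L) - a_ref))
  e2 <- max(abs(run_T(1e-3, 40L) - a_ref))
  ratio <- e1 / e2
  # order 4 gives ~16 asymptotically; higher-order terms at the coarse
  # step can push the observed ratio above that, never far below
  expect_gt(ratio, 12)
  expect_lt(ratio, 100)
})

test_that("per-projection mass is conserved over 1000 steps", {
  lat <- fix_ellipse$lattice  # ~500 hexes
  co <- make_barreloid_coordinates()
  im <- scale_interactions(co)
  f1 <- make_linear_field(lat, 0, 1)
  f2 <- make_linear_field(lat, 84, 1)
  gd <- compute_projection_guidance(im, list(f1, f2), lat)
  p <- model_params(N = 41, steps = 1000L)
  st <- init_state(lat, p, seed = 2)
  m0 <- projection_mass(st, lat)
  st2 <- rk4_step(st, gd, p, lat, 1000L)
  m1 <- projection_mass(st2, lat)
  expect_lt(max(abs(m1 - m0) / m0), 1e-3)
})

test_that("with no reaction the dynamics are a heat equation: peaks spread", {
  lat <- build_lattice(make_ellipse_boundary(0.5, 0.5, 64), 0.05)
  H <- lat$n_hex
  p <- model_params(N = 1, alpha = 0, beta = 0, D = 0.5, epsilon = 0,
                    dt = 5e-4)
  a0 <- matrix(0, H, 1L)
  centre_hex <- which.min(rowSums(lat$centres^2))
  a0[centre_hex, 1L] <- 1
  st <- structure(list(a = a0, c = matrix(0, H, 1L), step = 0L, seed = 1L),
                  class = "sim_state")
  gd <- zero_guidance(lat, 1L)
  maxes <- numeric(5L)
  spreads <- numeric(5L)
  for (i in 1:5) {
    st <- rk4_step(st, gd, p, lat, 20L)
    maxes[i] <- max(st$a)
    w <- st$a[, 1L] / sum(st$a)
    spreads[i] <- sum(w * rowSums(lat$centres^2))
  }
  expect_true(all(diff(maxes) < 0))
  expect_true(all(diff(spreads) > 0))
  expect_equal(sum(st$a), 1, tolerance = 1e-9)  # heat kernel conserves mass
})

test_that("in isolation a projection migrates toward its guidance extremum", {
  lat <- fix_ellipse$lattice
  im <- structure(list(gamma = matrix(c(2, 0), 1L), labels = "solo"),
                  class = "interaction_matrix")
  rownames(im$gamma) <- "solo"
  f1 <- make_linear_field(lat, 0, 1)
  f2 <- make_linear_field(lat, 90, 1)
  gd <- compute_projection_guidance(im, list(f1, f2), lat)
  p <- model_params(N = 1, epsilon = 0, beta = 0)
  st <- init_state(lat, p, seed = 3, a_lo = 0.3, a_hi = 0.3)
  x_mean0 <- sum(st$a[, 1L] * lat$centres[, 1L]) / sum(st$a)
  st2 <- rk4_step(st, gd, p, lat, 4000L)
  x_mean1 <- sum(st2$a[, 1L] * lat$centres[, 1L]) / sum(st2$a)
  expect_gt(x_mean1, x_mean0 + 0.1)
})

test_that("initial states are reproducible and correctly distributed", {
  lat <- fix_ellipse$lattice
  p <- model_params(N = 4)
  s1 <- init_state(lat, p, seed = 42)
  s2 <- init_state(lat, p, seed = 42)
  expect_identical(s1$a, s2$a)
  expect_true(all(s1$c == 0))
  expect_true(all(s1$a > 0.2 & s1$a < 0.4))
  expect_equal(mean(s1$a), 0.3, tolerance = 3 / sqrt(length(s1$a)))
  s3 <- init_state(lat, p, seed = 1, a_lo = 0.3, a_hi = 0.3)
  expect_true(all(s3$a == 0.3))
  expect_error(init_state(lat, p, 1, a_lo = 0.5, a_hi = 0.4))
})

test_that("numerical instability is detected, not propagated", {
  lat <- build_lattice(make_ellipse_boundary(0.4, 0.3, 64), 0.06)
  gd <- fix_guidance5$guidance  # wrong lattice size is irrelevant; build anew
  co <- data.frame(label = paste0("P", 1:3), p = 1:3, q = c(0, 1, 0.5))
  im <- scale_interactions(co)
  f1 <- make_linear_field(lat, 0, 1)
  f2 <- make_linear_field(lat, 90, 1)
  gdl <- compute_projection_guidance(im, list(f1, f2), lat)
  bad <- model_params(N = 3, D = 0.5, dt = 0.05, steps = 400L)  # D dt / d^2 >> 1
  st <- init_state(lat, bad, seed = 1)
  expect_error(rk4_step(st, gdl, bad, lat, 400L), "instability")
  run <- run_simulation(lat, gdl, bad, seed = 1, snapshot_every = 100L,
                        compute_delta = FALSE)
  expect_false(run$stable)
})
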