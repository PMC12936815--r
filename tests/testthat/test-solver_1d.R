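# Uniform 1D reference model: closed-form steady behaviour and transients.

test_that("steady 1D: no-reaction limit, linear-kinetics closed form, flux balance", {
  cfg0 <- scenario(kinetics = surface_kinetics(Vmax = 0, A_gamma = 0))
  s0 <- solve_steady_1d(cfg0, 5)
  expect_equal(s0$C, rep(5, length(s0$y)))
  expect_equal(s0$J, 0)

  cfg <- preset_cfg()
  Da <- cfg$da_glu
  s <- solve_steady_1d(cfg, 1e-7)
  expect_equal(s$C_s / 1e-7, 1 / (1 + Da), tolerance = 1e-8)

  # profile exactly linear; slope times D equals the surface MM rate
  s10 <- solve_steady_1d(cfg, 10)
  slope <- diff(s10$C) / diff(s10$y)
  expect_equal(max(slope), min(slope), tolerance = 1e-12)
  expect_equal(cfg$transport$D_glu * slope[1], s10$J, tolerance = 1e-10)
  # flux-balance residual
  res <- cfg$transport$D_glu / cfg$transport$H * (10 - s10$C_s) - s10$J
  expect_lt(abs(res) / s10$J, 1e-10)
})

test_that("steady 1D reproduces the calibration anchors", {
  cfg <- preset_cfg()
  s <- solve_steady_1d(cfg, 10)
  expect_equal(s$C_s / 10, 0.17, tolerance = 1e-9)
  expect_equal(s$C_p_s / 10, 0.05, tolerance = 1e-9)
})

test_that("surface concentration is strictly decreasing in Da at fixed bulk", {
  scales <- c(0.25, 0.5, 1, 2, 4)
  Cs <- vapply(scales, function(f) {
    cfg <- scenario(kinetics = surface_kinetics(Gamma_mean = 1.2e-9 * f))
    solve_steady_1d(cfg, 5)$C_s
  }, 0)
  expect_true(all(diff(Cs) < 0))
})

test_that("1D transient relaxes to the steady solution and rises monotonically", {
  cfg <- preset_cfg()
  tr <- solve_transient_1d(cfg, 10, t_end = 400)
  st <- solve_steady_1d(cfg, 10)
  expect_equal(tail(tr$C_s_glu, 1), st$C_s, tolerance = 5e-3)
  expect_equal(tail(tr$C_s_h2o2, 1), st$C_p_s, tolerance = 5e-3)
  # monotone approach of the surface peroxide series after the initial ramp
  expect_true(all(diff(tr$C_s_h2o2) > -1e-10))
  # terminal glucose profile linear within 0.5% at all nodes
  prof <- tr$terminal$glucose[1, ]
  lin <- st$C_s + (10 - st$C_s) * tr$grid$y / cfg$transport$H
  expect_lt(max(abs(prof - lin)) / 10, 5e-3)
})

test_that("reaction-free relaxation matches the Fourier-series diffusion oracle", {
  cfg <- scenario(kinetics = surface_kinetics(Vmax = 0, kGOD = 0, A_gamma = 0))
  H <- cfg$transport$H; D <- cfg$transport$D_glu; Cb <- 10
  tr <- solve_transient_1d(cfg, Cb, coupled = FALSE, t_end = 30)
  series_oracle <- function(yv, t) {
    n <- 0:200
    lam <- (2 * n + 1) * pi / (2 * H)
    dec <- exp(-D * lam^2 * t)
    u <- vapply(yv, function(y)
      sum(2 / (H * lam) * (-1)^n * cos(lam * y) * dec), 0)
    Cb * (1 - u)
  }
  for (tq in c(2, 5, 20)) {
    k <- which.min(abs(tr$times - tq)); tk <- tr$times[k]
    num <- tr$snapshots[[which.min(vapply(tr$snapshots, function(s) abs(s$t - tq), 0))]]
    # compare the surface value (most sensitive point) at the snapshot time
    expect_equal(num$glucose[1, 1], series_oracle(0, num$t), tolerance = 1e-2)
  }
  # surface series against the oracle on a time comb
  pick <- tr$times > 1
  num_s <- tr$C_s_glu[pick]
  ora_s <- vapply(tr$times[pick], function(t) series_oracle(0, t), 0)
  expect_lt(max(abs(num_s - ora_s)) / Cb, 1e-2)
})

test_that("1D transient agrees with an independent stiff integrator (deSolve)", {
  cfg <- preset_cfg()
  ny <- 100; stretch <- 100
  tr <- solve_transient_1d(cfg, 10, ny = ny, stretch = stretch, t_end = 200)

  # independent method-of-lines path: same spatial grid, dense lsoda
  H <- cfg$transport$H; Dg <- cfg$transport$D_glu; Dp <- cfg$transport$D_h2o2
  Km <- cfg$kinetics$Km; jm <- cfg$j_max
  kG <- cfg$kinetics$kGOD; de <- cfg$kinetics$delta_enz
  s <- seq(0, 1, length.out = ny); y <- H * (stretch^s - 1) / (stretch - 1)
  dy <- diff(y); hy <- c(dy[1] / 2, (dy[-1] + dy[-(ny - 1)]) / 2, dy[ny - 1] / 2)
  nuk <- ny - 1
  rhs <- function(t, st, p) {
    Cg <- st[1:nuk]; Cp <- st[nuk + 1:nuk]
    fl <- function(C, D, Ctop) {
      f <- D * diff(c(C, Ctop)) / dy
      d <- f; d[2:nuk] <- f[2:nuk] - f[1:(nuk - 1)]; d
    }
    dg <- fl(Cg, Dg, 10); dp <- fl(Cp, Dp, 0)
    dg[1] <- dg[1] - jm * Cg[1] / (Km + Cg[1])
    dp[1] <- dp[1] + kG * de * Cg[1] - jm * Cp[1] / (Km + Cp[1])
    Mg <- hy[1:nuk]; Mp <- hy[1:nuk]; Mp[1] <- Mp[1] + de
    list(c(dg / Mg, dp / Mp))
  }
  out <- deSolve::ode(rep(0, 2 * nuk), tr$times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-13)
  ref_p <- out[, 1 + nuk + 1]
  # pointwise agreement of the surface peroxide series, and of t90
  expect_lt(max(abs(tr$C_s_h2o2 - ref_p)) / max(ref_p), 5e-3)
  t90_ref <- time_to_90(tr$times, ref_p, steady = tail(ref_p, 1))
  expect_equal(t90_of(tr), t90_ref, tolerance = 5e-3)
})
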