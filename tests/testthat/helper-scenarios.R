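# Shared fixtures: scenarios and grids used across the suite. Grids are kept
# modest so individual solves stay well under a second; resolution-sensitive
# checks build their own refined grids.

preset_cfg <- function(...) scenario(...)

uniform_cfg <- function() scenario(kinetics = surface_kinetics(A_gamma = 0))

small_grid <- function(nx = 24, ny = 60)
  suppressWarnings(grid_2d(nx = nx, ny = ny))

# Independent brute-force steady solver used as the oracle for the pseudo-2D
# Newton path: the residual is assembled with plain loops (no shared code with
# the package operators) and solved by Newton with a dense finite-difference
# Jacobian on all unknowns.
brute_force_steady <- function(cfg, C_bulk, nx, ny, stretch = 50) {
  L <- cfg$transport$L; H <- cfg$transport$H; D <- cfg$transport$D_glu
  x <- seq(0, L, length.out = nx)
  s <- seq(0, 1, length.out = ny)
  y <- H * (stretch^s - 1) / (stretch - 1)
  g <- 1 + cfg$kinetics$A_gamma *
    cos(2 * pi * x / cfg$kinetics$lambda_het + cfg$kinetics$phase)
  Km <- cfg$kinetics$Km; jm <- cfg$j_max
  dx <- x[2] - x[1]
  wx <- rep(dx, nx); wx[c(1, nx)] <- dx / 2
  nuk <- ny - 1
  resid <- function(Cv) {
    C <- matrix(Cv, nx, nuk)
    f <- matrix(0, nx, nuk)
    for (i in 1:nx) for (j in 1:nuk) {
      up <- if (j < nuk) C[i, j + 1] else C_bulk
      acc <- D * wx[i] * (up - C[i, j]) / (y[j + 1] - y[j])
      if (j > 1) acc <- acc + D * wx[i] * (C[i, j - 1] - C[i, j]) / (y[j] - y[j - 1])
      hj <- if (j == 1) (y[2] - y[1]) / 2
            else (y[j + 1] - y[j - 1]) / 2
      if (i > 1)  acc <- acc + D * hj * (C[i - 1, j] - C[i, j]) / dx
      if (i < nx) acc <- acc + D * hj * (C[i + 1, j] - C[i, j]) / dx
      if (j == 1) acc <- acc - wx[i] * jm * g[i] * C[i, 1] / (Km + C[i, 1])
      f[i, j] <- acc
    }
    as.numeric(f)
  }
  n <- nx * nuk
  Cv <- rep(C_bulk, n)
  scale <- max(abs(D * wx * C_bulk / (y[ny] - y[ny - 1])))
  for (it in 1:40) {
    f <- resid(Cv)
    if (max(abs(f)) / scale < 1e-12) break
    J <- matrix(0, n, n)
    h <- pmax(1e-7 * abs(Cv), 1e-9)
    for (k in 1:n) {
      Cp <- Cv; Cp[k] <- Cp[k] + h[k]
      J[, k] <- (resid(Cp) - f) / h[k]
    }
    Cv <- Cv - solve(J, f)
  }
  list(x = x, y = y, C = matrix(Cv, nx, nuk), Cs = matrix(Cv, nx, nuk)[, 1],
       resid = resid, scale = scale)
}
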