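# Rate laws, heterogeneity profile, dimensionless groups, validity regimes.

test_that("site-density profile: uniform limit, extrema and mean conservation", {
  kin0 <- surface_kinetics(A_gamma = 0, lambda_het = 10e-6)
  x <- seq(0, 10e-6, length.out = 257)
  expect_equal(gamma_profile(x, kin0), rep(kin0$Gamma_mean, length(x)))

  kin <- surface_kinetics(A_gamma = 0.5, lambda_het = 10e-6, phase = 0)
  expect_equal(gamma_profile(0, kin), 1.5 * kin$Gamma_mean)

  # trapezoidal mean over an integer number of periods recovers the mean
  for (nper in c(1, 2)) {
    xs <- seq(0, nper * 10e-6, length.out = 2048 * nper + 1)
    G <- gamma_profile(xs, kin)
    m <- (sum(G) - (G[1] + G[length(G)]) / 2) / (length(G) - 1)
    expect_equal(m, kin$Gamma_mean, tolerance = 1e-12)
  }

  bad <- surface_kinetics(A_gamma = 0.5, lambda_het = 10e-6)
  bad$A_gamma <- 1.2   # bypass constructor to hit the profile guard
  expect_error(gamma_profile(0, bad), "negative site density")
  expect_error(surface_kinetics(A_gamma = 1.2), "A_gamma")
})

test_that("Michaelis-Menten surface rate: anchors, monotonicity, saturation bound", {
  expect_equal(mm_surface_rate(2.5, Gamma = 1, Vmax = 2, Km = 2.5), 1)   # half-saturation
  expect_equal(mm_surface_rate(0, Gamma = 1, Vmax = 2, Km = 2.5), 0)
  expect_equal(mm_surface_rate(7.5, Gamma = 1, Vmax = 2, Km = 2.5), 1.5) # 3 Km -> 3/4
  expect_error(mm_surface_rate(-1, 1, 1, 1), "nonnegative")

  set.seed(7)
  for (rep in 1:20) {
    Vmax <- runif(1, 0.1, 10); Gam <- runif(1, 0.1, 5); Km <- runif(1, 0.2, 20)
    C <- sort(runif(50, 0, 100))
    R <- mm_surface_rate(C, Gam, Vmax, Km)
    expect_true(all(diff(R) >= 0))
    expect_true(all(R <= Vmax * Gam + 1e-15))
    # concavity
    expect_true(all(diff(diff(R) / diff(C)) <= 1e-12))
  }
})

test_that("enzymatic production flux is first order with the stated magnitude", {
  expect_equal(god_production_flux(0, 0.015, 1e-4), 0)
  expect_equal(god_production_flux(3.4, 0.015, 1e-4),
               2 * god_production_flux(1.7, 0.015, 1e-4))
  expect_equal(god_production_flux(1.7, 0.015, 1e-4), 2.55e-6)
})

test_that("dimensionless groups: lateral ratio identities and the calibrated Da", {
  cfg <- scenario(kinetics = surface_kinetics(lambda_het = 200e-9))
  expect_equal(dimensionless_groups(cfg)$Pi, (200e-9 / 100e-6)^2)  # 4e-6

  cfgH <- scenario(transport = transport_params(H = 200e-6),
                   kinetics = surface_kinetics(lambda_het = 200e-9))
  expect_equal(dimensionless_groups(cfgH)$Pi,
               dimensionless_groups(cfg)$Pi / 4)

  # independent oracle: areal rate from the flux-balance quadratic at the
  # surface-depletion anchor (Cs/Cb = 0.17 at 10 mM), Da = Jmax H / (D Km)
  k0 <- 6.7e-10 / 100e-6
  Cs <- 1.7
  Jmax <- k0 * (10 - Cs) * (2.5 + Cs) / Cs
  Da_oracle <- Jmax * 100e-6 / (6.7e-10 * 2.5)
  g <- dimensionless_groups(scenario())
  expect_equal(g$Da_glu, Da_oracle, tolerance = 1e-12)
  expect_equal(g$Da_glu, 8.2, tolerance = 0.01)
  expect_equal(g$Da_p, g$Da_glu * 6.7e-10 / 1.5e-9, tolerance = 1e-12)
})

test_that("validity report classifies the scale-separation regimes", {
  nm <- validity_report(scenario(kinetics = surface_kinetics(lambda_het = 200e-9)),
                        theta = 0.2)
  expect_equal(nm$regime, "pseudo2D_valid")
  expect_true(all(vapply(nm$flags, function(f) f$pass, TRUE)))

  br <- validity_report(scenario(kinetics = surface_kinetics(lambda_het = 15e-6)))
  expect_equal(br$lam_over_H, 0.15, tolerance = 1e-12)
  expect_equal(br$regime, "breakdown")

  marg <- validity_report(scenario(kinetics = surface_kinetics(lambda_het = 2e-6)))
  expect_equal(marg$regime, "marginal")

  cov <- validity_report(scenario(kinetics = surface_kinetics(lambda_het = 200e-9)),
                         theta = 0.03)
  expect_false(cov$flags$coverage$pass)
})

test_that("scenario validation rejects out-of-range inputs with all violations listed", {
  expect_error(scenario(C_bulk_list = c(5, -1)), "\\(0, 50\\]")
  expect_error(transport_params(H = -1), "strictly positive")
  err <- tryCatch(scenario(transport = transport_params(H = 5e-9, L = 10e-6)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "L/1000")
})
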