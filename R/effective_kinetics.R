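# Observables: lateral averaging, effective surface concentration and flux,
# apparent Michaelis-Menten fitting, diffusion-layer thickness, response time.

#' Laterally averaged concentration profile
#'
#' Trapezoidal mean over `x` of a pseudo-2D field, per `y` row, yielding the
#' effective one-dimensional profile. Exact for fields constant in `x`.
#'
#' @param sol A `"steady_2d"` object (or a bare `nx x ny` matrix plus `grid`).
#' @param grid The [grid_2d()] when `sol` is a bare matrix.
#' @param C_bulk Normalization value; taken from `sol` when available.
#' @return A list of class `"averaged_profile"`: `y`, `C_bar`, `C_norm`
#'   (`C_bar / C_bulk`).
#' @export
x_average <- function(sol, grid = NULL, C_bulk = NULL) {
  if (inherits(sol, "steady_2d")) {
    grid <- sol$grid; C_bulk <- if (is.null(C_bulk)) sol$C_bulk else C_bulk
    M <- sol$C
  } else M <- sol
  stopifnot(is.matrix(M), !is.null(grid), nrow(M) == grid$nx)
  wx <- if (grid$nx == 1) 1 else grid$wx
  C_bar <- as.numeric(colSums(M * wx) / sum(wx))
  structure(list(y = grid$y, C_bar = C_bar,
                 C_norm = if (!is.null(C_bulk) && C_bulk > 0) C_bar / C_bulk else NULL,
                 C_bulk = C_bulk),
            class = "averaged_profile")
}

#' Effective surface concentration and flux of a converged solution
#'
#' `C_eff_s` is the lateral (trapezoidal) mean of the surface concentration
#' `C_s(x)`; `J_eff` the lateral mean of the surface flux. By the discrete
#' flux balance the surface flux equals the local Michaelis-Menten rate, and
#' a one-sided second-order stencil on the stretched grid reproduces it; the
#' stencil value is returned alongside as a cross-check.
#'
#' @param sol A `"steady_2d"` or `"steady_1d"` object.
#' @return A list with `C_eff_s` (mM), `J_eff` (mol m^-2 s^-1) and
#'   `J_eff_stencil` (finite-difference estimate, 2D only).
#' @export
effective_surface_and_flux <- function(sol) {
  if (inherits(sol, "steady_1d"))
    return(list(C_eff_s = sol$C_s, J_eff = sol$J, J_eff_stencil = sol$J))
  stopifnot(inherits(sol, "steady_2d"))
  g <- sol$grid
  wx <- if (g$nx == 1) 1 else g$wx
  # one-sided three-point first derivative at y = 0 on a nonuniform grid
  h1 <- g$y[2] - g$y[1]; h2 <- g$y[3] - g$y[2]
  d0 <- -(2 * h1 + h2) / (h1 * (h1 + h2)) * sol$C[, 1] +
        (h1 + h2) / (h1 * h2) * sol$C[, 2] -
        h1 / (h2 * (h1 + h2)) * sol$C[, 3]
  list(C_eff_s = sum(sol$C_s * wx) / sum(wx),
       J_eff = sum(sol$J * wx) / sum(wx),
       J_eff_stencil = sol$D * sum(d0 * wx) / sum(wx))
}

#' Fit apparent Michaelis-Menten parameters to effective data
#'
#' Nonlinear least squares of `J = Vmax_eff * C / (Km_eff + C)` against pairs
#' of effective *surface* concentration and effective flux (the literal
#' apparent-kinetics form: fitting against surface rather than bulk
#' concentration makes the uniform 1D fit return the intrinsic parameters
#' exactly). A Lineweaver-Burk linearization provides the starting values
#' only; the estimates come from `minpack.lm::nlsLM`.
#'
#' @param pairs A data frame (or list) with columns/components `C_s`
#'   (effective surface concentration, mM) and `J` (effective flux).
#' @return A list of class `"effective_mm"`: `Km_eff` (mM), `Vmax_eff`
#'   (flux units), residual norm and fit diagnostics.
#' @examples
#' C <- c(0.05, 0.2, 0.8, 2.5, 8, 20)
#' fit_effective_mm(data.frame(C_s = C, J = 3 * C / (2.5 + C)))
#' @export
fit_effective_mm <- function(pairs) {
  C_s <- pairs$C_s; J <- pairs$J
  stopifnot(length(C_s) == length(J))
  if (length(C_s) < 5)
    stop("need at least 5 (C_s, J) pairs for an apparent-kinetics fit", call. = FALSE)
  if (max(C_s) / min(C_s) < 10)
    stop("C_s values must span at least one decade", call. = FALSE)
  ok <- C_s > 0 & J > 0
  lb <- stats::lm(I(1 / J[ok]) ~ I(1 / C_s[ok]))     # initial guess only
  V0 <- 1 / stats::coef(lb)[[1]]; K0 <- stats::coef(lb)[[2]] * V0
  if (!is.finite(V0) || V0 <= 0) V0 <- max(J)
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(C_s)
  df <- data.frame(C_s = C_s, J = J)
  fit <- minpack.lm::nlsLM(J ~ V * C_s / (K + C_s), data = df,
                           start = list(V = V0, K = K0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  est <- stats::coef(fit)
  structure(list(Km_eff = est[["K"]], Vmax_eff = est[["V"]],
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 start = c(V = V0, K = K0), n = length(C_s),
                 C_s = C_s, J = J),
            class = "effective_mm")
}

#' @export
print.effective_mm <- function(x, ...) {
  cat(sprintf("<effective_mm> Km_eff = %.5g mM, Vmax_eff = %.5g (resid %.2e, n = %d)\n",
              x$Km_eff, x$Vmax_eff, x$resid_norm, x$n))
  invisible(x)
}

#' Steady concentration sweep
#'
#' Runs the steady model over the scenario's bulk-concentration list for the
#' uniform 1D reference and (optionally) the heterogeneous pseudo-2D model,
#' collecting effective surface concentrations and fluxes.
#'
#' @param cfg A [scenario()].
#' @param grid A [grid_2d()] for the pseudo-2D solves.
#' @param what `"both"`, `"1d"` or `"2d"`.
#' @param C_bulk_list Concentrations (mM); defaults to `cfg$C_bulk_list`.
#' @return A data frame with columns `model` (`"1d"`/`"2d"`), `C_bulk`,
#'   `C_eff_s`, `J_eff`.
#' @export
sweep_steady <- function(cfg, grid = grid_2d(cfg$transport$L, cfg$transport$H),
                         what = c("both", "1d", "2d"),
                         C_bulk_list = cfg$C_bulk_list) {
  what <- match.arg(what)
  rows <- list()
  if (what %in% c("both", "1d")) {
    for (cb in C_bulk_list) {
      s <- solve_steady_1d(cfg, cb)
      rows[[length(rows) + 1]] <- data.frame(model = "1d", C_bulk = cb,
                                             C_eff_s = s$C_s, J_eff = s$J)
    }
  }
  if (what %in% c("both", "2d")) {
    for (cb in C_bulk_list) {
      s <- solve_steady_2d(cfg, cb, grid)
      rows[[length(rows) + 1]] <- data.frame(model = "2d", C_bulk = cb,
                                             C_eff_s = s$C_eff_s, J_eff = s$J_eff)
    }
  }
  do.call(rbind, rows)
}

#' Apparent kinetics of a scenario (1D reference and pseudo-2D)
#'
#' Orchestrates the steady sweep and the apparent Michaelis-Menten fits for
#' the uniform 1D reference and the heterogeneous pseudo-2D model, and
#' normalizes the pseudo-2D maximal rate and saturation flux by the 1D
#' values (the 1D normalized quantities are 1 by construction).
#'
#' @inheritParams sweep_steady
#' @return A list of class `"effective_kinetics"`: fits `fit_1d`, `fit_2d`,
#'   normalized `Vmax_rel` and `R_sat_rel`, `Km_eff_1d`, `Km_eff_2d`, and the
#'   sweep data frame.
#' @export
effective_kinetics <- function(cfg, grid = grid_2d(cfg$transport$L, cfg$transport$H),
                               C_bulk_list = cfg$C_bulk_list) {
  sw <- sweep_steady(cfg, grid, "both", C_bulk_list)
  d1 <- sw[sw$model == "1d", ]; d2 <- sw[sw$model == "2d", ]
  f1 <- fit_effective_mm(data.frame(C_s = d1$C_eff_s, J = d1$J_eff))
  f2 <- fit_effective_mm(data.frame(C_s = d2$C_eff_s, J = d2$J_eff))
  structure(list(fit_1d = f1, fit_2d = f2,
                 Km_eff_1d = f1$Km_eff, Km_eff_2d = f2$Km_eff,
                 Vmax_rel = f2$Vmax_eff / f1$Vmax_eff,
                 R_sat_rel = d2$J_eff[which.max(d2$C_bulk)] /
                             d1$J_eff[which.max(d1$C_bulk)],
                 sweep = sw),
            class = "effective_kinetics")
}

#' @export
print.effective_kinetics <- function(x, ...) {
  cat("<effective_kinetics> apparent parameters from the steady sweep\n")
  cat(sprintf("  1D uniform   : Km_eff = %.4g mM, Vmax_eff = %.5g (normalized 1)\n",
              x$Km_eff_1d, x$fit_1d$Vmax_eff))
  cat(sprintf("  pseudo-2D    : Km_eff = %.4g mM, Vmax_eff/1D = %.4f, R_sat/1D = %.4f\n",
              x$Km_eff_2d, x$Vmax_rel, x$R_sat_rel))
  invisible(x)
}

#' Effective diffusion-layer thickness (99% recovery distance)
#'
#' Smallest height at which the laterally averaged concentration recovers to
#' the given fraction of bulk, with linear interpolation between bracketing
#' nodes. Returns `H` with a saturation flag if the profile never reaches the
#' threshold; 0 if it starts above it.
#'
#' @param profile An `"averaged_profile"` (from [x_average()]) or a
#'   `"steady_1d"` solution.
#' @param threshold Recovery fraction (default 0.99).
#' @return Thickness in m, with attribute `saturated`.
#' @examples
#' p <- structure(list(y = seq(0, 1e-4, length.out = 101),
#'                     C_norm = 0.2 + 0.8 * seq(0, 1, length.out = 101)),
#'                class = "averaged_profile")
#' diffusion_layer_thickness(p)  # 0.9875 * H for the linear profile
#' @export
diffusion_layer_thickness <- function(profile, threshold = 0.99) {
  if (inherits(profile, "steady_1d")) {
    r <- profile$C / profile$C_bulk; y <- profile$y
  } else {
    r <- profile$C_norm; y <- profile$y
    if (is.null(r)) stop("profile lacks a normalized concentration", call. = FALSE)
  }
  if (any(diff(r) < -1e-9))
    warning("averaged profile is not monotone; first crossing reported")
  if (r[1] >= threshold) return(structure(0, saturated = FALSE))
  idx <- which(r >= threshold)
  if (!length(idx)) return(structure(y[length(y)], saturated = TRUE))
  j <- idx[1]
  d99 <- y[j - 1] + (threshold - r[j - 1]) * (y[j] - y[j - 1]) / (r[j] - r[j - 1])
  structure(d99, saturated = FALSE)
}

#' Time to 90% of steady state
#'
#' First crossing of `frac * steady` by the series, with linear interpolation
#' between samples. For non-monotone series the first crossing is returned
#' (documented tie-break).
#'
#' @param times Sample times (s).
#' @param series Signal samples.
#' @param steady Steady-state value; defaults to the last sample.
#' @param frac Crossing fraction (default 0.9).
#' @return Crossing time (s).
#' @examples
#' t <- seq(0, 50, by = 0.01)
#' time_to_90(t, 1 - exp(-0.1 * t), steady = 1)  # ln(10)/0.1 = 23.03
#' @export
time_to_90 <- function(times, series, steady = utils::tail(series, 1), frac = 0.9) {
  stopifnot(length(times) == length(series), length(times) > 1)
  th <- frac * steady
  idx <- which(series >= th)
  if (!length(idx))
    stop("series never reaches the threshold within the horizon; increase sim_time",
         call. = FALSE)
  j <- idx[1]
  if (j == 1) return(times[1])
  times[j - 1] + (th - series[j - 1]) * (times[j] - times[j - 1]) /
    (series[j] - series[j - 1])
}

#' Response time of a transient solution's surface series
#'
#' Convenience wrapper extracting [time_to_90()] from the laterally averaged
#' surface series of a transient solution (peroxide by default).
#'
#' @param sol A transient solution from [solve_transient_1d()] or
#'   [solve_transient_2d()].
#' @param what `"h2o2"` or `"glucose"`.
#' @param frac Crossing fraction (default 0.9).
#' @return Crossing time (s).
#' @export
t90_of <- function(sol, what = c("h2o2", "glucose"), frac = 0.9) {
  what <- match.arg(what)
  s <- if (what == "h2o2") sol$C_s_h2o2 else sol$C_s_glu
  time_to_90(sol$times, s, frac = frac)
}
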