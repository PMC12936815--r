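# Pseudo-2D solver: 2D diffusion with a nonlinear heterogeneous surface
# condition at y = 0, no-flux lateral walls and a Dirichlet top boundary.
# Conservative vertex-centred finite volumes; damped Newton with line search
# on the steady residual; variable-step BDF2 for transients.

# Newton solve of one species' steady field.
#   op          assembled operator (assemble_operator)
#   C_top       Dirichlet value at y = H (mM)
#   rate, drate areal consumption rate at the surface nodes and its derivative,
#               functions of the surface concentration vector (mol m^-2 s^-1)
#   source      areal production flux at the surface nodes (vector, may be 0)
#   C0          initial iterate
# `bot_floor` keeps the line search on the physical branch of the surface
# flux balance (the MM law has a spurious root below -Km).
newton_species <- function(op, C_top, rate, drate, source, C0,
                           rtol = 1e-11, maxit = 60, bot_floor = -Inf) {
  bot <- op$bot
  wxb <- op$wx_bot
  resid <- function(C) {
    f <- as.numeric(op$Lmat %*% C) + op$top_coef * C_top
    f[bot] <- f[bot] + wxb * (source - rate(C[bot]))
    f
  }
  scale <- max(abs(op$top_coef) * abs(C_top), abs(wxb * source), 0)
  if (scale == 0) {                     # no forcing at all: zero field
    C <- numeric(op$n)
    return(list(C = C, residual = 0, iters = 0L, resid_fun = resid))
  }
  C <- C0
  f <- resid(C)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) / scale < rtol) break
    J <- op$Lmat
    diag(J)[bot] <- diag(op$Lmat)[bot] - wxb * drate(C[bot])
    dC <- as.numeric(Matrix::solve(J, -f))
    lam <- 1; fn <- f
    repeat {
      Cn <- C + lam * dC
      admissible <- min(Cn[bot]) > bot_floor
      if (admissible) fn <- resid(Cn)
      if ((admissible &&
           max(abs(fn)) <= max(abs(f)) * (1 - 0.25 * lam)) || lam < 1e-8) break
      lam <- lam / 2
    }
    C <- C + lam * dC
    f <- fn
  }
  res <- max(abs(f)) / scale
  if (res > rtol * 100)
    stop(sprintf("Newton did not converge: scaled residual %.3g after %d iterations",
                 res, it), call. = FALSE)
  if (min(C) < -1e-8 * max(abs(C), C_top))
    stop("solver produced negative concentrations (not clipped); refine the grid",
         call. = FALSE)
  list(C = C, residual = res, iters = it, resid_fun = resid)
}

# attach bottom dual widths to an operator (kept out of assemble_operator to
# keep that function purely geometric)
op_with_bottom <- function(grid, D) {
  op <- assemble_operator(grid, D)
  op$wx_bot <- if (grid$nx == 1) 1 else grid$wx
  op
}

# surface rate-law closures for a scenario on lateral nodes x
surface_laws <- function(cfg, x, uniform = FALSE) {
  kin <- cfg$kinetics
  g <- if (uniform) rep(1, length(x))
       else het_factor(x, kin$A_gamma, kin$lambda_het, kin$phase)
  act <- active_rate_params(cfg)
  list(
    g = g,
    rate_glu  = function(C) act$j_max * g * C / (act$Km + C),
    drate_glu = function(C) act$j_max * g * act$Km / (act$Km + C)^2,
    # peroxide consumption: same areal rate scale and Km as the colorimetric
    # peroxidase step, modulated by the same site-density profile
    rate_p  = function(C) cfg$j_max * g * C / (cfg$kinetics$Km + C),
    drate_p = function(C) cfg$j_max * g * cfg$kinetics$Km / (cfg$kinetics$Km + C)^2
  )
}

wrap_field <- function(C, grid, C_top) {
  cbind(matrix(C, nrow = grid$nx), rep(C_top, grid$nx))  # nx x ny, top appended
}

lateral_mean <- function(v, wx) sum(v * wx) / sum(wx)

#' Steady pseudo-2D solve for glucose
#'
#' Solves the steady diffusion problem for glucose over the heterogeneous
#' surface: Laplace's equation in the layer, `C = C_bulk` at `y = H`, no-flux
#' lateral walls, and the Michaelis-Menten flux balance
#' `D dC/dy = j_max g(x) C_s / (Km + C_s)` at `y = 0` (the electrochemical
#' rate constants are used when `cfg$mode == "electrochemical"`).
#'
#' @param cfg A [scenario()].
#' @param C_bulk Bulk glucose concentration (mM).
#' @param grid A [grid_2d()]; defaults to the 64 x 160 stretched grid.
#' @param uniform Force a uniform surface (`g = 1`) regardless of `A_gamma`.
#' @param rtol Relative residual tolerance of the Newton solve.
#' @return An object of class `"steady_2d"`: the concentration field
#'   (`nx x ny`, mM), surface arrays `C_s(x)` and `J(x)`, laterally averaged
#'   `C_eff_s` and `J_eff`, and conservation/convergence diagnostics.
#' @examples
#' \donttest{
#' sol <- solve_steady_2d(scenario(), 10, grid_2d(nx = 24, ny = 60))
#' sol$C_eff_s / 10
#' }
#' @export
solve_steady_2d <- function(cfg, C_bulk, grid = grid_2d(cfg$transport$L, cfg$transport$H),
                            uniform = FALSE, rtol = 1e-11) {
  stopifnot(inherits(cfg, "scenario"), C_bulk > 0)
  op <- op_with_bottom(grid, cfg$transport$D_glu)
  laws <- surface_laws(cfg, grid$x, uniform)
  ns <- newton_species(op, C_bulk, laws$rate_glu, laws$drate_glu,
                       source = numeric(grid$nx), C0 = rep(C_bulk, op$n),
                       rtol = rtol, bot_floor = -0.45 * active_rate_params(cfg)$Km)
  finish_steady(ns, op, grid, cfg, C_bulk, laws, species = "glucose",
                rate = laws$rate_glu, source = numeric(grid$nx))
}

finish_steady <- function(ns, op, grid, cfg, C_top, laws, species, rate, source) {
  Cs <- ns$C[op$bot]
  J <- rate(Cs)                                   # mol m^-2 s^-1, by flux balance
  wx <- op$wx_bot
  influx <- sum(op$top_coef[op$topmost] * (C_top - ns$C[op$topmost]))
  consumed <- sum(wx * (rate(Cs) - source))
  consv <- if (abs(consumed) > 0) (influx - consumed) / abs(consumed) else influx
  structure(list(
    x = grid$x, y = grid$y, C = wrap_field(ns$C, grid, C_top),
    C_s = Cs, J = J, g = laws$g,
    C_eff_s = lateral_mean(Cs, wx), J_eff = lateral_mean(J, wx),
    net_uptake = lateral_mean(J - source, wx), D = op$D,
    C_bulk = C_top, species = species, grid = grid,
    residual = ns$residual, iters = ns$iters, conservation = consv),
    class = "steady_2d")
}

#' @export
print.steady_2d <- function(x, ...) {
  cat(sprintf("<steady_2d> %s, C_bulk = %.4g mM, grid %d x %d\n",
              x$species, x$C_bulk, x$grid$nx, x$grid$ny))
  cat(sprintf("  C_eff_s = %.5g mM (%.4f of bulk), J_eff = %.5g mol m^-2 s^-1\n",
              x$C_eff_s, x$C_eff_s / x$C_bulk, x$J_eff))
  cat(sprintf("  residual %.2e, conservation error %.2e, %d Newton iterations\n",
              x$residual, x$conservation, x$iters))
  invisible(x)
}

#' Steady coupled colorimetric solve (glucose + hydrogen peroxide)
#'
#' Glucose is consumed at the surface by the heterogeneous Michaelis-Menten
#' law; hydrogen peroxide is produced by the enzymatic conversion layer
#' (`kGOD * delta_enz * C_glu,s(x)`, following the local surface glucose) and
#' consumed by the heterogeneous peroxidase-like step, with a zero Dirichlet
#' value at the bulk boundary (the reservoir contains no peroxide).
#'
#' @inheritParams solve_steady_2d
#' @return A list of class `"steady_coupled"` with components `glucose` and
#'   `h2o2`, both `"steady_2d"` objects.
#' @export
solve_colorimetric_coupled <- function(cfg, C_bulk,
                                       grid = grid_2d(cfg$transport$L, cfg$transport$H),
                                       uniform = FALSE, rtol = 1e-11) {
  stopifnot(cfg$mode == "colorimetric")
  glu <- solve_steady_2d(cfg, C_bulk, grid, uniform, rtol)
  op <- op_with_bottom(grid, cfg$transport$D_h2o2)
  laws <- surface_laws(cfg, grid$x, uniform)
  src <- god_production_flux(glu$C_s, cfg$kinetics$kGOD, cfg$kinetics$delta_enz)
  C0 <- rep(min(0.01, 0.01 * C_bulk), op$n)
  ns <- newton_species(op, 0, laws$rate_p, laws$drate_p, source = src, C0 = C0,
                       rtol = rtol, bot_floor = -0.45 * cfg$kinetics$Km)
  p <- finish_steady(ns, op, grid, cfg, 0, laws, species = "h2o2",
                     rate = laws$rate_p, source = src)
  p$production <- src
  structure(list(glucose = glu, h2o2 = p, C_bulk = C_bulk), class = "steady_coupled")
}

#' @export
print.steady_coupled <- function(x, ...) {
  cat(sprintf("<steady_coupled> colorimetric, C_bulk = %.4g mM\n", x$C_bulk))
  cat(sprintf("  glucose: C_eff_s/C_bulk = %.4f; peroxide surface mean = %.5g mM\n",
              x$glucose$C_eff_s / x$C_bulk, x$h2o2$C_eff_s))
  invisible(x)
}

# ---- transients -----------------------------------------------------------

#' Graded time grid for the implicit transient integrator
#'
#' Deterministic step sequence growing geometrically from `dt0` to `dt_max`;
#' small early steps resolve the boundary-condition step, large late steps
#' track the slow surface-film relaxation. `refine` divides every step (and
#' `dt0`) by the given factor, for time-convergence checks.
#'
#' @param t_end Horizon (s).
#' @param dt0 Initial step (s).
#' @param growth Geometric growth factor per step.
#' @param dt_max Step ceiling (s).
#' @param refine Integer refinement factor.
#' @return Increasing vector of times from 0 to `t_end`.
#' @export
time_grid <- function(t_end, dt0 = 0.02, growth = 1.04, dt_max = 1,
                      refine = 1L) {
  dt0 <- dt0 / refine; dt_max <- dt_max / refine
  tt <- 0; dt <- dt0
  while (tt[length(tt)] < t_end) {
    tt <- c(tt, min(tt[length(tt)] + dt, t_end))
    dt <- min(dt * growth^(1 / refine), dt_max)
  }
  tt
}

# BDF2 step residual coefficients for variable steps
bdf2_coefs <- function(h, h_prev) {
  if (is.na(h_prev)) return(c(1 / h, -1 / h, 0))        # backward Euler start
  r <- h / h_prev
  c((1 + 2 * r) / ((1 + r) * h), -(1 + r) / h, r^2 / ((1 + r) * h))
}

# One implicit step of one species: solve
#   M (a1 C + a2 C_n + a3 C_nm1) = L C + top_coef C_top + wx (source - rate(C_bot))
step_species <- function(op, mass, C_top, rate, drate, source, a, C_n, C_nm1,
                         rtol = 1e-9) {
  bot <- op$bot; wxb <- op$wx_bot
  rhs_const <- mass * (a[2] * C_n + a[3] * C_nm1) - op$top_coef * C_top
  rhs_const[bot] <- rhs_const[bot] - wxb * source
  scale <- max(abs(op$top_coef) * abs(C_top), abs(wxb * source),
               max(abs(mass * a[1] * C_n)), 1e-300)
  C <- C_n
  for (it in 1:25) {
    f <- mass * a[1] * C - as.numeric(op$Lmat %*% C) + rhs_const
    f[bot] <- f[bot] + wxb * rate(C[bot])
    if (max(abs(f)) / scale < rtol) break
    J <- -op$Lmat
    diag(J) <- diag(J) + mass * a[1]
    diag(J)[bot] <- diag(J)[bot] + wxb * drate(C[bot])
    C <- C + as.numeric(Matrix::solve(J, -f))
  }
  if (max(abs(f)) / scale > rtol * 100)
    stop("transient step failed to converge", call. = FALSE)
  C
}

# Core transient integrator shared by the 1D (nx = 1) and pseudo-2D paths.
transient_core <- function(cfg, C_bulk, grid, uniform, coupled, ic, times,
                           n_snapshots = 12, rtol = 1e-9) {
  laws <- surface_laws(cfg, grid$x, uniform)
  op_g <- op_with_bottom(grid, cfg$transport$D_glu)
  mass <- op_g$mass
  kin <- cfg$kinetics
  Cg <- if (ic == "bathed") rep(C_bulk, op_g$n) else numeric(op_g$n)
  if (coupled) {
    op_p <- op_with_bottom(grid, cfg$transport$D_h2o2)
    mass_p <- op_p$mass
    # the enzymatic conversion film stores peroxide: extra capacitance
    # delta_enz on the surface control volumes (see the methods vignette)
    mass_p[op_p$bot] <- mass_p[op_p$bot] + op_p$wx_bot * kin$delta_enz
    Cp <- numeric(op_p$n)
  }
  nt <- length(times)
  wxb <- op_g$wx_bot
  Cs_g <- Cs_p <- J_t <- numeric(nt)
  Cs_g[1] <- lateral_mean(Cg[op_g$bot], wxb)
  Cs_p[1] <- 0
  J_t[1] <- lateral_mean(laws$rate_glu(Cg[op_g$bot]), wxb)
  snap_idx <- unique(round(seq(1, nt, length.out = n_snapshots)))
  snaps <- vector("list", length(snap_idx)); names(snaps) <- times[snap_idx]
  store_snap <- function(k, Cg, Cp) {
    s <- list(t = times[k], glucose = wrap_field(Cg, grid, C_bulk))
    if (coupled) s$h2o2 <- wrap_field(Cp, grid, 0)
    s
  }
  si <- 1
  if (snap_idx[1] == 1) { snaps[[1]] <- store_snap(1, Cg, if (coupled) Cp); si <- 2 }
  Cg_nm1 <- NULL; Cp_nm1 <- NULL; h_prev <- NA_real_
  for (k in 2:nt) {
    h <- times[k] - times[k - 1]
    a <- bdf2_coefs(h, h_prev)
    Cg_new <- step_species(op_g, mass, C_bulk, laws$rate_glu, laws$drate_glu,
                           numeric(grid$nx), a,
                           Cg, if (is.null(Cg_nm1)) Cg else Cg_nm1, rtol)
    if (coupled) {
      src <- god_production_flux(Cg_new[op_g$bot], kin$kGOD, kin$delta_enz)
      Cp_new <- step_species(op_p, mass_p, 0, laws$rate_p, laws$drate_p, src, a,
                             Cp, if (is.null(Cp_nm1)) Cp else Cp_nm1, rtol)
      Cp_nm1 <- Cp; Cp <- Cp_new
    }
    Cg_nm1 <- Cg; Cg <- Cg_new; h_prev <- h
    Cs_g[k] <- lateral_mean(Cg[op_g$bot], wxb)
    if (coupled) Cs_p[k] <- lateral_mean(Cp[op_p$bot], wxb)
    J_t[k] <- lateral_mean(laws$rate_glu(Cg[op_g$bot]), wxb)
    if (si <= length(snap_idx) && k == snap_idx[si]) {
      snaps[[si]] <- store_snap(k, Cg, if (coupled) Cp); si <- si + 1
    }
  }
  out <- list(times = times, C_s_glu = Cs_g, J_eff = J_t,
              C_bulk = C_bulk, ic = ic, coupled = coupled, grid = grid,
              snapshots = snaps,
              terminal = list(glucose = wrap_field(Cg, grid, C_bulk)))
  if (coupled) {
    out$C_s_h2o2 <- Cs_p
    out$terminal$h2o2 <- wrap_field(Cp, grid, 0)
  }
  out
}

#' Transient pseudo-2D solve
#'
#' Time-dependent response after a change of the bulk glucose boundary:
#' implicit variable-step BDF2 on the finite-volume operators, with the
#' deterministic graded [time_grid()]. Two initial-condition protocols:
#' `"step"` (default) starts from a glucose-free layer with the bulk value
#' applied at `y = H` from `t = 0+` (sensor dipped into the sample), while
#' `"bathed"` starts from glucose equilibrated at `C_bulk` throughout with
#' the reaction switched on at `t = 0`. Peroxide always starts at zero.
#'
#' @inheritParams solve_steady_2d
#' @param C_bulk_step Bulk glucose concentration applied at the top (mM).
#' @param coupled Solve the colorimetric glucose + peroxide pair (`TRUE`) or
#'   glucose only.
#' @param ic Initial-condition protocol, `"step"` or `"bathed"`.
#' @param t_end Horizon (s); defaults to `cfg$sim_time`.
#' @param times Explicit time grid (overrides `t_end`).
#' @param n_snapshots Number of stored field snapshots.
#' @return A list of class `"transient_2d"`: output `times`, laterally
#'   averaged surface series `C_s_glu`, `C_s_h2o2`, `J_eff`, field
#'   `snapshots`, and `terminal` fields.
#' @export
solve_transient_2d <- function(cfg, C_bulk_step,
                               grid = grid_2d(cfg$transport$L, cfg$transport$H,
                                              nx = 48, ny = 100, stretch = 100),
                               coupled = cfg$mode == "colorimetric",
                               ic = c("step", "bathed"),
                               t_end = cfg$sim_time, times = NULL,
                               uniform = FALSE, n_snapshots = 12) {
  ic <- match.arg(ic)
  if (is.null(times)) times <- time_grid(t_end)
  structure(transient_core(cfg, C_bulk_step, grid, uniform, coupled, ic, times,
                           n_snapshots),
            class = "transient_2d")
}

#' @export
print.transient_2d <- function(x, ...) {
  cat(sprintf("<transient_2d> %s, C_bulk = %.4g mM, %d steps to t = %.4g s (ic = %s)\n",
              if (x$coupled) "colorimetric (glucose + H2O2)" else "glucose",
              x$C_bulk, length(x$times) - 1, max(x$times), x$ic))
  cat(sprintf("  terminal surface glucose %.5g mM%s\n",
              utils::tail(x$C_s_glu, 1),
              if (x$coupled) sprintf(", surface H2O2 %.5g mM", utils::tail(x$C_s_h2o2, 1))
              else ""))
  invisible(x)
}
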