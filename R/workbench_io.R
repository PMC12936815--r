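# Configuration files, result serialization, run manifests and the
# synthetic-fixture generator for spectra-comparison workflows.

#' Load a scenario from a YAML configuration file
#'
#' Missing fields fall back to the calibrated preset defaults; unknown keys
#' and out-of-range values are rejected with a message listing every
#' violation at once. An empty file therefore yields the full default
#' scenario.
#'
#' Recognized top-level keys: `transport` (D_glu, D_h2o2, H, L), `kinetics`
#' (Km, Vmax, Gamma_mean, A_gamma, lambda_het, phase, kGOD, delta_enz,
#' Km_el, Vmax_el), `mode`, `C_bulk_list`, `sim_time`, `E_op`, `T`, `seed`.
#'
#' @param path Path to a YAML file.
#' @return A validated [scenario()].
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  violations <- character()
  known_top <- c("transport", "kinetics", "mode", "C_bulk_list", "sim_time",
                 "E_op", "T", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    violations <- c(violations, paste("unknown keys:", paste(unknown, collapse = ", ")))
  tr_known <- c("D_glu", "D_h2o2", "H", "L")
  kin_known <- c("Km", "Vmax", "Gamma_mean", "A_gamma", "lambda_het", "phase",
                 "kGOD", "delta_enz", "Km_el", "Vmax_el")
  if (!is.null(raw$transport)) {
    u <- setdiff(names(raw$transport), tr_known)
    if (length(u)) violations <- c(violations, paste("unknown transport keys:",
                                                     paste(u, collapse = ", ")))
  }
  if (!is.null(raw$kinetics)) {
    u <- setdiff(names(raw$kinetics), kin_known)
    if (length(u)) violations <- c(violations, paste("unknown kinetics keys:",
                                                     paste(u, collapse = ", ")))
  }
  if (length(violations))
    stop("invalid configuration:\n", paste0("  - ", violations, collapse = "\n"),
         call. = FALSE)
  tr <- utils::modifyList(.defaults[tr_known], raw$transport %||% list())
  kin_def <- c(.defaults[c("Km", "Vmax", "Gamma_mean", "A_gamma", "kGOD",
                           "Km_el", "Vmax_el")],
               list(lambda_het = NULL, phase = 0, delta_enz = NULL))
  kin <- utils::modifyList(kin_def, raw$kinetics %||% list())
  scenario(transport = do.call(transport_params, tr),
           kinetics = do.call(surface_kinetics, kin[kin_known]),
           mode = raw$mode %||% "colorimetric",
           C_bulk_list = unlist(raw$C_bulk_list) %||% default_sweep(),
           sim_time = raw$sim_time %||% 400,
           E_op = raw$E_op %||% .defaults$E_op,
           T = raw$T %||% .defaults$T,
           seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-precision CSV so regression comparisons are bitwise stable
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a scenario end to end and write its outputs
#'
#' Executes the requested pipeline and serializes results (full-precision
#' CSV, JSON for fitted parameters) together with a JSON run manifest
#' recording the configuration echo, package version, grid summary,
#' convergence diagnostics, wall time, seed and every output file written.
#' Given identical configuration and seed the numeric outputs are
#' byte-identical across runs.
#'
#' @param cfg A [scenario()].
#' @param outdir Output directory (created if needed).
#' @param task One of `"steady"` (concentration sweep + apparent kinetics),
#'   `"transient"` (response to a bulk step at the largest sweep
#'   concentration), `"colorimetric"` (coupled steady solve + proxy spectra),
#'   `"sensitivity"` (parameter sweep), `"validate-regime"`.
#' @param grid A [grid_2d()].
#' @return The manifest (invisibly), of class `"run_manifest"`.
#' @export
run_scenario <- function(cfg, outdir,
                         task = c("steady", "transient", "colorimetric",
                                  "sensitivity", "validate-regime"),
                         grid = grid_2d(cfg$transport$L, cfg$transport$H)) {
  task <- match.arg(task)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  files <- character(); diag <- list()
  out <- function(name) file.path(outdir, name)

  if (task == "steady") {
    ek <- effective_kinetics(cfg, grid)
    sw <- ek$sweep
    sw$J_norm <- sw$J_eff / max(sw$J_eff[sw$model == "1d"])
    files <- c(files, write_csv_full(sw, out("sweep.csv")))
    fitj <- list(Km_eff_1d = ek$Km_eff_1d, Km_eff_2d = ek$Km_eff_2d,
                 Vmax_eff_1d = ek$fit_1d$Vmax_eff, Vmax_eff_2d = ek$fit_2d$Vmax_eff,
                 Vmax_rel = ek$Vmax_rel, R_sat_rel = ek$R_sat_rel,
                 resid_1d = ek$fit_1d$resid_norm, resid_2d = ek$fit_2d$resid_norm)
    jsonlite::write_json(fitj, out("effective_kinetics.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, out("effective_kinetics.json"))
    diag$fit <- fitj
  } else if (task == "transient") {
    cb <- max(cfg$C_bulk_list)
    tr2 <- solve_transient_2d(cfg, cb, t_end = cfg$sim_time)
    ser <- data.frame(t = tr2$times, C_s_glu = tr2$C_s_glu, J_eff = tr2$J_eff)
    if (tr2$coupled) ser$C_s_h2o2 <- tr2$C_s_h2o2
    files <- c(files, write_csv_full(ser, out("surface_series.csv")))
    diag$t90_glu <- time_to_90(tr2$times, tr2$C_s_glu)
    if (tr2$coupled) diag$t90_h2o2 <- t90_of(tr2)
  } else if (task == "colorimetric") {
    cbs <- cfg$C_bulk_list
    cons <- vapply(cbs, function(cb)
      solve_colorimetric_coupled(cfg, cb, grid)$h2o2$J_eff, 0)
    # cumulative consumption over the incubation window (s)
    t_inc <- cfg$sim_time
    sp <- absorbance_spectra(pmax(cons, 0) * t_inc, labels = cbs)
    spdf <- data.frame(wavelength_nm = sp$wavelengths, sp$absorbance)
    names(spdf) <- c("wavelength_nm", sprintf("C_%g_mM", cbs))
    files <- c(files, write_csv_full(spdf, out("spectra.csv")))
    diag$band_centre <- apply(sp$absorbance, 2, max)
  } else if (task == "sensitivity") {
    sens <- sensitivity_sweep(cfg, grid, C_bulk_list = cfg$C_bulk_list)
    files <- c(files, write_csv_full(as.data.frame(sens), out("sensitivity.csv")))
    diag$sigma_blank <- attr(sens, "sigma_blank")
  } else if (task == "validate-regime") {
    vr <- validity_report(cfg)
    jsonlite::write_json(list(Pi = vr$Pi, lam_over_H = vr$lam_over_H,
                              regime = vr$regime,
                              flags = lapply(vr$flags, function(f)
                                list(value = f$value, threshold = f$threshold,
                                     pass = f$pass))),
                         out("validity.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, out("validity.json"))
    diag$regime <- vr$regime
  }

  manifest <- list(
    package = "p2dsensor",
    version = as.character(utils::packageVersion("p2dsensor")),
    task = task,
    config = config_echo(cfg),
    grid = list(nx = grid$nx, ny = grid$ny, stretch = grid$stretch,
                nodes_first_5um = sum(grid$y < 5e-6)),
    diagnostics = diag,
    seed = cfg$seed,
    wall_time_s = proc.time()[["elapsed"]] - t0,
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

config_echo <- function(cfg) {
  list(transport = unclass(cfg$transport),
       kinetics = unclass(cfg$kinetics),
       mode = cfg$mode, C_bulk_list = cfg$C_bulk_list,
       sim_time = cfg$sim_time, E_op = cfg$E_op, T = cfg$T, seed = cfg$seed,
       derived = list(j_max = cfg$j_max, j_max_el = cfg$j_max_el,
                      da_glu = cfg$da_glu, da_p = cfg$da_p,
                      delta_enz = cfg$kinetics$delta_enz))
}

#' Synthetic reference spectra for validation plumbing
#'
#' Generates noisy Gaussian-band absorbance spectra emulating the qualitative
#' behaviour of reported chromogenic measurements (band-centre absorbance
#' rising monotonically with glucose concentration). These are synthetic
#' stand-ins for external spectra that are not printed in any source; they
#' exercise the RMSE validation machinery, nothing more. Reproducible from
#' the seed; noise is i.i.d. Gaussian and spectra are not clipped (blank
#' readings may dip slightly below zero, as real baselines do).
#'
#' @param cfg A [scenario()] supplying the seed and model parameters.
#' @param concentrations Glucose concentrations (mM), within the sweep range.
#' @param noise_sd Noise standard deviation (AU).
#' @param grid A [grid_2d()] for the underlying steady solves.
#' @param t_inc Incubation window (s) for the cumulative consumption.
#' @param ... Band parameters passed to [absorbance_spectra()].
#' @return A list with `model` (noiseless `"spectrum_set"`) and `fixture`
#'   (noisy `"spectrum_set"`).
#' @export
generate_fixture_spectra <- function(cfg = scenario(),
                                     concentrations = c(0.5, 5, 10),
                                     noise_sd = 0.02,
                                     grid = grid_2d(cfg$transport$L, cfg$transport$H,
                                                    nx = 24, ny = 80),
                                     t_inc = cfg$sim_time, ...) {
  stopifnot(all(concentrations >= 0.01), all(concentrations <= 12))
  cons <- vapply(concentrations, function(cb)
    solve_colorimetric_coupled(cfg, cb, grid)$h2o2$J_eff * t_inc, 0)
  model <- absorbance_spectra(cons, labels = concentrations, ...)
  fixture <- model
  set.seed(cfg$seed)
  fixture$absorbance <- model$absorbance +
    stats::rnorm(length(model$absorbance), sd = noise_sd)
  list(model = model, fixture = fixture)
}

#' Write a spectrum set as CSV (wavelength, one column per concentration)
#' @param sp A `"spectrum_set"`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_spectra_csv <- function(sp, path) {
  df <- data.frame(wavelength_nm = sp$wavelengths, sp$absorbance,
                   check.names = FALSE)
  write_csv_full(df, path)
  invisible(path)
}

#' Read a spectrum-set CSV written by [write_spectra_csv()]
#' @param path CSV path.
#' @return A `"spectrum_set"` (band parameters unknown, set to NA).
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  structure(list(wavelengths = df[[1]],
                 absorbance = as.matrix(df[, -1, drop = FALSE]),
                 center = NA_real_, width = NA_real_, scale = NA_real_),
            class = "spectrum_set")
}
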