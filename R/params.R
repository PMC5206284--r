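#' Construct a model parameter set
#'
#' Bundles every physical constant of the planar lamellipodium model into a
#' validated list of class `"lam_params"`. Units are fixed to pN, um and min
#' throughout; angles are stored in radians (configuration files may supply
#' degrees, see [read_parameters()]). Defaults are the reference parameter set
#' of the model (the "simulation 2" myosin twisting constant); use
#' [default_parameters()] for named presets.
#'
#' @param L filament length (um).
#' @param mu_A adhesion friction coefficient (pN min um^-2).
#' @param v polymerization speed (um min^-1).
#' @param v_M myosin walking speed (um min^-1).
#' @param phi0 equilibrium cross-link angle (rad); equals the branching angle.
#' @param phi_bar myosin cutoff angle (rad): myosin engages only on filament
#'   pairs crossing at an angle above `phi_bar`.
#' @param mu_S cross-link stretching constant (pN min um^-1).
#' @param mu_T cross-link twisting constant (pN um).
#' @param mu_SM_bar myosin stretching constant (pN min um^-1), slope of the
#'   cutoff law for the effective stretching stiffness.
#' @param mu_TM_bar myosin twisting constant (pN um), slope of the cutoff law
#'   for the effective twisting stiffness.
#' @param f_mem membrane force line density (pN um^-1), pulling the barbed
#'   ends rearward.
#' @param f_stress stress-fibre force line density (pN um^-1), pulling the
#'   pointed ends rearward, used when the force is modelled as constant
#'   (size-dependent closures are configured via [stress_fibre_model()]).
#' @param mu_B bending stiffness (pN um^2). Documented for completeness; the
#'   rigid-filament reduction is its infinite-stiffness limit, so it does not
#'   enter any computation here.
#' @param A0 equilibrium inner area of a fragment (um^2); used only to set the
#'   default reference size of [stress_fibre_model()].
#' @param N total filament number (documentation only).
#' @param eta filament length density in parameter space; fixed to 1 (no
#'   filament ends inside the modelled strip).
#' @param omega_floor lower clamp for the filament angle (rad). Reaching it
#'   during integration raises a "collapse" event, since the continuum model
#'   cannot represent a fully collapsed network.
#'
#' @return A list of class `"lam_params"`.
#' @seealso [default_parameters()], [bistability_condition()]
#' @export
model_parameters <- function(L = 8, mu_A = 0.14, v = 3, v_M = 1,
                             phi0 = 70 * pi / 180, phi_bar = 100 * pi / 180,
                             mu_S = 4.2e-3, mu_T = 4.2e-3,
                             mu_SM_bar = 4.2e-3, mu_TM_bar = 1.8e-2,
                             f_mem = 0, f_stress = 0,
                             mu_B = 0.7, A0 = 300, N = 9000, eta = 1,
                             omega_floor = 1e-6) {
  p <- list(L = L, mu_A = mu_A, v = v, v_M = v_M,
            phi0 = phi0, phi_bar = phi_bar,
            mu_S = mu_S, mu_T = mu_T,
            mu_SM_bar = mu_SM_bar, mu_TM_bar = mu_TM_bar,
            f_mem = f_mem, f_stress = f_stress,
            mu_B = mu_B, A0 = A0, N = N, eta = eta,
            omega_floor = omega_floor)
  validate_parameters(p)
  class(p) <- "lam_params"
  p
}

validate_parameters <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  if (p$L <= 0) stop("L must be positive")
  if (p$mu_A <= 0) stop("mu_A must be positive")
  if (p$v < 0 || p$v_M < 0) stop("speeds v and v_M must be nonnegative")
  for (nm in c("mu_S", "mu_T", "mu_SM_bar", "mu_TM_bar", "mu_B")) {
    if (p[[nm]] < 0) stop(nm, " must be nonnegative")
  }
  if (!(p$phi0 > 0 && p$phi0 < p$phi_bar && p$phi_bar < pi)) {
    stop("angles must satisfy 0 < phi0 < phi_bar < pi (cutoff model assumption)")
  }
  if (p$eta != 1) stop("eta is fixed to 1 (no filament ends inside the modelled strip)")
  if (p$omega_floor <= 0 || p$omega_floor >= pi / 2) {
    stop("omega_floor must lie in (0, pi/2)")
  }
  invisible(p)
}

#' Reference parameter presets
#'
#' Returns the reference parameter table of the model. The two presets differ
#' only in the myosin twisting constant `mu_TM_bar`: `"simulation1"` uses
#' 1.4e-2 pN um, `"simulation2"` (the default) 1.8e-2 pN um. Both satisfy the
#' myosin-dominance condition of [bistability_condition()]; the larger value
#' gives a more robust myosin-influenced equilibrium.
#'
#' @param preset `"simulation2"` (default) or `"simulation1"`.
#' @param ... further overrides passed to [model_parameters()].
#' @return A `"lam_params"` object.
#' @export
default_parameters <- function(preset = c("simulation2", "simulation1"), ...) {
  preset <- match.arg(preset)
  mu_TM_bar <- switch(preset, simulation1 = 1.4e-2, simulation2 = 1.8e-2)
  args <- list(...)
  if (is.null(args$mu_TM_bar)) args$mu_TM_bar <- mu_TM_bar
  do.call(model_parameters, args)
}

#' @export
print.lam_params <- function(x, ...) {
  cat("Planar lamellipodium model parameters (pN, um, min; angles in rad)\n")
  fmt <- function(v) format(v, digits = 6)
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, fmt(x[[nm]])))
  cond <- bistability_condition(x)
  cat(sprintf("  myosin-dominance condition: %s (ratio %.4g %s threshold %.4g)\n",
              if (cond$holds) "holds" else "fails",
              cond$ratio, if (cond$holds) ">" else "<=", cond$threshold))
  invisible(x)
}

#' Threshold of the myosin-dominance condition
#'
#' The torque function of the planar angle equation has three interior zeroes
#' (a cross-link-dominated one and a myosin-influenced pair) exactly when the
#' stiffness ratio `mu_TM_bar / mu_T` strictly exceeds
#' \deqn{\frac{\bar\varphi + \pi - 2\varphi_0 +
#'   2\sqrt{(\pi-\varphi_0)(\bar\varphi-\varphi_0)}}{(\pi-\bar\varphi)^2}.}
#' This function evaluates that right-hand side. It is strictly increasing in
#' `phi_bar` and diverges as `phi_bar` approaches pi: a narrow myosin
#' engagement window must be compensated by a stiff myosin filament.
#'
#' @param phi0 equilibrium cross-link angle (rad), in (0, pi).
#' @param phi_bar myosin cutoff angle (rad), with `phi0 <= phi_bar < pi`.
#' @return The dimensionless threshold for `mu_TM_bar / mu_T`.
#' @export
bistability_threshold <- function(phi0, phi_bar) {
  if (any(phi_bar >= pi)) stop("phi_bar must be strictly below pi")
  if (any(phi0 > phi_bar)) stop("phi0 must not exceed phi_bar")
  if (any(phi0 <= 0)) stop("phi0 must be positive")
  (phi_bar + pi - 2 * phi0 + 2 * sqrt((pi - phi0) * (phi_bar - phi0))) /
    (pi - phi_bar)^2
}

#' Check the myosin-dominance condition for a parameter set
#'
#' Evaluates whether `mu_TM_bar / mu_T` strictly exceeds
#' [bistability_threshold()], i.e. whether a myosin-influenced stable
#' equilibrium angle exists in addition to the cross-link-dominated one.
#' Also reports the simpler sufficient criterion
#' `mu_TM_bar * (pi - phi_bar)^2 > 4 * mu_T * (pi - phi0)`, the limiting form
#' of the threshold for cutoff angles close to pi, as a diagnostic.
#'
#' @param params a `"lam_params"` object.
#' @return A list with elements `holds` (logical), `ratio`, `threshold`,
#'   `margin` (`ratio - threshold`), and the approximate criterion
#'   `approx_lhs`, `approx_rhs`, `approx_holds`.
#' @export
bistability_condition <- function(params) {
  stopifnot(inherits(params, "lam_params"))
  thr <- bistability_threshold(params$phi0, params$phi_bar)
  ratio <- if (params$mu_T > 0) params$mu_TM_bar / params$mu_T else Inf
  lhs <- params$mu_TM_bar * (pi - params$phi_bar)^2
  rhs <- 4 * params$mu_T * (pi - params$phi0)
  list(holds = ratio > thr,
       ratio = ratio,
       threshold = thr,
       margin = ratio - thr,
       approx_lhs = lhs,
       approx_rhs = rhs,
       approx_holds = lhs > rhs)
}

#' Write a parameter set to a configuration file
#'
#' Serializes all fields as a flat key/value JSON or YAML file (chosen by the
#' file extension). Angles are written in radians together with an explicit
#' `angle_unit` key so that hand-edited files may use degrees instead.
#'
#' @param params a `"lam_params"` object.
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "lam_params"))
  x <- unclass(params)
  x$angle_unit <- "radians"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    stop("unsupported config extension (use .json, .yaml or .yml): ", path)
  }
  invisible(path)
}

#' Read a parameter set from a configuration file
#'
#' Accepts the flat key/value layout written by [write_parameters()]. The
#' optional key `angle_unit` (`"radians"`, default, or `"degrees"`) controls
#' the interpretation of `phi0` and `phi_bar`. Missing keys fall back to the
#' [model_parameters()] defaults; unknown keys are an error.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @param overrides named list applied on top of the file contents (angles in
#'   radians), e.g. from command-line flags.
#' @return A `"lam_params"` object.
#' @export
read_parameters <- function(path, overrides = list()) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension (use .json, .yaml or .yml): ", path)
  }
  unit <- x$angle_unit %||% "radians"
  x$angle_unit <- NULL
  x <- lapply(x, function(v) if (is.numeric(v)) as.numeric(v) else v)
  if (grepl("^deg", unit, ignore.case = TRUE)) {
    for (nm in c("phi0", "phi_bar")) {
      if (!is.null(x[[nm]])) x[[nm]] <- x[[nm]] * pi / 180
    }
  } else if (!grepl("^rad", unit, ignore.case = TRUE)) {
    stop("angle_unit must be 'radians' or 'degrees', got: ", unit)
  }
  known <- names(formals(model_parameters))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown parameter keys: ", paste(bad, collapse = ", "))
  x[names(overrides)] <- overrides
  do.call(model_parameters, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
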