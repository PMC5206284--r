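#' Size-regulating force closure for the fragment model
#'
#' In the two-lamellipodia fragment the membrane and stress-fibre forces may
#' regulate the fragment size `Y = y + yhat` (um). Two closures are
#' supported: `target = "stress"` makes the stress-fibre force size-dependent
#' with constant membrane force, `target = "membrane"` the reverse. The
#' force-size law is either `"linear"` (`f = f_ref + kappa (Y - Y0)`),
#' `"hinge"` (`f = f_ref + kappa (Y - Y0)_+`, engaged only above the reference
#' size), or `"constant"`. The hinge is only continuous; for Jacobian and
#' eigenvalue work a C1-smoothed hinge of configurable `width` is used (the
#' exact hinge is recovered with `width = 0`), since the stability analysis
#' assumes a continuously differentiable force law.
#'
#' @param form `"hinge"`, `"linear"` or `"constant"`.
#' @param target `"stress"` (size-dependent stress-fibre force) or
#'   `"membrane"` (size-dependent membrane force).
#' @param kappa force-law slope (pN um^-2), nonnegative; the reference value
#'   5e-2 corresponds to the inner-pulling constant of the full-model
#'   simulations.
#' @param Y0 reference size (um); defaults, via [fragment_defaults()], to the
#'   diameter of the disc with the equilibrium inner area.
#' @param width smoothing width of the hinge (um).
#' @param f_ref force offset (pN um^-1).
#' @return A list of class `"lam_sfm"`.
#' @export
stress_fibre_model <- function(form = c("hinge", "linear", "constant"),
                               target = c("stress", "membrane"),
                               kappa = 5e-2, Y0 = 2 * sqrt(300 / pi),
                               width = 0.1, f_ref = 0) {
  form <- match.arg(form)
  target <- match.arg(target)
  stopifnot(kappa >= 0, width >= 0, Y0 > 0)
  structure(list(form = form, target = target, kappa = kappa, Y0 = Y0,
                 width = width, f_ref = f_ref),
            class = "lam_sfm")
}

#' Evaluate the size-dependent force and its slope
#'
#' @param sfm a `"lam_sfm"` object.
#' @param Y fragment size(s) (um); vectorized.
#' @return `sf_force`: force values (pN um^-1); `sf_slope`: derivative with
#'   respect to `Y` (pN um^-2).
#' @export
sf_force <- function(sfm, Y) {
  stopifnot(inherits(sfm, "lam_sfm"))
  z <- Y - sfm$Y0
  val <- switch(sfm$form,
    constant = rep_len(0, length(Y)),
    linear = sfm$kappa * z,
    hinge = {
      w <- sfm$width
      if (w == 0) sfm$kappa * pmax(z, 0)
      else ifelse(z <= 0, 0,
                  ifelse(z < w, sfm$kappa * z^2 / (2 * w),
                         sfm$kappa * (z - w / 2)))
    })
  sfm$f_ref + val
}

#' @rdname sf_force
#' @export
sf_slope <- function(sfm, Y) {
  stopifnot(inherits(sfm, "lam_sfm"))
  z <- Y - sfm$Y0
  switch(sfm$form,
    constant = rep_len(0, length(Y)),
    linear = rep_len(sfm$kappa, length(Y)),
    hinge = {
      w <- sfm$width
      if (w == 0) sfm$kappa * (z > 0)
      else ifelse(z <= 0, 0, ifelse(z < w, sfm$kappa * z / w, sfm$kappa))
    })
}

# membrane and stress-fibre forces at size Y under the chosen closure
fragment_forces <- function(params, sfm, Y) {
  if (sfm$target == "stress") {
    list(f_stress = sf_force(sfm, Y), f_mem = params$f_mem)
  } else {
    list(f_stress = params$f_stress, f_mem = sf_force(sfm, Y))
  }
}

#' Fragment state
#'
#' State of the back-to-back pair of planar lamellipodia: total size
#' `Y = y + yhat` (um) and the two filament angles `omega` (front) and
#' `omega_hat` (rear), both in (0, pi/2].
#'
#' @param Y total size (um), positive.
#' @param omega,omega_hat filament angles (rad) of the two lamellipodia.
#' @return A list of class `"lam_fragment_state"`.
#' @export
fragment_state <- function(Y, omega, omega_hat) {
  stopifnot(Y > 0)
  for (w in c(omega, omega_hat)) {
    if (w <= 0 || w > pi / 2) stop("angles must lie in (0, pi/2]")
  }
  structure(list(Y = Y, omega = omega, omega_hat = omega_hat),
            class = "lam_fragment_state")
}

#' Right-hand side of the coupled fragment system
#'
#' Time derivatives of `(Y, omega, omega_hat)` for the back-to-back pair.
#' Both lamellipodia feel the same membrane and stress-fibre forces (total
#' force on the fragment vanishes), one of which may depend on the size `Y`:
#' \deqn{\dot Y = -\tfrac{2}{\mu^A L}(f_{mem}+f_{stress}(Y)) +
#'   v(\sin\omega + \sin\hat\omega),}
#' and each angle obeys the decoupled-form planar angle equation
#' `cos(w) (delta_f(Y)/4 + h(w)) / g(w)`. The system is symmetric under
#' exchange of the two angles.
#'
#' @param state a `"lam_fragment_state"` (or list with `Y`, `omega`,
#'   `omega_hat`).
#' @param params a `"lam_params"` object.
#' @param sfm a `"lam_sfm"` force closure.
#' @return Named numeric vector `c(Y_dot, omega_dot, omega_hat_dot)`.
#' @export
fragment_rhs <- function(state, params, sfm) {
  stopifnot(inherits(params, "lam_params"), inherits(sfm, "lam_sfm"))
  p <- params
  state <- lapply(state, unname)
  f <- fragment_forces(p, sfm, state$Y)
  df <- f$f_stress - f$f_mem
  angle_dot <- function(w) {
    cos(w) * (df / 4 + h_torque(w, p)) / g_drag(w, p)
  }
  c(Y_dot = -2 / (p$mu_A * p$L) * (f$f_mem + f$f_stress) +
      p$v * (sin(state$omega) + sin(state$omega_hat)),
    omega_dot = angle_dot(state$omega),
    omega_hat_dot = angle_dot(state$omega_hat))
}

#' Stationary fragment size for given angles
#'
#' At a steady state the size equation requires
#' \deqn{f_{stress}(Y) = -f_{mem} + \tfrac{\mu^A L v}{2}
#'   (\sin\omega + \sin\hat\omega)}
#' (with the roles of the two forces exchanged under the `"membrane"`
#' closure). The size-dependent force is nondecreasing in `Y`, so the scalar
#' equation is solved by monotone bracketing ([stats::uniroot()]).
#'
#' @param omega,omega_hat the two angles (rad).
#' @param params a `"lam_params"` object.
#' @param sfm a size-dependent `"lam_sfm"` (`form` not `"constant"`).
#' @return The stationary size `Y_star` (um).
#' @export
stationary_size <- function(omega, omega_hat, params, sfm) {
  stopifnot(inherits(params, "lam_params"), inherits(sfm, "lam_sfm"))
  if (sfm$form == "constant") stop("stationary size requires a size-dependent force closure")
  p <- params
  const_force <- if (sfm$target == "stress") p$f_mem else p$f_stress
  target <- -const_force + p$mu_A * p$L * p$v / 2 * (sin(omega) + sin(omega_hat))
  fn <- function(Y) sf_force(sfm, Y) - target
  lo <- 1e-8
  hi <- sfm$Y0 + 1
  while (fn(hi) < 0 && hi < 1e8) hi <- 2 * hi
  if (fn(hi) < 0 || fn(lo) > 0) {
    stop("no stationary size: required force ", format(target),
         " outside the range of the force law (inconsistent forces)")
  }
  stats::uniroot(fn, c(lo, hi), tol = 1e-14)$root
}

#' Analytic Jacobian of the coupled fragment system
#'
#' Chain-rule differentiation of [fragment_rhs()] through the drag, the
#' torque balance, the cosine factors and the force closure. The matrix has
#' the arrow structure (size row full; each angle row couples only to the
#' size through the force slope), which at the steady states yields two fast
#' angle eigenvalues and one slow size eigenvalue of order the force slope
#' (see [slow_eigenvalue_estimate()]).
#'
#' @param state a fragment state; for eigenvalue interpretation it should be
#'   an equilibrium (a warning is raised when the residual is large).
#' @param params a `"lam_params"` object.
#' @param sfm a `"lam_sfm"` force closure.
#' @param check_equilibrium warn if `max |rhs|` exceeds `1e-6`.
#' @return A list with `jacobian` (3x3 matrix, rows/cols Y, omega,
#'   omega_hat) and `eigenvalues` (complex, sorted by decreasing real part).
#' @export
fragment_jacobian <- function(state, params, sfm, check_equilibrium = TRUE) {
  stopifnot(inherits(params, "lam_params"), inherits(sfm, "lam_sfm"))
  J <- fragment_jac_matrix(state, params, sfm)
  if (check_equilibrium) {
    res <- max(abs(fragment_rhs(state, params, sfm)))
    if (res > 1e-6) {
      warning("state is not an equilibrium (|rhs| = ", format(res),
              "); eigenvalues do not describe local stability of a steady state")
    }
  }
  ev <- eigen(J, only.values = TRUE)$values
  list(jacobian = J, eigenvalues = ev[order(-Re(ev))])
}

fragment_jac_matrix <- function(state, params, sfm) {
  p <- params
  state <- lapply(state, unname)
  Y <- state$Y
  f <- fragment_forces(p, sfm, Y)
  df <- f$f_stress - f$f_mem
  slope <- sf_slope(sfm, Y)
  ddf_dY <- if (sfm$target == "stress") slope else -slope

  angle_row <- function(w) {
    hw <- h_torque(w, p)
    hp <- h_torque_prime(w, p)
    gw <- g_drag(w, p)
    gp <- g_drag_prime(w, p)
    core <- df / 4 + hw
    dY <- cos(w) * ddf_dY / (4 * gw)
    dw <- (-sin(w) * core + cos(w) * hp) / gw - cos(w) * core * gp / gw^2
    c(dY = dY, dw = dw)
  }
  r1 <- angle_row(state$omega)
  r2 <- angle_row(state$omega_hat)
  J <- rbind(c(-2 * slope / (p$mu_A * p$L),
               p$v * cos(state$omega), p$v * cos(state$omega_hat)),
             c(r1["dY"], r1["dw"], 0),
             c(r2["dY"], 0, r2["dw"]))
  dimnames(J) <- list(c("Y", "omega", "omega_hat"), c("Y", "omega", "omega_hat"))
  J
}

#' Leading-order eigenvalues of the size-angle coupling
#'
#' For a small force-law slope `kappa` the fragment linearization splits into
#' two fast angle modes and one slow size mode. First-order eigenvalue
#' perturbation of the arrow-structured Jacobian gives
#' \deqn{\lambda_{1} = A h'(\omega) + O(\kappa),\quad
#'   \lambda_{2} = \hat A h'(\hat\omega) + O(\kappa),}
#' with the positive factors `A = cos(w)/g(w)`, and the slow mode
#' \deqn{\lambda_3 = \kappa\Bigl(-\frac{2}{\mu^A L}
#'   - \frac{v\cos\omega}{4 h'(\omega)}
#'   - \frac{v\cos\hat\omega}{4 h'(\hat\omega)}\Bigr) + O(\kappa^2)}
#' (sign of the angle-coupling terms reversed under the `"membrane"`
#' closure). Since `h' < 0` at both stable angles, the angle terms are
#' destabilizing — polymerization feeds size growth back into steeper
#' angles — and the steady states are stable only while the direct size
#' relaxation `-2/(mu_A L)` dominates, which the smallness of `mu_A v L`
#' guarantees.
#'
#' @param state an equilibrium fragment state.
#' @param params a `"lam_params"` object.
#' @param sfm a `"lam_sfm"` force closure.
#' @return A list with `lambda1`, `lambda2`, `lambda3` (min^-1), the factors
#'   `A`, `A_hat`, and the slope `kappa` used.
#' @export
slow_eigenvalue_estimate <- function(state, params, sfm) {
  stopifnot(inherits(params, "lam_params"), inherits(sfm, "lam_sfm"))
  p <- params
  kap <- sf_slope(sfm, state$Y)
  sgn <- if (sfm$target == "stress") 1 else -1
  w <- state$omega
  wh <- state$omega_hat
  hpw <- h_torque_prime(w, p)
  hpwh <- h_torque_prime(wh, p)
  if (hpw >= 0 || hpwh >= 0) {
    warning("h'(omega) >= 0 at the state: slow-mode expansion assumes stable angles")
  }
  A <- cos(w) / g_drag(w, p)
  A_hat <- cos(wh) / g_drag(wh, p)
  list(lambda1 = A * hpw,
       lambda2 = A_hat * hpwh,
       lambda3 = kap * (-2 / (p$mu_A * p$L) -
                          sgn * (p$v * cos(w) / (4 * hpw) +
                                 p$v * cos(wh) / (4 * hpwh))),
       A = A, A_hat = A_hat, kappa = kap)
}

#' Fragment protrusion speed
#'
#' At a steady state the fragment translates at
#' \deqn{\dot y = -\dot{\hat y} = \tfrac{v}{2}(\sin\omega - \sin\hat\omega),}
#' zero for symmetric states, nonzero for polarized ones; the magnitude is
#' bounded by `v`. Swapping the angles flips the sign.
#'
#' @param omega,omega_hat the two angles (rad).
#' @param v polymerization speed (um min^-1).
#' @return Speed (um min^-1).
#' @export
fragment_speed <- function(omega, omega_hat, v) {
  v / 2 * (sin(omega) - sin(omega_hat))
}

# damped Newton iteration on the fragment RHS; returns state or NULL
fragment_newton <- function(Y, w, wh, params, sfm, tol = 1e-11, maxit = 80) {
  s <- c(Y, w, wh)
  for (i in seq_len(maxit)) {
    st <- list(Y = s[1], omega = s[2], omega_hat = s[3])
    r <- fragment_rhs(st, params, sfm)
    if (max(abs(r)) < tol) {
      return(fragment_state(s[1], s[2], s[3]))
    }
    J <- fragment_jac_matrix(st, params, sfm)
    if (any(!is.finite(J))) return(NULL)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      cand <- s - lam * step
      ok <- cand[1] > 0 && all(cand[2:3] > params$omega_floor) &&
        all(cand[2:3] <= pi / 2)
      if (ok) {
        rc <- fragment_rhs(list(Y = cand[1], omega = cand[2],
                                omega_hat = cand[3]), params, sfm)
        if (max(abs(rc)) < max(abs(r)) || lam < 1e-3) break
      }
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    s <- unname(cand)
  }
  NULL
}

#' Steady states of the coupled fragment system
#'
#' Locates the equilibria of [fragment_rhs()] by Newton iteration seeded at
#' every pair of torque-balance zeroes from [h_zeros()] (size seeded from
#' [stationary_size()]). Under the myosin-dominance condition and for small
#' membrane force, small `mu_A v L` and a gentle force-law slope there are
#' exactly four stable steady states: the two symmetric ones (both angles
#' cross-link-dominated, or both myosin-influenced; stationary fragment) and
#' the two polarized ones (one angle of each kind; moving fragment).
#' Equilibria involving the separatrix angle are also returned, flagged
#' unstable. Convergence failures of individual seeds are reported as
#' messages without aborting the remaining seeds.
#'
#' @param params a `"lam_params"` object; for the coupled analysis the
#'   adhesion-polymerization product `mu_A * v * L` must be small (see
#'   [fragment_defaults()] and [coupling_bound()]).
#' @param sfm a size-dependent `"lam_sfm"`.
#' @param include_unstable also seed combinations involving the separatrix
#'   zero (default `TRUE`).
#' @return A data frame with one row per distinct equilibrium: `Y`, `omega`,
#'   `omega_hat`, `label` (`"symmetric-CL"`, `"symmetric-MY"`,
#'   `"polarized-front-CL"`, `"polarized-front-MY"`, or `"separatrix"`),
#'   `stable`, `speed` (um min^-1), `max_re_lambda`, and eigenvalue columns
#'   `re_lambda1..3`, `im_lambda1..3` (sorted by decreasing real part).
#' @export
fragment_steady_states <- function(params, sfm, include_unstable = TRUE) {
  stopifnot(inherits(params, "lam_params"), inherits(sfm, "lam_sfm"))
  hz <- h_zeros(params)
  if (nrow(hz) < 1) stop("no torque-balance zeroes found")
  w10 <- hz$omega[hz$branch == "linear"][1]
  quad <- hz$omega[hz$branch == "quadratic"]
  w30 <- if (length(quad)) min(quad) else NA_real_
  w20 <- if (length(quad) == 2) max(quad) else NA_real_

  stable_seeds <- stats::na.omit(c(w10, w30))
  seeds <- expand.grid(w = stable_seeds, wh = stable_seeds)
  if (include_unstable && !is.na(w20)) {
    extra <- rbind(expand.grid(w = w20, wh = c(stable_seeds, w20)),
                   expand.grid(w = stable_seeds, wh = w20))
    seeds <- rbind(seeds, extra)
  }

  found <- list()
  for (i in seq_len(nrow(seeds))) {
    w <- seeds$w[i]; wh <- seeds$wh[i]
    Y <- tryCatch(stationary_size(w, wh, params, sfm), error = function(e) NA_real_)
    if (is.na(Y)) {
      message(sprintf("seed (%.4f, %.4f): no stationary size", w, wh))
      next
    }
    st <- fragment_newton(Y, w, wh, params, sfm)
    if (is.null(st)) {
      message(sprintf("seed (%.4f, %.4f): Newton iteration failed", w, wh))
      next
    }
    dup <- any(vapply(found, function(f) {
      abs(f$Y - st$Y) < 1e-6 && abs(f$omega - st$omega) < 1e-8 &&
        abs(f$omega_hat - st$omega_hat) < 1e-8
    }, logical(1)))
    if (!dup) found[[length(found) + 1L]] <- st
  }
  if (!length(found)) stop("no fragment steady states found from any seed")

  classify_angle <- function(w) {
    refs <- c(CL = w10, MY = if (is.na(w30)) -Inf else w30,
              SEP = if (is.na(w20)) Inf else w20)
    names(refs)[which.min(abs(w - refs))]
  }
  rows <- lapply(found, function(st) {
    jac <- fragment_jacobian(st, params, sfm, check_equilibrium = FALSE)
    ev <- jac$eigenvalues
    kinds <- c(classify_angle(st$omega), classify_angle(st$omega_hat))
    label <- if (any(kinds == "SEP")) "separatrix"
    else if (all(kinds == "CL")) "symmetric-CL"
    else if (all(kinds == "MY")) "symmetric-MY"
    else if (kinds[1] == "CL") "polarized-front-CL"
    else "polarized-front-MY"
    data.frame(Y = st$Y, omega = st$omega, omega_hat = st$omega_hat,
               label = label,
               stable = all(Re(ev) < 0),
               speed = fragment_speed(st$omega, st$omega_hat, params$v),
               max_re_lambda = max(Re(ev)),
               re_lambda1 = Re(ev[1]), re_lambda2 = Re(ev[2]),
               re_lambda3 = Re(ev[3]),
               im_lambda1 = Im(ev[1]), im_lambda2 = Im(ev[2]),
               im_lambda3 = Im(ev[3]))
  })
  out <- do.call(rbind, rows)
  out[order(out$label), , drop = FALSE]
}

#' Reference setup for the coupled fragment analyses
#'
#' Returns the parameter set and force closure used by default for the
#' fragment model: the reference table with the adhesion coefficient lowered
#' to `mu_A` (default 1e-4 pN min um^-2) and a hinge stress-fibre closure
#' with slope 5e-2 pN um^-2 around the disc-equivalent reference size
#' `2 sqrt(A0/pi)`. The coupled steady-state structure exists only for a
#' small adhesion-polymerization product `mu_A v L` (at the full reference
#' adhesion the size equation is inconsistent with any admissible angle);
#' the default sits well inside the empirically determined bound, see
#' [coupling_bound()], and yields polarized-fragment speeds of about
#' 1 um/min.
#'
#' @param preset passed to [default_parameters()].
#' @param mu_A adhesion coefficient for the coupled analyses (pN min um^-2).
#' @param kappa,width hinge slope and smoothing width of the closure.
#' @param ... further overrides for [default_parameters()].
#' @return A list with elements `params` and `sfm`.
#' @export
fragment_defaults <- function(preset = "simulation2", mu_A = 1e-4,
                              kappa = 5e-2, width = 0.1, ...) {
  params <- default_parameters(preset, mu_A = mu_A, ...)
  sfm <- stress_fibre_model("hinge", "stress", kappa = kappa,
                            Y0 = 2 * sqrt(params$A0 / pi), width = width)
  list(params = params, sfm = sfm)
}

#' Empirical adhesion bound for four-state coexistence
#'
#' The fragment analysis requires `mu_A v L` "small"; this routine makes the
#' bound concrete for a given setup by bisecting on a scale factor applied to
#' the adhesion coefficient for the largest value at which
#' [fragment_steady_states()] still returns all four stable states.
#'
#' @param params a `"lam_params"` object (its `mu_A` is scaled).
#' @param sfm a `"lam_sfm"`.
#' @param scale_max upper end of the searched scale range.
#' @param tol relative bisection tolerance.
#' @return The largest adhesion coefficient (pN min um^-2) with four stable
#'   steady states, within tolerance.
#' @export
coupling_bound <- function(params, sfm, scale_max = 1e4, tol = 1e-2) {
  stopifnot(inherits(params, "lam_params"))
  ok <- function(scale) {
    p <- params
    p$mu_A <- params$mu_A * scale
    ss <- tryCatch(
      suppressMessages(fragment_steady_states(p, sfm, include_unstable = FALSE)),
      error = function(e) NULL)
    !is.null(ss) && sum(ss$stable) == 4 &&
      setequal(ss$label[ss$stable],
               c("symmetric-CL", "symmetric-MY",
                 "polarized-front-CL", "polarized-front-MY"))
  }
  if (!ok(1)) stop("four stable states absent already at the given mu_A")
  lo <- 1
  hi <- 2
  while (ok(hi) && hi < scale_max) {
    lo <- hi
    hi <- 2 * hi
  }
  if (hi >= scale_max) return(params$mu_A * lo)
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (ok(mid)) lo <- mid else hi <- mid
  }
  params$mu_A * lo
}

#' Finite-difference parameter sensitivities of the moving fragment
#'
#' Central finite differences of the polarized-state angles and the fragment
#' speed with respect to the adhesion coefficient and the two myosin
#' constants. At the reference setup the speed increases with adhesion
#' strength (small-adhesion regime) and with the myosin twisting constant,
#' while the myosin stretching constant leaves the equilibrium angles — and
#' hence the speed — unchanged (it only enters the drag).
#'
#' @param params a `"lam_params"` object admitting the polarized state.
#' @param sfm a size-dependent `"lam_sfm"`.
#' @param rel_delta relative half-width of the central differences.
#' @return A data frame with columns `parameter`, `d_omega_CL`, `d_omega_MY`,
#'   `d_speed` (derivative values in the parameter's own units) and `sign`
#'   (of `d_speed`, with 0 for magnitudes below `1e-8` um/min per unit).
#' @export
sensitivity_report <- function(params, sfm, rel_delta = 1e-3) {
  stopifnot(inherits(params, "lam_params"), inherits(sfm, "lam_sfm"))
  polarized <- function(p) {
    ss <- suppressMessages(fragment_steady_states(p, sfm, include_unstable = FALSE))
    row <- ss[ss$label == "polarized-front-CL", , drop = FALSE]
    if (nrow(row) != 1) stop("polarized state not found")
    c(omega_CL = row$omega, omega_MY = row$omega_hat, speed = row$speed)
  }
  base <- polarized(params)
  rows <- lapply(c("mu_A", "mu_TM_bar", "mu_SM_bar"), function(nm) {
    dlt <- rel_delta * params[[nm]]
    pp <- pm <- params
    pp[[nm]] <- params[[nm]] + dlt
    pm[[nm]] <- params[[nm]] - dlt
    d <- (polarized(pp) - polarized(pm)) / (2 * dlt)
    data.frame(parameter = nm,
               d_omega_CL = d[["omega_CL"]],
               d_omega_MY = d[["omega_MY"]],
               d_speed = d[["speed"]],
               sign = ifelse(abs(d[["speed"]]) < 1e-8, 0L,
                             as.integer(sign(d[["speed"]]))))
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  out
}

#' Integrate the coupled fragment system
#'
#' Adaptive-step time integration of the full fragment dynamics, tracking the
#' individual positions `y`, `yhat` (whose sum is the size `Y`) and the
#' passive lateral positions `x`, `xhat`. Stops early with a collapse event
#' if either angle reaches `params$omega_floor`. The terminal state is
#' classified against the torque-balance zeroes: `"symmetric-CL"`,
#' `"symmetric-MY"`, `"polarized"` (steady within `steady_tol`),
#' `"collapse-event"`, or `"transient"` if no steady state was reached.
#'
#' @param state0 a `"lam_fragment_state"` (initial `y` and `yhat` are each
#'   taken as `Y/2`; lateral positions start at 0).
#' @param params a `"lam_params"` object.
#' @param sfm a `"lam_sfm"` force closure.
#' @param t_end final time (min).
#' @param dt_max maximal output interval (min).
#' @param rtol,atol solver tolerances.
#' @param steady_tol max |rhs| of the core system below which the terminal
#'   state counts as steady.
#' @return A list of class `"lam_fragment_run"` with `trajectory` (data frame
#'   `t, Y, omega, omega_hat, y, yhat, x, xhat, speed`), `outcome`,
#'   `terminal` (fragment state), `terminal_speed`, and `collapsed`.
#' @export
integrate_fragment <- function(state0, params, sfm, t_end, dt_max = 0.25,
                               rtol = 1e-10, atol = 1e-12, steady_tol = 1e-8) {
  stopifnot(inherits(params, "lam_params"), inherits(sfm, "lam_sfm"), t_end > 0)
  p <- params
  deriv <- function(t, y, parms) {
    st <- list(Y = y[1], omega = y[2], omega_hat = y[3])
    core <- fragment_rhs(st, p, sfm)
    f <- fragment_forces(p, sfm, y[1])
    ydot <- -(f$f_mem + f$f_stress) / (p$mu_A * p$L) + p$v * sin(y[2])
    xr <- planar_rhs(list(x = 0, y = 0, omega = y[2]), p,
                     f_mem = f$f_mem, f_stress = f$f_stress)[["x_dot"]]
    xhr <- planar_rhs(list(x = 0, y = 0, omega = y[3]), p,
                      f_mem = f$f_mem, f_stress = f$f_stress)[["x_dot"]]
    list(c(unname(core), ydot, xr, xhr))
  }
  rootfun <- function(t, y, parms) min(y[2], y[3]) - p$omega_floor
  times <- seq(0, t_end, by = min(dt_max, t_end))
  y0 <- c(Y = state0$Y, omega = state0$omega, omega_hat = state0$omega_hat,
          yfront = state0$Y / 2, x = 0, xhat = 0)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      rootfunc = rootfun)
  sol <- as.data.frame(sol)
  names(sol) <- c("t", "Y", "omega", "omega_hat", "y", "x", "xhat")
  sol$yhat <- sol$Y - sol$y
  sol$speed <- fragment_speed(sol$omega, sol$omega_hat, p$v)
  collapsed <- max(sol$t) < t_end - 1e-9

  term <- sol[nrow(sol), ]
  terminal <- list(Y = term$Y, omega = term$omega, omega_hat = term$omega_hat)
  res <- max(abs(fragment_rhs(terminal, p, sfm)))
  hz <- h_zeros(p)
  quad <- hz$omega[hz$branch == "quadratic"]
  w20 <- if (length(quad) == 2) max(quad) else -Inf
  side <- function(w) if (w > w20) "CL" else "MY"
  outcome <- if (collapsed) {
    "collapse-event"
  } else if (res > steady_tol) {
    "transient"
  } else if (side(term$omega) == side(term$omega_hat)) {
    paste0("symmetric-", side(term$omega))
  } else {
    "polarized"
  }
  structure(list(trajectory = sol[, c("t", "Y", "omega", "omega_hat",
                                      "y", "yhat", "x", "xhat", "speed")],
                 outcome = outcome,
                 terminal = terminal,
                 terminal_speed = fragment_speed(term$omega, term$omega_hat, p$v),
                 residual = res,
                 collapsed = collapsed),
            class = "lam_fragment_run")
}
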