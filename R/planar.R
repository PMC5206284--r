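#' Planar lamellipodium state
#'
#' State of a single translationally invariant strip of lamellipodium: the
#' lateral reference position `x` of the plus family, the leading-edge-normal
#' position `y`, and the common filament angle `omega` to the x-axis. The
#' crossing angle between the families is `phi = pi - 2*omega` and is derived,
#' never stored. `omega = pi/2` means parallel filaments (no crossings);
#' small `omega` a collapsed, nearly antiparallel network.
#'
#' @param x lateral position (um).
#' @param y leading-edge-normal position (um).
#' @param omega filament angle (rad), in (0, pi/2].
#' @return A list of class `"lam_planar_state"`.
#' @export
planar_state <- function(x = 0, y = 0, omega) {
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (omega <= 0 || omega > pi / 2) {
    stop("omega must lie in (0, pi/2]; omega = 0 is the fully collapsed degenerate state")
  }
  structure(list(x = x, y = y, omega = omega), class = "lam_planar_state")
}

#' Net turning-torque density of the angle equation
#'
#' The angle dynamics of the planar lamellipodium are driven (up to positive
#' factors) by
#' \deqn{h(\omega) = \mu^T(\pi - 2\omega - \varphi_0)
#'   - 2\omega\,\overline{\mu^{TM}}(\pi - 2\omega - \bar\varphi)_+ ,}
#' the balance between the cross-link torque (restoring the crossing angle
#' towards `phi0`) and the myosin torque (driving it towards pi once above the
#' cutoff). `h` is continuous and piecewise smooth with a kink at the cutoff
#' angle `omega = (pi - phi_bar)/2`.
#'
#' @param omega filament angle(s) (rad); vectorized.
#' @param params a `"lam_params"` object.
#' @return Torque density values (pN um).
#' @export
h_torque <- function(omega, params) {
  stopifnot(inherits(params, "lam_params"))
  phi <- pi - 2 * omega
  params$mu_T * (phi - params$phi0) -
    2 * omega * params$mu_TM_bar * pmax(phi - params$phi_bar, 0)
}

# derivative of h on the smooth branch containing omega; at the kink the
# linear (above-cutoff) branch is used
h_torque_prime <- function(omega, params) {
  phi <- pi - 2 * omega
  ifelse(phi > params$phi_bar,
         8 * params$mu_TM_bar * omega -
           2 * params$mu_T - 2 * params$mu_TM_bar * (pi - params$phi_bar),
         -2 * params$mu_T)
}

#' Effective rotational drag of the angle equation
#'
#' \deqn{g(\omega) = \frac{L^2}{24}\left[\mu^A + 4\sin^2\omega\cos\omega\,
#'   (\mu^S + \mu^{SM}(\pi-2\omega))\right],}
#' the strictly positive drag coefficient dividing the angle dynamics:
#' substrate friction plus inter-family friction from cross-links and (above
#' the cutoff) myosin, weighted by the crossing density `2 cos(omega)`.
#'
#' @inheritParams h_torque
#' @return Drag values (pN min um).
#' @export
g_drag <- function(omega, params) {
  stopifnot(inherits(params, "lam_params"))
  mu_SM <- cutoff_stiffness(params, pi - 2 * omega)$mu_SM
  params$L^2 / 24 *
    (params$mu_A + 4 * sin(omega)^2 * cos(omega) * (params$mu_S + mu_SM))
}

g_drag_prime <- function(omega, params) {
  phi <- pi - 2 * omega
  mu_SM <- params$mu_SM_bar * pmax(phi - params$phi_bar, 0)
  dmu_SM <- ifelse(phi > params$phi_bar, -2 * params$mu_SM_bar, 0)
  params$L^2 / 24 * 4 *
    ((2 * sin(omega) * cos(omega)^2 - sin(omega)^3) * (params$mu_S + mu_SM) +
       sin(omega)^2 * cos(omega) * dmu_SM)
}

#' Right-hand side of the planar lamellipodium ODE system
#'
#' Time derivatives of `(x, y, omega)` for a single planar lamellipodium with
#' membrane force `f_mem` on the barbed ends and stress-fibre force `f_stress`
#' on the pointed ends, both normal to the leading edge. The friction brackets
#' multiplying each derivative are strictly positive, so the system is solved
#' explicitly. With these forces the angle equation decouples and equals
#' `cos(omega) * (delta_f/4 + h(omega)) / g(omega)` with
#' `delta_f = f_stress - f_mem` (see [h_torque()], [g_drag()]).
#'
#' @param state a `"lam_planar_state"` (or a list with `x`, `y`, `omega`).
#' @param params a `"lam_params"` object.
#' @param f_mem,f_stress optional force overrides (pN um^-1); default from
#'   `params`.
#' @return Named numeric vector `c(x_dot, y_dot, omega_dot)` in (um min^-1,
#'   um min^-1, rad min^-1).
#' @export
planar_rhs <- function(state, params, f_mem = params$f_mem,
                       f_stress = params$f_stress) {
  stopifnot(inherits(params, "lam_params"))
  w <- unname(state$omega)
  f_mem <- unname(f_mem)
  f_stress <- unname(f_stress)
  p <- params
  mu_SM <- cutoff_stiffness(p, pi - 2 * w)$mu_SM
  cw <- cos(w)

  x_dot <- (p$mu_A * p$v * cw + 4 * p$mu_S * p$v * cw^2 +
              4 * mu_SM * (p$v - p$v_M) * cw^2) /
    (p$mu_A + 4 * (p$mu_S + mu_SM) * cw)

  y_dot <- -(f_mem + f_stress) / (p$mu_A * p$L) + p$v * sin(w)

  bracket <- p$mu_A + 4 * sin(w)^2 * cw * (p$mu_S + mu_SM)
  omega_dot <- (6 / p$L^2 * cw * (f_stress - f_mem) +
                  24 / p$L^2 * p$mu_T * (pi - 2 * w - p$phi0) * cw -
                  48 / p$L^2 * p$mu_TM_bar * pmax(pi - 2 * w - p$phi_bar, 0) *
                    w * cw) / bracket

  c(x_dot = x_dot, y_dot = y_dot, omega_dot = omega_dot)
}

#' Zeroes of the turning-torque balance
#'
#' Finds all roots of [h_torque()] in `(0, pi/2)` exactly, branch by branch:
#' the above-cutoff branch is linear with root `(pi - phi0)/2` (present
#' whenever `phi0 < phi_bar`, i.e. always under the parameter invariants), and
#' the below-cutoff branch is the quadratic
#' \deqn{4\overline{\mu^{TM}}\omega^2 -
#'   (2\mu^T + 2\overline{\mu^{TM}}(\pi-\bar\varphi))\omega +
#'   \mu^T(\pi-\varphi_0) = 0,}
#' solved in closed form. When the myosin-dominance condition of
#' [bistability_condition()] holds there are exactly three simple zeroes
#' `omega_10 > omega_20 > omega_30`, with `omega_10 = (pi - phi0)/2` above the
#' cutoff angle and the pair `omega_20 > omega_30` below it; when it fails
#' only `omega_10` remains.
#'
#' @param params a `"lam_params"` object.
#' @return A data frame sorted by decreasing `omega` with columns `omega`
#'   (rad), `branch` (`"linear"` or `"quadratic"`), `dh` (the branch
#'   derivative of h at the root, pN um) and `simple` (logical, `|dh|` above
#'   tolerance).
#' @export
h_zeros <- function(params) {
  stopifnot(inherits(params, "lam_params"))
  p <- params
  hinge <- (pi - p$phi_bar) / 2
  roots <- data.frame(omega = numeric(0), branch = character(0))

  w10 <- (pi - p$phi0) / 2
  if (w10 > hinge && w10 < pi / 2) {
    roots <- rbind(roots, data.frame(omega = w10, branch = "linear"))
  }

  if (p$mu_TM_bar > 0) {
    a <- 4 * p$mu_TM_bar
    b <- -(2 * p$mu_T + 2 * p$mu_TM_bar * (pi - p$phi_bar))
    cc <- p$mu_T * (pi - p$phi0)
    disc <- b^2 - 4 * a * cc
    if (disc > 0) {
      # numerically stable quadratic roots
      q <- -(b - sqrt(disc)) / 2   # b < 0 here
      cand <- c(q / a, cc / q)
      cand <- cand[cand > 0 & cand < hinge]
      if (length(cand)) {
        roots <- rbind(roots, data.frame(omega = cand, branch = "quadratic"))
      }
    } else if (disc == 0) {
      cand <- -b / (2 * a)
      if (cand > 0 && cand < hinge) {
        roots <- rbind(roots, data.frame(omega = cand, branch = "quadratic"))
      }
    }
  }

  roots <- roots[order(-roots$omega), , drop = FALSE]
  rownames(roots) <- NULL
  roots$dh <- h_torque_prime(roots$omega, params)
  residual <- abs(h_torque(roots$omega, params))
  if (any(residual > 1e-12)) {
    stop("internal error: closed-form root fails to annihilate h (residual ",
         max(residual), ")")
  }
  roots$simple <- abs(roots$dh) > 1e-10
  roots
}

#' Stationary angles of the single planar lamellipodium
#'
#' For constant forces the angle equation decouples; its equilibria are
#' `omega = pi/2` (parallel filaments, no crossings) together with the roots
#' of `delta_f/4 + h(omega) = 0`, `delta_f = f_stress - f_mem`, again found in
#' closed form per branch. For `delta_f` small (within [delta_f_bound()])
#' there are exactly four equilibria with the stability pattern unstable /
#' stable / unstable / stable in decreasing order of angle: the
#' cross-link-dominated stable state
#' `omega_1 = (pi - phi0)/2 + delta_f/(8 mu_T)` (exact, the above-cutoff
#' branch being linear) and the myosin-influenced stable state `omega_3`,
#' separated by the unstable `omega_2`. Stability is judged by the sign of the
#' numerical derivative of the full right-hand side of [planar_rhs()]
#' (equivalent to the sign of the branch derivative of h for simple roots,
#' since drag and `cos` are positive on the open interval).
#'
#' @param params a `"lam_params"` object.
#' @param f_mem,f_stress optional force overrides (pN um^-1).
#' @return A data frame sorted by decreasing angle with columns `index`
#'   (0..3 when four equilibria exist), `omega`, `classification`
#'   (`"parallel-degenerate"`, `"crosslink"`, `"separatrix"`, `"myosin"`),
#'   `stable`, `dRHS_domega` (min^-1), `y_dot`, `x_dot` (um min^-1).
#' @export
planar_steady_states <- function(params, f_mem = params$f_mem,
                                 f_stress = params$f_stress) {
  stopifnot(inherits(params, "lam_params"))
  p <- params
  df <- f_stress - f_mem
  hinge <- (pi - p$phi_bar) / 2
  omegas <- pi / 2
  branch <- "boundary"

  w1 <- (pi - p$phi0) / 2 + df / (8 * p$mu_T)
  if (w1 > hinge && w1 < pi / 2) {
    omegas <- c(omegas, w1)
    branch <- c(branch, "linear")
  }

  if (p$mu_TM_bar > 0) {
    a <- 4 * p$mu_TM_bar
    b <- -(2 * p$mu_T + 2 * p$mu_TM_bar * (pi - p$phi_bar))
    cc <- p$mu_T * (pi - p$phi0) + df / 4
    disc <- b^2 - 4 * a * cc
    if (disc > 0) {
      q <- -(b - sqrt(disc)) / 2
      cand <- unique(c(q / a, cc / q))
      cand <- cand[cand > 0 & cand < hinge]
      omegas <- c(omegas, cand)
      branch <- c(branch, rep("quadratic", length(cand)))
    }
  }

  ord <- order(-omegas)
  omegas <- omegas[ord]
  branch <- branch[ord]
  n <- length(omegas)
  if (n != 4) {
    warning("expected 4 stationary angles, found ", n,
            " (force difference too large or myosin-dominance condition violated)")
  }

  drhs <- vapply(omegas, function(w) {
    d <- 1e-7
    wm <- max(w - d, p$omega_floor)
    wp <- min(w + d, pi / 2)
    rp <- planar_rhs(list(x = 0, y = 0, omega = wp), p, f_mem, f_stress)[["omega_dot"]]
    rm <- planar_rhs(list(x = 0, y = 0, omega = wm), p, f_mem, f_stress)[["omega_dot"]]
    (rp - rm) / (wp - wm)
  }, numeric(1))

  classification <- if (n == 4) {
    c("parallel-degenerate", "crosslink", "separatrix", "myosin")
  } else {
    cls <- rep("other", n)
    cls[branch == "boundary"] <- "parallel-degenerate"
    cls[branch == "linear"] <- "crosslink"
    cls
  }

  speeds <- t(vapply(omegas, steady_speeds, numeric(2),
                     params = p, f_mem = f_mem, f_stress = f_stress))
  data.frame(index = seq_len(n) - 1L,
             omega = omegas,
             classification = classification,
             stable = drhs < 0,
             dRHS_domega = drhs,
             y_dot = speeds[, 1],
             x_dot = speeds[, 2])
}

#' Steady protrusion and lateral-flow speeds
#'
#' At a stationary angle `omega*` the strip protrudes at
#' \deqn{\dot y = v\sin\omega_* - (f_{stress}+f_{mem})/(\mu^A L)}
#' and the filament families drift laterally at
#' \deqn{\dot x = \Bigl(v - v^M\frac{4\mu^{SM}\cos\omega_*}{\mu^A +
#'   4(\mu^S+\mu^{SM})\cos\omega_*}\Bigr)\cos\omega_* ,}
#' with `mu_SM` from the cutoff law at `phi = pi - 2 omega*`. Above the cutoff
#' branch the myosin correction vanishes and the lateral flow is the pure
#' polymerization drift `v cos(omega*)`; in the collapsed state actin-myosin
#' interaction reduces it.
#'
#' @param omega_star stationary angle (rad).
#' @param params a `"lam_params"` object.
#' @param f_mem,f_stress optional force overrides (pN um^-1).
#' @return Named numeric vector `c(y_dot, x_dot)` (um min^-1).
#' @export
steady_speeds <- function(omega_star, params, f_mem = params$f_mem,
                          f_stress = params$f_stress) {
  stopifnot(inherits(params, "lam_params"))
  p <- params
  mu_SM <- cutoff_stiffness(p, pi - 2 * omega_star)$mu_SM
  cw <- cos(omega_star)
  y_dot <- p$v * sin(omega_star) - (f_stress + f_mem) / (p$mu_A * p$L)
  x_dot <- (p$v - p$v_M * 4 * mu_SM * cw /
              (p$mu_A + 4 * (p$mu_S + mu_SM) * cw)) * cw
  c(y_dot = y_dot, x_dot = x_dot)
}

#' Largest force difference preserving four stationary angles
#'
#' The four-equilibrium structure of [planar_steady_states()] persists only
#' for `delta_f = f_stress - f_mem` in a window around zero: a large positive
#' difference merges the myosin pair, a large negative one pushes the
#' cross-link root into the cutoff kink. The window bounds are located by
#' bisection on the equilibrium count and reported so that callers know what
#' "small enough" means for their parameter set.
#'
#' @param params a `"lam_params"` object.
#' @param tol bisection tolerance on `delta_f` (pN um^-1).
#' @return Named numeric vector `c(lower, upper)`: the widest open interval of
#'   `delta_f` on which four equilibria were found.
#' @export
delta_f_bound <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "lam_params"))
  count4 <- function(df) {
    ss <- suppressWarnings(planar_steady_states(params, f_mem = 0, f_stress = df))
    nrow(ss) == 4
  }
  if (!count4(0)) stop("parameter set has fewer than four equilibria at delta_f = 0")
  bisect_edge <- function(sign) {
    lo <- 0
    hi <- sign * 1e-4
    while (count4(hi) && abs(hi) < 1e6) {
      lo <- hi
      hi <- 2 * hi
    }
    if (abs(hi) >= 1e6) return(sign * Inf)
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      if (count4(mid)) lo <- mid else hi <- mid
    }
    lo
  }
  c(lower = bisect_edge(-1), upper = bisect_edge(1))
}

#' Integrate the planar lamellipodium ODE system
#'
#' Adaptive-step time integration of [planar_rhs()] (via [deSolve::ode()],
#' `lsoda`). Integration stops early with a collapse event if the angle
#' reaches the configured floor `params$omega_floor`, since the continuum
#' model cannot represent a fully collapsed network.
#'
#' @param state0 initial `"lam_planar_state"`.
#' @param params a `"lam_params"` object.
#' @param t_end final time (min).
#' @param dt_max maximal output/step interval (min).
#' @param rtol,atol solver tolerances.
#' @return A data frame of class `"lam_trajectory"` with columns `t`, `x`,
#'   `y`, `omega`, `phi`, `y_dot`, `x_dot`, `myosin_active`, and attributes
#'   `collapsed` (logical) and `params`.
#' @export
integrate_planar <- function(state0, params, t_end, dt_max = 0.05,
                             rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "lam_params"), t_end > 0)
  p <- params
  deriv <- function(t, y, parms) {
    r <- planar_rhs(list(x = y[1], y = y[2], omega = y[3]), p)
    list(unname(r))
  }
  rootfun <- function(t, y, parms) y[3] - p$omega_floor
  times <- seq(0, t_end, by = min(dt_max, t_end))
  sol <- deSolve::ode(y = c(x = state0$x, y = state0$y, omega = state0$omega),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      rootfunc = rootfun)
  sol <- as.data.frame(sol)
  names(sol) <- c("t", "x", "y", "omega")
  rates <- t(apply(sol, 1, function(r) {
    planar_rhs(list(x = r[["x"]], y = r[["y"]], omega = r[["omega"]]), p)
  }))
  sol$phi <- pi - 2 * sol$omega
  sol$y_dot <- rates[, "y_dot"]
  sol$x_dot <- rates[, "x_dot"]
  sol$myosin_active <- sol$phi > p$phi_bar
  attr(sol, "collapsed") <- max(sol$t) < t_end - 1e-9
  attr(sol, "params") <- p
  class(sol) <- c("lam_trajectory", "data.frame")
  sol
}

#' Write a trajectory to CSV
#'
#' @param traj a `"lam_trajectory"` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
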