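#' Coordinate change between the two filament families
#'
#' Under the planar two-family ansatz a crossing between a plus-family
#' filament (label `alpha_plus`, arclength `s_plus`) and a minus-family
#' filament occurs at
#' \deqn{\alpha^- = \alpha^+ + 2x + (2s^+ + L)\cos\omega, \qquad s^- = s^+ .}
#' The map is affine and bijective in `(alpha, s)` for `omega < pi/2`; its
#' Jacobian factor `|d alpha^- / d s^+| = 2 cos(omega)` measures the density
#' of crossings, maximal at `omega = 0` (collapsed network) and vanishing at
#' `omega = pi/2` (parallel filaments, no crossings — a degenerate geometry
#' for which a warning is raised).
#'
#' @param alpha_plus plus-family filament label (um); vectorized.
#' @param s_plus arclength position on the plus filament (um), in `[-L, 0]`.
#' @param state a `"lam_planar_state"` (only `x` and `omega` are used).
#' @param params a `"lam_params"` object (supplies `L`).
#' @return A list with `alpha_minus`, `s_minus`, `jacobian_factor`
#'   (`2 cos(omega)`), and the crossing angle `phi = pi - 2*omega`.
#' @export
planar_coordinate_change <- function(alpha_plus, s_plus, state, params) {
  stopifnot(inherits(params, "lam_params"))
  if (any(s_plus < -params$L - 1e-12 | s_plus > 1e-12)) {
    stop("s_plus must lie in [-L, 0]")
  }
  w <- state$omega
  if (abs(w - pi / 2) < 1e-12) {
    warning("omega = pi/2: families are parallel, no crossings (degenerate map)")
  }
  list(alpha_minus = alpha_plus + 2 * state$x + (2 * s_plus + params$L) * cos(w),
       s_minus = s_plus,
       jacobian_factor = 2 * cos(w),
       phi = pi - 2 * w)
}

#' Rigid-filament force/torque balance by quadrature
#'
#' Independent oracle for [planar_rhs()]: instead of the closed-form planar
#' reduction, this routine substitutes the rigid-filament ansatz
#' `F = F0 + (s + L/2) d(omega)` of both families directly into the integral
#' force balance (substrate friction, cross-link friction, myosin friction
#' with walking speed `v_M`) and the integral torque balance (lever-arm
#' moments of the same force densities plus the cross-link and myosin twist
#' torques), evaluates the arclength integrals by Gauss-Legendre quadrature,
#' and solves the resulting linear system for `(x_dot, y_dot, omega_dot)`.
#' Because the residual is affine in the velocities, the matrix is assembled
#' from residual evaluations at unit velocity vectors.
#'
#' The integrands are polynomials of degree at most two in `s`, so any
#' `n_nodes >= 3` gives exact integrals and results independent of
#' `n_nodes`. The twist torque signs are fixed, per family, by the physical
#' requirement that the cross-link torque drives the crossing angle towards
#' its equilibrium value `phi0` (validated by the sign of `omega_dot` on
#' either side of the cross-link equilibrium angle).
#'
#' @param state a `"lam_planar_state"`.
#' @param params a `"lam_params"` object.
#' @param forces optional list with 2-vectors `f0` (barbed-end force density)
#'   and `fL` (pointed-end force density), pN um^-1; defaults to the normal
#'   membrane/stress-fibre forces `(0, -f_mem)` and `(0, -f_stress)` from
#'   `params`.
#' @param n_nodes number of quadrature nodes (>= 3).
#' @return Named numeric vector `c(x_dot, y_dot, omega_dot)`.
#' @export
rhs_by_quadrature <- function(state, params, forces = NULL, n_nodes = 5) {
  stopifnot(inherits(params, "lam_params"), n_nodes >= 3)
  p <- params
  w <- state$omega
  if (is.null(forces)) {
    forces <- list(f0 = c(0, -p$f_mem), fL = c(0, -p$f_stress))
  }
  L <- p$L
  quad <- pracma::gaussLegendre(n_nodes, -L, 0)
  s <- quad$x
  wt <- quad$w

  dplus <- c(cos(w), sin(w))          # tangent of the + family
  dminus <- c(-cos(w), sin(w))        # tangent of the - family (angle pi - omega)
  dperp <- c(-sin(w), cos(w))
  phi <- pi - 2 * w
  jac <- 2 * cos(w)                   # |d alpha* / d s|, crossing density
  ms <- cutoff_stiffness(p, phi)
  mu_hat_S <- p$mu_S * jac
  mu_hat_SM <- ms$mu_SM * jac
  mu_hat_T <- p$mu_T * jac
  mu_hat_TM <- ms$mu_TM * jac

  # residual of (force balance x, force balance y, torque balance) at
  # velocities u = (x_dot, y_dot, omega_dot); affine in u
  residual <- function(u) {
    xd <- u[1]; yd <- u[2]; wd <- u[3]
    fx <- 0; fy <- 0; trq <- 0
    for (k in seq_along(s)) {
      r <- s[k] + L / 2
      # material velocities D_t F = dF/dt - v dF/ds of the binding site
      DtFp <- c(xd - r * wd * sin(w), yd + r * wd * cos(w)) - p$v * dplus
      DtFm <- c(-xd + r * wd * sin(w), yd + r * wd * cos(w)) - p$v * dminus
      rel <- DtFp - DtFm
      relM <- rel + p$v_M * (dplus - dminus)
      dens <- p$mu_A * DtFp + mu_hat_S * rel + mu_hat_SM * relM
      fx <- fx + wt[k] * dens[1]
      fy <- fy + wt[k] * dens[2]
      # lever-arm moment of the friction force density
      trq <- trq + wt[k] * r * sum(dperp * dens)
    }
    # twist torques: constant in s under the ansatz
    twist <- -mu_hat_T * (phi - p$phi0) * L - mu_hat_TM * (phi - pi) * L
    lhs_torque <- (L / 2) * sum(dperp * forces$f0) -
      (L / 2) * sum(dperp * forces$fL)
    c(forces$f0[1] + forces$fL[1] - fx,
      forces$f0[2] + forces$fL[2] - fy,
      lhs_torque - twist - trq)
  }

  r0 <- residual(c(0, 0, 0))
  A <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- 1
    A[, j] <- residual(e) - r0
  }
  if (abs(det(A)) < 1e-14) stop("singular force-balance system (degenerate geometry)")
  u <- solve(A, -r0)
  c(x_dot = u[1], y_dot = u[2], omega_dot = u[3])
}
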