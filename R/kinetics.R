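#' Transient actin-myosin linker kinetics
#'
#' Describes the age-structured population of myosin connections between
#' crossing filament pairs in the fast-turnover limit: connections are created
#' at rate `beta` (per unconnected crossing) and break at rate `zeta`, both of
#' which may depend on the crossing angle `phi`. The elastic constants
#' `kappa_SM` (stretching) and `kappa_TM` (twisting) of an individual myosin
#' filament convert the surviving population into effective macroscopic
#' stiffnesses, see [effective_stiffness()].
#'
#' The breakage rate may in general depend on the stretch of the connection;
#' in the fast-turnover limit connections never accumulate stretch, so only
#' the zero-stretch rate `zeta(phi)` enters.
#'
#' @param beta creation rate (min^-1): a nonnegative constant or a function of
#'   the crossing angle `phi` (rad).
#' @param zeta breakage rate at zero stretch (min^-1): a positive constant or
#'   a function of `phi`.
#' @param kappa_SM myosin stretching elasticity (pN um^-1).
#' @param kappa_TM myosin twisting elasticity (pN um).
#' @return A list of class `"lam_kinetics"` with `beta` and `zeta` normalized
#'   to vectorized functions of `phi`.
#' @export
linker_kinetics <- function(beta, zeta, kappa_SM = 1, kappa_TM = 1) {
  as_rate <- function(r, name) {
    if (is.function(r)) return(r)
    if (is.numeric(r) && length(r) == 1L && is.finite(r)) {
      force(r)
      return(function(phi) rep_len(r, length(phi)))
    }
    stop(name, " must be a numeric scalar or a function of phi")
  }
  stopifnot(is.numeric(kappa_SM), kappa_SM >= 0, is.numeric(kappa_TM), kappa_TM >= 0)
  structure(list(beta = as_rate(beta, "beta"), zeta = as_rate(zeta, "zeta"),
                 kappa_SM = kappa_SM, kappa_TM = kappa_TM),
            class = "lam_kinetics")
}

#' Limiting age density of myosin connections
#'
#' In the fast-turnover limit (linker lifetime short against the monomer
#' residence time) the age distribution of connections at a crossing with
#' angle `phi` equilibrates to
#' \deqn{\rho_0^M(a) = \frac{\beta\,\zeta}{\beta+\zeta}\, e^{-\zeta a},}
#' with `beta = beta(phi)` and `zeta = zeta(phi)` evaluated at zero stretch.
#' Its integral over all ages, `beta / (beta + zeta)`, is the occupancy
#' probability of the crossing and is always below one. A possible initial
#' time layer is ignored, consistent with the limit.
#'
#' @param kin a `"lam_kinetics"` object.
#' @param phi crossing angle (rad), scalar.
#' @param a connection age (min), vector of nonnegative values.
#' @return Density values, same length as `a`.
#' @export
age_density <- function(kin, phi, a) {
  stopifnot(inherits(kin, "lam_kinetics"))
  if (any(a < 0)) stop("age a must be nonnegative")
  b <- kin$beta(phi)
  z <- kin$zeta(phi)
  if (any(b < 0)) stop("beta(phi) must be nonnegative")
  if (any(z <= 0)) stop("zeta(phi) must be positive (immortal linkers are unphysical)")
  b * z / (b + z) * exp(-z * a)
}

#' Effective myosin stiffness coefficients from linker kinetics
#'
#' Integrating the stretching and twisting energies of individual connections
#' against the limiting age density yields angle-dependent macroscopic
#' stiffnesses
#' \deqn{\mu^{SM}(\varphi) = \frac{\beta\,\kappa^{SM}}{\zeta(\beta+\zeta)},
#'   \qquad \mu^{TM}(\varphi) = \frac{\beta\,\kappa^{TM}}{\beta+\zeta}.}
#' Both vanish when no connections are created (`beta(phi) = 0`); the
#' stretching coefficient carries an extra `1/zeta` because stretch is
#' accumulated over the connection lifetime, while twist is set at creation.
#'
#' @inheritParams age_density
#' @return Named numeric vector `c(mu_SM = , mu_TM = )` in (pN min um^-1,
#'   pN um).
#' @export
effective_stiffness <- function(kin, phi) {
  stopifnot(inherits(kin, "lam_kinetics"))
  b <- kin$beta(phi)
  z <- kin$zeta(phi)
  if (any(z <= 0)) stop("zeta(phi) must be positive (immortal linkers are unphysical)")
  c(mu_SM = b * kin$kappa_SM / (z * (b + z)),
    mu_TM = b * kin$kappa_TM / (b + z))
}

#' Cutoff model for the effective myosin stiffnesses
#'
#' Working model used by all reduced-model analyses: myosin engages only on
#' filament pairs crossing at an angle above the cutoff `phi_bar`, and the
#' effective stiffnesses grow linearly in the excess angle,
#' \deqn{\mu^{SM}(\varphi) = \overline{\mu^{SM}}\,(\varphi-\bar\varphi)_+,
#'   \qquad \mu^{TM}(\varphi) = \overline{\mu^{TM}}\,(\varphi-\bar\varphi)_+.}
#' Both are continuous, piecewise linear, zero on `[0, phi_bar]`, monotone
#' nondecreasing, and Lipschitz with constants `mu_SM_bar` / `mu_TM_bar`.
#'
#' @param params a `"lam_params"` object.
#' @param phi crossing angle(s) (rad) in `[0, pi]`; vectorized.
#' @return A list with numeric vectors `mu_SM` (pN min um^-1) and `mu_TM`
#'   (pN um).
#' @export
cutoff_stiffness <- function(params, phi) {
  stopifnot(inherits(params, "lam_params"))
  if (any(phi < 0 | phi > pi)) stop("phi must lie in [0, pi]")
  excess <- pmax(phi - params$phi_bar, 0)
  list(mu_SM = params$mu_SM_bar * excess,
       mu_TM = params$mu_TM_bar * excess)
}
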