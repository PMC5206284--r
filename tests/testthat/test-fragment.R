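test_that("stress-fibre closures: values, slopes, smoothed hinge is C1", {
  sfm <- stress_fibre_model("linear", "stress", kappa = 0.1, Y0 = 20)
  expect_equal(sf_force(sfm, c(19, 20, 22)), c(-0.1, 0, 0.2))
  expect_equal(sf_slope(sfm, 21), 0.1)
  hin <- stress_fibre_model("hinge", "stress", kappa = 0.1, Y0 = 20,
                            width = 0.2)
  expect_equal(sf_force(hin, 19), 0)
  expect_equal(sf_force(hin, 25), 0.1 * (5 - 0.1), tolerance = 1e-14)
  # smooth transition: value and slope continuous at both joints
  eps <- 1e-9
  expect_equal(sf_force(hin, 20 + eps), sf_force(hin, 20 - eps),
               tolerance = 1e-12)
  expect_equal(sf_slope(hin, 20 + eps), 0, tolerance = 1e-8)
  expect_equal(sf_slope(hin, 20.2 - eps), 0.1, tolerance = 1e-8)
  exact <- stress_fibre_model("hinge", "stress", kappa = 0.1, Y0 = 20,
                              width = 0)
  expect_equal(sf_force(exact, 21), 0.1)
})

test_that("fragment dynamics are symmetric under exchange of the two angles", {
  fd <- frag_setup()
  r <- fragment_rhs(list(Y = 19.6, omega = 0.9, omega_hat = 0.3),
                    fd$params, fd$sfm)
  rs <- fragment_rhs(list(Y = 19.6, omega = 0.3, omega_hat = 0.9),
                     fd$params, fd$sfm)
  expect_equal(r[["Y_dot"]], rs[["Y_dot"]])
  expect_equal(r[["omega_dot"]], rs[["omega_hat_dot"]])
  expect_equal(r[["omega_hat_dot"]], rs[["omega_dot"]])
  # equal angles at the parallel limit: both angle derivatives vanish
  r2 <- fragment_rhs(list(Y = 19.6, omega = pi / 2, omega_hat = pi / 2),
                     fd$params, fd$sfm)
  expect_equal(r2[["omega_dot"]], 0)
  expect_equal(r2[["omega_hat_dot"]], 0)
})

test_that("stationary size inverts the force balance", {
  p <- table1_params(mu_A = 1e-4, f_mem = 0)
  sfm <- stress_fibre_model("linear", "stress", kappa = 0.05, Y0 = 20)
  w <- 0.9
  Y <- stationary_size(w, w, p, sfm)
  expect_equal(Y, 20 + p$mu_A * p$L * p$v * sin(w) / 0.05, tolerance = 1e-9)
  # stiff size control pins the size to the reference
  stiff <- stress_fibre_model("linear", "stress", kappa = 50, Y0 = 20)
  expect_equal(stationary_size(w, w, p, stiff), 20, tolerance = 1e-3)
  # at the stationary size the full rhs vanishes when both angles balance h
  fd <- frag_setup()
  ss <- suppressMessages(fragment_steady_states(fd$params, fd$sfm,
                                                include_unstable = FALSE))
  for (i in seq_len(nrow(ss))) {
    r <- fragment_rhs(list(Y = ss$Y[i], omega = ss$omega[i],
                           omega_hat = ss$omega_hat[i]), fd$params, fd$sfm)
    expect_lt(max(abs(r)), 1e-10)
  }
  # inconsistent forces: requested force below the closure's range
  neg <- table1_params(mu_A = 1e-4, f_mem = 1)  # requires negative f_stress
  expect_error(stationary_size(0.9, 0.9, neg,
                               stress_fibre_model("hinge", "stress",
                                                  kappa = 0.05, Y0 = 20)),
               "no stationary size")
})

test_that("four stable steady states with the expected labels and speeds", {
  fd <- frag_setup()
  ss <- suppressMessages(fragment_steady_states(fd$params, fd$sfm))
  stable <- ss[ss$stable, ]
  expect_equal(nrow(stable), 4)
  expect_setequal(stable$label,
                  c("symmetric-CL", "symmetric-MY",
                    "polarized-front-CL", "polarized-front-MY"))
  expect_true(all(stable$max_re_lambda < 0))
  # symmetric states are stationary; polarized ones move, antisymmetrically
  sym <- stable[grepl("symmetric", stable$label), ]
  expect_equal(sym$speed, c(0, 0), tolerance = 1e-12)
  pol <- stable[grepl("polarized", stable$label), ]
  expect_equal(sort(pol$speed), sort(-pol$speed), tolerance = 1e-10)
  expect_gt(max(abs(pol$speed)), 0.5)
  expect_true(all(abs(stable$speed) <= fd$params$v))
  # separatrix-involving equilibria are found and unstable
  sep <- ss[ss$label == "separatrix", ]
  expect_gt(nrow(sep), 0)
  expect_true(all(!sep$stable))
  # exchange symmetry maps the steady-state set onto itself with flipped speed
  for (i in seq_len(nrow(stable))) {
    j <- which(abs(stable$omega - stable$omega_hat[i]) < 1e-8 &
                 abs(stable$omega_hat - stable$omega[i]) < 1e-8)
    expect_length(j, 1)
    expect_equal(stable$speed[j], -stable$speed[i], tolerance = 1e-10)
  }
})

test_that("steady-state angles approach the torque zeroes as coupling shrinks", {
  fd <- frag_setup()
  shift <- function(scale) {
    p <- fd$params
    p$mu_A <- fd$params$mu_A * scale
    ss <- suppressMessages(fragment_steady_states(p, fd$sfm,
                                                  include_unstable = FALSE))
    pol <- ss[ss$label == "polarized-front-CL", ]
    c(abs(pol$omega - W10), abs(pol$omega_hat - W30))
  }
  s1 <- shift(1)
  s2 <- shift(0.5)
  s4 <- shift(0.25)
  # first-order perturbation: deviations scale linearly with mu_A v L
  expect_equal(s1 / s2, c(2, 2), tolerance = 0.1)
  expect_equal(s2 / s4, c(2, 2), tolerance = 0.1)
})

test_that("without the myosin branch only the symmetric cross-link state remains", {
  fd <- frag_setup()
  p <- fd$params
  p$mu_TM_bar <- 0
  ss <- suppressMessages(fragment_steady_states(p, fd$sfm))
  expect_equal(sum(ss$stable), 1)
  expect_equal(ss$label[ss$stable], "symmetric-CL")
})

test_that("analytic Jacobian matches central finite differences", {
  fd <- frag_setup()
  states <- list(list(Y = 19.6, omega = 0.9, omega_hat = 0.3),
                 list(Y = 20.1, omega = 1.2, omega_hat = 1.0),
                 list(Y = 19.2, omega = 0.4, omega_hat = 0.25))
  for (st in states) {
    J <- suppressWarnings(fragment_jacobian(st, fd$params, fd$sfm))$jacobian
    Jn <- matrix(0, 3, 3)
    x0 <- c(st$Y, st$omega, st$omega_hat)
    for (j in 1:3) {
      d <- 1e-6 * max(1, abs(x0[j]))
      xp <- x0; xp[j] <- x0[j] + d
      xm <- x0; xm[j] <- x0[j] - d
      rp <- fragment_rhs(list(Y = xp[1], omega = xp[2], omega_hat = xp[3]),
                         fd$params, fd$sfm)
      rm <- fragment_rhs(list(Y = xm[1], omega = xm[2], omega_hat = xm[3]),
                         fd$params, fd$sfm)
      Jn[, j] <- (rp - rm) / (2 * d)
    }
    expect_equal(unname(J), Jn, tolerance = 1e-6)
  }
  # warns off-equilibrium
  expect_warning(fragment_jacobian(states[[1]], fd$params, fd$sfm),
                 "not an equilibrium")
})

test_that("zero force slope decouples the size: one zero eigenvalue", {
  fd <- frag_setup()
  p <- fd$params
  sfm0 <- stress_fibre_model("constant", "stress")
  st <- list(Y = 19.6, omega = W10, omega_hat = W30)
  J <- suppressWarnings(fragment_jacobian(st, p, sfm0))
  ev <- sort(Re(J$eigenvalues), decreasing = TRUE)
  expect_equal(ev[1], 0, tolerance = 1e-14)
  # the two angle eigenvalues are the decoupled single-strip rates
  expect_equal(sort(ev[2:3]),
               sort(c(cos(W10) / g_drag(W10, p) * lamellipod:::h_torque_prime(W10, p),
                      cos(W30) / g_drag(W30, p) * lamellipod:::h_torque_prime(W30, p))),
               tolerance = 1e-8)
})

test_that("slow-mode eigenvalue estimate converges at second order in the slope", {
  fd <- frag_setup()
  p <- fd$params
  errs <- vapply(c(1e-5, 5e-6, 2.5e-6), function(kap) {
    sfm <- stress_fibre_model("linear", "stress", kappa = kap, Y0 = 20)
    ss <- suppressMessages(fragment_steady_states(p, sfm,
                                                  include_unstable = FALSE))
    pol <- ss[ss$label == "polarized-front-CL", ]
    st <- fragment_state(pol$Y, pol$omega, pol$omega_hat)
    est <- slow_eigenvalue_estimate(st, p, sfm)
    expect_lt(est$lambda3, 0)
    # the slow eigenvalue is the one of smallest magnitude
    abs(pol$re_lambda1 - est$lambda3)
  }, numeric(1))
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.25)
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.25)
  # zero slope: slow mode estimate vanishes
  sfm0 <- stress_fibre_model("constant", "stress")
  st <- list(Y = 19.6, omega = W10, omega_hat = W30)
  expect_equal(slow_eigenvalue_estimate(st, p, sfm0)$lambda3, 0)
})

test_that("fragment speed formula: zero, reference value, antisymmetry", {
  expect_equal(fragment_speed(0.7, 0.7, 3), 0)
  expect_equal(fragment_speed(0.9599, 0.1751, 3), 0.9673914042,
               tolerance = 1e-9)
  expect_equal(fragment_speed(0.3, 1.1, 2), -fragment_speed(1.1, 0.3, 2))
  expect_lte(abs(fragment_speed(pi / 2, 1e-6, 3)), 3)
})

test_that("speed rises with adhesion and myosin twist, ignores myosin stretch", {
  fd <- frag_setup()
  sr <- sensitivity_report(fd$params, fd$sfm)
  expect_equal(sr$sign[sr$parameter == "mu_A"], 1L)
  expect_equal(sr$sign[sr$parameter == "mu_TM_bar"], 1L)
  expect_equal(sr$sign[sr$parameter == "mu_SM_bar"], 0L)
  expect_equal(sr$d_omega_CL[sr$parameter == "mu_SM_bar"], 0, tolerance = 1e-8)
})

test_that("symmetric and asymmetric fixtures reach their predicted outcomes", {
  fd <- frag_setup()
  sym <- make_fixture("symmetric", fd$params, fd$sfm)[[1]]
  run_s <- integrate_fragment(sym, fd$params, fd$sfm, t_end = 120)
  expect_equal(run_s$outcome, "symmetric-CL")
  expect_equal(run_s$terminal_speed, 0, tolerance = 1e-8)

  asym <- make_fixture("asymmetric", fd$params, fd$sfm)[[1]]
  run_a <- integrate_fragment(asym, fd$params, fd$sfm, t_end = 120)
  expect_equal(run_a$outcome, "polarized")
  expect_gt(abs(run_a$terminal_speed), 0.5)
  # terminal drift of y - yhat matches twice the speed formula
  tr <- run_a$trajectory
  n <- nrow(tr)
  drift <- ((tr$y[n] - tr$yhat[n]) - (tr$y[n - 1] - tr$yhat[n - 1])) /
    (tr$t[n] - tr$t[n - 1])
  expect_equal(drift, 2 * run_a$terminal_speed, tolerance = 1e-6)
})

test_that("weak myosin: every fixture reverts to the symmetric cross-link state", {
  fd <- frag_setup()
  p <- fd$params
  thr <- bistability_threshold(p$phi0, p$phi_bar)
  p$mu_TM_bar <- 0.95 * thr * p$mu_T
  for (kind in c("symmetric", "asymmetric")) {
    fx <- make_fixture(kind, p, fd$sfm)[[1]]
    run <- integrate_fragment(fx, p, fd$sfm, t_end = 150)
    expect_equal(run$outcome, "symmetric-CL")
  }
})

test_that("size-dependent membrane force gives the same four-state structure", {
  fd <- frag_setup()
  p <- fd$params
  p$f_stress <- 1e-3  # constant pull from stress fibres
  sfm_b <- stress_fibre_model("linear", "membrane", kappa = 0.05, Y0 = 20,
                              f_ref = 0)
  ss <- suppressMessages(fragment_steady_states(p, sfm_b,
                                                include_unstable = FALSE))
  expect_equal(sum(ss$stable), 4)
  expect_setequal(ss$label[ss$stable],
                  c("symmetric-CL", "symmetric-MY",
                    "polarized-front-CL", "polarized-front-MY"))
})

test_that("adhesion bound reports a finite four-state existence edge", {
  fd <- frag_setup()
  bound <- coupling_bound(fd$params, fd$sfm)
  expect_gt(bound, fd$params$mu_A)
  expect_lt(bound, 0.14)  # far below the single-strip reference adhesion
})
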