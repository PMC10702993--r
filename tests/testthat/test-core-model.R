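test_that("SIpInRS derivatives match hand-evaluated flows", {
  p <- ref_params()
  # no infected: only direct immunization moves mass
  expect_equal(unname(sipinrs_derivatives(c(1, 0, 0, 0), p)),
               c(-0.1, 0, 0, 0.1))
  # term-by-term hand evaluation at the reference initial state
  d <- sipinrs_derivatives(c(0.96, 0.02, 0.02, 0), p)
  expect_equal(unname(d), c(-0.11232, 0.00804, 0.00628, 0.098),
               tolerance = 1e-12)
})

test_that("derivative components sum to zero for all three systems", {
  set.seed(11)
  p <- ref_params()
  rp <- reduced_params()
  sp <- sirs_params()
  for (i in 1:25) {
    s4 <- random_state()
    expect_equal(sum(sipinrs_derivatives(s4, p)), 0, tolerance = 1e-12)
    s3 <- random_state()[1:3]
    s3 <- s3 / sum(s3)
    expect_equal(sum(sirs_derivatives(s3, sp)), 0, tolerance = 1e-12)
    s2 <- s4[1:2]
    d2 <- model3_derivatives(s2, rp)
    # reduced system conserves S + I + R with R = 1 - S - I implied:
    # dR = beta*I - eps*(1-S-I) + gamma*S must balance X + Y
    dR <- rp$beta * s2[2] - rp$epsilon * (1 - sum(s2)) + rp$gamma * s2[1]
    expect_equal(sum(d2) + dR, 0, tolerance = 1e-12)
  }
})

test_that("SIRS derivatives match the comparator flow", {
  sp <- sirs_params(alpha = 0.45, beta = 0.06, epsilon = 0.05)
  d <- sirs_derivatives(c(0.96, 0.04, 0), sp)
  expect_equal(d[["I"]], 0.45 * 0.96 * 0.04 - 0.06 * 0.04, tolerance = 1e-14)
  # disease-free with no immune pool is stationary (no direct immunization)
  expect_equal(unname(sirs_derivatives(c(1, 0, 0), sp)), c(0, 0, 0))
})

test_that("reduced-model flow vanishes at both closed-form equilibria", {
  rp <- reduced_params(alpha = 0.45, beta = 0.06, gamma = 0.1, epsilon = 0.05)
  expect_equal(unname(model3_derivatives(c(0.05 / 0.15, 0), rp)), c(0, 0),
               tolerance = 1e-14)
  expect_equal(max(abs(model3_derivatives(c(0.06 / 0.45, 0.0135 / 0.0495), rp))),
               0, tolerance = 1e-9)
  # generic point, term by term
  d <- model3_derivatives(c(0.5, 0.1), rp)
  expect_equal(unname(d), c(-0.45 * 0.05 - 0.05 + 0.05 * 0.4,
                            0.0225 - 0.006), tolerance = 1e-14)
})

test_that("invalid states are rejected", {
  p <- ref_params()
  expect_error(sipinrs_derivatives(c(0.5, -0.1, 0.3, 0.3), p), "negative")
  expect_error(sipinrs_derivatives(c(NaN, 0, 0, 1), p), "non-finite")
  expect_error(sipinrs_derivatives(c(0.5, 0.1, 0.1, 0.1), p), "sum")
  expect_error(model3_derivatives(c(0.8, 0.5), reduced_params()), "S \\+ I > 1")
  expect_error(sipinrs_params(alpha1 = 1.2), "outside")
})

test_that("RK4 trajectories stay on the simplex and converge under step halving", {
  p <- ref_params()
  traj <- integrate_sipinrs(c(0.96, 0.02, 0.02, 0), p, t_end = 100, dt = 0.1)
  m <- as.matrix(traj[, c("S", "Ip", "In", "R")])
  expect_lt(max(abs(rowSums(m) - 1)), 1e-6)
  expect_gte(min(m), -1e-9)
  half <- integrate_sipinrs(c(0.96, 0.02, 0.02, 0), p, t_end = 100, dt = 0.05)
  expect_lt(max(abs(unlist(tail(traj, 1)[-1]) - unlist(tail(half, 1)[-1]))),
            1e-5)
  expect_error(integrate_sipinrs(c(0.96, 0.02, 0.02, 0), p, t_end = 10, dt = 0),
               "dt")
})

test_that("with all contagion off, S and R balance at gamma/epsilon ratio", {
  p <- sipinrs_params(alpha1 = 0, alpha2 = 0, theta1 = 0, theta2 = 0,
                      beta1 = 0, beta2 = 0, gamma = 0.1, epsilon = 0.05)
  traj <- integrate_sipinrs(c(1, 0, 0, 0), p, t_end = 300, dt = 0.1)
  term <- unlist(tail(traj, 1))
  expect_equal(term[["S"]], 1 / 3, tolerance = 1e-6)
  expect_equal(term[["R"]], 2 / 3, tolerance = 1e-6)
})

test_that("merged disseminators reduce exactly to the two-compartment model", {
  full <- sipinrs_params(alpha1 = 0.45, alpha2 = 0.45, theta1 = 0, theta2 = 0,
                         beta1 = 0.06, beta2 = 0.06, gamma = 0.1,
                         epsilon = 0.05)
  red <- reduced_params(alpha = 0.45, beta = 0.06, gamma = 0.1, epsilon = 0.05)
  t4 <- integrate_sipinrs(c(0.96, 0.02, 0.02, 0), full, t_end = 150, dt = 0.1)
  t2 <- integrate_model3(c(0.96, 0.04), red, t_end = 150, dt = 0.1)
  expect_lt(max(abs(t4$Ip + t4$In - t2$I)), 1e-9)
  expect_lt(max(abs(t4$S - t2$S)), 1e-9)
})

test_that("RK4 integration agrees with an adaptive-solver oracle", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  f <- function(t, y, parms) {
    S <- y[1]; Ip <- y[2]; In <- y[3]; R <- y[4]
    list(c(-p$alpha1 * S * Ip - p$alpha2 * S * In - p$gamma * S + p$epsilon * R,
           p$alpha1 * S * Ip + p$theta1 * In - p$theta2 * Ip - p$beta1 * Ip,
           p$alpha2 * S * In + p$theta2 * Ip - p$theta1 * In - p$beta2 * In,
           p$beta1 * Ip + p$beta2 * In + p$gamma * S - p$epsilon * R))
  }
  ode <- deSolve::ode(c(0.96, 0.02, 0.02, 0), c(0, 50, 100), f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  traj <- integrate_sipinrs(c(0.96, 0.02, 0.02, 0), p, t_end = 100, dt = 0.1)
  got <- as.matrix(traj[traj$t %in% c(50, 100), c("S", "Ip", "In", "R")])
  expect_equal(unname(got), unname(ode[2:3, 2:5]), tolerance = 1e-7)
})

test_that("trajectory CSV round-trips at full precision", {
  traj <- integrate_sipinrs(c(0.96, 0.02, 0.02, 0), ref_params(),
                            t_end = 5, dt = 0.1)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$Ip, traj$Ip, tolerance = 1e-15)
  expect_equal(names(back), c("t", "S", "Ip", "In", "R"))
})

test_that("model config files populate parameters and run settings", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("alpha2: 0.8", "epsilon: 0.03",
               "initial:", "  S: 0.90", "  Ip: 0.02", "  In: 0.08", "  R: 0.0",
               "t_end: 50", "dt: 0.05"), f)
  cfg <- read_model_config(f)
  expect_equal(cfg$params$alpha2, 0.8)
  expect_equal(cfg$params$alpha1, 0.45)  # default preserved
  expect_equal(cfg$params$epsilon, 0.03)
  expect_equal(unname(cfg$initial), c(0.90, 0.02, 0.08, 0))
  expect_equal(cfg$dt, 0.05)
})
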