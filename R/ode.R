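#' Time derivatives of the SIpInRS mean-field system
#'
#' Rate of change of the four compartment fractions under mass-action
#' infection and linear conversion/immunization/degradation flows:
#' \deqn{dS/dt = -\alpha_1 S Ip - \alpha_2 S In - \gamma S + \epsilon R}
#' \deqn{dIp/dt = \alpha_1 S Ip + \theta_1 In - \theta_2 Ip - \beta_1 Ip}
#' \deqn{dIn/dt = \alpha_2 S In + \theta_2 Ip - \theta_1 In - \beta_2 In}
#' \deqn{dR/dt = \beta_1 Ip + \beta_2 In + \gamma S - \epsilon R}
#' The population is closed, so the four components always sum to zero.
#'
#' @param state Numeric vector `(S, Ip, In, R)` of compartment fractions
#'   (non-negative, summing to 1).
#' @param params A [sipinrs_params()] object.
#' @return Named numeric vector `(S, Ip, In, R)` of derivatives.
#' @examples
#' sipinrs_derivatives(c(0.96, 0.02, 0.02, 0), sipinrs_params())
#' @export
sipinrs_derivatives <- function(state, params) {
  stopifnot(inherits(params, "sipinrs_params"))
  y <- validate_fractions(state, c("S", "Ip", "In", "R"))
  sipinrs_rhs(y, params)
}

# unvalidated right-hand side, shared with the integrator (whose RK stages
# may transiently leave the simplex by O(dt) amounts)
sipinrs_rhs <- function(y, p) {
  S <- y[[1L]]; Ip <- y[[2L]]; In <- y[[3L]]; R <- y[[4L]]
  inf_p <- p$alpha1 * S * Ip
  inf_n <- p$alpha2 * S * In
  c(S = -inf_p - inf_n - p$gamma * S + p$epsilon * R,
    Ip = inf_p + p$theta1 * In - p$theta2 * Ip - p$beta1 * Ip,
    In = inf_n + p$theta2 * Ip - p$theta1 * In - p$beta2 * In,
    R = p$beta1 * Ip + p$beta2 * In + p$gamma * S - p$epsilon * R)
}

#' Time derivatives of the baseline SIRS comparator
#'
#' Classical SIRS flow without a direct susceptible-to-immune path:
#' \deqn{dS/dt = -\alpha S I + \epsilon R,\quad dI/dt = \alpha S I - \beta I,
#' \quad dR/dt = \beta I - \epsilon R.}
#'
#' @param state Numeric vector `(S, I, R)` of fractions.
#' @param params A [sirs_params()] object.
#' @return Named derivative vector `(S, I, R)`.
#' @export
sirs_derivatives <- function(state, params) {
  stopifnot(inherits(params, "sirs_params"))
  y <- validate_fractions(state, c("S", "I", "R"))
  sirs_rhs(y, params)
}

sirs_rhs <- function(y, p) {
  S <- y[[1L]]; I <- y[[2L]]; R <- y[[3L]]
  inf <- p$alpha * S * I
  c(S = -inf + p$epsilon * R, I = inf - p$beta * I,
    R = p$beta * I - p$epsilon * R)
}

#' Time derivatives of the reduced two-compartment model
#'
#' The reduced model follows `(S, I)` with `I = Ip + In` merged and
#' `R = 1 - S - I` implied:
#' \deqn{X = -\alpha S I - \gamma S + \epsilon (1 - S - I)}
#' \deqn{Y = \alpha S I - \beta I}
#' This is the system whose equilibria and contagion threshold are analyzed
#' in [equilibrium_points()] and [compute_R0()].
#'
#' @param state Numeric vector `(S, I)` with `S, I >= 0` and `S + I <= 1`.
#' @param params A [reduced_params()] object.
#' @return Named derivative vector `(S, I)`.
#' @export
model3_derivatives <- function(state, params) {
  stopifnot(inherits(params, "reduced_params"))
  if (length(state) != 2L) stop("state must be (S, I)", call. = FALSE)
  if (any(!is.finite(state))) stop("invalid state: non-finite fraction", call. = FALSE)
  if (any(state < -1e-12)) stop("invalid state: negative fraction", call. = FALSE)
  if (sum(state) > 1 + 1e-9) stop("invalid state: S + I > 1", call. = FALSE)
  model3_rhs(stats::setNames(as.numeric(state), c("S", "I")), params)
}

model3_rhs <- function(y, p) {
  S <- y[[1L]]; I <- y[[2L]]
  c(S = -p$alpha * S * I - p$gamma * S + p$epsilon * (1 - S - I),
    I = p$alpha * S * I - p$beta * I)
}

# Classic fixed-step fourth-order Runge-Kutta. Tiny negative excursions
# (above -1e-6) are clipped to zero after each step; divergence aborts with
# the offending time in the error message.
rk4_integrate <- function(rhs, y0, params, t_end, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_end < dt) stop("t_end must be at least dt", call. = FALSE)
  n_steps <- floor(round(t_end / dt, 9))
  out <- matrix(NA_real_, n_steps + 1L, length(y0),
                dimnames = list(NULL, names(y0)))
  out[1L, ] <- y <- y0
  for (i in seq_len(n_steps)) {
    k1 <- rhs(y, params)
    k2 <- rhs(y + dt / 2 * k1, params)
    k3 <- rhs(y + dt / 2 * k2, params)
    k4 <- rhs(y + dt * k3, params)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop("integration diverged at t = ", format(i * dt), call. = FALSE)
    y[y < 0 & y > -1e-6] <- 0
    out[i + 1L, ] <- y
  }
  data.frame(t = dt * (0:n_steps), out)
}

#' Integrate the SIpInRS system with fixed-step RK4
#'
#' @param initial Initial fractions `(S, Ip, In, R)`, summing to 1.
#' @param params A [sipinrs_params()] object.
#' @param t_end Integration horizon (default 200; all reference trajectories
#'   plateau well before that).
#' @param dt Step size (default 0.1).
#' @return A `contagion_trajectory`: a data frame with columns
#'   `t, S, Ip, In, R` and the parameters attached as attribute `"parameters"`.
#' @examples
#' traj <- integrate_sipinrs(c(0.96, 0.02, 0.02, 0), sipinrs_params(),
#'                           t_end = 50)
#' tail(traj, 1)
#' @export
integrate_sipinrs <- function(initial, params, t_end = 200, dt = 0.1) {
  stopifnot(inherits(params, "sipinrs_params"))
  y0 <- validate_fractions(initial, c("S", "Ip", "In", "R"))
  as_trajectory(rk4_integrate(sipinrs_rhs, y0, params, t_end, dt), params)
}

#' Integrate the baseline SIRS comparator with fixed-step RK4
#'
#' @inheritParams integrate_sipinrs
#' @param initial Initial fractions `(S, I, R)`.
#' @param params A [sirs_params()] object.
#' @return A `contagion_trajectory` with columns `t, S, I, R`.
#' @export
integrate_sirs <- function(initial, params, t_end = 200, dt = 0.1) {
  stopifnot(inherits(params, "sirs_params"))
  y0 <- validate_fractions(initial, c("S", "I", "R"))
  as_trajectory(rk4_integrate(sirs_rhs, y0, params, t_end, dt), params)
}

#' Integrate the reduced two-compartment model with fixed-step RK4
#'
#' @inheritParams integrate_sipinrs
#' @param initial Initial `(S, I)` pair with `S + I <= 1`.
#' @param params A [reduced_params()] object.
#' @return A `contagion_trajectory` with columns `t, S, I`.
#' @export
integrate_model3 <- function(initial, params, t_end = 200, dt = 0.1) {
  stopifnot(inherits(params, "reduced_params"))
  if (length(initial) != 2L || any(initial < 0) || sum(initial) > 1 + 1e-9)
    stop("initial must be (S, I) with S, I >= 0 and S + I <= 1", call. = FALSE)
  y0 <- stats::setNames(as.numeric(initial), c("S", "I"))
  as_trajectory(rk4_integrate(model3_rhs, y0, params, t_end, dt), params)
}

as_trajectory <- function(df, params) {
  attr(df, "parameters") <- params
  class(df) <- c("contagion_trajectory", "data.frame")
  df
}

#' @export
print.contagion_trajectory <- function(x, ...) {
  comps <- setdiff(names(x), "t")
  cat(sprintf("Contagion trajectory: %d points, t in [%g, %g], compartments %s\n",
              nrow(x), min(x$t), max(x$t), paste(comps, collapse = "/")))
  last <- x[nrow(x), comps, drop = FALSE]
  cat("terminal:", paste(sprintf("%s = %.4f", comps, unlist(last)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes one row per time-grid point with header `t,S,Ip,In,R` (or the
#' trajectory's own compartments), at full double precision.
#'
#' @param traj A `contagion_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- as.data.frame(lapply(traj, function(col) sprintf("%.17g", col)),
                       check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' Also accepts any CSV with a `t` column and one numeric column per
#' compartment (e.g. an observed sentiment time series to compare against).
#'
#' @param path CSV file path.
#' @return A `contagion_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("trajectory CSV needs a 't' column", call. = FALSE)
  as_trajectory(df, NULL)
}
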