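#' Transition rates of the SIpInRS model
#'
#' Bundles the eight per-round (or per-unit-time) transition rates of the
#' emotional-contagion model. All rates are dimensionless probabilities and
#' must lie in \eqn{[0, 1]}. The defaults are the reference parameterization
#' used throughout the package's built-in scenarios.
#'
#' @param alpha1 Positive infection rate: susceptible to positive disseminator
#'   on contact with positive sentiment.
#' @param alpha2 Negative infection rate: susceptible to negative disseminator.
#' @param theta1 Purification rate: negative disseminator converts to positive.
#' @param theta2 Incitement rate: positive disseminator converts to negative.
#' @param beta1 Immunization rate of positive disseminators.
#' @param beta2 Immunization rate of negative disseminators.
#' @param gamma Direct immunization rate: susceptible to immune without ever
#'   disseminating.
#' @param epsilon Degradation rate: immune reverts to susceptible (memory
#'   decay / renewed attention).
#'
#' @return An object of class `sipinrs_params`: a named list of the eight
#'   rates.
#' @examples
#' p <- sipinrs_params()
#' p$alpha1
#' @export
sipinrs_params <- function(alpha1 = 0.45, alpha2 = 0.40,
                           theta1 = 0.05, theta2 = 0.02,
                           beta1 = 0.06, beta2 = 0.04,
                           gamma = 0.10, epsilon = 0.05) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, theta1 = theta1,
            theta2 = theta2, beta1 = beta1, beta2 = beta2,
            gamma = gamma, epsilon = epsilon)
  check_rates(p)
  structure(p, class = "sipinrs_params")
}

#' Parameters of the reduced (merged-disseminator) model
#'
#' The reduced model merges the two disseminator compartments into a single
#' infected fraction `I = Ip + In`, with a unified infection rate `alpha` and
#' immunization rate `beta`; `gamma` and `epsilon` keep their meaning from
#' [sipinrs_params()]. This is the system on which the contagion threshold and
#' equilibrium analysis operate (see [compute_R0()]).
#'
#' @param alpha Merged infection rate.
#' @param beta Merged immunization rate.
#' @param gamma Direct immunization rate.
#' @param epsilon Degradation rate.
#' @return An object of class `reduced_params`.
#' @export
reduced_params <- function(alpha = 0.45, beta = 0.06,
                           gamma = 0.10, epsilon = 0.05) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon)
  check_rates(p)
  structure(p, class = "reduced_params")
}

#' Parameters of the baseline SIRS comparator
#'
#' The classical susceptible-infected-recovered-susceptible model used as the
#' experimental comparator. It has no direct-immunization path: every
#' individual that becomes immune must pass through the infected state.
#'
#' @param alpha Infection rate.
#' @param beta Immunization rate.
#' @param epsilon Degradation (immunity-loss) rate.
#' @return An object of class `sirs_params`.
#' @export
sirs_params <- function(alpha = 0.45, beta = 0.06, epsilon = 0.05) {
  p <- list(alpha = alpha, beta = beta, epsilon = epsilon)
  check_rates(p)
  structure(p, class = "sirs_params")
}

check_rates <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0 || v > 1)
      stop("rate '", nm, "' = ", v, " is outside [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sipinrs_params <- function(x, ...) {
  cat("SIpInRS rates:\n")
  cat(sprintf("  infection  alpha1 = %.3g  alpha2 = %.3g\n", x$alpha1, x$alpha2))
  cat(sprintf("  conversion theta1 = %.3g  theta2 = %.3g\n", x$theta1, x$theta2))
  cat(sprintf("  immunity   beta1  = %.3g  beta2  = %.3g  gamma = %.3g\n",
              x$beta1, x$beta2, x$gamma))
  cat(sprintf("  degradation epsilon = %.3g\n", x$epsilon))
  invisible(x)
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("Reduced model rates: alpha = %.3g, beta = %.3g, gamma = %.3g, epsilon = %.3g\n",
              x$alpha, x$beta, x$gamma, x$epsilon))
  invisible(x)
}

#' Read model parameters and run settings from a YAML or JSON config
#'
#' The config may carry any of the keys `alpha1, alpha2, theta1, theta2,
#' beta1, beta2, gamma, epsilon` (missing rates fall back to the reference
#' defaults), an `initial` block with `S, Ip, In, R`, and the integration
#' settings `t_end` and `dt`.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A list with elements `params` ([sipinrs_params()]), `initial`
#'   (named fraction vector), `t_end` and `dt`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rate_keys <- c("alpha1", "alpha2", "theta1", "theta2",
                 "beta1", "beta2", "gamma", "epsilon")
  params <- do.call(sipinrs_params, cfg[intersect(names(cfg), rate_keys)])
  initial <- c(S = 0.96, Ip = 0.02, In = 0.02, R = 0)
  if (!is.null(cfg$initial)) {
    ini <- unlist(cfg$initial)
    initial[names(ini)] <- ini
  }
  validate_fractions(initial, c("S", "Ip", "In", "R"))
  list(params = params,
       initial = initial,
       t_end = if (is.null(cfg$t_end)) 200 else cfg$t_end,
       dt = if (is.null(cfg$dt)) 0.1 else cfg$dt)
}

# Shared validator for compartment-fraction vectors: finite, non-negative,
# summing to one within 1e-9.
validate_fractions <- function(x, nms, tol = 1e-9) {
  if (length(x) != length(nms))
    stop("state must have ", length(nms), " components (",
         paste(nms, collapse = ", "), ")", call. = FALSE)
  if (any(!is.finite(x))) stop("invalid state: non-finite fraction", call. = FALSE)
  if (any(x < -1e-12)) stop("invalid state: negative fraction", call. = FALSE)
  if (abs(sum(x) - 1) > tol)
    stop("invalid state: fractions sum to ", sum(x), ", not 1", call. = FALSE)
  stats::setNames(as.numeric(x), nms)
}
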