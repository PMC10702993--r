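#' Contagion threshold of the reduced model
#'
#' The threshold separating extinction of disseminators from endemic
#' contagion. At the disseminator-free equilibrium the susceptible fraction is
#' \eqn{S_0 = \epsilon/(\gamma+\epsilon)}, so
#' \deqn{R_0 = \frac{\alpha S_0}{\beta}
#'           = \frac{\alpha\,\epsilon}{\beta\,(\gamma+\epsilon)}.}
#' When \eqn{R_0 \le 1} the system settles at the disseminator-free point
#' `P0`; when \eqn{R_0 > 1} an endemic point `Pstar` with positive infected
#' fraction appears (see [equilibrium_points()]).
#'
#' @param params A [reduced_params()] object with `beta > 0` and
#'   `gamma + epsilon > 0`.
#' @return The threshold, a positive scalar.
#' @examples
#' compute_R0(reduced_params(alpha = 0.45, beta = 0.06,
#'                           gamma = 0.1, epsilon = 0.05)) # 2.5
#' @export
compute_R0 <- function(params) {
  stopifnot(inherits(params, "reduced_params"))
  if (params$beta <= 0 || params$gamma + params$epsilon <= 0)
    stop("contagion threshold undefined: beta and gamma + epsilon must be positive",
         call. = FALSE)
  params$alpha * params$epsilon / (params$beta * (params$gamma + params$epsilon))
}

#' Equilibrium points of the reduced model
#'
#' The disseminator-free point \eqn{P_0 = (\epsilon/(\gamma+\epsilon),\; 0)}
#' always exists. The endemic point
#' \deqn{P^* = \left(\frac{\beta}{\alpha},\;
#'   \frac{\epsilon\alpha - \epsilon\beta - \gamma\beta}
#'        {\alpha(\epsilon+\beta)}\right)}
#' exists (with positive infected fraction) exactly when \eqn{R_0 > 1}. Both
#' returned points are stationary: [model3_derivatives()] vanishes there to
#' within 1e-10.
#'
#' @inheritParams compute_R0
#' @return A list with `P0` (named `(S, I)` vector) and `Pstar` (named vector,
#'   or `NULL` when `R0 <= 1`).
#' @export
equilibrium_points <- function(params) {
  R0 <- compute_R0(params)
  a <- params$alpha; b <- params$beta; g <- params$gamma; e <- params$epsilon
  P0 <- c(S = e / (g + e), I = 0)
  Pstar <- NULL
  if (R0 > 1)
    Pstar <- c(S = b / a, I = (e * a - e * b - g * b) / (a * (e + b)))
  list(P0 = P0, Pstar = Pstar)
}

#' Jacobian of the reduced model at a point
#'
#' Matrix of partial derivatives of the reduced flow `(X, Y)` with respect to
#' `(S, I)`:
#' \deqn{J = \begin{pmatrix} -\alpha I - \gamma - \epsilon &
#'   -\alpha S - \epsilon \\ \alpha I & \alpha S - \beta \end{pmatrix}}
#'
#' @inheritParams compute_R0
#' @param point Named or plain numeric `(S, I)` pair on the simplex.
#' @return A 2x2 numeric matrix with dimnames `(S, I)`.
#' @export
jacobian_matrix <- function(params, point) {
  stopifnot(inherits(params, "reduced_params"))
  if (length(point) != 2L || any(!is.finite(point)))
    stop("point must be a finite (S, I) pair", call. = FALSE)
  S <- point[[1L]]; I <- point[[2L]]
  a <- params$alpha
  matrix(c(-a * I - params$gamma - params$epsilon, -a * S - params$epsilon,
           a * I, a * S - params$beta),
         nrow = 2, byrow = TRUE, dimnames = list(c("S", "I"), c("S", "I")))
}

#' Coefficients of the characteristic equation of a 2x2 Jacobian
#'
#' For \eqn{\lambda^2 + b\lambda + c = 0}: `b` is minus the trace and `c` the
#' determinant. Exposed for cross-checks against the eigenvalue route used by
#' [classify_stability()] (Routh-Hurwitz: stable iff `b > 0` and `c > 0`).
#'
#' @param J A 2x2 numeric matrix.
#' @return Named vector `c(b, c)`.
#' @export
characteristic_coefficients <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 2L), all(is.finite(J)))
  c(b = -(J[1, 1] + J[2, 2]), c = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
}

#' Classify the local stability of an equilibrium from its Jacobian
#'
#' Eigenvalue-based classification with a +-1e-12 marginal band on the real
#' parts, so that the knife-edge `R0 = 1` case is reported as `"marginal"`
#' rather than misclassified by floating-point noise.
#'
#' @param J A 2x2 numeric Jacobian matrix.
#' @return A list with `label` (`"stable"`, `"unstable"` or `"marginal"`) and
#'   `eigenvalues` (complex pair).
#' @export
classify_stability <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == 2L), all(is.finite(J)))
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  label <- if (all(re < -1e-12)) "stable"
           else if (any(re > 1e-12)) "unstable"
           else "marginal"
  list(label = label, eigenvalues = ev)
}

#' Full equilibrium and stability report for the reduced model
#'
#' Computes the contagion threshold, both equilibrium points, their Jacobians'
#' eigenvalues and stability labels in one pass.
#'
#' @inheritParams compute_R0
#' @return An object of class `equilibrium_report`: a list with `R0`, `P0`,
#'   `Pstar` (or `NULL`), `eigenvalues_P0`, `eigenvalues_Pstar` (or `NULL`),
#'   `stability_P0`, and `stability_Pstar` (`"absent"` when `R0 <= 1`).
#' @examples
#' equilibrium_report(reduced_params())
#' @export
equilibrium_report <- function(params) {
  R0 <- compute_R0(params)
  eq <- equilibrium_points(params)
  s0 <- classify_stability(jacobian_matrix(params, eq$P0))
  rep <- list(R0 = R0, P0 = eq$P0, Pstar = eq$Pstar,
              eigenvalues_P0 = s0$eigenvalues, eigenvalues_Pstar = NULL,
              stability_P0 = s0$label, stability_Pstar = "absent",
              parameters = params)
  if (!is.null(eq$Pstar)) {
    ss <- classify_stability(jacobian_matrix(params, eq$Pstar))
    rep$eigenvalues_Pstar <- ss$eigenvalues
    rep$stability_Pstar <- ss$label
  }
  structure(rep, class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Contagion threshold R0 = %.6g\n", x$R0))
  cat(sprintf("P0    = (S = %.6f, I = %.6f)  [%s]\n",
              x$P0[["S"]], x$P0[["I"]], x$stability_P0))
  if (is.null(x$Pstar)) {
    cat("Pstar = absent (R0 <= 1)\n")
  } else {
    cat(sprintf("Pstar = (S = %.6f, I = %.6f)  [%s]\n",
                x$Pstar[["S"]], x$Pstar[["I"]], x$stability_Pstar))
  }
  invisible(x)
}

#' Serialize an equilibrium report as JSON
#'
#' @param report An [equilibrium_report()] object.
#' @return A JSON string with `R0`, the equilibrium coordinates, eigenvalue
#'   real/imaginary parts, and stability labels.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "equilibrium_report"))
  ev <- function(v) if (is.null(v)) NULL else
    list(re = Re(v), im = Im(v))
  jsonlite::toJSON(list(
    R0 = report$R0,
    P0 = as.list(report$P0),
    Pstar = if (is.null(report$Pstar)) NULL else as.list(report$Pstar),
    eigenvalues_P0 = ev(report$eigenvalues_P0),
    eigenvalues_Pstar = ev(report$eigenvalues_Pstar),
    stability_P0 = report$stability_P0,
    stability_Pstar = report$stability_Pstar
  ), auto_unbox = TRUE, digits = NA, null = "null")
}
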