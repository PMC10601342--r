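#' Kinetic parameters of the two-state transcription model
#'
#' Bundles the per-gene rates of the spliced/unspliced kinetics
#' \deqn{du/dt = \alpha^{(k)} - \beta u, \qquad ds/dt = \beta u - \gamma s,}
#' where the transcription rate \eqn{\alpha^{(k)}} equals `alpha` during
#' induction and 0 during repression. All genes share one parameter set; the
#' gene-to-gene variation comes from per-gene rescaling of latent time.
#'
#' @param alpha Transcription rate during induction (molecules per unit time).
#' @param beta Splicing rate (1/time).
#' @param gamma Degradation rate (1/time). Must differ from `beta`: the
#'   closed-form solution has a \eqn{\gamma - \beta} denominator.
#' @param t_switch Time at which transcription switches off. Defaults to
#'   `t_max / 2`.
#' @param t_max Maximum latent time of the simulated process.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params() # the defaults used throughout the simulations
#' @export
kinetic_params <- function(alpha = 5, beta = 0.3, gamma = 0.5,
                           t_max = 25, t_switch = t_max / 2) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            is.numeric(t_switch), is.numeric(t_max))
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("alpha, beta and gamma must all be positive", call. = FALSE)
  if (beta == gamma)
    stop("beta and gamma must differ (gamma - beta appears as a denominator ",
         "in the closed-form solution)", call. = FALSE)
  if (t_switch <= 0 || t_switch > t_max)
    stop("t_switch must lie in (0, t_max]", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         t_switch = t_switch, t_max = t_max),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>  alpha =", x$alpha, " beta =", x$beta,
      " gamma =", x$gamma, "\n                  t_switch =", x$t_switch,
      " t_max =", x$t_max, "\n")
  invisible(x)
}

#' Closed-form solution of the transcription kinetics
#'
#' Evaluates the analytical solution of the two-rate ODE system at elapsed
#' time `tau` since the last state change:
#' \deqn{u(\tau) = u_0 e^{-\beta\tau} + \frac{\alpha^{(k)}}{\beta}(1 - e^{-\beta\tau})}
#' \deqn{s(\tau) = s_0 e^{-\gamma\tau} + \frac{\alpha^{(k)}}{\gamma}(1 - e^{-\gamma\tau})
#'   + \frac{\alpha^{(k)} - \beta u_0}{\gamma - \beta}(e^{-\gamma\tau} - e^{-\beta\tau})}
#'
#' @param params A [kinetic_params()] object.
#' @param tau Non-negative elapsed time(s) since the state switch; vectorized.
#' @param u0,s0 Initial unspliced/spliced abundance at `tau = 0`.
#' @param state `"on"` (transcription at rate `alpha`) or `"off"` (rate 0).
#'
#' @return A list with numeric vectors `u` and `s`, same length as `tau`.
#' @examples
#' p <- kinetic_params()
#' solve_dynamics(p, tau = 1) # early induction from u0 = s0 = 0
#' @export
solve_dynamics <- function(params, tau, u0 = 0, s0 = 0,
                           state = c("on", "off")) {
  stopifnot(inherits(params, "kinetic_params"))
  state <- match.arg(state)
  if (any(tau < 0)) stop("tau must be non-negative", call. = FALSE)
  a <- if (state == "on") params$alpha else 0
  b <- params$beta
  g <- params$gamma
  eb <- exp(-b * tau)
  eg <- exp(-g * tau)
  u <- u0 * eb + a / b * (1 - eb)
  s <- s0 * eg + a / g * (1 - eg) + (a - b * u0) / (g - b) * (eg - eb)
  list(u = u, s = s)
}

#' True RNA velocity from spliced/unspliced abundance
#'
#' The defining identity of RNA velocity: \eqn{v = ds/dt = \beta u - \gamma s}.
#' Works elementwise on vectors or matrices.
#'
#' @param u,s Unspliced and spliced abundances (same shape).
#' @param params A [kinetic_params()] object supplying `beta` and `gamma`.
#' @return Velocities, same shape as the inputs.
#' @examples
#' p <- kinetic_params()
#' true_velocity(p$alpha / p$beta, p$alpha / p$gamma, p) # steady state: 0
#' @export
true_velocity <- function(u, s, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(u) != length(s))
    stop("u and s must have the same shape", call. = FALSE)
  params$beta * u - params$gamma * s
}
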