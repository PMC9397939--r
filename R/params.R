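#' Epileptor model parameters
#'
#' Bundles the constants of the Epileptor neural-mass model together with the
#' network-level control parameters: the global coupling strength `w`, the
#' additive noise standard deviation `sigma`, and the excitability values used
#' by the seizure protocol.
#'
#' The defaults are the standard Epileptor constants: `I1 = 3.1`, `I2 = 0.45`,
#' `gamma = 0.01`, `tau0 = 6667`, `tau1 = 1`, `tau2 = 10`, giving the
#' characteristic time-scale separation `tau0 >> tau2 >> tau1` between the
#' slow permittivity variable, the spike-wave subsystem and the fast
#' oscillatory subsystem. An epileptogenic-zone (EZ) node is instantiated at
#' `x0_ez = -1.6`, above the critical excitability of an isolated node
#' (approximately -2.061), while surround nodes stay in the non-epileptic
#' range (default `x0_surround = -2.2`, admissible range `[-2.3, -2.09]`).
#'
#' @param x0_surround homogeneous excitability of the non-epileptic surround
#'   nodes (unitless).
#' @param w global connectivity strength scaling the diffusive coupling
#'   (unitless, `>= 0`).
#' @param sigma standard deviation of the additive noise entering the fast
#'   subsystem (`x2`, `y2` equations of the full model; `x` equation of the
#'   reduced model).
#' @param x0_ez excitability assigned to the active EZ node on activation.
#' @param I1,I2,gamma,tau0,tau1,tau2 Epileptor constants; override only for
#'   methodological experiments.
#' @return An object of class `epileptor_params` (a named list).
#' @examples
#' p <- epileptor_params(x0_surround = -2.2, w = 0.5)
#' p$tau0
#' @export
epileptor_params <- function(x0_surround = -2.2, w = 0, sigma = 0,
                             x0_ez = -1.6,
                             I1 = 3.1, I2 = 0.45, gamma = 0.01,
                             tau0 = 6667, tau1 = 1, tau2 = 10) {
  stopifnot(w >= 0, sigma >= 0)
  if (!(tau0 > tau2 && tau2 > tau1 && tau1 > 0))
    stop("time-scale separation requires tau0 > tau2 > tau1 > 0")
  structure(list(x0_surround = x0_surround, w = w, sigma = sigma,
                 x0_ez = x0_ez, I1 = I1, I2 = I2, gamma = gamma,
                 tau0 = tau0, tau1 = tau1, tau2 = tau2),
            class = "epileptor_params")
}

#' @export
print.epileptor_params <- function(x, ...) {
  cat("Epileptor parameters\n")
  cat(sprintf("  constants: I1=%g I2=%g gamma=%g tau0=%g tau1=%g tau2=%g\n",
              x$I1, x$I2, x$gamma, x$tau0, x$tau1, x$tau2))
  cat(sprintf("  control:   x0_surround=%g x0_ez=%g w=%g sigma=%g\n",
              x$x0_surround, x$x0_ez, x$w, x$sigma))
  invisible(x)
}

# internal: list of constants handed to the C++ integrator
.par_list <- function(params) {
  params[c("I1", "I2", "gamma", "tau0", "tau1", "tau2")]
}
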