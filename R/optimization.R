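#' Optimize the asphericity of the positive lens's anterior surface
#'
#' Reproduces the study's aberration-correction step: derivative-free
#' minimization of the RMS wavefront error over the conic constant and
#' the second and fourth even-asphere polynomial terms (k, a2, a4) of the
#' anterior surface of the telescope's positive lens, starting from the
#' spherical design (0, 0, 0). Optimization is performed on the centred
#' system (decentration is applied afterwards, never re-optimized).
#' Candidates whose sag becomes undefined inside the aperture, or that
#' leave the bounds, are rejected as infinite merit.
#'
#' @param sys centred [optical_system()] (from [assemble_system()]).
#' @param target_surface index of the surface to optimize; defaults to
#'   the assembly's recorded anterior positive-lens surface.
#' @param n_grid pupil sampling used in the merit function.
#' @param bounds list with elements `k`, `a2`, `a4`: absolute bounds.
#' @param rms_remove RMS convention for the merit, see [rms_wavefront()].
#' @param maxit iteration budget per simplex run.
#' @return object of class `optimization_result`: `k`, `a2`, `a4`,
#'   `achieved_rms` (waves), `start_rms`, `iterations`, `converged`.
#' @export
optimize_asphere <- function(sys, target_surface = attr(sys, "target_surface"),
                             n_grid = 32,
                             bounds = list(k = 50, a2 = 0.05, a4 = 0.01),
                             rms_remove = c("piston", "tilt"),
                             maxit = 500) {
  if (is.null(target_surface))
    stop("target_surface not given and not recorded on the system")
  check_target_surface(sys, target_surface)
  guess_env <- new.env()
  guess_env$a <- NULL
  merit <- function(par) {
    if (abs(par[1]) > bounds$k || abs(par[2]) > bounds$a2 ||
        abs(par[3]) > bounds$a4) return(1e6)
    s2 <- apply_asphere(sys, par, target_surface)
    wf <- try(compute_wavefront(s2, n_grid = n_grid, guess = guess_env$a),
              silent = TRUE)
    if (inherits(wf, "try-error")) return(1e6)
    guess_env$a <- wf$aim_a
    rms_wavefront(wf, rms_remove)
  }
  start_rms <- merit(c(0, 0, 0))
  ctrl <- list(maxit = maxit, reltol = 1e-12,
               parscale = c(0.5, 3e-4, 1e-4))
  o1 <- stats::optim(c(0, 0, 0), merit, method = "Nelder-Mead", control = ctrl)
  o2 <- stats::optim(o1$par, merit, method = "Nelder-Mead", control = ctrl)
  best <- if (o2$value <= o1$value) o2 else o1
  # re-evaluate the optimum cold (no aiming warm start) so the recorded
  # merit is exactly reproducible from the returned parameters
  wf_final <- compute_wavefront(apply_asphere(sys, best$par, target_surface),
                                n_grid = n_grid)
  achieved <- rms_wavefront(wf_final, rms_remove)
  res <- list(k = best$par[1], a2 = best$par[2], a4 = best$par[3],
              achieved_rms = achieved, start_rms = start_rms,
              iterations = unname(o1$counts[1] + o2$counts[1]),
              converged = achieved <= start_rms + 1e-9,
              target_surface = target_surface, n_grid = n_grid)
  class(res) <- "optimization_result"
  res
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "optimization_result: k=%.5f a2=%.3e a4=%.3e; RMS %.5f -> %.6f waves (%d evals)\n",
    x$k, x$a2, x$a4, x$start_rms, x$achieved_rms, x$iterations))
  invisible(x)
}

check_target_surface <- function(sys, target_surface) {
  if (target_surface < 1 || target_surface > length(sys$surfaces))
    stop("target_surface out of range")
  s <- sys$surfaces[[target_surface]]
  if (s$kind != "conic_asphere" || s$n_after <= media_before(sys)[target_surface])
    stop("target_surface is not the anterior surface of a positive lens")
  invisible(TRUE)
}

apply_asphere <- function(sys, par, target_surface) {
  s <- sys$surfaces[[target_surface]]
  s$conic_k <- par[1]; s$a2 <- par[2]; s$a4 <- par[3]
  sys$surfaces[[target_surface]] <- s
  sys
}

#' Write an optimization result onto a system
#'
#' Returns a new system with the optimized (k, a2, a4) written to the
#' target surface; the input system is unmodified.
#'
#' @param sys the [optical_system()] the result was obtained on (or its
#'   decentred twin).
#' @param result an [optimize_asphere()] result.
#' @param target_surface surface index; defaults to the result's record.
#' @return a new `optical_system`.
#' @export
apply_result <- function(sys, result, target_surface = result$target_surface) {
  if (!isTRUE(result$converged)) stop("optimization result did not converge")
  check_target_surface(sys, target_surface)
  apply_asphere(sys, c(result$k, result$a2, result$a4), target_surface)
}
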