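# Quasi-Newton (BFGS, inverse-Hessian update) minimiser with Armijo
# backtracking. Small and self-contained so that accepted steps, the
# monotonicity of the target and fixed-atom masks are fully under our control.

bfgs_minimize <- function(fn, x0, tol = 1e-3, max_iter = 2000) {
  x <- as.numeric(x0)
  n <- length(x)
  ev <- fn(x)
  f <- ev$value
  g <- as.numeric(ev$gradient)
  H <- diag(n)
  trace <- f
  it <- 0L
  converged <- max(abs(g)) < tol
  while (!converged && it < max_iter) {
    p <- -as.numeric(H %*% g)
    slope <- sum(p * g)
    if (!is.finite(slope) || slope >= 0) {
      H <- diag(n)
      p <- -g
      slope <- sum(p * g)
      if (slope >= 0) break
    }
    alpha <- 1
    accepted <- FALSE
    while (alpha > 1e-14) {
      xn <- x + alpha * p
      evn <- fn(xn)
      if (is.finite(evn$value) && evn$value <= f + 1e-4 * alpha * slope) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    s <- xn - x
    gn <- as.numeric(evn$gradient)
    y <- gn - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      Hy <- as.numeric(H %*% y)
      # standard inverse-BFGS update
      H <- H - rho * (outer(s, Hy) + outer(Hy, s)) +
        rho * (1 + rho * sum(y * Hy)) * outer(s, s)
    } else {
      H <- diag(n)
    }
    x <- xn; f <- evn$value; g <- gn
    trace <- c(trace, f)
    it <- it + 1L
    converged <- max(abs(g)) < tol
  }
  list(par = x, value = f, gradient = g, iterations = it,
       converged = converged, trace = trace)
}

#' Constrained geometry optimisation
#'
#' Minimises the engine energy over the free atoms with a BFGS descent and
#' backtracking line search; atoms under the `fixed` mask are returned
#' bit-identical to the input. Converges when the largest gradient component
#' on any free atom drops below `tol`.
#'
#' @param engine A `qr_engine` (see [surrogate_engine()]).
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param fixed Logical mask of length n; `TRUE` atoms do not move.
#' @param tol Gradient-component tolerance (engine units / Angstrom).
#' @param max_iter Iteration cap; exceeding it raises a convergence error
#'   carrying the last state unless `partial = TRUE`.
#' @param partial Return the best state instead of erroring on
#'   non-convergence.
#' @return List with `coords`, `energy`, `iterations`, `converged`, `trace`
#'   (accepted energies).
#' @export
optimize_geometry <- function(engine, coords, fixed = rep(FALSE, nrow(coords)),
                              tol = 1e-3, max_iter = 2000, partial = FALSE) {
  coords <- rbind3(coords)
  stopifnot(length(fixed) == nrow(coords))
  free <- which(!fixed)
  if (length(free) == 0) {
    ev <- engine_energy(engine, coords)
    return(list(coords = coords, energy = ev$value, iterations = 0L,
                converged = TRUE, trace = ev$value))
  }
  cur <- coords
  fn <- function(x) {
    cur[free, ] <- matrix(x, ncol = 3)
    ev <- engine_energy(engine, cur)
    list(value = ev$value, gradient = as.numeric(ev$gradient[free, ]))
  }
  res <- bfgs_minimize(fn, as.numeric(coords[free, ]), tol = tol, max_iter = max_iter)
  out <- coords
  out[free, ] <- matrix(res$par, ncol = 3)
  if (!res$converged && !partial) {
    cnd <- rlang::error_cnd(class = "qrsite_convergence_error",
                            message = sprintf(
                              "geometry optimisation did not converge in %d iterations (max |g| = %.3g)",
                              res$iterations, max(abs(res$gradient))),
                            coords = out, energy = res$value)
    rlang::cnd_signal(cnd)
  }
  list(coords = out, energy = res$value, iterations = res$iterations,
       converged = res$converged, trace = res$trace)
}
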