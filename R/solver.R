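# Small dense nonlinear solvers used by the steady-state hydraulic solve.
# Hand-written because the solve is 2-dimensional, must be deterministic,
# and needs the constrained multi-start fallback described alongside it.

.num_jacobian <- function(fn, x, f0 = fn(x), h = 1e-6) {
  n <- length(x)
  m <- length(f0)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    dx <- h * max(1, abs(x[j]))
    xp <- x
    xp[j] <- xp[j] + dx
    J[, j] <- (fn(xp) - f0) / dx
  }
  J
}

#' Powell dog-leg root finder
#'
#' Trust-region Newton iteration for small square nonlinear systems, using
#' the classic dog-leg step (Newton step when it fits in the trust region,
#' otherwise a blend of the steepest-descent Cauchy point and the Newton
#' direction). The Jacobian is formed by forward differences.
#'
#' @param fn Function mapping a numeric vector to a residual vector of the
#'   same length.
#' @param x0 Starting point.
#' @param max_iter Iteration cap.
#' @param ftol Residual infinity-norm for convergence.
#' @param delta0 Initial trust radius.
#' @return A list with `x`, `fnorm` (infinity norm of the residual),
#'   `iterations` and `converged`.
#' @export
dogleg_solve <- function(fn, x0, max_iter = 80, ftol = 1e-14, delta0 = 0.5) {
  x <- x0
  f <- fn(x)
  if (any(!is.finite(f))) return(list(x = x, fnorm = Inf, iterations = 0, converged = FALSE))
  delta <- delta0
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < ftol) {
      return(list(x = x, fnorm = max(abs(f)), iterations = it - 1, converged = TRUE))
    }
    J <- .num_jacobian(fn, x, f)
    g <- drop(crossprod(J, f))                     # gradient of 0.5*||f||^2
    gnorm <- sqrt(sum(g^2))
    p_newton <- tryCatch(-solve(J, f), error = function(e) NULL)
    if (gnorm < 1e-300) break
    Jg <- drop(J %*% g)
    alpha <- gnorm^2 / max(sum(Jg^2), 1e-300)
    p_cauchy <- -alpha * g
    step <- if (!is.null(p_newton) && sqrt(sum(p_newton^2)) <= delta) {
      p_newton
    } else if (sqrt(sum(p_cauchy^2)) >= delta) {
      -(delta / gnorm) * g
    } else if (is.null(p_newton)) {
      p_cauchy
    } else {
      # blend along the dog leg to the trust boundary
      d <- p_newton - p_cauchy
      a <- sum(d^2)
      b <- 2 * sum(p_cauchy * d)
      cc <- sum(p_cauchy^2) - delta^2
      tau <- (-b + sqrt(max(b^2 - 4 * a * cc, 0))) / (2 * a)
      p_cauchy + tau * d
    }
    f_new <- fn(x + step)
    if (any(!is.finite(f_new))) {
      delta <- delta / 4
      next
    }
    actual <- sum(f^2) - sum(f_new^2)
    pred <- sum(f^2) - sum((f + J %*% step)^2)
    rho <- if (pred > 0) actual / pred else -1
    if (rho > 1e-4) {
      x <- x + step
      f <- f_new
    }
    if (rho > 0.75 && sqrt(sum(step^2)) > 0.9 * delta) {
      delta <- min(2 * delta, 10)
    } else if (rho < 0.25) {
      delta <- max(delta / 4, 1e-12)
    }
    if (delta < 1e-11) break
  }
  list(x = x, fnorm = max(abs(f)), iterations = max_iter, converged = max(abs(f)) < ftol)
}

#' Constrained multi-start fallback for the hydraulic solve
#'
#' Minimizes `|r1| + |r2|` over leaf and xylem potentials subject to
#' `psi_s >= psi_x >= psi_l`, enforced by the parameterization
#' `psi_x = psi_s - u^2`, `psi_l = psi_x - v^2`. Nelder-Mead polishing from
#' `n_starts` seeded random starting points; the best point wins. Seeding
#' makes the fallback path bit-reproducible.
#'
#' @param resfun Residual function taking `c(psix, psil)`.
#' @param psis Soil water potential \[MPa\].
#' @param n_starts Number of random starts (default 100).
#' @param seed Integer seed for the start sampling.
#' @param span Maximum sampled potential drop per segment \[MPa\].
#' @param polish Number of best-ranked starts refined by Nelder-Mead.
#' @param extra_starts Optional matrix of additional `(psix, psil)` starts
#'   (one per row), e.g. the previous hour's solution as a warm start.
#' @return A list with `x = c(psix, psil)` and `objective`.
#' @export
fallback_multistart <- function(resfun, psis, n_starts = 100, seed = 1,
                                span = 6, polish = 2, extra_starts = NULL) {
  obj <- function(s) {
    psix <- psis - s[1]^2
    psil <- psix - s[2]^2
    sum(abs(resfun(c(psix, psil))))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  starts <- matrix(sqrt(runif(2 * n_starts, 0, span)), ncol = 2)
  starts[1, ] <- c(sqrt(0.05), sqrt(0.25))        # one deterministic start
  if (!is.null(extra_starts)) {
    u <- pmax(psis - extra_starts[, 1], 0)
    v <- pmax(extra_starts[, 1] - extra_starts[, 2], 0)
    starts <- rbind(cbind(sqrt(u), sqrt(v)), starts)
  }
  vals <- vapply(seq_len(nrow(starts)), function(i) obj(starts[i, ]), numeric(1))
  best <- NULL
  for (i in order(vals)[seq_len(min(polish, nrow(starts)))]) {
    fit <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 120, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-15) break
  }
  psix <- psis - best$par[1]^2
  list(x = c(psix, psix - best$par[2]^2), objective = best$value)
}

#' Brute-force grid oracle for the steady-state solve
#'
#' Exhaustive grid search over `(psi_x, psi_l)` at `fine` resolution
#' (default 1e-3 MPa), minimizing `|r1| + |r2|` subject to
#' `psi_s >= psi_x >= psi_l`. Used to validate [solve_steady()]; it shares
#' only the residual definition with the solver, not its iteration.
#'
#' @param resfun Vectorized residual function `resfun(psix, psil)`
#'   returning a list with components `r1` and `r2` of the same length as
#'   its inputs.
#' @param psis Soil water potential \[MPa\].
#' @param span Search depth below `psis` \[MPa\].
#' @param fine Grid resolution \[MPa\].
#' @param tfun Optional transpiration-demand function of leaf potential.
#'   When the system has several equilibria (the vulnerability curves make
#'   the supply curve non-monotone), every grid point whose residual is
#'   below 1% of the local flux qualifies as a root, and the physical
#'   branch -- the highest leaf potential, reached by continuity from wet
#'   conditions -- is selected among them.
#' @return A list with `x = c(psix, psil)` and `objective`.
#' @export
grid_oracle <- function(resfun, psis, span = 8, fine = 1e-3, tfun = NULL) {
  psix_v <- seq(psis - span, psis, by = fine)
  psil_v <- psix_v
  best_val <- rep(Inf, length(psil_v))
  best_psix <- rep(NA_real_, length(psil_v))
  for (j in seq_along(psil_v)) {
    pl <- psil_v[j]
    px <- psix_v[psix_v >= pl]
    r <- resfun(px, rep(pl, length(px)))
    val <- abs(r$r1) + abs(r$r2)
    i <- which.min(val)
    best_val[j] <- val[i]
    best_psix[j] <- px[i]
  }
  pick <- which.min(best_val)
  if (!is.null(tfun)) {
    is_root <- which(best_val <= 0.01 * pmax(tfun(psil_v), 1e-12))
    if (length(is_root)) {
      # the solution is the highest leaf potential at which both equations
      # hold to within 1% of the local flux (the model's accuracy standard,
      # on the branch reached by continuity from wet conditions)
      pick <- max(is_root)
    }
  }
  x <- c(best_psix[pick], psil_v[pick])
  r <- resfun(x[1], x[2])
  list(x = x, objective = abs(r$r1) + abs(r$r2))
}
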