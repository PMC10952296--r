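#' Initialize an age-structured tissue cohort set
#'
#' Cohorts discretize the age distribution of conducting tissue (xylem or
#' leaves) into classes of equal width, each carrying the minimum water
#' potential it has experienced. New tissue starts undamaged
#' (`psimin = 0`, i.e. born at full conductance and full of water). The
#' default initial distribution is the steady state implied by constant
#' turnover: a truncated exponential in age.
#'
#' @param n_classes Number of age classes (>= 1).
#' @param max_age Oldest representable age \[days\].
#' @param distribution `"exponential"` (truncated, steady-state under
#'   constant turnover) or `"uniform"`.
#' @param turnover Turnover rate \[day-1\] defining the exponential shape;
#'   defaults to `3 / max_age`.
#' @param tissue `"xylem"` or `"leaf"` (bookkeeping tag).
#' @return An object of class `cohort_set` with fields `age` (class
#'   midpoints, days), `width`, `p` (density, sums to 1) and `psimin`.
#' @export
#' @examples
#' init_cohorts(10, max_age = 100, distribution = "uniform")
init_cohorts <- function(n_classes, max_age,
                         distribution = c("exponential", "uniform"),
                         turnover = NULL, tissue = "xylem") {
  stopifnot(n_classes >= 1, max_age > 0)
  distribution <- match.arg(distribution)
  width <- max_age / n_classes
  age <- (seq_len(n_classes) - 0.5) * width
  p <- switch(distribution,
    uniform = rep(1 / n_classes, n_classes),
    exponential = {
      mu <- if (is.null(turnover)) 3 / max_age else turnover
      if (mu < 0) stop("turnover must be >= 0", call. = FALSE)
      w <- exp(-mu * age)
      w / sum(w)
    }
  )
  if (any(!is.finite(p)) || abs(sum(p) - 1) > 1e-12) {
    stop("initial age distribution is not normalizable", call. = FALSE)
  }
  structure(
    list(age = age, width = width, p = p,
         psimin = rep(0, n_classes), tissue = tissue),
    class = "cohort_set"
  )
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("<cohort_set> ", x$tissue, ", ", length(x$p), " classes x ",
      signif(x$width, 3), " d; min(psimin) = ", signif(min(x$psimin), 3),
      " MPa\n", sep = "")
  invisible(x)
}

#' Record the current water potential in the cohort memory
#'
#' Every living class keeps the running minimum of the potential it has
#' experienced: `psimin_i <- min(psimin_i, psi_now)`. Idempotent for a
#' repeated value; a recovering potential leaves the memory unchanged (no
#' refilling).
#'
#' @param cohorts A [init_cohorts()] object.
#' @param psi_now Current tissue water potential \[MPa, <= 0\].
#' @return The updated `cohort_set`.
#' @export
update_min_potential <- function(cohorts, psi_now) {
  if (psi_now > 1e-9) stop("`psi_now` must be <= 0", call. = FALSE)
  cohorts$psimin <- pmin(cohorts$psimin, psi_now)
  cohorts
}

#' Effective conductance of a damaged cohort population
#'
#' Discrete form of the age integral: each class contributes the
#' conductance it had at its own minimum potential, weighted by its density
#' — `k = sum_i p_i kmax exp(-q |psimin_i|^p)`. Never exceeds `kmax`; with
#' no damage history it equals `kmax`.
#'
#' @param cohorts A [init_cohorts()] object.
#' @param traits A [plant_traits()] object; the tissue tag of `cohorts`
#'   selects the xylem or leaf vulnerability parameters.
#' @param psi_now Optional current potential \[MPa\]: when supplied, each
#'   class is evaluated at `min(psimin_i, psi_now)`, i.e. the current state
#'   may push conductance below the stored memory but never above it.
#' @return Effective conductance \[m s-1 MPa-1\].
#' @export
effective_conductivity <- function(cohorts, traits, psi_now = NULL) {
  if (cohorts$tissue == "xylem") {
    kmax <- traits$kxmax; q <- traits$qx; p <- traits$px
  } else {
    kmax <- traits$klmax; q <- traits$ql; p <- traits$pl
  }
  psi <- if (is.null(psi_now)) cohorts$psimin else pmin(cohorts$psimin, psi_now)
  sum(cohorts$p * .vuln(psi, kmax, q, p))
}

# Effective vulnerability curve over a vector of candidate current
# potentials; cohorts are first compressed to unique psimin values so the
# cost scales with the number of distinct damage states, not classes.
.effective_curve <- function(cohorts, kmax, q, p) {
  grp <- split(cohorts$p, cohorts$psimin)
  pm <- as.numeric(names(grp))
  wt <- vapply(grp, sum, numeric(1))
  function(psi) {
    out <- numeric(length(psi))
    for (i in seq_along(pm)) {
      out <- out + wt[i] * .vuln(pmin(psi, pm[i]), kmax, q, p)
    }
    out
  }
}

#' Advance cohort ages, turnover and recruitment
#'
#' Upwind advection of the age density by `dt` (an exact one-class shift
#' when `dt` equals the class width), removal of turnover mass from the
#' oldest occupied classes first, recruitment of new undamaged tissue at
#' age zero, and renormalization to a unit density. Removing damaged old
#' cohorts and recruiting undamaged tissue is the only way effective
#' conductance recovers.
#'
#' @param cohorts A [init_cohorts()] object.
#' @param lambda Recruitment rate \[fraction day-1\] (>= 0).
#' @param mu Turnover rate \[fraction day-1\] (>= 0).
#' @param dt Time step \[days\]; must not exceed the class width.
#' @return The updated `cohort_set`.
#' @export
advance_cohorts <- function(cohorts, lambda = 0, mu = 0, dt = cohorts$width) {
  stopifnot(lambda >= 0, mu >= 0, dt > 0)
  if (dt > cohorts$width + 1e-12) {
    stop("dt must not exceed the cohort class width", call. = FALSE)
  }
  n <- length(cohorts$p)
  p <- cohorts$p
  psimin <- cohorts$psimin

  # turnover first: oldest tissues die before the ageing shift merges
  # younger mass into the truncation class, so dying cohorts cannot taint
  # the memory of their successors
  demand <- mu * dt
  if (demand > sum(p) + 1e-12) {
    stop("turnover demand exceeds total tissue mass", call. = FALSE)
  }
  i <- n
  while (demand > 1e-300 && i >= 1) {
    take <- min(p[i], demand)
    p[i] <- p[i] - take
    demand <- demand - take
    i <- i - 1
  }
  psimin[p <= 1e-300] <- 0  # an empty class carries no memory

  # ageing: shift a fraction f of each class into the next; mass reaching
  # the end of the oldest class stays there (truncation)
  f <- dt / cohorts$width
  if (f >= 1 - 1e-12 && n > 1) {
    # exact one-class shift: memories travel with their mass; the oldest
    # class absorbs its predecessor and keeps the more damaged memory
    psimin_new <- c(psimin[1], psimin[-n])
    psimin_new[n] <- min(psimin[n], psimin[n - 1])
    p_new <- c(0, p[-n])
    p_new[n] <- p[n] + p[n - 1]
    p <- p_new
    psimin <- psimin_new
  } else if (f > 1e-12 && n > 1) {
    inflow <- c(0, p[-n] * f)
    p_new <- p * (1 - f) + inflow
    p_new[n] <- p[n] + inflow[n]
    # partial shifts mix mass between classes; a receiving class keeps the
    # more damaged (more negative) memory so irreversibility holds
    psimin_new <- psimin
    recv <- inflow > 0
    psimin_new[recv] <- pmin(psimin[recv], c(0, psimin[-n])[recv])
    p <- p_new
    psimin <- psimin_new
  }

  # recruitment: new tissue at age zero, born undamaged and full of water.
  # With dt = class width the ageing shift empties class 1, so recruits get
  # a clean psimin = 0; if survivors share the class, their (more damaged)
  # memory is kept for the whole class -- the conservative choice.
  born <- lambda * dt
  if (born > 0) {
    if (p[1] <= 1e-300) psimin[1] <- 0
    p[1] <- p[1] + born
  }

  tot <- sum(p)
  if (tot <= 0) stop("cohort population emptied", call. = FALSE)
  cohorts$p <- p / tot
  cohorts$psimin <- psimin
  cohorts
}
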