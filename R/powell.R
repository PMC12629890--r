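#' Powell's derivative-free minimiser with box bounds
#'
#' Classic direction-set method (sequential univariate line searches with
#' the Powell direction-replacement heuristic), chosen for robustness on
#' non-differentiable objectives such as the inclusion-disagreement
#' co-alignment cost, whose indicator term makes gradients useless.  Line
#' searches use golden-section/parabolic interpolation ([stats::optimize()])
#' restricted to the segment of the search line inside the box.
#'
#' @param fn objective, a function of a numeric vector.
#' @param p0 start point (must lie inside the box).
#' @param lower,upper box bounds, same length as `p0`.
#' @param ptol parameter tolerance: convergence when no coordinate moved
#'   more than this in a full sweep.
#' @param ftol relative function tolerance.
#' @param maxeval maximum number of objective evaluations.
#' @param maxiter maximum number of direction-set sweeps.
#' @return List with `par`, `value`, `n_evaluations`, `iterations` and
#'   `converged`.
#' @export
powell_minimize <- function(fn, p0, lower, upper, ptol = 1e-4, ftol = 1e-8,
                            maxeval = 1e4, maxiter = 100) {
  n <- length(p0)
  stopifnot(length(lower) == n, length(upper) == n,
            all(lower <= upper), all(p0 >= lower - 1e-12), all(p0 <= upper + 1e-12))
  p0 <- pmin(pmax(p0, lower), upper)
  nev <- 0L
  budget_hit <- FALSE
  f <- function(x) {
    nev <<- nev + 1L
    if (nev > maxeval) budget_hit <<- TRUE
    fn(x)
  }

  line_search <- function(p, d, fp) {
    tlo <- -Inf
    thi <- Inf
    for (i in seq_len(n)) {
      if (abs(d[i]) > 1e-15) {
        t1 <- (lower[i] - p[i]) / d[i]
        t2 <- (upper[i] - p[i]) / d[i]
        tlo <- max(tlo, min(t1, t2))
        thi <- min(thi, max(t1, t2))
      }
    }
    if (!is.finite(tlo) || !is.finite(thi) || thi - tlo < 1e-12) {
      return(list(t = 0, f = fp))
    }
    opt <- optimize(function(t) f(pmin(pmax(p + t * d, lower), upper)),
                    c(tlo, thi), tol = max(ptol / 2, 1e-6))
    if (opt$objective < fp) list(t = opt$minimum, f = opt$objective)
    else list(t = 0, f = fp)
  }

  dirs <- diag(n)
  p <- p0
  fp <- f(p)
  iter <- 0L
  converged <- FALSE
  while (iter < maxiter && !budget_hit) {
    iter <- iter + 1L
    p_start <- p
    f_start <- fp
    delta <- 0
    ibig <- 1L
    for (i in seq_len(n)) {
      ls <- line_search(p, dirs[, i], fp)
      dec <- fp - ls$f
      if (dec > delta) {
        delta <- dec
        ibig <- i
      }
      p <- pmin(pmax(p + ls$t * dirs[, i], lower), upper)
      fp <- ls$f
      if (budget_hit) break
    }
    if (budget_hit) break
    if (2 * (f_start - fp) <= ftol * (abs(f_start) + abs(fp)) + 1e-20 ||
        max(abs(p - p_start)) < ptol) {
      converged <- TRUE
      break
    }
    # Powell extrapolation and direction replacement (Numerical-Recipes form)
    pe <- pmin(pmax(2 * p - p_start, lower), upper)
    fe <- f(pe)
    if (fe < f_start) {
      tmp <- 2 * (f_start - 2 * fp + fe) * (f_start - fp - delta)^2 -
        delta * (f_start - fe)^2
      if (tmp < 0) {
        dnew <- p - p_start
        nrm <- sqrt(sum(dnew^2))
        if (nrm > 1e-14) {
          dnew <- dnew / nrm
          ls <- line_search(p, dnew, fp)
          p <- pmin(pmax(p + ls$t * dnew, lower), upper)
          fp <- ls$f
          dirs[, ibig] <- dirs[, n]
          dirs[, n] <- dnew
        }
      }
    }
  }
  list(par = p, value = fp, n_evaluations = nev, iterations = iter,
       converged = converged)
}
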