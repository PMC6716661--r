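#' Control parameters for the simulated-annealing minimizer
#'
#' The annealer proposes moves `x + r * V` with `r ~ U(-1, 1)` per
#' coordinate, accepts uphill moves with probability `exp(-dg / k)`, rescales
#' the step vector `V` every `s` iterations so that roughly half of all
#' moves are accepted, and cools the control parameter (temperature) as
#' `k <- rk * k` every `m` iterations.  The run stops when `k` falls below
#' `k_min`, when the same solution is retained for `stop_repeat` successive
#' iterations, or after `max_iter` iterations.
#'
#' @param k0 Initial temperature.  `NULL` (default) uses
#'   `max(1, log(|g(x0)|))`, guarded so it stays positive when the objective
#'   at the start is at most 1.
#' @param rk Cooling rate in `[0, 1]`; default 0.95.
#' @param m Iterations per temperature stage.
#' @param s Iterations between step-vector adaptations.
#' @param step Positive step size(s), recycled to the problem dimension.
#' @param max_iter Iteration budget.
#' @param stop_repeat Length of the identical-solution streak that stops the
#'   run early.
#' @param k_min Temperature below which the run stops.  The stopping
#'   temperature is a tuning constant with no canonical value; it is exposed
#'   here rather than hard-wired.
#' @param seed Optional integer seed for a reproducible trajectory.
#' @param trace Logical; record the best objective value per temperature
#'   stage.
#' @return A list of class `sann_control`.
#' @export
sann_control <- function(k0 = NULL, rk = 0.95, m = 100L, s = 20L, step = 1,
                         max_iter = 20000L, stop_repeat = 500L,
                         k_min = 1e-8, seed = NULL, trace = FALSE) {
  stopifnot(rk >= 0, rk <= 1, m >= 1, s >= 1, max_iter >= 1,
            stop_repeat >= 1, all(step > 0), k_min > 0)
  structure(
    list(k0 = k0, rk = rk, m = as.integer(m), s = as.integer(s), step = step,
         max_iter = as.integer(max_iter), stop_repeat = as.integer(stop_repeat),
         k_min = k_min, seed = seed, trace = isTRUE(trace)),
    class = "sann_control"
  )
}

#' Minimize a function by simulated annealing
#'
#' A stochastic global minimizer robust to local extrema and poor starting
#' values.  Non-finite proposals are rejected (treated as infinitely uphill),
#' so hard constraints can be imposed by returning `Inf` from the objective.
#' The returned solution is the best point ever visited, not merely the
#' final one.
#'
#' @param objective Function of a numeric vector returning a scalar; must be
#'   finite at `x0`.
#' @param x0 Numeric starting vector.
#' @param control A [sann_control()] object.
#' @return A list of class `sann_result` with elements `x_opt`, `f_opt`,
#'   `n_iter`, `accepted_frac` and (if requested) `trace`, a tibble of
#'   `(iteration, best_f)` pairs.
#' @examples
#' res <- sann_minimize(function(x) (x - 2)^2, 10,
#'                      sann_control(max_iter = 5000, seed = 1))
#' res$x_opt
#' @export
sann_minimize <- function(objective, x0, control = sann_control()) {
  if (!inherits(control, "sann_control")) {
    abort("`control` must be created by sann_control().",
          class = "ggfit_error_input")
  }
  if (!is.null(control$seed)) set.seed(control$seed)
  d <- length(x0)
  f0 <- objective(x0)
  if (!is.finite(f0)) {
    abort("The objective is not finite at the starting point.",
          class = "ggfit_error_domain")
  }
  k <- control$k0 %||% max(1, log(max(abs(f0), 1)))
  V <- rep_len(control$step, d)
  x <- x0
  fx <- f0
  x_best <- x0
  f_best <- f0
  n_acc_total <- 0L
  n_acc_window <- 0L
  streak <- 0L
  it <- 0L
  tr_it <- integer(0)
  tr_f <- numeric(0)
  while (it < control$max_iter && k > control$k_min &&
         streak < control$stop_repeat) {
    it <- it + 1L
    xp <- x + runif(d, -1, 1) * V
    fp <- objective(xp)
    dg <- fp - fx
    accept <- is.finite(fp) && (dg <= 0 || runif(1) < exp(-dg / k))
    if (accept) {
      x <- xp
      fx <- fp
      n_acc_total <- n_acc_total + 1L
      n_acc_window <- n_acc_window + 1L
      streak <- 0L
      if (fx < f_best) {
        f_best <- fx
        x_best <- x
      }
    } else {
      streak <- streak + 1L
    }
    if (it %% control$s == 0L) {
      rate <- n_acc_window / control$s
      if (rate > 0.6) {
        V <- V * (1 + 2 * (rate - 0.6))
      } else if (rate < 0.4) {
        V <- V / (1 + 2 * (0.4 - rate))
      }
      n_acc_window <- 0L
    }
    if (it %% control$m == 0L) {
      k <- control$rk * k
      if (control$trace) {
        tr_it <- c(tr_it, it)
        tr_f <- c(tr_f, f_best)
      }
    }
  }
  out <- list(
    x_opt = x_best,
    f_opt = f_best,
    n_iter = it,
    accepted_frac = if (it > 0) n_acc_total / it else 0,
    f0 = f0
  )
  if (control$trace) out$trace <- tibble(iteration = tr_it, best_f = tr_f)
  class(out) <- "sann_result"
  out
}

#' @export
print.sann_result <- function(x, ...) {
  cat("Simulated annealing result\n")
  cat("  f_opt:", format(x$f_opt), "after", x$n_iter, "iterations\n")
  cat("  x_opt:", paste(format(x$x_opt, digits = 6), collapse = ", "), "\n")
  cat("  acceptance fraction:", format(x$accepted_frac, digits = 3), "\n")
  invisible(x)
}
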