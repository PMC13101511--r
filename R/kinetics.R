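#' Kinetic parameters of the branched first-order model
#'
#' Constructs and validates the parameter vector of the two-pool branched
#' first-order model
#' \deqn{dS/dt = -k_{tot} S, \qquad dP/dt = f k_{tot} S - k_2 P,}
#' where \eqn{S} is the parent concentration (mg/L), \eqn{P} the intermediate
#' concentration (mg/L), \eqn{k_{tot}} the total parent degradation rate
#' constant (1/d), \eqn{f} the dimensionless branching fraction of parent flux
#' channelled into the intermediate, and \eqn{k_2} the intermediate
#' degradation rate constant (1/d). The effective intermediate formation rate
#' constant is \eqn{k_a = f\,k_{tot}}.
#'
#' @param k_tot Total parent degradation rate constant, 1/d. Must be > 0.
#' @param f Branching fraction in \[0, 1\].
#' @param k2 Intermediate degradation rate constant, 1/d. Must be >= 0.
#' @param S0 Initial parent concentration, mg/L. Must be >= 0.
#' @param P0 Initial intermediate concentration, mg/L. Must be >= 0.
#'   Defaults to 0: degradation cultures start without intermediate.
#'
#' @return An object of class \code{kinetic_params}: a named list with the
#'   five fields above plus the derived \code{k_a = f * k_tot}.
#' @examples
#' p <- kinetic_params(k_tot = 0.142, f = 0.4437, k2 = 0.150, S0 = 60)
#' p$k_a
#' @export
kinetic_params <- function(k_tot, f, k2, S0, P0 = 0) {
  vals <- c(k_tot = k_tot, f = f, k2 = k2, S0 = S0, P0 = P0)
  if (!all(is.finite(vals))) {
    stop("kinetic_params: all parameters must be finite numbers, got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (k_tot <= 0) stop("kinetic_params: k_tot must be > 0 (got ", k_tot, ")")
  if (k2 < 0) stop("kinetic_params: k2 must be >= 0 (got ", k2, ")")
  if (f < 0 || f > 1) stop("kinetic_params: f must lie in [0, 1] (got ", f, ")")
  if (S0 < 0) stop("kinetic_params: S0 must be >= 0 (got ", S0, ")")
  if (P0 < 0) stop("kinetic_params: P0 must be >= 0 (got ", P0, ")")
  structure(
    list(k_tot = k_tot, f = f, k2 = k2, S0 = S0, P0 = P0, k_a = f * k_tot),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Branched first-order kinetic parameters\n")
  cat(sprintf("  k_tot = %g 1/d   (parent degradation)\n", x$k_tot))
  cat(sprintf("  f     = %g       (branching fraction)\n", x$f))
  cat(sprintf("  k_a   = %g 1/d   (intermediate formation, f * k_tot)\n", x$k_a))
  cat(sprintf("  k2    = %g 1/d   (intermediate degradation)\n", x$k2))
  cat(sprintf("  S0    = %g mg/L  P0 = %g mg/L\n", x$S0, x$P0))
  invisible(x)
}

# Rate-degeneracy threshold for switching to the equal-rate limit formula.
# The Bateman branch is evaluated through expm1 and is cancellation-stable,
# so the switch only guards the removable 0/0 at k2 == k_tot; the limit
# formula's own error, O(|k2 - k_tot| t^2), is negligible below this gap.
.DEGENERATE_EPS <- 1e-12

# Concentrations in (-1e-12, 0) are float noise and clipped to 0; anything
# more negative indicates a bug and raises.
.clip_nonneg <- function(x, what) {
  bad <- x < -1e-12
  if (any(bad)) {
    stop(what, ": negative concentration beyond numerical noise (min ",
         min(x), ")")
  }
  pmax(x, 0)
}

.check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0 || !all(is.finite(times))) {
    stop("times must be a non-empty finite numeric vector")
  }
  if (any(times < 0)) stop("times must be >= 0 (days)")
  invisible(times)
}

.as_params <- function(params) {
  if (!inherits(params, "kinetic_params")) {
    stop("expected a 'kinetic_params' object; see kinetic_params()")
  }
  params
}

#' Closed-form (Bateman) solution of the branched model
#'
#' Evaluates the analytic solution of the coupled first-order system at the
#' requested times: \eqn{S(t) = S_0 e^{-k_{tot} t}} and, for
#' \eqn{k_2 \neq k_{tot}},
#' \deqn{P(t) = P_0 e^{-k_2 t} + \frac{f k_{tot} S_0}{k_2 - k_{tot}}
#'   \left(e^{-k_{tot} t} - e^{-k_2 t}\right),}
#' with the analytic limit
#' \eqn{P(t) = P_0 e^{-k_{tot} t} + f k_{tot} S_0\, t\, e^{-k_{tot} t}}
#' when \eqn{|k_2 - k_{tot}|} falls below 1e-12 1/d (the Bateman branch is
#' evaluated through \code{expm1} and is stable arbitrarily close to the
#' equal-rate point; the switch only guards the removable singularity).
#'
#' @param params A \code{\link{kinetic_params}} object.
#' @param times Numeric vector of times in days, all >= 0.
#' @return A \code{state_trajectory}: data.frame with columns \code{time},
#'   \code{S} (parent, mg/L) and \code{P} (intermediate, mg/L).
#' @seealso \code{\link{solve_numeric}} for the ODE-integrator cross-check.
#' @examples
#' p <- kinetic_params(0.142, 0.4437, 0.150, 60)
#' closed_form_solution(p, times = c(0, 7, 15))
#' @export
closed_form_solution <- function(params, times) {
  params <- .as_params(params)
  .check_times(times)
  S <- params$S0 * exp(-params$k_tot * times)
  dk <- params$k2 - params$k_tot
  if (abs(dk) > .DEGENERATE_EPS) {
    # exp(-k_tot t) - exp(-k2 t) = -exp(-k_tot t) * expm1(-dk t):
    # stable against cancellation when the two rates are close
    P <- params$P0 * exp(-params$k2 * times) -
      (params$f * params$k_tot * params$S0 / dk) *
        exp(-params$k_tot * times) * expm1(-dk * times)
  } else {
    P <- params$P0 * exp(-params$k_tot * times) +
      params$f * params$k_tot * params$S0 * times * exp(-params$k_tot * times)
  }
  out <- data.frame(time = times,
                    S = .clip_nonneg(S, "closed_form_solution"),
                    P = .clip_nonneg(P, "closed_form_solution"))
  class(out) <- c("state_trajectory", "data.frame")
  out
}

#' Numerical solution of the branched model by adaptive ODE integration
#'
#' Integrates the coupled right-hand sides \code{dS/dt = -k_tot * S} and
#' \code{dP/dt = f * k_tot * S - k2 * P} with \code{deSolve::ode} (lsoda,
#' adaptive step). Serves as the internal cross-check oracle for
#' \code{\link{closed_form_solution}}.
#'
#' @inheritParams closed_form_solution
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return A \code{state_trajectory} data.frame (\code{time}, \code{S},
#'   \code{P}).
#' @export
solve_numeric <- function(params, times, rtol = 1e-12, atol = 1e-12) {
  params <- .as_params(params)
  .check_times(times)
  t_u <- sort(unique(c(0, times)))
  rhs <- function(t, y, p) {
    list(c(-p$k_tot * y[1], p$f * p$k_tot * y[1] - p$k2 * y[2]))
  }
  sol <- try(deSolve::ode(
    y = c(S = params$S0, P = params$P0), times = t_u, func = rhs,
    parms = params, rtol = rtol, atol = atol
  ), silent = TRUE)
  if (inherits(sol, "try-error")) {
    stop("solve_numeric: ODE integration failed: ", attr(sol, "condition")$message)
  }
  if (any(!is.finite(sol[, c("S", "P")]))) {
    diag <- attr(sol, "istate")
    stop("solve_numeric: integrator returned non-finite state (istate = ",
         paste(diag, collapse = ","), ")")
  }
  idx <- match(times, sol[, "time"])
  out <- data.frame(time = times,
                    S = .clip_nonneg(sol[idx, "S"], "solve_numeric"),
                    P = .clip_nonneg(sol[idx, "P"], "solve_numeric"))
  class(out) <- c("state_trajectory", "data.frame")
  out
}

#' First-order half-life
#'
#' Time for a first-order-decaying concentration to halve: \code{log(2) / k}.
#'
#' @param k First-order rate constant, 1/d. Must be > 0.
#' @return Half-life in days.
#' @examples
#' half_life(0.142) # about 4.88 days
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("half_life: rate constant k must be finite and > 0")
  }
  log(2) / k
}

#' Effective intermediate formation rate constant
#'
#' \code{k_a = f * k_tot}: the portion of the total parent degradation rate
#' routed into the tracked intermediate.
#'
#' @param f Branching fraction in \[0, 1\].
#' @param k_tot Total parent degradation rate constant, 1/d (> 0).
#' @return \code{f * k_tot}, in 1/d.
#' @export
formation_rate_constant <- function(f, k_tot) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("formation_rate_constant: f must lie in [0, 1]")
  }
  if (!is.numeric(k_tot) || any(!is.finite(k_tot)) || any(k_tot <= 0)) {
    stop("formation_rate_constant: k_tot must be > 0")
  }
  f * k_tot
}

#' Time and height of the intermediate concentration peak
#'
#' For \code{P0 = 0} the Bateman intermediate rises to a single maximum at
#' \deqn{t_{peak} = \frac{\ln(k_2 / k_{tot})}{k_2 - k_{tot}}}
#' (equal-rate limit \eqn{1/k_{tot}}), independent of \code{f} and \code{S0},
#' then declines. At the returned time \eqn{dP/dt = 0}.
#'
#' @param params A \code{\link{kinetic_params}} object with \code{f > 0},
#'   \code{S0 > 0}, \code{P0 = 0} and \code{k2 > 0}.
#' @return A list with \code{peak_time} (days) and \code{peak_conc} (mg/L).
#' @export
intermediate_peak <- function(params) {
  params <- .as_params(params)
  if (params$f == 0) stop("intermediate_peak: no intermediate formed (f = 0)")
  if (params$S0 <= 0) stop("intermediate_peak: S0 must be > 0")
  if (params$P0 != 0) stop("intermediate_peak: requires P0 = 0")
  if (params$k2 <= 0) stop("intermediate_peak: requires k2 > 0")
  dk <- params$k2 - params$k_tot
  t_peak <- if (abs(dk) > .DEGENERATE_EPS) log(params$k2 / params$k_tot) / dk
            else 1 / params$k_tot
  traj <- closed_form_solution(params, t_peak)
  list(peak_time = t_peak, peak_conc = traj$P[1])
}
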