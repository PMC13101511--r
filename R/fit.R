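# Model predictions for each observation row of a tidy table.
.predict_rows <- function(params, df) {
  traj <- closed_form_solution(params, df$time)
  ifelse(df$compound == "parent", traj$S, traj$P)
}

# theta <-> params transforms: rates on log scale, f on logit scale.
# Enforces k_tot > 0, k2 > 0, 0 < f < 1 without hard optimizer bounds.
.theta_to_params <- function(theta, fix_S0 = NULL, P0 = 0) {
  S0 <- if (is.null(fix_S0)) exp(theta[["log_S0"]]) else fix_S0
  kinetic_params(
    k_tot = exp(theta[["log_k_tot"]]),
    f = stats::plogis(theta[["logit_f"]]),
    k2 = exp(theta[["log_k2"]]),
    S0 = S0, P0 = P0
  )
}

# Data-driven starting values: k_tot from a log-linear regression of the
# positive parent concentrations on time; S0 from the earliest parent mean.
.default_init <- function(df) {
  par_rows <- df[df$compound == "parent" & df$conc > 0, , drop = FALSE]
  k0 <- 1e-10
  if (nrow(par_rows) >= 2 && length(unique(par_rows$time)) >= 2) {
    sl <- stats::coef(stats::lm(log(par_rows$conc) ~ par_rows$time))[[2]]
    k0 <- max(-sl, 1e-10)
  }
  t0 <- min(df$time[df$compound == "parent"])
  S0 <- mean(df$conc[df$compound == "parent" & df$time == t0], na.rm = TRUE)
  if (!is.finite(S0) || S0 <= 0) S0 <- max(df$conc, na.rm = TRUE)
  kinetic_params(k_tot = k0, f = 0.5, k2 = k0, S0 = S0)
}

.run_nls_lm <- function(resid_fun, theta0) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     gtol = 0, maxiter = 500)
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun, control = ctrl)
  if (!fit$info %in% 1:4) {
    stop("nonlinear least squares did not converge (info = ", fit$info,
         ": ", fit$message, ")")
  }
  fit
}

.series_sigma <- function(res, compound) {
  vapply(c("parent", "intermediate"), function(cmp) {
    r <- res[compound == cmp]
    if (length(r) == 0) return(NA_real_)
    sqrt(mean(r^2))
  }, numeric(1))
}

.pooled_r_squared <- function(obs, pred, compound) {
  ssr <- sum((obs - pred)^2)
  sst <- sum(unlist(lapply(unique(compound), function(cmp) {
    y <- obs[compound == cmp]
    (y - mean(y))^2
  })))
  if (sst == 0) stop("R-squared undefined: zero total sum of squares ",
                     "(all observations identical within each series)")
  1 - ssr / sst
}

.per_series_r2 <- function(obs, pred, compound) {
  vapply(c("parent", "intermediate"), function(cmp) {
    sel <- compound == cmp
    if (!any(sel)) return(NA_real_)
    y <- obs[sel]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y - pred[sel])^2) / sst
  }, numeric(1))
}

#' Globally fit the branched first-order model
#'
#' Minimises the pooled sum of squared residuals of the parent and
#' intermediate series against the closed-form branched model, by
#' Levenberg-Marquardt nonlinear least squares. Rates are optimised on the
#' log scale and the branching fraction on the logit scale, so the
#' constraints \code{k_tot > 0}, \code{k2 > 0}, \code{0 < f < 1} hold by
#' construction. The fit is deterministic given the data and options, and
#' invariant to the row order of the input table.
#'
#' @param data A \code{\link{time_course_data}} object containing both a
#'   \code{parent} and an \code{intermediate} series.
#' @param init Optional \code{\link{kinetic_params}} starting point. Default:
#'   \code{k_tot} from a log-linear regression on the parent series,
#'   \code{f = 0.5}, \code{k2 = k_tot}, \code{S0} = earliest parent mean.
#' @param fix_S0 If \code{TRUE}, fix the initial parent concentration at
#'   \code{nominal_S0} instead of estimating it.
#' @param nominal_S0 Value used when \code{fix_S0 = TRUE} (defaults to the
#'   data-driven initial estimate).
#' @param weighting \code{"none"} (raw mg/L residuals, the default) or
#'   \code{"inv_var"} (one reweighting pass with per-series inverse-variance
#'   weights from an initial unweighted fit).
#' @param lod_policy How censored observations enter the objective:
#'   \code{"exclude"} (default) or \code{"half_lod"} (substitute LOD/2).
#' @return A \code{fit_result} object: list with \code{params_hat}
#'   (\code{kinetic_params}, including \code{k_a}), \code{k_a_hat},
#'   \code{residuals} (observed - predicted, mg/L, in canonical row order),
#'   \code{r_squared} (pooled), \code{r_squared_by_series},
#'   \code{sigma_hat} (per-series residual SD, mg/L), \code{converged},
#'   \code{n_obs}, \code{objective_value}, and the fitting options.
#' @examples
#' p <- kinetic_params(0.142, 0.4437, 0.150, 60)
#' d <- simulate_timecourse(p, design_spec(noise_sigma_parent = 0,
#'                                         noise_sigma_intermediate = 0))
#' fit_branched_model(d)$params_hat
#' @export
fit_branched_model <- function(data, init = NULL, fix_S0 = FALSE,
                               nominal_S0 = NULL,
                               weighting = c("none", "inv_var"),
                               lod_policy = c("exclude", "half_lod")) {
  weighting <- match.arg(weighting)
  lod_policy <- match.arg(lod_policy)
  data <- time_course_data(as.data.frame(data))
  df <- .usable_rows(data, lod_policy)
  for (cmp in c("parent", "intermediate")) {
    sel <- df$compound == cmp
    if (!any(sel)) {
      stop("fit_branched_model: the ", cmp,
           " series has no usable observations (all censored or absent)")
    }
    if (length(unique(df$time[sel])) < 3) {
      stop("fit_branched_model: need >= 3 distinct time points for the ",
           cmp, " series")
    }
  }
  if (nrow(df) < 4) {
    stop("fit_branched_model: need at least 4 usable observations, have ",
         nrow(df))
  }
  if (is.null(init)) init <- .default_init(df)
  init <- .as_params(init)
  S0_fixed <- if (fix_S0) {
    if (is.null(nominal_S0)) init$S0 else nominal_S0
  } else NULL
  theta0 <- c(log_k_tot = log(init$k_tot),
              logit_f = stats::qlogis(min(max(init$f, 1e-6), 1 - 1e-6)),
              log_k2 = log(max(init$k2, 1e-10)))
  if (!fix_S0) theta0 <- c(theta0, log_S0 = log(init$S0))

  w <- rep(1, nrow(df))
  do_fit <- function(w) {
    resid_fun <- function(theta) {
      p <- .theta_to_params(theta, fix_S0 = S0_fixed)
      sqrt(w) * (df$conc - .predict_rows(p, df))
    }
    .run_nls_lm(resid_fun, theta0)
  }
  fit <- do_fit(w)
  if (weighting == "inv_var") {
    p1 <- .theta_to_params(fit$par, fix_S0 = S0_fixed)
    sig <- .series_sigma(df$conc - .predict_rows(p1, df), df$compound)
    sig[!is.finite(sig) | sig <= 0] <- 1
    w <- 1 / sig[df$compound]^2
    fit <- do_fit(w)
  }
  params_hat <- .theta_to_params(fit$par, fix_S0 = S0_fixed)
  pred <- .predict_rows(params_hat, df)
  res <- df$conc - pred
  structure(list(
    model = "branched",
    params_hat = params_hat,
    k_a_hat = params_hat$f * params_hat$k_tot,
    residuals = res,
    fitted = pred,
    data_used = df,
    r_squared = .pooled_r_squared(df$conc, pred, df$compound),
    r_squared_by_series = .per_series_r2(df$conc, pred, df$compound),
    sigma_hat = .series_sigma(res, df$compound),
    converged = fit$info %in% 1:4,
    n_obs = nrow(df),
    objective_value = sum((sqrt(w) * res)^2),
    weights = w,
    options = list(fix_S0 = fix_S0, nominal_S0 = S0_fixed,
                   weighting = weighting, lod_policy = lod_policy)
  ), class = "fit_result")
}

#' Fit a single-compound first-order decay
#'
#' Least-squares fit of \code{S(t) = S0 * exp(-k * t)} to a parent-only
#' series, for single-substrate degradation summaries.
#'
#' @inheritParams fit_branched_model
#' @return A \code{fit_result} with \code{model = "single"}; the decay rate
#'   is reported as \code{params_hat$k_tot}.
#' @export
fit_single_first_order <- function(data, init = NULL,
                                   lod_policy = c("exclude", "half_lod")) {
  lod_policy <- match.arg(lod_policy)
  data <- time_course_data(as.data.frame(data))
  df <- .usable_rows(data, lod_policy)
  df <- df[df$compound == "parent", , drop = FALSE]
  if (nrow(df) == 0) {
    stop("fit_single_first_order: parent series has no usable observations")
  }
  if (length(unique(df$time)) < 3 || nrow(df) < 4) {
    stop("fit_single_first_order: need >= 3 distinct times and >= 4 observations")
  }
  if (is.null(init)) init <- .default_init(df)
  theta0 <- c(log_k = log(max(init$k_tot, 1e-10)), log_S0 = log(init$S0))
  resid_fun <- function(theta) {
    df$conc - exp(theta[["log_S0"]]) * exp(-exp(theta[["log_k"]]) * df$time)
  }
  fit <- .run_nls_lm(resid_fun, theta0)
  k_hat <- exp(fit$par[["log_k"]])
  S0_hat <- exp(fit$par[["log_S0"]])
  pred <- S0_hat * exp(-k_hat * df$time)
  res <- df$conc - pred
  sst <- sum((df$conc - mean(df$conc))^2)
  structure(list(
    model = "single",
    params_hat = kinetic_params(k_tot = k_hat, f = 0, k2 = 0, S0 = S0_hat),
    k_a_hat = 0,
    residuals = res,
    fitted = pred,
    data_used = df,
    r_squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
    r_squared_by_series = c(parent = if (sst > 0) 1 - sum(res^2) / sst
                                     else NA_real_,
                            intermediate = NA_real_),
    sigma_hat = c(parent = sqrt(mean(res^2)), intermediate = NA_real_),
    converged = fit$info %in% 1:4,
    n_obs = nrow(df),
    objective_value = sum(res^2),
    weights = rep(1, nrow(df)),
    options = list(lod_policy = lod_policy)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global %s first-order fit (%d observations)\n",
              x$model, x$n_obs))
  p <- x$params_hat
  cat(sprintf("  k_tot = %.4g 1/d (half-life %.3g d)\n",
              p$k_tot, half_life(p$k_tot)))
  if (x$model == "branched") {
    cat(sprintf("  f = %.4g   k_a = %.4g 1/d   k2 = %.4g 1/d\n",
                p$f, x$k_a_hat, p$k2))
  }
  cat(sprintf("  S0 = %.4g mg/L   pooled R^2 = %.4g   converged: %s\n",
              p$S0, x$r_squared, x$converged))
  invisible(x)
}

#' Pooled coefficient of determination of a fit
#'
#' Recomputes \eqn{R^2 = 1 - SSR/SST} for a fitted model against a dataset,
#' pooling squared residuals over both series and measuring SST as squared
#' deviations from each series' own mean (so a global fit of two series of
#' different magnitude is not dominated by the between-series spread).
#'
#' @param result A \code{fit_result}.
#' @param data A \code{\link{time_course_data}} object (defaults to the data
#'   the model was fitted to).
#' @return The pooled R-squared (<= 1).
#' @export
goodness_of_fit <- function(result, data = NULL) {
  if (!inherits(result, "fit_result")) stop("expected a 'fit_result'")
  df <- if (is.null(data)) result$data_used
        else .usable_rows(time_course_data(as.data.frame(data)),
                          result$options$lod_policy)
  if (result$model == "single") df <- df[df$compound == "parent", , drop = FALSE]
  pred <- if (result$model == "branched") .predict_rows(result$params_hat, df)
          else result$params_hat$S0 * exp(-result$params_hat$k_tot * df$time)
  .pooled_r_squared(df$conc, pred, df$compound)
}

#' Percentage of substrate degraded
#'
#' \code{100 * (initial - residual) / initial}, floored at 0 when the
#' residual concentration exceeds the initial (abiotic-control) value.
#'
#' @param initial Initial or abiotic-control concentration, mg/L (> 0).
#' @param residual Residual concentration, mg/L (>= 0).
#' @return Percent degraded in \[0, 100\].
#' @examples
#' percent_degraded(50, 2.45) # fluorene-style summary, ~95.1
#' @export
percent_degraded <- function(initial, residual) {
  if (!is.numeric(initial) || any(!is.finite(initial)) || any(initial <= 0)) {
    stop("percent_degraded: initial must be > 0")
  }
  if (!is.numeric(residual) || any(!is.finite(residual)) || any(residual < 0)) {
    stop("percent_degraded: residual must be >= 0")
  }
  pmax(0, 100 * (initial - residual) / initial)
}
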