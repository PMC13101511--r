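test_that("noiseless data reproduce the generating parameters exactly", {
  truth <- study_params()
  fit <- fit_branched_model(noiseless_data(truth))
  expect_true(fit$converged)
  for (par in c("k_tot", "f", "k2", "S0")) {
    expect_equal(fit$params_hat[[par]], truth[[par]], tolerance = 1e-6)
  }
  expect_identical(fit$k_a_hat, fit$params_hat$f * fit$params_hat$k_tot)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-10)
  expect_equal(unname(fit$sigma_hat), c(0, 0), tolerance = 1e-7)
})

test_that("noiseless recovery holds across randomized truths", {
  for (truth in random_params(20, seed = 41)) {
    fit <- fit_branched_model(noiseless_data(truth))
    for (par in c("k_tot", "f", "k2", "S0")) {
      expect_equal(fit$params_hat[[par]], truth[[par]], tolerance = 1e-5)
    }
  }
})

test_that("zero intermediate drives the branching fraction to zero", {
  truth <- kinetic_params(0.2, 0.5, 0.15, 100)
  d <- as.data.frame(noiseless_data(truth))
  d$conc[d$compound == "intermediate"] <- 0
  fit <- fit_branched_model(time_course_data(d))
  expect_lt(fit$params_hat$f, 1e-6)
  # and the parent rate matches a log-linear regression oracle
  par_rows <- d[d$compound == "parent", ]
  k_lm <- -unname(coef(lm(log(conc) ~ time, par_rows))[2])
  expect_equal(fit$params_hat$k_tot, 0.2, tolerance = 1e-6)
  expect_equal(fit$params_hat$k_tot, k_lm, tolerance = 1e-6)
})

test_that("single first-order fit recovers truth and degrades gracefully", {
  times <- c(0, 1, 3, 5, 7, 9, 11, 13, 15)
  d <- time_course_data(data.frame(
    time = times, compound = "parent", replicate = "R1",
    conc = 50 * exp(-0.5 * times)
  ))
  fit <- fit_single_first_order(d)
  expect_equal(fit$params_hat$k_tot, 0.5, tolerance = 1e-6)
  expect_equal(fit$params_hat$S0, 50, tolerance = 1e-6)
  # constant series: no decay signal
  dc <- time_course_data(data.frame(
    time = times, compound = "parent", replicate = "R1", conc = 42
  ))
  fitc <- fit_single_first_order(dc)
  expect_lt(fitc$params_hat$k_tot, 1e-8)
  # composition identity: half-life of recovered k = ln 2 is one day
  dln <- time_course_data(data.frame(
    time = times, compound = "parent", replicate = "R1",
    conc = 10 * exp(-log(2) * times)
  ))
  expect_equal(half_life(fit_single_first_order(dln)$params_hat$k_tot), 1.0,
               tolerance = 1e-6)
})

test_that("pooled R-squared matches a by-hand computation and its edge cases", {
  truth <- study_params()
  d <- simulate_timecourse(truth, design_spec(noise_sigma_parent = 2,
                                              noise_sigma_intermediate = 2,
                                              lod_intermediate = 0,
                                              seed = 99))
  fit <- fit_branched_model(d)
  # spreadsheet-style oracle on the same numbers
  df <- fit$data_used
  pred <- fit$fitted
  ssr <- sum((df$conc - pred)^2)
  sst <- sum((df$conc[df$compound == "parent"] -
                mean(df$conc[df$compound == "parent"]))^2) +
         sum((df$conc[df$compound == "intermediate"] -
                mean(df$conc[df$compound == "intermediate"]))^2)
  expect_equal(fit$r_squared, 1 - ssr / sst, tolerance = 1e-12)
  expect_equal(goodness_of_fit(fit), fit$r_squared, tolerance = 1e-12)
  expect_equal(goodness_of_fit(fit, d), fit$r_squared, tolerance = 1e-12)
  # predictions replaced by series means -> R^2 = 0 by definition
  expect_equal(pyrekin:::.pooled_r_squared(
    df$conc,
    ave(df$conc, df$compound),
    df$compound
  ), 0)
  expect_error(pyrekin:::.pooled_r_squared(rep(1, 4), rep(1, 4),
                                           rep("parent", 4)),
               "undefined")
})

test_that("objective is invariant to record order and the fit is a fixed point", {
  d <- simulate_timecourse(study_params(),
                           design_spec(noise_sigma_parent = 2,
                                       noise_sigma_intermediate = 1,
                                       seed = 5))
  fit1 <- fit_branched_model(d)
  perm <- as.data.frame(d)[sample(nrow(d)), ]
  fit2 <- fit_branched_model(time_course_data(perm))
  expect_identical(fit1$objective_value, fit2$objective_value)
  expect_identical(unlist(fit1$params_hat), unlist(fit2$params_hat))
  # refitting from the optimum returns the optimum
  fit3 <- fit_branched_model(d, init = fit1$params_hat)
  expect_equal(unlist(fit3$params_hat), unlist(fit1$params_hat),
               tolerance = 1e-8)
})

test_that("estimator error shrinks when measurement noise is halved", {
  truth <- study_params()
  err_at <- function(sigma) {
    errs <- vapply(1:50, function(s) {
      d <- simulate_timecourse(truth, design_spec(
        noise_sigma_parent = sigma, noise_sigma_intermediate = sigma,
        lod_intermediate = 0, seed = 1000 + s))
      fit <- fit_branched_model(d)
      mean(abs(c(fit$params_hat$k_tot / truth$k_tot - 1,
                 fit$params_hat$f / truth$f - 1,
                 fit$params_hat$k2 / truth$k2 - 1)))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(0.5), err_at(1))
})

test_that("degenerate inputs raise informative fitting errors", {
  d <- as.data.frame(noiseless_data())
  all_cens <- d
  all_cens$below_lod[all_cens$compound == "intermediate"] <- TRUE
  expect_error(fit_branched_model(time_course_data(all_cens)),
               "no usable observations")
  few <- d[c(1, 2, 28, 29), ]
  expect_error(fit_branched_model(time_course_data(few)), "distinct time")
  expect_error(fit_branched_model(d[d$compound == "parent", ]),
               "intermediate")
})

test_that("percent_degraded implements the floored percentage", {
  expect_equal(percent_degraded(100, 25), 75.0)
  expect_equal(percent_degraded(50, 50), 0.0)
  expect_equal(percent_degraded(50, 2.45), 100 * (50 - 2.45) / 50)
  expect_equal(round(percent_degraded(50, 2.45), 1), 95.1)
  expect_equal(percent_degraded(50, 60), 0)
  expect_error(percent_degraded(0, 1), "> 0")
})
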