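test_that("diffusivity is recovered from noiseless erfc observations", {
  for (D0 in c(16, 53)) {
    obs <- expand.grid(distance_um = c(50, 100, 150),
                       time_s = seq(300, 3600, by = 300))
    obs$value <- erfc_profile(obs$distance_um, obs$time_s, D0)
    fit <- fit_diffusivity(obs)
    expect_true(fit$converged)
    expect_lt(abs(fit$estimate - D0) / D0, 0.02)
    expect_lt(fit$sse, 1e-6)
  }
})

test_that("diffusivity fit is invariant under the sqrt(Dt) similarity scaling", {
  obs <- expand.grid(distance_um = c(50, 100, 150),
                     time_s = seq(300, 3600, by = 300))
  obs$value <- erfc_profile(obs$distance_um, obs$time_s, 30)
  f1 <- fit_diffusivity(obs)
  scaled <- data.frame(distance_um = 2 * obs$distance_um,
                       time_s = 4 * obs$time_s, value = obs$value)
  f2 <- fit_diffusivity(scaled)
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-3)
})

test_that("degenerate all-zero observations pin the estimate with a flag", {
  obs <- expand.grid(distance_um = c(50, 100, 150),
                     time_s = c(300, 600, 900))
  obs$value <- 0
  fit <- fit_diffusivity(obs)
  expect_false(fit$converged)
  expect_true(fit$flat_objective || fit$at_bound)
  expect_equal(fit$estimate, fit$bounds[1])
  # invalid distances rejected outright
  obs$distance_um[1] <- -5
  expect_error(fit_diffusivity(obs), "strictly positive")
})

test_that("permeability is recovered exactly from self-generated traces", {
  dom <- strip_with_roi()
  for (truth in list(c(D = 16, P = 0.5), c(D = 53, P = 0.41),
                     c(D = 1, P = 0.05), c(D = 500, P = 50))) {
    obs <- model_trace(dom, truth["D"], truth["P"])
    fit <- fit_permeability(obs, dom, truth["D"])
    expect_true(fit$converged)
    expect_lt(abs(fit$estimate - truth["P"]) / truth["P"], 0.02)
  }
})

test_that("the SSE objective is unimodal around the true permeability", {
  dom <- strip_with_roi()
  obs <- model_trace(dom, 16, 0.5, times = seq(600, 3000, 600))
  sse_at <- function(P) {
    m <- model_trace(dom, 16, P, times = obs$time_s)$value
    sum((m - obs$value)^2)
  }
  grid <- c(0.05, 0.15, 0.5, 1.5, 5)
  s <- vapply(grid, sse_at, numeric(1))
  expect_lt(s[3], 1e-12)
  expect_true(all(diff(s[3:5]) > 0))   # increasing moving up from the optimum
  expect_true(all(diff(s[1:3]) < 0))   # decreasing moving toward it
})

test_that("permeability recovery is robust to 5% multiplicative imaging noise", {
  dom <- make_transport_domain(default_network(),
                               window = c(2200, 3800, -800, 800), dx_um = 50)
  dye <- list("20kDa" = list(D_um2_s = 16, P_um_s = 0.62))
  errs <- vapply(1:20, function(s) {
    g <- gen_dextran_timelapse(dom, dyes = dye, noise_sd = 0.05,
                               output_times_s = seq(0, 3600, 600),
                               dt_s = 10, seed = 1000 + s)
    obs <- stack_roi_trace(g$stacks[["20kDa"]], dom$rois$central_polygon)[-1, ]
    fit <- fit_permeability(obs, dom, 16, config = list(dt_s = 10))
    abs(fit$estimate - 0.62) / 0.62
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("membrane-insensitive traces are flagged as unidentifiable", {
  dom <- strip_with_roi()
  # P far above the diffusion-limited regime: the trace carries no
  # information about the membrane
  obs <- model_trace(dom, 16, 500)
  fit <- fit_permeability(obs, dom, 16)
  expect_false(fit$converged)
  expect_true(fit$flat_objective || fit$at_bound)
})

test_that("recovery report tabulates relative errors and guards scenarios", {
  truth <- ground_truth("demo", 1,
                        parameters = c(P_20kDa = 0.62, D_20kDa = 16))
  dom <- strip_with_roi()
  obs <- model_trace(dom, 16, 0.62)
  fit <- fit_permeability(obs, dom, 16)
  rep1 <- joint_recovery_report(truth, list(P_20kDa = fit))
  expect_equal(nrow(rep1), 1)
  expect_lt(abs(rep1$rel_error), 0.02)

  expect_equal(nrow(joint_recovery_report(truth, list())), 0)

  attr(fit, "scenario_id") <- "other"
  expect_error(joint_recovery_report(truth, list(P_20kDa = fit)),
               "scenario 'other'")
  attr(fit, "scenario_id") <- NULL
  expect_error(joint_recovery_report(truth, list(nope = fit)),
               "no parameter named 'nope'")
})

test_that("two-dye recovery preserves the permeability ordering", {
  dom <- strip_with_roi()
  gen <- gen_dextran_timelapse(dom, C_lumen = 1, noise_sd = 0,
                               output_times_s = seq(0, 3600, 600), seed = 4)
  fits <- lapply(names(gen$series), function(nm) {
    tr <- gen$series[[nm]]$roi_traces
    obs <- data.frame(time_s = tr$time_s, value = tr$central_polygon)[-1, ]
    fit_permeability(obs, dom, gen$truth$parameters[[paste0("D_", nm)]],
                     config = list(dt_s = 10))
  })
  names(fits) <- paste0("P_", names(gen$series))
  rep2 <- joint_recovery_report(gen$truth, fits)
  expect_true(all(abs(rep2$rel_error) < 0.02))
  expect_gt(rep2$estimate[rep2$parameter == "P_20kDa"],
            rep2$estimate[rep2$parameter == "P_40kDa"])
})
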