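test_that("flux units convert a linear decline correctly", {
  tt <- seq(0, 600, 1)
  ev <- data.frame(time_s = c(100, 200, 300, 400),
                   agent = c("oligomycin", "fccp_step", "rotenone",
                             "antimycin_a"))
  tr <- oxygraph_trace(tt, 200 - 0.05 * tt, ev)
  fl <- compute_flux_trace(tr, window_s = 120)
  expect_equal(fl$flux, rep(20, nrow(fl)), tolerance = 1e-9)  # 0.05*2*1000/5
  flat <- compute_flux_trace(oxygraph_trace(tt, rep(150, length(tt)), ev), 120)
  expect_equal(flat$flux, rep(0, nrow(flat)))
  half <- oxygraph_trace(tt, 200 - 0.05 * tt, ev, cell_count = 1e7)
  expect_equal(compute_flux_trace(half, 120)$flux[1], 10, tolerance = 1e-9)
  expect_error(compute_flux_trace(tr, window_s = 400),
               class = "immunoflux_input_error")
})

test_that("event protocol ordering is validated", {
  tt <- seq(0, 600, 1)
  bad <- data.frame(time_s = c(100, 200, 300, 400),
                    agent = c("fccp_step", "oligomycin", "rotenone",
                              "antimycin_a"))
  expect_error(oxygraph_trace(tt, 200 - 0.01 * tt, bad),
               class = "immunoflux_input_error")
  no_fccp <- data.frame(time_s = c(100, 300, 400),
                        agent = c("oligomycin", "rotenone", "antimycin_a"))
  expect_error(oxygraph_trace(tt, 200 - 0.01 * tt, no_fccp),
               class = "immunoflux_input_error")
})

test_that("noiseless piecewise traces are recovered exactly", {
  tr <- toy_trace(routine = 50, leak = 12, ets = 130, rox = 6)
  st <- extract_state_fluxes(tr)
  expect_equal(st$routine, 50, tolerance = 1e-6)
  expect_equal(st$leak, 12, tolerance = 1e-6)
  expect_equal(st$ets, 130, tolerance = 1e-6)
  expect_equal(st$rox, 6, tolerance = 1e-6)
  expect_length(st$flags, 0)
})

test_that("ETS is the maximum over FCCP titration plateaus", {
  tr <- toy_trace(ets = 130, fccp_fractions = c(90, 130, 110) / 130)
  st <- extract_state_fluxes(tr)
  expect_equal(sort(st$ets_steps), c(90, 110, 130), tolerance = 1e-6)
  expect_equal(st$ets, 130, tolerance = 1e-6)
})

test_that("noisy traces with injection artifacts recover states within 5%", {
  tr <- toy_trace(routine = 50, leak = 12, ets = 130, rox = 6, noise_sd = 1,
                  artifact_size = 2, seed = 42)
  st <- extract_state_fluxes(tr)
  est <- c(st$routine, st$leak, st$ets, st$rox)
  expect_true(all(abs(est - c(50, 12, 130, 6)) / c(50, 12, 130, 6) < 0.05))
})

test_that("a too-short state window raises an error naming the state", {
  tr <- toy_trace()
  expect_error(extract_state_fluxes(tr, settle_s = 440),
               "ROUTINE", class = "immunoflux_input_error")
})

test_that("BHI closed form and degenerate components", {
  pr <- derive_profile(list(routine = 4, leak = 2, ets = 6, rox = 1))
  expect_equal(pr$atp_linked, 2)
  expect_equal(pr$proton_leak, 1)
  expect_equal(pr$reserve_capacity, 2)
  expect_equal(pr$non_mitochondrial, 1)
  expect_equal(pr$bhi, log10(4))
  # balanced numerator and denominator: (2*2)/(2*2) = 1 -> log 0
  bal <- derive_profile(list(routine = 6, leak = 4, ets = 8, rox = 2))
  expect_equal(bal$bhi, 0)
  flagged <- derive_profile(list(routine = 4, leak = 2, ets = 6, rox = 0))
  expect_true(is.na(flagged$bhi))
  expect_match(flagged$flags, "non_mitochondrial")
})

test_that("BHI is scale-invariant and flux scales with concentration", {
  tr <- toy_trace(routine = 40, leak = 10, ets = 100, rox = 5)
  st <- extract_state_fluxes(tr)
  tr2 <- tr; tr2$o2 <- tr$o2 * 3
  st2 <- extract_state_fluxes(tr2)
  expect_equal(st2$routine, 3 * st$routine, tolerance = 1e-8)
  expect_equal(st2$ets, 3 * st$ets, tolerance = 1e-8)
  expect_equal(derive_profile(st2)$bhi, derive_profile(st)$bhi,
               tolerance = 1e-9)
  s <- list(routine = 4, leak = 2, ets = 6, rox = 1)
  s10 <- lapply(s, `*`, 10)
  expect_equal(derive_profile(s10)$bhi, derive_profile(s)$bhi)
})

test_that("state recovery over a wide flux range stays within 3% median error", {
  errs <- matrix(NA_real_, 50, 4)
  set.seed(90)
  for (i in 1:50) {
    routine <- runif(1, 20, 80)
    states <- c(routine = routine,
                leak = routine * runif(1, 0.15, 0.4),
                ets = routine * runif(1, 1.8, 2.6),
                rox = runif(1, 2, routine * 0.15))
    tr <- toy_trace(states["routine"], states["leak"], states["ets"],
                    states["rox"], noise_sd = 0.01 * routine / 400,
                    artifact_size = 2, seed = 9000 + i)
    st <- extract_state_fluxes(tr)
    errs[i, ] <- abs(c(st$routine, st$leak, st$ets, st$rox) - states) / states
  }
  expect_true(all(apply(errs, 2, median) < 0.03))
})

test_that("memory covariate adjustment recovers coefficients and flags 59%", {
  # zero-noise null covariate: adjusted means equal raw means
  samples <- data.frame(
    donor = paste0("d", 1:12),
    age_group = rep(c("young", "old"), each = 6),
    bhi = rep(c(2.0, 1.5), each = 6),
    memory_pct = c(30, 33, 35, 38, 40, 42, 36, 38, 41, 43, 45, 47))
  # the zero-noise fit is intentionally exact; silence the perfect-fit note
  res <- suppressWarnings(adjust_bhi_for_memory(samples))
  expect_equal(unname(res$all$adjusted_means["young"]), 2.0, tolerance = 1e-8)
  expect_equal(unname(res$all$adjusted_means["old"]), 1.5, tolerance = 1e-8)

  # known coefficients with small noise: recovery within 3 SE
  set.seed(12)
  b0 <- 2.2; b1 <- -0.5; b2 <- -0.01
  mem <- runif(20, 25, 55)
  grp <- rep(c(0, 1), each = 10)
  sim <- data.frame(donor = paste0("d", 1:20),
                    age_group = ifelse(grp == 1, "old", "young"),
                    memory_pct = mem,
                    bhi = b0 + b1 * grp + b2 * mem + rnorm(20, 0, 0.05))
  fit <- adjust_bhi_for_memory(sim)
  est <- fit$all$coefficients; se <- fit$all$se
  expect_lt(abs(est[1] - b0), 3 * se[1])
  expect_lt(abs(est["group_old"] - b1), 3 * se["group_old"])
  expect_lt(abs(est["memory_pct"] - b2), 3 * se["memory_pct"])

  # the high-memory donor among a 26-48% group is flagged
  outl <- data.frame(
    donor = paste0("o", 1:14),
    age_group = rep(c("young", "old"), each = 7),
    bhi = c(rnorm(7, 2, 0.1), rnorm(7, 1.6, 0.1)),
    memory_pct = c(27, 29, 31, 33, 35, 37, 39,
                   33, 38, 41, 44, 46, 48, 59))
  flagged <- adjust_bhi_for_memory(outl)
  expect_true("o14" %in% flagged$outliers)
  expect_false("o8" %in% flagged$outliers)
  expect_false(is.null(flagged$without_outliers))

  const <- samples; const$memory_pct <- 40
  expect_warning(adjust_bhi_for_memory(const), "constant")
})

test_that("respiration comparison reports direction and validates groups", {
  samples <- data.frame(age_group = rep(c("young", "old"), each = 4),
                        bhi = c(2.1, 2.0, 2.2, 1.9, 1.5, 1.4, 1.6, 1.5),
                        non_mitochondrial = c(5, 6, 5, 6, 9, 8, 9, 10),
                        reserve_capacity = c(80, 85, 78, 82, 40, 45, 38, 44))
  cmp <- compare_respiration(samples)
  expect_equal(cmp$direction, c(1, -1, 1))
  expect_equal(cmp$p_value[cmp$metric == "bhi"],
               welch_ttest(samples$bhi[1:4], samples$bhi[5:8])$p_value)
  ident <- samples; ident$bhi <- 1; ident$non_mitochondrial <- 2
  ident$reserve_capacity <- 3
  expect_equal(compare_respiration(ident)$p_value, rep(1, 3))
  expect_error(compare_respiration(samples[samples$age_group == "old", ]),
               class = "immunoflux_input_error")
})

test_that("planted reserve-capacity difference is detected at study n", {
  hits <- 0; n_seeds <- 25
  for (s in 1:n_seeds) {
    sim <- simulate_oxygraph(study_config(seed = 400 + s))
    prof <- lapply(sim$traces, function(tr)
      derive_profile(extract_state_fluxes(tr)))
    samples <- sim$cohort
    samples$bhi <- vapply(prof[samples$donor], `[[`, numeric(1), "bhi")
    samples$non_mitochondrial <- vapply(prof[samples$donor], `[[`, numeric(1),
                                        "non_mitochondrial")
    samples$reserve_capacity <- vapply(prof[samples$donor], `[[`, numeric(1),
                                       "reserve_capacity")
    cmp <- compare_respiration(samples)
    hits <- hits + (cmp$p_value[cmp$metric == "reserve_capacity"] < 0.05)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("oxygraph CSV readers reconstruct the trace", {
  td <- withr::local_tempdir()
  tt <- seq(0, 600, 1)
  write.csv(data.frame(time_s = tt, o2_nmol_per_ml = 200 - 0.05 * tt),
            file.path(td, "trace.csv"), row.names = FALSE)
  write.csv(data.frame(time_s = c(100, 200, 300, 400),
                       agent = c("oligomycin", "fccp_step", "rotenone",
                                 "antimycin_a")),
            file.path(td, "events.csv"), row.names = FALSE)
  tr <- read_oxygraph_csv(file.path(td, "trace.csv"),
                          file.path(td, "events.csv"))
  expect_s3_class(tr, "oxygraph_trace")
  expect_equal(length(tr$time), length(tt))
})
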