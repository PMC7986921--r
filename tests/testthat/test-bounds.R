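test_that("total-power bound equals lambda_max times total power", {
  qd <- q_matrix_set(list(q_matrix(matrix(c(2, 0, 0, 1), 2, 2) + 0i)))
  expect_equal(tp_bound(qd, 1), 2)
  expect_equal(tp_bound(q_matrix_set(list(q_rank1())), 5), 10)
  expect_error(tp_bound(qd, 0), class = "trigsar_domain_error")
  # any same-power drive stays below; equality for the eigenvector profile
  qr <- random_hermitian_psd(4, seed = 1)
  qs <- q_matrix_set(list(qr))
  e <- eigen(qr, symmetric = TRUE)
  set.seed(2)
  for (k in 1:50) {
    s <- simplex_amplitudes(4, k + 10)
    ph <- runif(4, -pi, pi)
    expect_lte(sar(qr, drive_vector(s, ph)), tp_bound(qs, 1) * (1 + 1e-12))
  }
  v <- e$vectors[, 1]
  expect_equal(sar(qr, drive_vector(Mod(v), Arg(v))), tp_bound(qs, 1),
               tolerance = 1e-12)
})

test_that("lower and upper bounds collapse onto the exact value for easy cases", {
  s <- c(1, 2)
  expect_equal(upper_bound(q_rank1(), s), 9, tolerance = 1e-12)
  expect_equal(lower_bound(q_rank1(), s), 9, tolerance = 1e-12)
  qd <- q_matrix(diag(c(2, 1, 3)) + 0i)
  s3 <- c(0.5, 1, 0.2)
  ref <- sum(s3^2 * c(2, 1, 3))
  expect_equal(lower_bound(qd, s3), ref, tolerance = 1e-12)
  expect_equal(upper_bound(qd, s3), ref, tolerance = 1e-12)
  expect_equal(maximize_phases(qd, s3)$max_sar, ref, tolerance = 1e-9)
})

test_that("LB <= TM <= UB across a random ensemble, tight when rank 1", {
  for (seed in 1:20) {
    qr <- random_hermitian_psd(6, rank = 3, seed = seed + 300)
    s <- simplex_amplitudes(6, seed + 320)
    tm <- maximize_phases(qr, s)$max_sar
    expect_lte(lower_bound(qr, s), tm * (1 + 1e-9))
    expect_gte(upper_bound(qr, s), tm * (1 - 1e-9))
  }
  for (seed in 1:10) {
    q1 <- random_hermitian_psd(6, rank = 1, seed = seed + 340)
    s <- simplex_amplitudes(6, seed + 360)
    tm <- maximize_phases(q1, s)$max_sar
    expect_equal(lower_bound(q1, s), tm, tolerance = 1e-9)
    expect_equal(upper_bound(q1, s), tm, tolerance = 1e-9)
  }
})

test_that("rp calibration returns unit factors when references are already worst-case", {
  # diagonal Q: SAR phase-independent, any reference is exact
  qd <- q_matrix_set(list(q_matrix(diag(c(2, 1, 3)) + 0i)))
  m <- calibrate_rp(qd, n_samples = 20, refine = 0)
  expect_equal(unname(m$zeta), c(1, 1), tolerance = 1e-9)
  # rank-1 Q with the eigenvector phases as reference: already the maximizer
  q1 <- q_rank1()
  psi <- eigen_info(q1)$psi
  m1 <- calibrate_rp(q_matrix_set(list(q1)),
                     reference_phases = list(psi), n_samples = 20, refine = 0)
  expect_equal(unname(m1$zeta), 1, tolerance = 1e-9)
})

test_that("rp estimate is capped at the total-power bound", {
  qs <- random_q_ensemble(5, nc = 4, seed = 400)
  s <- simplex_amplitudes(4, 401)
  model <- calibrate_rp(qs, n_samples = 20, refine = 0)
  model$zeta[] <- 1e9 # force the cap
  expect_equal(rp_estimate(qs, s, model), tp_bound(qs, sum(s^2)),
               tolerance = 1e-12)
  # diagonal-only set: estimate equals the exact phase-independent peak
  qd <- q_matrix_set(lapply(1:3, function(k) q_matrix(diag(c(k, 1, 2)) + 0i)))
  md <- calibrate_rp(qd, n_samples = 20, refine = 0)
  s3 <- simplex_amplitudes(3, 402)
  actual <- max(vapply(qd$matrices, function(m) sum(s3^2 * Re(diag(m))),
                       numeric(1)))
  expect_equal(rp_estimate(qd, s3, md), actual, tolerance = 1e-9)
})

test_that("calibrated rp stays conservative on held-out drives", {
  qs <- random_q_ensemble(40, nc = 6, seed = 410)
  model <- calibrate_rp(qs, n_samples = 100, seed = 411)
  amp <- drive_amplitude_matrix(random_drives(6, 500, with_phases = FALSE,
                                              seed = 999))
  tm <- worst_case_peak_batch(qs, amp)
  rp <- vapply(seq_len(nrow(amp)), function(i)
    rp_estimate(qs, amp[i, ], model), numeric(1))
  expect_true(all(rp >= tm * (1 - 1e-9)))
})

test_that("compare_methods orders the estimators and zeroes TM at its maximizer", {
  qs <- random_q_ensemble(30, nc = 5, seed = 420)
  model <- calibrate_rp(qs, n_samples = 100, seed = 421)
  drives <- random_drives(5, 200, seed = 422)
  rep <- compare_methods(qs, drives, model = model)
  d <- rep$drives
  expect_true(all(d$actual <= d$tm * (1 + 1e-9)))
  expect_true(all(d$lb <= d$tm * (1 + 1e-9)))
  expect_true(all(d$tm <= d$ub * (1 + 1e-9)))
  expect_true(all(d$tm <= d$rp * (1 + 1e-9)))
  expect_true(all(d$rp <= d$tp * (1 + 1e-9)))
  sm <- rep$summary
  mo <- setNames(sm$mean_overestimation_pct, sm$method)
  expect_lte(mo[["tm"]], mo[["rp"]] + 1e-9)
  expect_lte(mo[["rp"]], mo[["tp"]] + 1e-9)
  # a drive whose phases sit at the peak-matrix maximizer: actual == TM
  s <- simplex_amplitudes(5, 423)
  w <- worst_case_psar(qs, s)
  ph <- w$results$phases[[w$peak_index]]
  one <- tibble::tibble(drive = 1L, amplitudes = list(s), phases = list(ph))
  r1 <- compare_methods(qs, one, model = model, methods = "tm")
  expect_equal(r1$drives$tm, r1$drives$actual, tolerance = 1e-9)
})

test_that("overestimation histogram partitions the drives", {
  qs <- random_q_ensemble(10, nc = 4, seed = 430)
  model <- calibrate_rp(qs, n_samples = 30, refine = 0)
  rep <- compare_methods(qs, random_drives(4, 100, seed = 431), model = model)
  h <- overestimation_histogram(rep, binwidth = 10)
  for (m in unique(h$method))
    expect_equal(sum(h$count[h$method == m]), 100)
  expect_true(all(h$bin_hi > h$bin_lo))
})

test_that("report tidiers and plots expose the comparison", {
  qs <- random_q_ensemble(8, nc = 4, seed = 440)
  model <- calibrate_rp(qs, n_samples = 30, refine = 0)
  rep <- compare_methods(qs, random_drives(4, 50, seed = 441), model = model)
  long <- tidy(rep)
  expect_setequal(unique(long$method), c("tm", "rp", "tp", "lb", "ub"))
  expect_equal(nrow(long), 50 * 5)
  g <- glance(rep)
  expect_equal(g$n_drives, 50)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_overestimation(rep), "ggplot")
})
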