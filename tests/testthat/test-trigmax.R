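test_that("phase-form SAR matches closed forms and the quadratic form", {
  q <- q_closed_form()
  for (p2 in c(0, 1, -pi / 2, 2.5))
    expect_equal(sar_phase_form(q, c(1, 1), c(0, p2)),
                 2 + cos(p2 + pi / 2), tolerance = 1e-12)
  # zero off-diagonals: phase-independent
  qd <- q_matrix(diag(c(3, 1, 2)) + 0i)
  s <- c(1, 2, 0.5)
  for (seed in 1:3) {
    set.seed(seed)
    expect_equal(sar_phase_form(qd, s, runif(3, -pi, pi)),
                 sum(s^2 * c(3, 1, 2)), tolerance = 1e-12)
  }
  for (seed in 1:5) {
    qr <- random_hermitian_psd(4, seed = seed)
    s <- simplex_amplitudes(4, seed)
    set.seed(seed + 50)
    ph <- runif(4, -pi, pi)
    expect_equal(sar_phase_form(qr, s, ph),
                 sar(qr, drive_vector(s, ph)), tolerance = 1e-12)
  }
})

test_that("analytic gradient matches closed form and finite differences", {
  g <- sar_gradient(q_closed_form(), c(1, 1), c(0, 0))
  expect_equal(g[2], -sin(pi / 2), tolerance = 1e-12)
  for (seed in 1:5) {
    qr <- random_hermitian_psd(5, seed = seed + 10)
    s <- simplex_amplitudes(5, seed + 20)
    set.seed(seed + 30)
    ph <- runif(5, -pi, pi)
    ga <- sar_gradient(qr, s, ph)
    h <- 1e-6
    gn <- vapply(1:5, function(l) {
      e <- replace(numeric(5), l, h)
      (sar_phase_form(qr, s, ph + e) - sar_phase_form(qr, s, ph - e)) / (2 * h)
    }, numeric(1))
    expect_equal(ga, gn, tolerance = 1e-6)
  }
})

test_that("coordinate update is the exact 1-D maximizer", {
  # 2-channel closed form: updating phi1 with phi2 = 0 gives pi/2, SAR = 3
  q <- q_closed_form()
  up <- coordinate_update(q, c(1, 1), c(0, 0), 1)
  expect_equal(as.numeric(up), pi / 2, tolerance = 1e-12)
  expect_equal(sar_phase_form(q, c(1, 1), c(up, 0)), 3, tolerance = 1e-12)
  # zero-amplitude channel: phase kept, flagged degenerate
  qr <- random_hermitian_psd(3, seed = 40)
  up0 <- coordinate_update(qr, c(1, 0, 1), c(0.1, 0.7, -0.2), 2)
  expect_equal(as.numeric(up0), 0.7)
  expect_true(attr(up0, "degenerate"))
  # beats a dense 1-D scan along its coordinate on random instances
  grid <- seq(-pi, pi, length.out = 721)[-721]
  for (seed in 1:5) {
    q4 <- random_hermitian_psd(4, seed = seed + 60)
    s <- simplex_amplitudes(4, seed + 70)
    set.seed(seed + 80)
    ph <- runif(4, -pi, pi)
    for (l in 1:4) {
      up <- coordinate_update(q4, s, ph, l)
      f_up <- sar_phase_form(q4, s, replace(ph, l, up))
      f_scan <- max(vapply(grid, function(p)
        sar_phase_form(q4, s, replace(ph, l, p)), numeric(1)))
      expect_gte(f_up, f_scan - 1e-12)
    }
  }
})

test_that("maximize_phases solves the closed-form instances exactly", {
  f <- maximize_phases(q_closed_form(), c(1, 1))
  expect_equal(f$max_sar, 3, tolerance = 1e-9)
  d <- (f$phases[2] - f$phases[1]) %% (2 * pi)
  expect_equal(d, 2 * pi - pi / 2, tolerance = 1e-6)
  # rank-1 perfect constructive interference: sum_nm s_n |Q_nm| s_m
  f9 <- maximize_phases(q_rank1(), c(1, 2))
  expect_equal(f9$max_sar, 9, tolerance = 1e-9)
  expect_true(f$converged && f9$converged)
})

test_that("maximum is invariant to a global shift of the initial guess", {
  qr <- random_hermitian_psd(5, seed = 90)
  s <- simplex_amplitudes(5, 91)
  base <- maximize_phases(qr, s)$max_sar
  for (shift in c(1, -2.5)) {
    ctl <- trigmax_control(initial_phases = rep(shift, 5))
    expect_equal(maximize_phases(qr, s, ctl)$max_sar, base,
                 tolerance = 1e-9)
  }
})

test_that("gauss-seidel sweeps ascend monotonically; jacobi reaches the same value", {
  for (seed in 1:8) {
    qr <- random_hermitian_psd(6, seed = seed + 100)
    s <- simplex_amplitudes(6, seed + 110)
    fg <- maximize_phases(qr, s)
    expect_true(all(diff(fg$sar_history) >= -1e-12))
    fj <- maximize_phases(qr, s, trigmax_control(sweep_scheme = "jacobi"))
    expect_equal(fj$max_sar, fg$max_sar, tolerance = 1e-6)
  }
})

test_that("returned maximum never underestimates any phase setting", {
  for (seed in 1:5) {
    qr <- random_hermitian_psd(5, seed = seed + 120)
    s <- simplex_amplitudes(5, seed + 130)
    f <- maximize_phases(qr, s)
    set.seed(seed + 140)
    for (k in 1:200) {
      ph <- runif(5, -pi, pi)
      expect_lte(sar_phase_form(qr, s, ph), f$max_sar * (1 + 1e-9))
    }
    # and never exceeds the total-power Rayleigh bound
    lam <- eigen(qr, symmetric = TRUE, only.values = TRUE)$values[1]
    expect_lte(f$max_sar, lam * sum(s^2) * (1 + 1e-12))
  }
})

test_that("total-power bound is attained for the eigenvector amplitude profile", {
  qr <- random_hermitian_psd(5, seed = 150)
  e <- eigen(qr, symmetric = TRUE)
  v <- e$vectors[, 1]
  f <- maximize_phases(qr, Mod(v))
  expect_equal(f$max_sar, e$values[1], tolerance = 1e-9)
})

test_that("zero-amplitude channels are inert and reported at phase 0", {
  qr <- random_hermitian_psd(5, seed = 160)
  s <- c(0.8, 0, 0.5, 0, 0.3)
  f <- maximize_phases(qr, s)
  expect_equal(f$phases[c(2, 4)], c(0, 0))
  sub <- maximize_phases(qr[c(1, 3, 5), c(1, 3, 5)], s[c(1, 3, 5)])
  expect_equal(f$max_sar, sub$max_sar, tolerance = 1e-9)
})

test_that("worst_case_psar peaks over the set and is order-independent", {
  qd <- lapply(c(1, 3, 2), function(k) q_matrix(diag(2) * k + 0i))
  set_d <- q_matrix_set(qd)
  s <- c(1, 1)
  w <- worst_case_psar(set_d, s)
  expect_equal(w$peak_sar, 3 * sum(s^2), tolerance = 1e-12)
  expect_equal(w$peak_index, 2L)
  # singleton equals maximize_phases
  qr <- random_hermitian_psd(4, seed = 170)
  s4 <- simplex_amplitudes(4, 171)
  w1 <- worst_case_psar(q_matrix_set(list(qr)), s4)
  expect_equal(w1$peak_sar, maximize_phases(qr, s4)$max_sar, tolerance = 1e-12)
  # permutation of the set permutes per-matrix results, same peak
  qs <- random_q_ensemble(10, nc = 4, seed = 172)
  perm <- c(7, 2, 9, 1, 10, 3, 8, 5, 4, 6)
  w_a <- worst_case_psar(qs, s4)
  w_b <- worst_case_psar(q_matrix_set(qs$matrices[perm], validate = FALSE), s4)
  expect_equal(w_b$results$max_sar, w_a$results$max_sar[perm], tolerance = 1e-12)
  expect_equal(w_b$peak_sar, w_a$peak_sar, tolerance = 1e-12)
})

test_that("batched worst-case values agree with per-matrix maximization", {
  qs <- random_q_ensemble(15, nc = 5, seed = 180)
  amp <- drive_amplitude_matrix(random_drives(5, 4, with_phases = FALSE,
                                              seed = 181))
  b <- worst_case_sar_batch(qs, amp)
  pk <- worst_case_peak_batch(qs, amp)
  for (i in 1:4) {
    for (v in c(1, 8, 15))
      expect_equal(b[i, v], maximize_phases(qs$matrices[[v]], amp[i, ])$max_sar,
                   tolerance = 1e-9)
    expect_equal(pk[i], max(b[i, ]), tolerance = 1e-12)
  }
})

test_that("time-integrated worst case reduces to the static case and to a loop", {
  qs <- random_q_ensemble(12, nc = 4, seed = 190)
  s <- simplex_amplitudes(4, 191)
  static <- worst_case_psar(qs, s)
  traj1 <- tibble::tibble(duration = c(2e-3, 2e-3, 2e-3),
                          amplitudes = list(s, s, s))
  ti <- time_integrated_worst_case(qs, traj1)
  expect_equal(ti$peak_sar, static$peak_sar, tolerance = 1e-9)
  # two decoupled single-channel steps: duration-weighted diagonal terms
  q2 <- random_q_ensemble(5, nc = 3, seed = 192)
  traj2 <- tibble::tibble(duration = c(1e-3, 3e-3),
                          amplitudes = list(c(1, 0, 0), c(0, 1, 0)))
  ti2 <- time_integrated_worst_case(q2, traj2)
  expected <- vapply(q2$matrices, function(m)
    (1 * Re(m[1, 1]) + 3 * Re(m[2, 2])) / 4, numeric(1))
  expect_equal(ti2$results$max_sar, expected, tolerance = 1e-9)
  # random trajectory vs explicit per-step loop
  set.seed(193)
  amp <- drive_amplitude_matrix(random_drives(4, 10, with_phases = FALSE,
                                              seed = 194))
  dur <- runif(10, 0.5e-3, 3e-3)
  traj3 <- tibble::tibble(duration = dur,
                          amplitudes = lapply(1:10, function(i) amp[i, ]))
  ti3 <- time_integrated_worst_case(qs, traj3)
  loop <- rep(0, length(qs))
  for (t in 1:10) {
    wt <- worst_case_psar(qs, amp[t, ])
    loop <- loop + dur[t] * wt$results$max_sar
  }
  loop <- loop / sum(dur)
  expect_equal(ti3$results$max_sar, loop, tolerance = 1e-9)
  expect_error(time_integrated_worst_case(qs, tibble::tibble()),
               class = "trigsar_domain_error")
})

test_that("fixed_point_trace reports a non-increasing residual to convergence", {
  qr <- random_hermitian_psd(6, seed = 200)
  s <- simplex_amplitudes(6, 201)
  tr <- fixed_point_trace(qr, s, trigmax_control(epsilon = 1e-14,
                                                 epsilon_rel = 0))
  expect_equal(tr$iteration[1], 0L)
  expect_true(all(diff(tr$sar) >= -1e-12))
  expect_lt(tr$rel_residual[nrow(tr)], 1e-12)
})

test_that("degenerate inputs raise typed errors", {
  qr <- random_hermitian_psd(3, seed = 210)
  expect_error(maximize_phases(qr, c(0, 0, 0)), class = "trigsar_domain_error")
  expect_error(maximize_phases(qr, c(1, 1)), class = "trigsar_shape_error")
  expect_error(worst_case_psar(q_matrix_set(list(qr)), c(1, 1, 1),
                               trigmax_control(epsilon = -1)),
               class = "trigsar_domain_error")
})
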