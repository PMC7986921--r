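#' Control parameters for the phase maximization
#'
#' @param epsilon Absolute SAR-change stopping tolerance (W/kg), default 1e-6.
#' @param epsilon_rel Additional relative stopping criterion on
#'   `|dSAR| / SAR` (default 1e-12): iteration stops only when both the
#'   absolute and the relative change are below tolerance.
#' @param max_iterations Iteration cap (default 200).
#' @param sweep_scheme `"gauss_seidel"` (default) uses already-updated phases
#'   within the sweep, making every sweep an exact coordinate ascent and the
#'   SAR history monotone non-decreasing. `"jacobi"` updates all channels from
#'   the previous iterate; it is usually equivalent but can enter a two-cycle
#'   on symmetric instances (for two coupled channels the cosine argument
#'   flips sign each sweep while the SAR stays constant), which
#'   [maximize_phases()] detects via a stationarity check and repairs with
#'   coordinate sweeps.
#' @param initial_phases Starting phases (rad); default all zeros.
#' @param perturb_seed Seed for the (deterministic) escape perturbation used
#'   if the iteration lands on a stationary point that is not a maximum.
#' @return A list of class `trigmax_control`.
#' @export
trigmax_control <- function(epsilon = 1e-6, epsilon_rel = 1e-12,
                            max_iterations = 200L,
                            sweep_scheme = c("gauss_seidel", "jacobi"),
                            initial_phases = NULL, perturb_seed = 1L) {
  sweep_scheme <- match.arg(sweep_scheme)
  if (epsilon <= 0 || epsilon_rel < 0)
    stop_trigsar("stopping tolerances must be positive", "trigsar_domain_error")
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L)
    stop_trigsar("max_iterations must be >= 1", "trigsar_domain_error")
  structure(list(epsilon = epsilon, epsilon_rel = epsilon_rel,
                 max_iterations = max_iterations, sweep_scheme = sweep_scheme,
                 initial_phases = initial_phases,
                 perturb_seed = as.integer(perturb_seed)),
            class = "trigmax_control")
}

check_amp_phase <- function(q, amplitudes, phases = NULL) {
  q <- as_q_entries(q)
  nc <- nrow(q)
  if (length(amplitudes) != nc)
    stop_trigsar("amplitude length does not match Q", "trigsar_shape_error")
  if (any(amplitudes < 0) || any(!is.finite(amplitudes)))
    stop_trigsar("amplitudes must be finite and non-negative", "trigsar_domain_error")
  if (!is.null(phases) && length(phases) != nc)
    stop_trigsar("phase length does not match Q", "trigsar_shape_error")
  q
}

#' Local SAR in explicit phase form
#'
#' Evaluates the voxel SAR as a sum of cosines of phase differences,
#' `sum_n s_n^2 Q_nn + sum_{n<m} 2 s_n |Q_nm| s_m cos(-phi_n + theta_nm + phi_m)`,
#' where `theta_nm = Arg(Q_nm)`. Identical (to rounding) to the quadratic form
#' `Re(s' Q s)`; this is the representation whose coordinate-wise maximizer
#' has a closed form.
#'
#' @param q A [q_matrix].
#' @param amplitudes Per-channel amplitudes (sqrt(W)).
#' @param phases Per-channel phases (rad).
#' @return SAR in W/kg.
#' @export
sar_phase_form <- function(q, amplitudes, phases) {
  q <- check_amp_phase(q, amplitudes, phases)
  nc <- nrow(q)
  val <- sum(amplitudes^2 * Re(diag(q)))
  if (nc > 1L) {
    for (n in seq_len(nc - 1L)) for (m in seq.int(n + 1L, nc)) {
      val <- val + 2 * amplitudes[n] * Mod(q[n, m]) * amplitudes[m] *
        cos(-phases[n] + Arg(q[n, m]) + phases[m])
    }
  }
  val
}

#' Gradient of the voxel SAR with respect to the phases
#'
#' Analytic derivative of the cosine form of the SAR: component `l` is
#' `sum_{m>l} 2 s_l |Q_lm| s_m sin(-phi_l + theta_lm + phi_m)
#'  - sum_{n<l} 2 s_n |Q_nl| s_l sin(-phi_n + theta_nl + phi_l)`.
#' At any returned maximizer this gradient vanishes.
#'
#' @inheritParams sar_phase_form
#' @return Numeric gradient vector (W/kg per rad).
#' @export
sar_gradient <- function(q, amplitudes, phases) {
  q <- check_amp_phase(q, amplitudes, phases)
  nc <- nrow(q)
  g <- numeric(nc)
  for (l in seq_len(nc)) {
    if (l < nc) for (m in seq.int(l + 1L, nc))
      g[l] <- g[l] + 2 * amplitudes[l] * Mod(q[l, m]) * amplitudes[m] *
        sin(-phases[l] + Arg(q[l, m]) + phases[m])
    if (l > 1L) for (n in seq_len(l - 1L))
      g[l] <- g[l] - 2 * amplitudes[n] * Mod(q[n, l]) * amplitudes[l] *
        sin(-phases[n] + Arg(q[n, l]) + phases[l])
  }
  g
}

# off-diagonal coupling in complex form: Z[l] = sum_{m != l} s_l |Q_lm| s_m
# e^{i(theta_lm + phi_m)}. SAR as a function of phi_l alone is
# const + 2 Re(Z_l e^{-i phi_l}), maximized at phi_l = Arg(Z_l); its Cartesian
# parts are the X_l, Y_l of the two-argument arctangent update.
coupling_z <- function(q, amplitudes, phases, l) {
  nc <- nrow(q)
  idx <- setdiff(seq_len(nc), l)
  sum(amplitudes[l] * Mod(q[l, idx]) * amplitudes[idx] *
        exp(1i * (Arg(q[l, idx]) + phases[idx])))
}

#' Closed-form coordinate update of one channel phase
#'
#' Returns the phase of channel `l` that exactly maximizes the voxel SAR while
#' all other phases are held fixed: `phi_l = atan2(Y_l, X_l)` where `X_l` and
#' `Y_l` are the real and imaginary parts of the coupling sum
#' `sum_{m != l} s_l |Q_lm| s_m e^{i(theta_lm + phi_m)}`. When the channel is
#' decoupled or has zero amplitude (`X_l = Y_l = 0`), the SAR does not depend
#' on `phi_l` and the previous phase is kept, flagged via the `"degenerate"`
#' attribute.
#'
#' @inheritParams sar_phase_form
#' @param l Channel index to update.
#' @return Updated phase (rad), with logical attribute `degenerate`.
#' @export
coordinate_update <- function(q, amplitudes, phases, l) {
  q <- check_amp_phase(q, amplitudes, phases)
  l <- as.integer(l)
  if (l < 1L || l > nrow(q))
    stop_trigsar("channel index out of range", "trigsar_domain_error")
  z <- coupling_z(q, amplitudes, phases, l)
  if (Mod(z) == 0)
    return(structure(phases[l], degenerate = TRUE))
  structure(atan2(Im(z), Re(z)), degenerate = FALSE)
}

#' Worst-case phases for one Q-matrix by fixed-point iteration
#'
#' For a fixed amplitude set, finds the phase set maximizing the voxel SAR by
#' iterating the closed-form coordinate update `phi_l <- atan2(Y_l, X_l)` over
#' all channels until the SAR change falls below `epsilon` (absolutely) and
#' `epsilon_rel` (relatively). Convergence is exponential in practice: the
#' SAR surface is a sum of cosines whose local maxima are periodic repetitions
#' of the global maximum, so the iteration homes in on the worst case from the
#' all-zero start. A stationary point that is not a maximum (detected by a
#' positive Hessian eigenvalue at numerical stationarity) is escaped by a
#' small deterministic phase perturbation; such points are unstable for this
#' iteration and arise only from contrived symmetric starts.
#'
#' Because the SAR surface for three or more coupled channels can carry local
#' maxima below the global one, the iteration is run from a small
#' deterministic set of starting points — the configured initial phases plus
#' the phase vector of every eigenvector with a non-negligible eigenvalue —
#' and the best fixed point is returned. The dominant-eigenvector start is
#' the lower-bound construction: it sits in the basin of the global maximum
#' whenever one eigenvalue dominates, and the extra starts cover the
#' remaining rank-(<=3) directions.
#'
#' @param q A [q_matrix].
#' @param amplitudes Per-channel amplitudes (sqrt(W)); not all zero.
#' @param control A [trigmax_control].
#' @return A list of class `trigmax_fit`: `phases` (normalized so the first
#'   active channel has phase 0), `max_sar` (W/kg), `iterations`, `converged`,
#'   `sar_history` (of the winning start), `perturbed`, `jacobi_repair`.
#' @export
maximize_phases <- function(q, amplitudes, control = trigmax_control()) {
  q <- check_amp_phase(q, amplitudes)
  nc <- nrow(q)
  if (nc < 2L)
    stop_trigsar("phase maximization needs at least 2 channels", "trigsar_domain_error")
  if (all(amplitudes == 0))
    stop_trigsar("all-zero amplitude set", "trigsar_domain_error")
  phases0 <- control$initial_phases %||% numeric(nc)
  if (length(phases0) != nc)
    stop_trigsar("initial phases length mismatch", "trigsar_shape_error")

  active <- amplitudes > 0
  starts <- cbind(phases0, eigen_phase_starts(q))
  res <- NULL
  for (j in seq_len(ncol(starts))) {
    rj <- tm_fixed_point_cpp(q, amplitudes, starts[, j],
                             control$epsilon, control$epsilon_rel,
                             control$max_iterations,
                             control$sweep_scheme == "gauss_seidel")
    if (is.null(res) || rj$max_sar > res$max_sar) res <- rj
  }
  phases <- res$phases
  perturbed <- FALSE
  jacobi_repair <- FALSE
  # a Jacobi limit cycle has zero SAR change without stationarity;
  # repair with exact coordinate sweeps from the current iterate
  if (res$converged && control$sweep_scheme == "jacobi") {
    g <- sar_gradient(q, amplitudes, phases)
    if (max(abs(g)) > 1e-8 * max(1, abs(res$max_sar))) {
      jacobi_repair <- TRUE
      res2 <- tm_fixed_point_cpp(q, amplitudes, phases,
                                 control$epsilon, control$epsilon_rel,
                                 control$max_iterations, TRUE)
      res2$sar_history <- c(res$sar_history, res2$sar_history)
      res <- res2
      phases <- res$phases
    }
  }
  # certificate: if stationary but not a maximum, nudge and resume
  if (res$converged && any(active)) {
    h <- phase_hessian(q, amplitudes, phases)
    ev <- eigen(h[active, active, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    scale <- max(abs(ev), .Machine$double.eps)
    if (ev[1] > 1e-8 * scale) {
      perturbed <- TRUE
      # seeded, and isolated from the caller's RNG stream
      old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      set.seed(control$perturb_seed)
      phases[active] <- phases[active] +
        1e-3 * stats::runif(sum(active), -1, 1)
      if (is.null(old_seed)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
      res2 <- tm_fixed_point_cpp(q, amplitudes, phases,
                                 control$epsilon, control$epsilon_rel,
                                 control$max_iterations,
                                 control$sweep_scheme == "gauss_seidel")
      if (res2$max_sar >= res$max_sar) {
        res2$sar_history <- c(res$sar_history, res2$sar_history)
        res <- res2
      }
      phases <- res$phases
    }
  }
  # remove the global-shift degeneracy: first active channel reports phase 0;
  # zero-amplitude channels do not influence SAR and report phase 0
  if (any(active)) {
    ref <- which(active)[1]
    phases <- phases - phases[ref]
  }
  phases[!active] <- 0
  phases <- ((phases + pi) %% (2 * pi)) - pi
  structure(
    list(phases = phases, max_sar = res$max_sar,
         iterations = res$iterations, converged = res$converged,
         sar_history = res$sar_history, perturbed = perturbed,
         jacobi_repair = jacobi_repair, amplitudes = amplitudes),
    class = "trigmax_fit")
}

#' @export
print.trigmax_fit <- function(x, ...) {
  cat(sprintf("<trigmax_fit> max SAR %.6g W/kg in %d iteration(s)%s\n",
              x$max_sar, x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# phase vectors of the eigenvectors carrying non-negligible eigenvalues,
# used as deterministic extra starting points (columns nc x k, k <= 3)
eigen_phase_starts <- function(q) {
  e <- eigen(q, symmetric = TRUE)
  keep <- e$values > .tol_rank * max(e$values[1], 0)
  if (!any(keep)) return(matrix(numeric(0), nrow = nrow(q), ncol = 0))
  Arg(e$vectors[, keep, drop = FALSE])
}

# Hessian of the cosine-form SAR wrt phases (for the maximum certificate)
phase_hessian <- function(q, amplitudes, phases) {
  nc <- nrow(q)
  h <- matrix(0, nc, nc)
  for (n in seq_len(nc)) for (m in seq_len(nc)) {
    if (n == m) next
    c_nm <- 2 * amplitudes[n] * Mod(q[n, m]) * amplitudes[m] *
      cos(-phases[n] + Arg(q[n, m]) + phases[m])
    h[n, m] <- h[n, m] + c_nm / 2 # pair counted from both orientations
    h[n, n] <- h[n, n] - c_nm / 2
  }
  (h + t(h)) / 2
}

#' Convergence trace of the plain fixed-point iteration
#'
#' Runs the fixed-point sweep from the configured starting phases (all zeros
#' by default, the reference behaviour) on a single Q-matrix and returns the
#' SAR after every sweep, for convergence studies. Unlike [maximize_phases()]
#' no alternative starting points or escape logic are applied.
#'
#' @inheritParams maximize_phases
#' @return Tibble with `iteration` (0 = initial phases), `sar` (W/kg) and
#'   `rel_residual` (relative to the final value).
#' @export
fixed_point_trace <- function(q, amplitudes, control = trigmax_control()) {
  q <- check_amp_phase(q, amplitudes)
  phases <- control$initial_phases %||% numeric(nrow(q))
  res <- tm_fixed_point_cpp(q, amplitudes, phases,
                            control$epsilon, control$epsilon_rel,
                            control$max_iterations,
                            control$sweep_scheme == "gauss_seidel")
  h <- res$sar_history
  tibble::tibble(iteration = seq_along(h) - 1L, sar = h,
                 rel_residual = abs(res$max_sar - h) /
                   max(res$max_sar, .Machine$double.eps))
}

#' Worst-case peak SAR over a Q-matrix set
#'
#' Runs [maximize_phases()] independently on every matrix of the set (the
#' per-matrix problems are embarrassingly parallel and order-independent) and
#' reports the peak worst-case SAR and its arg-max matrix.
#'
#' @param qset A [q_matrix_set] (or [vop_set]).
#' @param amplitudes Per-channel amplitudes (sqrt(W)).
#' @param control A [trigmax_control].
#' @return A list of class `worst_case_result`: tibble `results` with one row
#'   per matrix (`matrix`, `max_sar`, `iterations`, `converged`, list-column
#'   `phases`), `peak_sar` (W/kg), `peak_index`, `amplitudes`.
#' @export
worst_case_psar <- function(qset, amplitudes, control = trigmax_control()) {
  stopifnot(inherits(qset, "q_matrix_set"))
  if (length(qset) == 0L)
    stop_trigsar("empty Q-matrix set", "trigsar_domain_error")
  fits <- lapply(qset$matrices, maximize_phases,
                 amplitudes = amplitudes, control = control)
  results <- tibble::tibble(
    matrix = seq_along(fits),
    max_sar = vapply(fits, `[[`, numeric(1), "max_sar"),
    iterations = vapply(fits, `[[`, integer(1), "iterations"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    phases = lapply(fits, `[[`, "phases"))
  peak <- which.max(results$max_sar)
  structure(
    list(results = results, peak_sar = results$max_sar[peak],
         peak_index = peak, amplitudes = amplitudes,
         sweep_scheme = control$sweep_scheme),
    class = "worst_case_result")
}

#' @export
print.worst_case_result <- function(x, ...) {
  cat(sprintf("<worst_case_result> peak worst-case SAR %.6g W/kg at matrix %d of %d\n",
              x$peak_sar, x$peak_index, nrow(x$results)))
  invisible(x)
}

#' Fast batched worst-case SAR values
#'
#' Per-matrix worst-case SAR for one or many amplitude sets, computed in
#' compiled code. Used by the Monte-Carlo comparison and audit routines where
#' millions of per-matrix maximizations are needed; agrees with
#' [maximize_phases()] to the stopping tolerance.
#'
#' @param qset A [q_matrix_set].
#' @param amplitudes Numeric vector (one amplitude set) or matrix with one row
#'   per amplitude set.
#' @param control A [trigmax_control].
#' @return Matrix of worst-case SAR values, `n_sets x n_matrices`.
#' @export
worst_case_sar_batch <- function(qset, amplitudes, control = trigmax_control()) {
  stopifnot(inherits(qset, "q_matrix_set"))
  if (is.vector(amplitudes)) amplitudes <- matrix(amplitudes, nrow = 1)
  nc <- qset$n_channels
  if (ncol(amplitudes) != nc)
    stop_trigsar("amplitude columns must match channel count", "trigsar_shape_error")
  tm_batch_cpp(qset_array(qset), amplitudes, batch_starts(qset),
               control$epsilon, control$epsilon_rel,
               control$max_iterations,
               control$sweep_scheme == "gauss_seidel")
}

# same deterministic start set as maximize_phases: zero phases plus the
# eigenvector phase vectors of each matrix, padded to a common count
batch_starts <- function(qset) {
  nc <- qset$n_channels
  st <- lapply(qset$matrices, function(m) cbind(0, eigen_phase_starts(m)))
  nstart <- max(vapply(st, ncol, integer(1)))
  starts <- array(0, dim = c(nc, nstart, length(qset)))
  for (v in seq_along(st))
    starts[, seq_len(ncol(st[[v]])), v] <- st[[v]]
  starts
}

#' Peak worst-case SAR over a set, batched over amplitude sets
#'
#' Equivalent to `apply(worst_case_sar_batch(...), 1, max)` but prunes with
#' the per-matrix magnitude-sum upper bound: matrices are scanned in
#' descending-bound order and skipped once no remaining bound can exceed the
#' best fixed-point value, so only the few matrices competing for the peak
#' are maximized exactly.
#'
#' @inheritParams worst_case_sar_batch
#' @return Numeric vector of peak worst-case SAR values, one per amplitude
#'   set.
#' @export
worst_case_peak_batch <- function(qset, amplitudes,
                                  control = trigmax_control()) {
  stopifnot(inherits(qset, "q_matrix_set"))
  if (is.vector(amplitudes)) amplitudes <- matrix(amplitudes, nrow = 1)
  if (ncol(amplitudes) != qset$n_channels)
    stop_trigsar("amplitude columns must match channel count", "trigsar_shape_error")
  tm_peak_cpp(qset_array(qset), amplitudes, batch_starts(qset),
              control$epsilon, control$epsilon_rel,
              control$max_iterations,
              control$sweep_scheme == "gauss_seidel")
}

#' Time-integrated worst-case peak SAR
#'
#' For a time-dependent amplitude trajectory (e.g. the per-time-step amplitude
#' settings of a multi-spoke RF pulse), the worst-case SAR of each Q-matrix is
#' the duration-weighted mean of the per-step worst cases, and the peak is
#' taken over matrices afterwards. With a single time step this reduces to
#' [worst_case_psar()].
#'
#' @param qset A [q_matrix_set].
#' @param trajectory Data frame with a `duration` column (s) and either an
#'   `amplitudes` list-column or one `amp_<k>` column per channel.
#' @param control A [trigmax_control].
#' @return A list of class `worst_case_result` with per-matrix time-averaged
#'   worst-case SAR in `results$max_sar` and the peak in `peak_sar`.
#' @export
time_integrated_worst_case <- function(qset, trajectory,
                                       control = trigmax_control()) {
  stopifnot(inherits(qset, "q_matrix_set"))
  trajectory <- as.data.frame(trajectory)
  if (nrow(trajectory) == 0L)
    stop_trigsar("empty amplitude trajectory", "trigsar_domain_error")
  if (is.null(trajectory$duration) || any(trajectory$duration <= 0))
    stop_trigsar("trajectory durations must be positive", "trigsar_domain_error")
  amp <- trajectory_amplitudes(trajectory, qset$n_channels)
  per_step <- worst_case_sar_batch(qset, amp, control) # steps x matrices
  wts <- trajectory$duration / sum(trajectory$duration)
  per_matrix <- as.numeric(crossprod(per_step, wts))
  peak <- which.max(per_matrix)
  structure(
    list(results = tibble::tibble(matrix = seq_along(per_matrix),
                                  max_sar = per_matrix),
         peak_sar = per_matrix[peak], peak_index = peak,
         n_steps = nrow(trajectory)),
    class = "worst_case_result")
}

trajectory_amplitudes <- function(trajectory, nc) {
  if (!is.null(trajectory$amplitudes))
    return(do.call(rbind, trajectory$amplitudes))
  cols <- paste0("amp_", seq_len(nc))
  if (!all(cols %in% names(trajectory)))
    stop_trigsar("trajectory needs `amplitudes` list-column or amp_<k> columns",
                 "trigsar_shape_error")
  as.matrix(trajectory[cols])
}
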