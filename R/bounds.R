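#' Total-power eigenvalue bound on the peak SAR
#'
#' The maximum of `Re(s' Q s)` over all drives with total power `P_tot` is
#' `lambda_max(Q) * P_tot` (Rayleigh quotient), attained only when the drive
#' amplitudes are proportional to the moduli of the dominant eigenvector.
#' Taken over a Q-matrix set this is the classical total-power (TP) estimate of
#' the worst-case peak SAR: safe for any amplitude distribution, and usually
#' far above what the actual amplitude set can reach.
#'
#' @param qset A [q_matrix_set].
#' @param total_power Total transmit power `P_tot` in W.
#' @return `pSAR_TP` in W/kg.
#' @export
tp_bound <- function(qset, total_power) {
  stopifnot(inherits(qset, "q_matrix_set"))
  if (total_power <= 0)
    stop_trigsar("total power must be positive", "trigsar_domain_error")
  max(lambda_max(qset)) * total_power
}

#' Eigenvector-phase lower bound on the worst-case SAR
#'
#' Evaluates the cosine form of the SAR at the phases `psi` of the dominant
#' eigenvector of `Q`. When `Q` has a single non-zero eigenvalue these phases
#' cancel every entry phase (`-psi_n + theta_nm + psi_m = 0`), all cosines sit
#' at 1, and the value equals the exact worst case; with more eigenvalues it
#' can only fall short, giving a fast, iteration-free lower bound.
#'
#' @param q A [q_matrix].
#' @param amplitudes Per-channel amplitudes (sqrt(W)).
#' @return `SAR_LB` in W/kg.
#' @export
lower_bound <- function(q, amplitudes) {
  q <- check_amp_phase(q, amplitudes)
  psi <- eigen_info(q)$psi
  sar_phase_form(q, amplitudes, psi)
}

#' Magnitude-sum upper bound on the worst-case SAR
#'
#' `sum_n sum_m s_n |Q_nm| s_m`: the value the cosine form would take if every
#' pair term could sit at its own maximum simultaneously. That is possible
#' exactly when the entry phases are consistent (rank-1 Q), so the bound is
#' tight there and conservative otherwise. Iteration-free.
#'
#' @inheritParams lower_bound
#' @return `SAR_UB` in W/kg.
#' @export
upper_bound <- function(q, amplitudes) {
  q <- check_amp_phase(q, amplitudes)
  as.numeric(amplitudes %*% Mod(q) %*% amplitudes)
}

psar_over_set <- function(qset, amplitudes, fun) {
  stopifnot(inherits(qset, "q_matrix_set"))
  max(vapply(qset$matrices, fun, numeric(1), amplitudes))
}

#' Peak lower/upper bound over a Q-matrix set
#'
#' Set-level peaks of [lower_bound()] / [upper_bound()]:
#' `pSAR_LB = max_j LB_j`, `pSAR_UB = max_j UB_j`.
#'
#' @param qset A [q_matrix_set].
#' @param amplitudes Per-channel amplitudes (sqrt(W)).
#' @return Peak bound in W/kg.
#' @export
psar_lb <- function(qset, amplitudes) psar_over_set(qset, amplitudes, lower_bound)

#' @rdname psar_lb
#' @export
psar_ub <- function(qset, amplitudes) psar_over_set(qset, amplitudes, upper_bound)

#' Default reference phase sets
#'
#' Two canonical reference settings for the reference-phases estimator: all
#' channels in phase (zero phases) and a circularly-polarized increment
#' `2*pi*(n-1)/Nc`. Suitable reference phases depend on the transmit array, so
#' user-supplied sets are accepted everywhere these defaults are.
#'
#' @param nc Number of channels.
#' @return List of phase vectors (rad).
#' @export
default_reference_phases <- function(nc) {
  list(zero = rep(0, nc),
       cp = 2 * pi * (seq_len(nc) - 1) / nc)
}

#' Calibrate correction factors for the reference-phases estimator
#'
#' For each reference phase set `P_k`, the correction factor `zeta_k` is the
#' largest ratio, over a seeded sample of amplitude sets, between the exact
#' worst-case peak SAR (from the trigonometric maximization) and the peak SAR
#' evaluated at the reference phases. The calibrated `zeta_k` then makes
#' `zeta_k * max_j Re(w_k' Q_j w_k)` conservative on the sampled amplitude
#' family by construction. Amplitude sets are drawn with per-channel powers
#' uniform on the simplex at unit total power (the ratio is scale-invariant in
#' total power, so one power level suffices). Because a finite sample can miss
#' the ratio's global maximum, the calibration then ascends the ratio over the
#' power simplex (Nelder-Mead on log-power coordinates) from the
#' highest-ratio sampled points — the nested-optimization idea with the exact
#' maximizer as the inner solver — and keeps the largest value found.
#'
#' @param qset A [q_matrix_set].
#' @param reference_phases List of phase vectors (default
#'   [default_reference_phases()]).
#' @param n_samples Number of sampled amplitude sets (default 200).
#' @param seed RNG seed for the sampling.
#' @param control A [trigmax_control] for the inner exact maximizer.
#' @param refine Number of local ratio ascents per reference set (default 5;
#'   0 disables refinement).
#' @return A list of class `rp_model`: `reference_phases`, `zeta`,
#'   `n_samples`, `seed`.
#' @export
calibrate_rp <- function(qset, reference_phases = NULL, n_samples = 200,
                         seed = 1L, control = trigmax_control(), refine = 5) {
  stopifnot(inherits(qset, "q_matrix_set"))
  nc <- qset$n_channels
  reference_phases <- reference_phases %||% default_reference_phases(nc)
  if (length(reference_phases) < 1L)
    stop_trigsar("at least one reference phase set is required", "trigsar_domain_error")
  if (n_samples < 1L)
    stop_trigsar("n_samples must be >= 1", "trigsar_domain_error")
  amp <- drive_amplitude_matrix(random_drives(nc, n_samples, total_power = 1,
                                              with_phases = FALSE, seed = seed))
  tm <- worst_case_peak_batch(qset, amp, control)
  zeta <- vapply(reference_phases, function(ph) {
    if (length(ph) != nc)
      stop_trigsar("reference phase set has wrong length", "trigsar_shape_error")
    bm <- rp_ref_matrices(qset, ph)
    ref <- real_form_peak(amp, bm)
    if (any(ref <= 0))
      stop_trigsar("reference phase set yields zero peak SAR; cannot calibrate",
                   "trigsar_validation_error")
    ratios <- tm / ref
    z <- max(ratios)
    if (refine > 0) {
      f <- function(lp) { # log-power coordinates on the simplex
        p <- exp(lp - max(lp)); p <- p / sum(p)
        s <- matrix(sqrt(p), 1)
        worst_case_peak_batch(qset, s, control) / real_form_peak(s, bm)
      }
      for (i in order(-ratios)[seq_len(min(refine, length(ratios)))]) {
        o <- stats::optim(log(amp[i, ]^2), f,
                          control = list(fnscale = -1, maxit = 200))
        z <- max(z, o$value)
      }
    }
    z
  }, numeric(1))
  structure(list(reference_phases = reference_phases, zeta = zeta,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "rp_model")
}

#' @export
print.rp_model <- function(x, ...) {
  cat(sprintf("<rp_model> %d reference set(s), zeta = %s (calibrated on %d amplitude sets)\n",
              length(x$zeta), paste(signif(x$zeta, 4), collapse = ", "),
              x$n_samples))
  invisible(x)
}

qset_array <- function(qset) {
  nc <- qset$n_channels
  vapply(qset$matrices, identity, matrix(0i, nc, nc))
}

# Batched amplitude-only estimators. For a fixed phase pattern p the value
# Re(w' Q w) with w = s * exp(1i p) equals s' B s with the real symmetric
# B = Re(Q * exp(1i (p_m - p_n))) — drive-independent. Peaks over a matrix
# list then batch over an amplitude matrix S as BLAS products.
real_form_peak <- function(S, bmats) {
  peak <- rep(-Inf, nrow(S))
  for (b in bmats) peak <- pmax(peak, rowSums((S %*% b) * S))
  peak
}

lb_matrices <- function(qset) {
  lapply(qset$matrices, function(q) {
    psi <- eigen_info(q)$psi
    tw <- exp(1i * outer(-psi, psi, "+")) # e^{i(psi_m - psi_n)}
    Re(q * tw)
  })
}

ub_matrices <- function(qset) lapply(qset$matrices, Mod)

rp_ref_matrices <- function(qset, ph) {
  tw <- exp(1i * outer(-ph, ph, "+"))
  lapply(qset$matrices, function(q) Re(q * tw))
}

#' Reference-phases estimate of the worst-case peak SAR
#'
#' `pSAR_RP = min_k zeta_k * max_j Re(w_k' Q_j w_k)` with `w_k` the drive
#' amplitudes carrying the k-th reference phase set, capped at the total-power
#' bound for the drive's total power (an estimate above the highest physically
#' achievable value carries no information).
#'
#' @param qset A [q_matrix_set].
#' @param amplitudes Per-channel amplitudes (sqrt(W)).
#' @param model An [calibrate_rp()] result.
#' @return `pSAR_RP` in W/kg.
#' @export
rp_estimate <- function(qset, amplitudes, model) {
  stopifnot(inherits(qset, "q_matrix_set"), inherits(model, "rp_model"))
  nc <- qset$n_channels
  qarr <- qset_array(qset)
  vals <- vapply(seq_along(model$zeta), function(k) {
    w <- matrix(amplitudes * exp(1i * model$reference_phases[[k]]), nrow = 1)
    model$zeta[[k]] * max(sar_many_cpp(qarr, w))
  }, numeric(1))
  min(min(vals), tp_bound(qset, sum(amplitudes^2)))
}

#' Compare worst-case SAR estimators on a set of drives
#'
#' For every drive (amplitudes plus phases), computes the actual peak SAR and
#' the five estimates of its worst case over phases: the exact trigonometric
#' maximization (TM), the reference-phases estimate (RP), the total-power
#' bound (TP), and the eigenvector-phase lower / magnitude-sum upper bounds
#' (LB/UB). Overestimation is reported as `(estimate - actual)/actual` in
#' percent; the summary mirrors the usual histogram presentation of method
#' comparisons.
#'
#' @param qset A [q_matrix_set].
#' @param drives Tibble from [random_drives()] (or any data frame with
#'   `amplitudes` and `phases` list-columns).
#' @param model Optional [calibrate_rp()] result; calibrated on `qset` with
#'   defaults when omitted.
#' @param control A [trigmax_control].
#' @param methods Character subset of `c("tm", "rp", "tp", "lb", "ub")`.
#' @return A list of class `bounds_report`: tibble `drives` with per-drive
#'   `actual` and estimate columns, tibble `summary` with mean/max
#'   overestimation percent per method, and `model`.
#' @export
compare_methods <- function(qset, drives, model = NULL,
                            control = trigmax_control(),
                            methods = c("tm", "rp", "tp", "lb", "ub")) {
  stopifnot(inherits(qset, "q_matrix_set"))
  methods <- match.arg(methods, several.ok = TRUE)
  drives <- tibble::as_tibble(drives)
  if (is.null(drives$phases) || any(vapply(drives$phases, is.null, logical(1))))
    stop_trigsar("drives need phases so the actual peak SAR is computable",
                 "trigsar_domain_error")
  amp <- drive_amplitude_matrix(drives)
  w <- amp * exp(1i * do.call(rbind, drives$phases))
  qarr <- qset_array(qset)
  actual <- apply(sar_many_cpp(qarr, w), 1, max)
  out <- tibble::tibble(drive = seq_len(nrow(drives)), actual = actual)
  if ("tm" %in% methods)
    out$tm <- worst_case_peak_batch(qset, amp, control)
  if ("rp" %in% methods || "tp" %in% methods)
    tp_all <- max(lambda_max(qset)) * rowSums(amp^2)
  if ("rp" %in% methods) {
    model <- model %||% calibrate_rp(qset, control = control)
    rp <- rep(Inf, nrow(amp))
    for (k in seq_along(model$zeta)) {
      refk <- real_form_peak(amp, rp_ref_matrices(qset,
                                                  model$reference_phases[[k]]))
      rp <- pmin(rp, model$zeta[[k]] * refk)
    }
    out$rp <- pmin(rp, tp_all)
  }
  if ("tp" %in% methods) out$tp <- tp_all
  if ("lb" %in% methods) out$lb <- real_form_peak(amp, lb_matrices(qset))
  if ("ub" %in% methods) out$ub <- real_form_peak(amp, ub_matrices(qset))
  est_cols <- intersect(c("tm", "rp", "tp", "lb", "ub"), names(out))
  summary <- dplyr::bind_rows(lapply(est_cols, function(m) {
    over <- 100 * (out[[m]] / out$actual - 1)
    tibble::tibble(method = m,
                   mean_overestimation_pct = mean(over),
                   max_overestimation_pct = max(over),
                   min_overestimation_pct = min(over))
  }))
  structure(list(drives = out, summary = summary, model = model,
                 n_matrices = length(qset)),
            class = "bounds_report")
}

#' @export
print.bounds_report <- function(x, ...) {
  cat(sprintf("<bounds_report> %d drives against %d matrices\n",
              nrow(x$drives), x$n_matrices))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Overestimation histogram of a method comparison
#'
#' Bins the per-drive overestimation percentages of each estimator, for export
#' or plotting alongside the scatter of estimate versus actual peak SAR.
#'
#' @param report A [compare_methods()] result.
#' @param binwidth Bin width in percent (default 5).
#' @return Tibble with `method`, `bin_lo`, `bin_hi`, `count`.
#' @export
overestimation_histogram <- function(report, binwidth = 5) {
  stopifnot(inherits(report, "bounds_report"))
  est_cols <- setdiff(names(report$drives), c("drive", "actual"))
  dplyr::bind_rows(lapply(est_cols, function(m) {
    over <- 100 * (report$drives[[m]] / report$drives$actual - 1)
    lo <- floor(min(over) / binwidth) * binwidth
    hi <- ceiling(max(over) / binwidth) * binwidth
    if (hi <= lo) hi <- lo + binwidth
    breaks <- seq(lo, hi, by = binwidth)
    h <- hist(over, breaks = breaks, plot = FALSE)
    tibble::tibble(method = m, bin_lo = h$breaks[-length(h$breaks)],
                   bin_hi = h$breaks[-1], count = h$counts)
  }))
}
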