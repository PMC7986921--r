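#' Synthetic phantom / transmit-array specification
#'
#' Describes an analytic surrogate of a multi-channel transmit array loaded by
#' a homogeneous lossy phantom: array elements sit on a cylindrical former
#' around the grid, and each channel's electric field decays away from its
#' element with a propagation phase. The fields are NOT solutions of Maxwell's
#' equations; they exist to produce Q-matrix ensembles with the structure seen
#' in simulated arrays — near an element one channel and one Cartesian
#' component dominate (near-rank-1 Q), deeper voxels mix components.
#'
#' @param shape Grid voxel counts, default `c(12, 12, 12)`.
#' @param voxel_size Voxel edge (m), default 5e-3.
#' @param sigma Phantom conductivity (S/m), default 0.5.
#' @param rho Phantom density (kg/m^3), default 1000.
#' @param n_channels Number of array elements, default 8.
#' @param element_model `"dipole_like"` (z-directed current, strongly dominant
#'   Ez) or `"loop_like"` (tangential-heavy field).
#' @param dominant_z Fraction of field power in the z component, in `[0, 1]`;
#'   defaults to 0.9 for dipoles and 0.4 for loops. 1 gives pure Ez and hence
#'   exactly rank-1 Q-matrices everywhere.
#' @param decay_length 1/e decay length of the field magnitude (m), default
#'   0.04.
#' @param wavelength In-tissue wavelength setting the propagation phase (m),
#'   default 0.12 (roughly tissue at 298 MHz).
#' @param former_radius Radius of the element circle (m); default 1.2 x the
#'   half-diagonal of the grid cross-section.
#' @param e0 Field scale at an element (V/m per sqrt(W)), default 30.
#' @param seed Seed (kept for provenance; the generator is deterministic).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(12, 12, 12), voxel_size = 5e-3,
                         sigma = 0.5, rho = 1000, n_channels = 8,
                         element_model = c("dipole_like", "loop_like"),
                         dominant_z = NULL, decay_length = 0.04,
                         wavelength = 0.12, former_radius = NULL,
                         e0 = 30, seed = 1L) {
  element_model <- match.arg(element_model)
  if (n_channels < 3)
    stop_trigsar("at least 3 channels", "trigsar_domain_error")
  if (decay_length <= 0)
    stop_trigsar("decay length must be positive", "trigsar_domain_error")
  dominant_z <- dominant_z %||%
    switch(element_model, dipole_like = 0.9, loop_like = 0.4)
  if (dominant_z < 0 || dominant_z > 1)
    stop_trigsar("dominant_z must be in [0, 1]", "trigsar_domain_error")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 sigma = sigma, rho = rho, n_channels = as.integer(n_channels),
                 element_model = element_model, dominant_z = dominant_z,
                 decay_length = decay_length, wavelength = wavelength,
                 former_radius = former_radius, e0 = e0,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate per-channel phantom fields
#'
#' Builds the [channel_field_set] described by a [phantom_spec]. For each
#' element at angle `2*pi*(c-1)/Nc` on the former, the field magnitude decays
#' as `e0 * exp(-d / decay_length)` with distance `d` from the element and
#' carries the propagation phase `-2*pi*d/wavelength`. The z component takes
#' `sqrt(dominant_z)` of the magnitude; the remainder is split between the
#' radial and azimuthal in-plane directions (radial-heavy for dipoles,
#' azimuthal-heavy for loops). Purely geometric, hence reproducible.
#'
#' @param spec A [phantom_spec].
#' @return A [channel_field_set].
#' @export
generate_phantom_fields <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  vs <- spec$voxel_size
  grid <- tissue_grid(shp, vs, spec$sigma, spec$rho)
  nc <- spec$n_channels
  # voxel centers, origin at grid center
  cx <- (seq_len(shp[1]) - (shp[1] + 1) / 2) * vs
  cy <- (seq_len(shp[2]) - (shp[2] + 1) / 2) * vs
  cz <- (seq_len(shp[3]) - (shp[3] + 1) / 2) * vs
  R <- spec$former_radius %||%
    (1.2 * sqrt((shp[1] * vs / 2)^2 + (shp[2] * vs / 2)^2))
  ang <- 2 * pi * (seq_len(nc) - 1) / nc
  ex_pos <- R * cos(ang); ey_pos <- R * sin(ang)
  tr_split <- switch(spec$element_model,
                     dipole_like = c(radial = 0.7, azim = 0.3),
                     loop_like = c(radial = 0.2, azim = 0.8))
  fz <- sqrt(spec$dominant_z)
  fr <- sqrt((1 - spec$dominant_z) * tr_split[["radial"]])
  fa <- sqrt((1 - spec$dominant_z) * tr_split[["azim"]])
  dims <- c(nc, shp)
  ex <- array(0i, dims); ey <- array(0i, dims); ez <- array(0i, dims)
  X <- array(cx, dim = shp)
  Y <- aperm(array(cy, dim = shp[c(2, 1, 3)]), c(2, 1, 3))
  for (c in seq_len(nc)) {
    dx <- X - ex_pos[c]; dy <- Y - ey_pos[c]
    dz2 <- array(rep(cz^2, each = shp[1] * shp[2]), dim = shp)
    d <- sqrt(dx^2 + dy^2 + dz2)
    mag <- spec$e0 * exp(-d / spec$decay_length)
    ph <- exp(-2i * pi * d / spec$wavelength)
    # in-plane unit vectors from the element towards the voxel
    rho_xy <- pmax(sqrt(dx^2 + dy^2), vs / 10)
    ur_x <- dx / rho_xy; ur_y <- dy / rho_xy
    ez[c, , , ] <- fz * mag * ph
    ex[c, , , ] <- mag * ph * (fr * ur_x - fa * ur_y)
    ey[c, , , ] <- mag * ph * (fr * ur_y + fa * ur_x)
  }
  channel_field_set(grid, ex, ey, ez)
}

#' Random rank-limited PSD Q-matrix ensemble
#'
#' Each matrix is `sum_{i=1..rank} v_i v_i^H` with independent standard
#' complex-Gaussian vectors `v_i` — Hermitian, positive semidefinite, rank at
#' most `rank` by construction, emulating the rank-(<=3) structure of
#' field-built Q-matrices. An optional diagonal boost adds
#' `diag_dominance * mean(diag) * I`, pushing the ensemble towards
#' phase-insensitive (diagonal-dominant) matrices; note any positive boost
#' raises the rank to full.
#'
#' @param count Number of matrices.
#' @param nc Channels per matrix.
#' @param rank Rank bound, 1 to 3 (default 3).
#' @param diag_dominance Non-negative diagonal boost factor (default 0).
#' @param seed RNG seed.
#' @return A [q_matrix_set] (unaveraged, abstract — no voxel indices).
#' @export
random_q_ensemble <- function(count, nc = 8, rank = 3, diag_dominance = 0,
                              seed = 1L) {
  if (rank < 1 || rank > 3)
    stop_trigsar("rank must be 1, 2 or 3", "trigsar_domain_error")
  if (count < 1)
    stop_trigsar("count must be >= 1", "trigsar_domain_error")
  set.seed(seed)
  mats <- lapply(seq_len(count), function(i) {
    q <- matrix(0i, nc, nc)
    for (r in seq_len(rank)) {
      v <- complex(real = rnorm(nc), imaginary = rnorm(nc)) / sqrt(2)
      q <- q + outer(Conj(v), v)
    }
    if (diag_dominance > 0)
      q <- q + diag_dominance * mean(Re(diag(q))) * diag(nc)
    (q + Conj(t(q))) / 2
  })
  q_matrix_set(mats, averaged = TRUE, validate = FALSE)
}

#' Random drive ensembles at fixed total power
#'
#' Draws drive vectors with per-channel powers uniform on the probability
#' simplex (scaled to `total_power`), amplitudes the square roots of those
#' powers, and — when requested — phases uniform on `(-pi, pi]`. Every drive
#' satisfies `sum(s_n^2) = total_power` to machine precision.
#'
#' @param nc Number of channels.
#' @param count Number of drives.
#' @param total_power Total power per drive (W), default 1.
#' @param with_phases Draw phases too (default TRUE).
#' @param seed RNG seed.
#' @return Tibble with `drive` id and list-columns `amplitudes` (and
#'   `phases`).
#' @export
random_drives <- function(nc, count, total_power = 1, with_phases = TRUE,
                          seed = 1L) {
  if (count < 1) stop_trigsar("count must be >= 1", "trigsar_domain_error")
  set.seed(seed)
  e <- matrix(stats::rexp(count * nc), count, nc)
  p <- e / rowSums(e) * total_power
  amps <- sqrt(p)
  out <- tibble::tibble(
    drive = seq_len(count),
    amplitudes = lapply(seq_len(count), function(i) amps[i, ]))
  if (with_phases) {
    ph <- matrix(stats::runif(count * nc, -pi, pi), count, nc)
    out$phases <- lapply(seq_len(count), function(i) ph[i, ])
  }
  out
}

#' Amplitude matrix of a drive tibble
#'
#' @param drives Tibble from [random_drives()].
#' @return Numeric matrix, one row per drive.
#' @export
drive_amplitude_matrix <- function(drives) {
  do.call(rbind, drives$amplitudes)
}

#' Brute-force worst-case SAR by exhaustive phase grid
#'
#' Independent oracle for the fixed-point maximizer: evaluates the SAR on a
#' dense grid over all phases (the first channel is pinned at 0 — SAR is
#' invariant under a global phase shift) and optionally polishes the best grid
#' node by quasi-Newton ascent with the analytic gradient. Cost grows as
#' `grid_points^(Nc-1)`; refuses more than 5 channels.
#'
#' @param q A [q_matrix].
#' @param amplitudes Per-channel amplitudes (sqrt(W)).
#' @param grid_points Grid resolution per phase (default 720).
#' @param refine Polish with BFGS ascent from the best node (default TRUE).
#' @return Best SAR found (W/kg) with attribute `phases`.
#' @export
brute_force_max <- function(q, amplitudes, grid_points = 720, refine = TRUE) {
  q <- check_amp_phase(q, amplitudes)
  nc <- nrow(q)
  if (nc > 5)
    stop_trigsar(paste("grid oracle limited to 5 channels",
                       "(cost ~ grid_points^(Nc-1)); use random_restart_max"),
                 "trigsar_domain_error")
  g <- grid_oracle_cpp(q, amplitudes, as.integer(grid_points))
  best <- g$max_sar
  phases <- g$phases
  if (refine && nc > 1) {
    r <- ascend_from(q, amplitudes, phases)
    if (r$value > best) { best <- r$value; phases <- r$phases }
  }
  structure(best, phases = phases)
}

ascend_from <- function(q, amplitudes, phases) {
  nc <- nrow(q)
  fn <- function(p) -sar_phase_form(q, amplitudes, c(0, p))
  gr <- function(p) -sar_gradient(q, amplitudes, c(0, p))[-1]
  o <- stats::optim(phases[-1], fn, gr, method = "BFGS",
                    control = list(maxit = 200, reltol = 1e-14))
  list(value = -o$value, phases = c(0, o$par))
}

#' Multi-start gradient-ascent worst-case SAR
#'
#' Cross-check for [brute_force_max()] on instances too large for the grid:
#' BFGS ascent of the cosine-form SAR from seeded random phase starts, keeping
#' the best stationary value.
#'
#' @inheritParams brute_force_max
#' @param n_starts Number of random restarts (default 32).
#' @param seed RNG seed.
#' @return Best SAR found (W/kg) with attribute `phases`.
#' @export
random_restart_max <- function(q, amplitudes, n_starts = 32, seed = 1L) {
  q <- check_amp_phase(q, amplitudes)
  nc <- nrow(q)
  set.seed(seed)
  best <- -Inf; best_ph <- numeric(nc)
  starts <- rbind(numeric(nc - 1),
                  matrix(stats::runif((n_starts - 1) * (nc - 1), -pi, pi),
                         n_starts - 1, nc - 1))
  for (i in seq_len(nrow(starts))) {
    r <- ascend_from(q, amplitudes, c(0, starts[i, ]))
    if (r$value > best) { best <- r$value; best_ph <- r$phases }
  }
  structure(best, phases = best_ph)
}

#' Monte-Carlo benchmark of worst-case SAR estimators
#'
#' Generates a seeded random drive ensemble at 1 W total power and runs the
#' requested estimators against a Q-matrix (or VOP) set via
#' [compare_methods()]. This is the desk-scale version of the standard
#' million-drive validation protocol; `n_drives` sets the scale.
#'
#' @param qset A [q_matrix_set] or [vop_set].
#' @param n_drives Number of random drives.
#' @param methods Estimators to run, subset of `c("tm","rp","tp","lb","ub")`.
#' @param seed RNG seed for the drive ensemble.
#' @param model Optional pre-calibrated [calibrate_rp()] model.
#' @param total_power Total power per drive (W), default 1.
#' @param control A [trigmax_control].
#' @return A [compare_methods()] report.
#' @export
benchmark_scenario <- function(qset, n_drives, methods = c("tm", "rp", "tp"),
                               seed = 1L, model = NULL, total_power = 1,
                               control = trigmax_control()) {
  drives <- random_drives(qset$n_channels, n_drives,
                          total_power = total_power, seed = seed)
  compare_methods(qset, drives, model = model, control = control,
                  methods = methods)
}
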