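test_that("build_q reproduces the conductivity/density prefactor", {
  # single channel, Ez = 1 V/m, sigma = 0.5 S/m, rho = 1000 kg/m^3:
  # Q = sigma/(2 rho) = 2.5e-4 W/kg per W. channel_field_set requires >= 3
  # channels, so embed the single active channel among silent ones.
  grid <- tissue_grid(c(1, 1, 1), 5e-3, sigma = 0.5, rho = 1000)
  dims <- c(3, 1, 1, 1)
  z <- array(0i, dims)
  ez <- z; ez[1, 1, 1, 1] <- 1 + 0i
  fs <- channel_field_set(grid, z, z, ez)
  q <- build_q(fs, c(1, 1, 1))
  expect_equal(Re(q[1, 1]), 2.5e-4, tolerance = 1e-12)
  expect_equal(max(Mod(q[-1, ])), 0)
})

test_that("identical channel fields give a rank-1 Q with equal magnitudes", {
  grid <- tissue_grid(c(1, 1, 1), 5e-3, sigma = 0.5, rho = 1000)
  dims <- c(3, 1, 1, 1)
  e <- array(0.3 + 0.4i, dims) # all channels identical
  fs <- channel_field_set(grid, e, array(0i, dims), array(0i, dims))
  q <- build_q(fs, c(1, 1, 1))
  ei <- eigen_info(q)
  expect_equal(ei$rank, 1L)
  expect_equal(max(Mod(q)), min(Mod(q)), tolerance = 1e-12)
})

test_that("Q from three Cartesian components has rank at most 3 for any Nc", {
  for (nc in c(4, 6, 8)) {
    fs <- random_field_set(shape = c(3, 3, 3), nc = nc, seed = nc)
    q <- build_q(fs, c(2, 2, 2))
    vals <- eigen(q, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(sum(vals > 1e-10 * vals[1]), 3L)
    expect_gte(min(vals), -1e-10 * vals[1]) # PSD
  }
})

test_that("build_q rejects voxels outside the mask and invalid tissue", {
  grid <- tissue_grid(c(2, 1, 1), 5e-3, sigma = 0.5, rho = 1000,
                      body_mask = array(c(TRUE, FALSE), c(2, 1, 1)))
  dims <- c(3, 2, 1, 1)
  fs <- channel_field_set(grid, array(1 + 0i, dims), array(0i, dims),
                          array(0i, dims))
  expect_error(build_q(fs, c(2, 1, 1)), class = "trigsar_domain_error")
  expect_error(build_q(fs, c(5, 1, 1)), class = "trigsar_domain_error")
})

test_that("sar matches the quadratic form and clamps correctly", {
  q <- matrix(c(2, 0, 0, 1), 2, 2)
  expect_equal(sar(q_matrix(q), drive_vector(c(1, 0), c(0.7, -2))), 2)
  # closed form: 2 + cos(-phi1 + pi/2 + phi2) at zero argument
  expect_equal(sar(q_closed_form(), drive_vector(c(1, 1), c(0, -pi/2))), 3)
  # random instances: quadratic form vs cosine form, two independent paths
  for (seed in 1:5) {
    qr <- random_hermitian_psd(5, seed = seed)
    s <- simplex_amplitudes(5, seed + 100)
    set.seed(seed + 200)
    ph <- runif(5, -pi, pi)
    expect_equal(sar(qr, drive_vector(s, ph)), sar_phase_form(qr, s, ph),
                 tolerance = 1e-12)
  }
})

test_that("sar is invariant under a global phase shift", {
  qr <- random_hermitian_psd(6, seed = 9)
  s <- simplex_amplitudes(6, 10)
  set.seed(11)
  ph <- runif(6, -pi, pi)
  for (shift in c(0.3, -2, pi)) {
    expect_equal(sar(qr, drive_vector(s, ph + shift)),
                 sar(qr, drive_vector(s, ph)), tolerance = 1e-12)
  }
})

test_that("eigen_info reports spectrum, dominant fraction and phases", {
  ei <- eigen_info(q_rank1()) # q = vv^H, v = (1, i)
  expect_equal(ei$values, c(2, 0), tolerance = 1e-12)
  expect_equal(ei$rank, 1L)
  # psi defined up to a global phase: difference must match Arg(v) mod 2pi
  expect_equal(exp(1i * diff(ei$psi)), exp(1i * pi / 2), tolerance = 1e-12)
  ei3 <- eigen_info(q_matrix(diag(3) + 0i))
  expect_equal(ei3$dominant_fraction, 1 / 3, tolerance = 1e-12)
})

test_that("non-Hermitian matrices are rejected beyond tolerance", {
  m <- matrix(c(1, 0.2 + 0.1i, 0.5, 1), 2, 2)
  expect_error(q_matrix(m), class = "trigsar_validation_error")
  # asymmetry below tolerance is symmetrized silently
  m2 <- matrix(c(1, 0.5i + 1e-12, -0.5i, 1), 2, 2)
  expect_silent(q_matrix(m2))
})

test_that("10g cube side matches the mass requirement on a uniform phantom", {
  # 5 mm isotropic voxels at 1000 kg/m^3: 0.125 g each; smallest odd cube
  # holding 10 g is 5^3 = 125 voxels = 15.625 g
  fs <- random_field_set(shape = c(7, 7, 7), nc = 3, seed = 2)
  qa <- average_10g(build_q_set(fs), fs$grid)
  ctr <- which(apply(qa$voxel_index, 1, function(v) all(v == 4L)))
  expect_equal(attr(qa, "cube_side")[ctr], 5L)
})

test_that("10g averaging is the identity on a constant Q field", {
  grid <- tissue_grid(c(7, 7, 7), 5e-3, 0.5, 1000)
  dims <- c(3, 7, 7, 7)
  fs <- channel_field_set(grid, array(1 + 2i, dims), array(0.5i, dims),
                          array(2 - 1i, dims))
  qs <- build_q_set(fs)
  qa <- average_10g(qs, grid)
  ctr <- which(apply(qa$voxel_index, 1, function(v) all(v == 4L)))
  expect_equal(qa$matrices[[ctr]], qs$matrices[[1]], tolerance = 1e-12)
})

test_that("10g averaging matches a direct mass-weighted loop", {
  # checkerboard of two Q values; oracle: explicit sum over the cube
  fs <- random_field_set(shape = c(7, 7, 7), nc = 3, seed = 3)
  qs <- build_q_set(fs)
  grid <- fs$grid
  qa <- average_10g(qs, grid)
  ctr_idx <- c(4L, 4L, 4L)
  ctr <- which(apply(qa$voxel_index, 1, function(v) all(v == ctr_idx)))
  side <- attr(qa, "cube_side")[ctr]
  h <- (side - 1L) / 2L
  mass <- voxel_mass(grid)
  num <- matrix(0i, 3, 3); den <- 0
  for (i in seq_along(qs$matrices)) {
    v <- qs$voxel_index[i, ]
    if (all(abs(v - ctr_idx) <= h)) {
      m <- mass[v[1], v[2], v[3]]
      num <- num + m * qs$matrices[[i]]
      den <- den + m
    }
  }
  expect_equal(qa$matrices[[ctr]], num / den, tolerance = 1e-12)
})

test_that("averaging commutes with convex combinations of Q fields", {
  fs1 <- random_field_set(shape = c(7, 7, 7), nc = 3, seed = 4)
  fs2 <- random_field_set(shape = c(7, 7, 7), nc = 3, seed = 5)
  q1 <- build_q_set(fs1); q2 <- build_q_set(fs2)
  al <- 0.3
  mix <- q_matrix_set(purrr::map2(q1$matrices, q2$matrices,
                                  ~ al * .x + (1 - al) * .y),
                      voxel_index = q1$voxel_index, validate = FALSE)
  grid <- fs1$grid
  a_mix <- average_10g(mix, grid)
  a1 <- average_10g(q1, grid); a2 <- average_10g(q2, grid)
  i <- which(apply(a_mix$voxel_index, 1, function(v) all(v == 4L)))
  expect_equal(a_mix$matrices[[i]],
               al * a1$matrices[[i]] + (1 - al) * a2$matrices[[i]],
               tolerance = 1e-12)
})

test_that("averaged matrices stay Hermitian PSD", {
  fs <- random_field_set(shape = c(7, 7, 7), nc = 4, seed = 6)
  qa <- average_10g(build_q_set(fs), fs$grid)
  for (i in seq(1, length(qa), by = 37)) {
    m <- qa$matrices[[i]]
    expect_lt(max(Mod(m - Conj(t(m)))), 1e-12 * max(Mod(m)))
    vals <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(vals), -1e-10 * vals[1])
  }
})

test_that("voxels that cannot reach the target mass are excluded with a warning", {
  # tissue ball too light: total mass ~ a few grams < 10 g
  shape <- c(5, 5, 5)
  mask <- array(FALSE, shape); mask[2:4, 2:4, 2:4] <- TRUE # 27 voxels, 3.4 g
  grid <- tissue_grid(shape, 5e-3, 0.5, 1000, body_mask = mask)
  dims <- c(3, shape)
  fs <- channel_field_set(grid, array(1 + 0i, dims), array(0i, dims),
                          array(0i, dims))
  qs <- build_q_set(fs)
  expect_warning(expect_error(average_10g(qs, grid)),
                 "excluded from 10g averaging")
})
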