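# 3-D cumulative sum with a zero-padded leading plane on each axis, so that
# box sums come out of inclusion-exclusion without bounds checks at 0.
cumsum3 <- function(a) {
  d <- dim(a)
  a <- apply(a, c(2, 3), cumsum)
  dim(a) <- d
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
  a <- aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
  out <- array(if (is.complex(a)) 0i else 0, dim = d + 1L)
  out[-1, -1, -1] <- a
  out
}

box_sum <- function(cs, lo, hi) {
  # sum of the source array over [lo, hi] inclusive, 1-based
  l <- lo; h <- hi + 1L
  cs[h[1], h[2], h[3]] - cs[l[1], h[2], h[3]] - cs[h[1], l[2], h[3]] - cs[h[1], h[2], l[3]] +
    cs[l[1], l[2], h[3]] + cs[l[1], h[2], l[3]] + cs[h[1], l[2], l[3]] - cs[l[1], l[2], l[3]]
}

#' 10g cubical averaging of a Q-matrix field
#'
#' Averages each Q-matrix entry over the smallest odd-sided cube, centered on
#' the voxel, whose enclosed tissue mass reaches `target_mass` grams (10 g by
#' default, the averaging mass of the IEC 60601-2-33 local SAR limit). The
#' average is mass-weighted over body voxels only: air voxels contribute zero
#' mass and zero SAR. Cubes are clipped to the grid at its boundary; a voxel
#' whose fully grown (clipped) cube never reaches the target mass is excluded
#' from the result with a warning. This integer-cube rule is a deliberate
#' simplification of full fractional-shell (IEC 62704-1 style) averaging; it
#' preserves Hermitian symmetry and positive semidefiniteness, since each
#' averaged matrix is a convex combination of PSD matrices.
#'
#' @param qset A raw [q_matrix_set] defined on every body voxel, with
#'   `voxel_index` set (e.g. from [build_q_set()]).
#' @param grid The [tissue_grid] the set was built on.
#' @param target_mass Averaging mass in grams (default 10).
#' @return A 10g-averaged [q_matrix_set]; attribute `cube_side` records the
#'   cube side (voxels) used at each retained voxel.
#' @export
average_10g <- function(qset, grid, target_mass = 10) {
  stopifnot(inherits(qset, "q_matrix_set"), inherits(grid, "tissue_grid"))
  if (qset$averaged)
    stop_trigsar("set is already averaged", "trigsar_domain_error")
  if (is.null(qset$voxel_index))
    stop_trigsar("averaging needs voxel indices", "trigsar_domain_error")
  if (target_mass <= 0)
    stop_trigsar("target mass must be positive", "trigsar_domain_error")
  nc <- qset$n_channels
  shp <- grid$shape
  target_kg <- target_mass * 1e-3

  mass <- voxel_mass(grid)
  mass_cs <- cumsum3(mass)

  # mass-weighted entry field: entry (n,m) as a complex volume, times mass
  idx <- qset$voxel_index
  lin <- idx[, 1] + shp[1] * (idx[, 2] - 1L) + shp[1] * shp[2] * (idx[, 3] - 1L)
  w <- mass[lin]
  ent_cs <- vector("list", nc * nc)
  qarr <- vapply(qset$matrices, identity, matrix(0i, nc, nc)) # [nc, nc, Nv]
  for (n in seq_len(nc)) for (m in seq_len(n)) {
    vol <- array(0i, dim = shp)
    vol[lin] <- w * qarr[n, m, ]
    ent_cs[[(n - 1L) * nc + m]] <- cumsum3(vol)
  }

  nv <- nrow(idx)
  out <- vector("list", nv)
  side <- integer(nv)
  keep <- logical(nv)
  max_half <- max(shp) # growing further cannot add voxels
  for (i in seq_len(nv)) {
    v <- idx[i, ]
    h <- 0L
    repeat {
      lo <- pmax(v - h, 1L); hi <- pmin(v + h, shp)
      m_in <- box_sum(mass_cs, lo, hi)
      if (m_in >= target_kg) break
      if (all(lo == 1L) && all(hi == shp)) { h <- NA_integer_; break }
      h <- h + 1L
      if (h > max_half) { h <- NA_integer_; break }
    }
    if (is.na(h)) next
    keep[i] <- TRUE
    side[i] <- 2L * h + 1L
    q <- matrix(0i, nc, nc)
    for (n in seq_len(nc)) for (m in seq_len(n)) {
      s <- box_sum(ent_cs[[(n - 1L) * nc + m]], lo, hi) / m_in
      q[n, m] <- s
      q[m, n] <- Conj(s)
    }
    out[[i]] <- q
  }
  if (!all(keep))
    rlang::warn(sprintf(
      "%d voxel(s) excluded from 10g averaging: clipped cube never reaches %g g",
      sum(!keep), target_mass))
  res <- q_matrix_set(out[keep], voxel_index = idx[keep, , drop = FALSE],
                      averaged = TRUE, validate = FALSE)
  attr(res, "cube_side") <- side[keep]
  res
}
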