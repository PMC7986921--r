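#' Q-matrix: local SAR as a Hermitian quadratic form
#'
#' A Q-matrix is the Hermitian positive-semidefinite `Nc x Nc` matrix such that
#' the local SAR in a voxel is `Re(s' Q s)` for the complex channel drive `s`
#' (units: W/kg per W of drive power). Incoming matrices are symmetrized as
#' `(Q + Q^H)/2`; an asymmetry norm above `1e-8 * ||Q||` is rejected rather
#' than silently repaired.
#'
#' @param entries Complex square matrix.
#' @return The validated (symmetrized) matrix with class `q_matrix`.
#' @export
q_matrix <- function(entries) {
  if (!is.matrix(entries) || nrow(entries) != ncol(entries))
    stop_trigsar("Q must be a square matrix", "trigsar_shape_error")
  storage.mode(entries) <- "complex"
  asym <- max(Mod(entries - Conj(t(entries))))
  scale <- max(Mod(entries), 1e-300)
  if (asym > .tol_herm * scale)
    stop_trigsar(sprintf("matrix is not Hermitian (asymmetry %.3g > %.3g tolerance)",
                         asym, .tol_herm * scale), "trigsar_validation_error")
  q <- (entries + Conj(t(entries))) / 2
  if (any(Re(diag(q)) < -.tol_herm * scale))
    stop_trigsar("negative diagonal entry: not a SAR matrix", "trigsar_validation_error")
  structure(q, class = c("q_matrix", "matrix", "array"))
}

as_q_entries <- function(q) {
  if (inherits(q, "q_matrix")) return(unclass(q))
  unclass(q_matrix(q))
}

#' A set of Q-matrices over body voxels
#'
#' Container for the per-voxel Q-matrices of a body region (raw or
#' 10g-averaged), all sharing the channel count. Voxel indices are 1-based
#' `(ix, iy, iz)` triples; they are optional for abstract ensembles.
#'
#' @param matrices List of `Nc x Nc` complex Hermitian PSD matrices.
#' @param voxel_index Optional integer matrix `Nv x 3` of unique voxel indices.
#' @param averaged Logical flag: has 10g cube averaging been applied?
#' @param labels Optional character annotations per matrix.
#' @param validate Validate Hermitian symmetry of every entry (default TRUE).
#' @return An object of class `q_matrix_set`.
#' @export
q_matrix_set <- function(matrices, voxel_index = NULL, averaged = FALSE,
                         labels = NULL, validate = TRUE) {
  if (length(matrices) == 0L)
    stop_trigsar("empty Q-matrix set", "trigsar_domain_error")
  nc <- nrow(matrices[[1]])
  if (validate) {
    matrices <- lapply(matrices, function(m) {
      if (nrow(m) != nc) stop_trigsar("inconsistent channel counts", "trigsar_shape_error")
      as_q_entries(m)
    })
  } else {
    # store plain complex matrices regardless of input class
    matrices <- lapply(matrices, function(m) {
      if (inherits(m, "q_matrix")) unclass(m) else m
    })
  }
  if (!is.null(voxel_index)) {
    voxel_index <- matrix(as.integer(voxel_index), ncol = 3)
    if (nrow(voxel_index) != length(matrices))
      stop_trigsar("voxel_index rows must match number of matrices", "trigsar_shape_error")
    if (anyDuplicated(voxel_index))
      stop_trigsar("duplicate voxel indices", "trigsar_validation_error")
  }
  structure(
    list(matrices = matrices, voxel_index = voxel_index,
         averaged = isTRUE(averaged), labels = labels,
         n_channels = as.integer(nc)),
    class = "q_matrix_set")
}

#' @export
print.q_matrix_set <- function(x, ...) {
  cat(sprintf("<q_matrix_set> %d matrices, %d channels, %s\n",
              length(x$matrices), x$n_channels,
              if (x$averaged) "10g-averaged" else "raw"))
  invisible(x)
}

#' @export
length.q_matrix_set <- function(x) length(x$matrices)

#' Build the Q-matrix of one voxel from per-channel fields
#'
#' Assembles `Q = sigma/(2 rho) * (Ex^H Ex + Ey^H Ey + Ez^H Ez)` from the three
#' Cartesian rank-1 outer products of the normalized per-channel field rows, so
#' `Re(s' Q s)` is the voxel's local SAR (W/kg) for drive `s`. Because Q is the
#' sum of three rank-1 terms it has rank at most 3 for any channel count.
#'
#' @param fields A [channel_field_set].
#' @param voxel Integer triple `(ix, iy, iz)`, 1-based.
#' @return A [q_matrix], W/kg per W.
#' @export
build_q <- function(fields, voxel) {
  stopifnot(inherits(fields, "channel_field_set"))
  voxel <- as.integer(voxel)
  g <- fields$grid
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > g$shape))
    stop_trigsar("voxel index outside the grid", "trigsar_domain_error")
  if (!g$body_mask[voxel[1], voxel[2], voxel[3]])
    stop_trigsar("voxel outside the body mask", "trigsar_domain_error")
  rho <- g$rho[voxel[1], voxel[2], voxel[3]]
  if (!is.finite(rho) || rho <= 0)
    stop_trigsar("zero or invalid tissue density at voxel", "trigsar_invalid_tissue")
  sig <- g$sigma[voxel[1], voxel[2], voxel[3]]
  ex <- fields$ex[, voxel[1], voxel[2], voxel[3]]
  ey <- fields$ey[, voxel[1], voxel[2], voxel[3]]
  ez <- fields$ez[, voxel[1], voxel[2], voxel[3]]
  pref <- sig / (2 * rho)
  q <- pref * (outer(Conj(ex), ex) + outer(Conj(ey), ey) + outer(Conj(ez), ez))
  # exact Hermitian by construction up to rounding; symmetrize and tag
  structure((q + Conj(t(q))) / 2, class = c("q_matrix", "matrix", "array"))
}

#' Build the raw Q-matrix field over all body voxels
#'
#' @param fields A [channel_field_set].
#' @return A raw (unaveraged) [q_matrix_set] covering every body-mask voxel.
#' @export
build_q_set <- function(fields) {
  stopifnot(inherits(fields, "channel_field_set"))
  idx <- which(fields$grid$body_mask, arr.ind = TRUE)
  mats <- lapply(seq_len(nrow(idx)), function(i) build_q(fields, idx[i, ]))
  q_matrix_set(mats, voxel_index = idx, averaged = FALSE, validate = FALSE)
}

#' Local SAR of a drive
#'
#' Evaluates `SAR = Re(s' Q s)` in W/kg for a drive with known phases. A tiny
#' negative residue from rounding is clamped to zero.
#'
#' @param q A [q_matrix] (or Hermitian matrix).
#' @param drive A [drive_vector] with phases.
#' @return SAR in W/kg (non-negative scalar).
#' @export
sar <- function(q, drive) {
  q <- as_q_entries(q)
  stopifnot(inherits(drive, "drive_vector"))
  s <- drive_weights(drive)
  if (length(s) != nrow(q))
    stop_trigsar("drive length does not match Q dimension", "trigsar_shape_error")
  val <- Re(Conj(s) %*% q %*% s)[1, 1]
  if (val < 0 && val > -.tol_rank * max(Mod(q)) * sum(drive$amplitudes^2)) val <- 0
  val
}

#' Eigen-structure diagnostics of a Q-matrix
#'
#' Eigendecomposition of the Hermitian Q-matrix: sorted spectrum, dominant
#' eigenvalue fraction `lambda_1 / sum(lambda)`, and the phases `psi` of the
#' dominant eigenvector (these phases drive the closed-form lower bound on the
#' worst-case SAR). A Q built from three Cartesian field components has rank at
#' most 3, so at most three eigenvalues exceed numerical zero.
#'
#' @param q A [q_matrix].
#' @return A list of class `eigen_info`: `values` (descending), `vectors`,
#'   `dominant_fraction`, `psi` (rad), `rank` (eigenvalues above
#'   `1e-10 * lambda_1`).
#' @export
eigen_info <- function(q) {
  q <- as_q_entries(q)
  e <- eigen(q, symmetric = TRUE)
  vals <- e$values # real, descending for symmetric = TRUE
  total <- sum(vals)
  v1 <- e$vectors[, 1]
  structure(
    list(values = vals, vectors = e$vectors,
         dominant_fraction = if (total > 0) vals[1] / total else NA_real_,
         psi = Arg(v1),
         rank = sum(vals > .tol_rank * max(vals[1], 0))),
    class = "eigen_info")
}

#' @export
print.eigen_info <- function(x, ...) {
  cat(sprintf("<eigen_info> rank %d, dominant fraction %.4f\n  lambda: %s\n",
              x$rank, x$dominant_fraction,
              paste(signif(x$values, 4), collapse = ", ")))
  invisible(x)
}

#' Largest eigenvalue of every matrix in a set
#'
#' @param qset A [q_matrix_set].
#' @return Numeric vector of `lambda_max` values (W/kg per W).
#' @export
lambda_max <- function(qset) {
  stopifnot(inherits(qset, "q_matrix_set"))
  vapply(qset$matrices,
         function(m) eigen(m, symmetric = TRUE, only.values = TRUE)$values[1],
         numeric(1))
}
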