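#' Compress a Q-matrix set to virtual observation points
#'
#' Reduces a large per-voxel Q-matrix set to a small set of virtual
#' observation points (VOPs) with a guaranteed overestimation bound. A matrix
#' `Q_j` is dominated by a VOP `V` when `V + delta * lambda_bar * I - Q_j` is
#' positive semidefinite, where `lambda_bar` is the largest eigenvalue over
#' the whole set; PSD dominance implies `Re(s' Q_j s) <= Re(s' V s) +
#' delta * lambda_bar * ||s||^2` for every drive `s`, so the VOP peak never
#' underestimates the full-set peak and overestimates it by at most
#' `delta * lambda_bar * P_tot`. Matrices are visited in descending
#' `lambda_max` order (ties broken by original index) and join the VOP list
#' when no existing VOP dominates them — a greedy first-fit pass chosen for
#' reproducibility; it makes no claim of minimal VOP counts.
#'
#' @param qset A [q_matrix_set].
#' @param delta Allowed overestimation as a fraction of `lambda_bar`
#'   (default 0.05).
#' @return A [q_matrix_set] subclass `vop_set` with fields `delta`,
#'   `delta_term` (`delta * lambda_bar`, the coefficient of `||s||^2` in the
#'   overestimation allowance) and `provenance` (tibble mapping each original
#'   matrix to its dominating VOP).
#' @export
compress_vops <- function(qset, delta = 0.05) {
  stopifnot(inherits(qset, "q_matrix_set"))
  if (delta <= 0 || delta >= 1)
    stop_trigsar("delta must be in (0, 1)", "trigsar_domain_error")
  lam <- lambda_max(qset)
  lam_bar <- max(lam)
  pad <- delta * lam_bar
  nc <- qset$n_channels
  eye <- diag(nc)
  ord <- order(-lam, seq_along(lam))
  vops <- list()
  dominator <- integer(length(qset))
  for (j in ord) {
    qj <- qset$matrices[[j]]
    hit <- 0L
    for (v in seq_along(vops)) {
      d <- vops[[v]] + pad * eye - qj
      mineig <- min(eigen(d, symmetric = TRUE, only.values = TRUE)$values)
      if (mineig >= -.tol_rank * lam_bar) { hit <- v; break }
    }
    if (hit == 0L) {
      vops[[length(vops) + 1L]] <- qj
      hit <- length(vops)
    }
    dominator[j] <- hit
  }
  res <- q_matrix_set(vops, averaged = qset$averaged, validate = FALSE)
  class(res) <- c("vop_set", class(res))
  res$delta <- delta
  res$delta_term <- pad
  res$provenance <- tibble::tibble(matrix = seq_along(lam),
                                   vop = dominator, lambda_max = lam)
  res
}

#' @export
print.vop_set <- function(x, ...) {
  src <- if (is.null(x$provenance)) "" else
    sprintf(" from %d matrices", nrow(x$provenance))
  cat(sprintf("<vop_set> %d VOPs%s (delta = %g, pad %.4g W/kg per W)\n",
              length(x$matrices), src, x$delta, x$delta_term))
  invisible(x)
}

#' Conservative peak SAR from a VOP set
#'
#' `max_v Re(s' V s) + delta_term * P_tot`: an upper estimate of the full-set
#' peak SAR that is exact up to the compression allowance.
#'
#' @param vops A [vop_set].
#' @param drive A [drive_vector] with phases.
#' @return Estimated peak SAR in W/kg.
#' @export
vop_psar <- function(vops, drive) {
  stopifnot(inherits(vops, "vop_set"))
  w <- matrix(drive_weights(drive), nrow = 1)
  max(sar_many_cpp(qset_array(vops), w)) + vops$delta_term * drive$total_power
}
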