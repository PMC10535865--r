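# Root-mean-square deviation with optimal rigid-body superposition
# (Kabsch / orthogonal Procrustes via SVD).

#' RMSD between two coordinate sets
#'
#' With `superpose = TRUE` (default) the mobile set is first
#' least-squares superposed onto the reference: both sets are centred
#' and the optimal rotation is obtained from the SVD of the covariance
#' matrix, with the usual sign correction so reflections are never
#' applied. Atoms must be in matched order.
#'
#' @param reference,coords `n x 3` coordinate matrices (Angstrom).
#' @param superpose superpose before computing the RMSD?
#' @return RMSD in Angstrom.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' rmsd(a, a)  # 0
#' @export
rmsd <- function(reference, coords, superpose = TRUE) {
  reference <- as.matrix(reference)
  coords <- as.matrix(coords)
  if (!all(dim(reference) == dim(coords)) || ncol(reference) != 3) {
    stop("coordinate sets must be n x 3 matrices with equal atom counts")
  }
  check_finite(as.numeric(reference), "reference")
  check_finite(as.numeric(coords), "coords")
  if (superpose) coords <- kabsch_superpose(reference, coords)
  sqrt(mean(rowSums((coords - reference)^2)))
}

#' Superpose one coordinate set onto another
#'
#' @inheritParams rmsd
#' @return the mobile coordinates after optimal rotation + translation
#'   onto the reference.
#' @export
kabsch_superpose <- function(reference, coords) {
  reference <- as.matrix(reference)
  coords <- as.matrix(coords)
  cr <- colMeans(reference)
  cm <- colMeans(coords)
  p <- sweep(coords, 2, cm)
  q <- sweep(reference, 2, cr)
  s <- svd(crossprod(p, q))      # t(P) %*% Q
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(p %*% rot, 2, cr, `+`)
}

#' RMSD of every frame of a trajectory to a reference frame
#'
#' @param traj a [trajectory()].
#' @param reference_frame index of the reference frame.
#' @param superpose superpose each frame first?
#' @return numeric vector of per-frame RMSDs (Angstrom).
#' @export
trajectory_rmsd <- function(traj, reference_frame = 1, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- frame_coords(traj, reference_frame)
  vapply(seq_len(traj$n_frames), function(f) {
    rmsd(ref, frame_coords(traj, f), superpose = superpose)
  }, numeric(1))
}
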