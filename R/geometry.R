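# Rigid-body superposition and per-frame geometric metrics.

#' Euclidean distance between two atoms of a coordinate frame
#'
#' @param frame N x 3 coordinate matrix (Angstrom)
#' @param atom_i,atom_j atom indices (1-based)
#' @return distance in Angstrom
#' @export
pair_distance <- function(frame, atom_i, atom_j) {
  n <- nrow(frame)
  if (atom_i < 1 || atom_i > n || atom_j < 1 || atom_j > n) {
    stop(sprintf("atom index out of range (have %d atoms, asked for %d and %d)",
                 n, atom_i, atom_j), call. = FALSE)
  }
  sqrt(sum((frame[atom_i, ] - frame[atom_j, ])^2))
}

#' Raw (unfitted) RMSD between congruent coordinate sets
#' @param a,b N x 3 coordinate matrices in matching atom order
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Kabsch superposition
#'
#' Finds the proper rigid motion (rotation + translation, no reflection)
#' minimizing the RMSD of `mobile` onto `reference` over point pairs in
#' matching order, via SVD of the covariance matrix. All atoms carry unit
#' weight.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, congruent order
#' @return list with `rotation` (3x3 proper orthogonal), `translation`
#'   (length-3), and `fitted_rmsd` (Angstrom). The fitted coordinates are
#'   `mobile %*% t(rotation)` plus the translation row-wise (see
#'   [apply_transform()]).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3) {
    stop("mobile and reference must be N x 3 with equal N", call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3) stop("superposition requires at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  m <- sweep(mobile, 2, cm); r <- sweep(reference, 2, cr)
  # degenerate (collinear/coincident) sets have no unique minimizer
  degen <- function(x) {
    s <- svd(x, nu = 0, nv = 0)$d
    s[2] <= 1e-10 * max(s[1], 1e-300)
  }
  if (degen(m) || degen(r)) {
    stop("degenerate (collinear or coincident) point set in superposition",
         call. = FALSE)
  }
  h <- crossprod(m, r)               # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- m %*% t(rot)
  list(rotation = rot,
       translation = as.numeric(cr - (rot %*% cm)),
       fitted_rmsd = sqrt(mean(rowSums((fitted - r)^2))))
}

#' Apply a rigid transform to coordinates
#' @param x N x 3 coordinates
#' @param tf transform as returned by [kabsch_superpose()]
#' @return transformed N x 3 coordinates
#' @export
apply_transform <- function(x, tf) {
  sweep(as.matrix(x) %*% t(tf$rotation), 2, tf$translation, "+")
}

#' RMSD after superposition on a fit selection
#'
#' The frame is superposed onto the reference using only the `fit_selection`
#' atoms (e.g. the stable LBD core); the RMSD is then computed over
#' `calc_selection` atoms (e.g. helix 12) without refitting. This is the
#' standard way to measure motion of a mobile element relative to a rigid
#' scaffold.
#'
#' @param frame,reference N x 3 coordinate matrices over the same topology
#' @param fit_selection,calc_selection integer atom-index vectors
#' @return RMSD of the calc selection in Angstrom
#' @export
rmsd_after_fit <- function(frame, reference, fit_selection, calc_selection) {
  if (length(fit_selection) == 0L || length(calc_selection) == 0L) {
    stop("empty fit or calc selection", call. = FALSE)
  }
  tf <- kabsch_superpose(frame[fit_selection, , drop = FALSE],
                         reference[fit_selection, , drop = FALSE])
  moved <- apply_transform(frame[calc_selection, , drop = FALSE], tf)
  rmsd(moved, reference[calc_selection, , drop = FALSE])
}
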