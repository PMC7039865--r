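#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` for two point
#' sets paired by index.  The returned rotation is always proper
#' (determinant +1).  Collinear/degenerate point sets are flagged and fall
#' back to a translation-only fit.
#'
#' @param mobile n x 3 coordinate matrix (A), n >= 3.
#' @param reference n x 3 coordinate matrix paired row-wise with `mobile`.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   coordinates are `mobile %*% t(rotation) + translation`), `rmsd` (A),
#'   `fitted` (transformed mobile coordinates) and `degenerate` (logical).
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' th <- pi / 3
#' R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' mob <- ref %*% t(R) + 5
#' superpose(mob, ref)$rmsd  # ~0
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3)
    stop_ip("input_error", "point sets must be paired n x 3 matrices")
  if (nrow(mobile) < 3)
    stop_ip("input_error", "superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  if (degenerate) {
    R <- diag(3)
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  fitted <- A %*% t(R) + matrix(cr, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       rmsd = rmsd, fitted = fitted, degenerate = degenerate)
}

#' Root-mean-square deviation after optimal superposition
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(mobile, reference) superpose(mobile, reference)$rmsd

#' Align every frame of a trajectory to a reference frame
#'
#' Each frame is superposed onto `reference_frame` using the atoms in
#' `fit_rows`; the rigid transform is then applied to all atoms.
#'
#' @param trajectory an `ip_trajectory`.
#' @param fit_rows atom row positions used for the fit (default: protein).
#' @param reference_frame 1-based list position of the reference frame.
#' @return the aligned `ip_trajectory`.
#' @export
align_trajectory <- function(trajectory, fit_rows = NULL,
                             reference_frame = 1L) {
  if (is.null(fit_rows))
    fit_rows <- select_atoms(trajectory$topology, segment = "protein")
  ref <- trajectory$frames[[reference_frame]]$coords[fit_rows, , drop = FALSE]
  for (i in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[i]]
    fit <- superpose(f$coords[fit_rows, , drop = FALSE], ref)
    trajectory$frames[[i]]$coords <-
      f$coords %*% t(fit$rotation) +
      matrix(fit$translation, nrow(f$coords), 3, byrow = TRUE)
  }
  trajectory
}

#' Re-image a frame so the protein sits at the box centre
#'
#' Optional periodic-boundary utility: shifts all coordinates so the protein
#' centre of mass lies at the box centre, then wraps non-protein atoms back
#' into the primary box.  Analyses assume frames are already imaged; this
#' helper recenters frames that are not.
#'
#' @param frame an `ip_frame` with a box.
#' @param topology the matching `ip_topology`.
#' @return the re-imaged `ip_frame`.
#' @export
reimage_frame <- function(frame, topology) {
  if (is.null(frame$box))
    stop_ip("input_error", "reimage_frame needs a frame with a box")
  prot <- select_atoms(topology, segment = "protein")
  if (!length(prot)) stop_ip("selection_error", "no protein atoms to centre")
  shift <- frame$box / 2 - colMeans(frame$coords[prot, , drop = FALSE])
  xyz <- sweep(frame$coords, 2, -shift)
  other <- setdiff(seq_len(nrow(xyz)), prot)
  for (k in 1:3)
    xyz[other, k] <- xyz[other, k] - frame$box[k] *
      floor(xyz[other, k] / frame$box[k])
  frame$coords <- xyz
  frame
}
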