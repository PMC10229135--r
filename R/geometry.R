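#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' mobile structure onto the reference over the selected atoms (SVD
#' solution with reflection correction), and reports the minimized
#' RMSD.
#'
#' @param reference,mobile `atoms x 3` coordinate matrices.
#' @param selection Atom indices used for the fit (default all).
#' @return List with `rotation` (3x3, det +1), `translation` (the fit
#'   maps `x` to `(x - cm_mobile) %*% rotation + cm_reference`),
#'   `rmsd` (Angstrom over the selection), and `transform(x)` applying
#'   the fit to any `n x 3` matrix.
#' @export
superpose_kabsch <- function(reference, mobile, selection = NULL) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  stopifnot(ncol(reference) == 3, ncol(mobile) == 3,
            nrow(reference) == nrow(mobile))
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  if (length(selection) < 3) stop("need >= 3 atoms to superpose")
  A <- reference[selection, , drop = FALSE]
  B <- mobile[selection, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  # collinear selections leave the rotation about the line undetermined
  if (svd(Ac)$d[2] < 1e-8 * max(svd(Ac)$d[1], 1))
    stop("degenerate (collinear) selection")
  H <- crossprod(Bc, Ac)           # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  R <- t(R)                         # so that x %*% R maps mobile -> ref
  fitted <- Bc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Ac)^2)))
  transform <- function(x) sweep(sweep(as.matrix(x), 2, cb) %*% R, 2,
                                 ca, `+`)
  list(rotation = R, translation = ca - as.vector(cb %*% R),
       rmsd = rmsd, transform = transform)
}

# plain (unfitted) RMSD between two frames over a selection
rmsd_plain <- function(a, b, selection) {
  d <- a[selection, , drop = FALSE] - b[selection, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Per-frame RMSD series relative to a reference frame
#'
#' Per frame: superpose on the fit selection, then report the RMSD over
#' the measure selection.  Separate fit and measure selections allow
#' e.g. ligand RMSD after superposition on the receptor.
#'
#' @param traj An `md_trajectory`.
#' @param reference Reference frame index (default 1) or an
#'   `atoms x 3` matrix.
#' @param fit_selection,measure_selection Atom indices or labels
#'   (default: all atoms for both).
#' @param fit If `FALSE`, no superposition is performed.
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, fit_selection = NULL,
                        measure_selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  ref <- if (is.matrix(reference)) reference else
    frame_matrix(traj, reference)
  fs <- resolve_selection(traj, fit_selection)
  ms <- resolve_selection(traj, measure_selection)
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_matrix(traj, f)
    if (fit) {
      sp <- superpose_kabsch(ref, m, fs)
      m <- sp$transform(m)
    }
    rmsd_plain(ref, m, ms)
  }, 0)
}

#' Root-mean-square fluctuation per atom
#'
#' Aligns every frame to the mean structure (two passes of
#' mean-structure refinement), then reports the per-atom RMS deviation
#' from the mean position.
#'
#' @param traj An `md_trajectory` with >= 2 frames.
#' @param selection Atoms to report (default all).
#' @param fit_selection Atoms used for the superposition (default:
#'   `selection`).
#' @return Named numeric vector of RMSF values (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL, fit_selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF is undefined for a single frame")
  sel <- resolve_selection(traj, selection)
  fs <- if (is.null(fit_selection)) sel else
    resolve_selection(traj, fit_selection)
  frames <- lapply(seq_len(nf), function(f) frame_matrix(traj, f))
  ref <- frames[[1]]
  for (pass in 1:2) {
    aligned <- lapply(frames, function(m)
      superpose_kabsch(ref, m, fs)$transform(m))
    ref <- Reduce(`+`, aligned) / nf
  }
  dev2 <- Reduce(`+`, lapply(aligned, function(m)
    rowSums((m - ref)^2))) / nf
  out <- sqrt(dev2[sel])
  names(out) <- traj$atom_labels[sel]
  out
}

# signed torsion angle (degrees) for one frame
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined dihedral: collinear atoms")
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral (torsion) angle time series
#'
#' Signed torsion by the standard atan2 convention, in degrees in
#' `(-180, 180]`; cis is 0 and trans is 180.  For a tryptophan chi2
#' angle the conventional atom quadruple is CA-CB-CG-CD1.
#'
#' @param traj An `md_trajectory`.
#' @param atom_quadruple Four distinct atom indices or labels.
#' @return Numeric vector of angles per frame (degrees).
#' @export
dihedral_series <- function(traj, atom_quadruple) {
  stopifnot(inherits(traj, "md_trajectory"))
  q <- resolve_selection(traj, atom_quadruple)
  if (length(q) != 4) stop("atom_quadruple must name 4 distinct atoms")
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_matrix(traj, f)
    torsion_angle(m[q[1], ], m[q[2], ], m[q[3], ], m[q[4], ])
  }, 0)
}

#' Interatomic or centroid distance time series
#'
#' @param traj An `md_trajectory`.
#' @param selection_a,selection_b Atom indices or labels (non-empty).
#' @param mode `"atom"` (both selections must be single atoms) or
#'   `"centroid"` (distance between selection centroids, covering
#'   ring-to-group distances).
#' @return Numeric vector of distances per frame (Angstrom).
#' @export
distance_series <- function(traj, selection_a, selection_b,
                            mode = c("atom", "centroid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "md_trajectory"))
  sa <- resolve_selection(traj, selection_a)
  sb <- resolve_selection(traj, selection_b)
  if (!length(sa) || !length(sb)) stop("selections must be non-empty")
  if (mode == "atom" && (length(sa) != 1 || length(sb) != 1))
    stop("atom mode requires single-atom selections")
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_matrix(traj, f)
    pa <- colMeans(m[sa, , drop = FALSE])
    pb <- colMeans(m[sb, , drop = FALSE])
    sqrt(sum((pa - pb)^2))
  }, 0)
}
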