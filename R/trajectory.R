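#' Wrap angles onto the canonical circle (-180, 180]
#'
#' Maps any finite angle in degrees to its canonical representative in
#' `(-180, 180]`, with -180 identified with +180.
#'
#' @param angle numeric vector of angles in degrees.
#' @return numeric vector of the same length, each value in `(-180, 180]` and
#'   equal to the input modulo 360.
#' @examples
#' wrap_angle(c(180, -180, 540, -270))
#' @export
wrap_angle <- function(angle) {
  if (!is.numeric(angle)) stop("`angle` must be numeric")
  if (any(!is.finite(angle))) stop("`angle` must be finite")
  y <- angle %% 360
  y[y > 180] <- y[y > 180] - 360
  # x %% 360 lies in [0, 360): 0 maps to 0, values in (180, 360) shift down,
  # so -180 (-> 180) and 180 (-> 180) share one representative
  y
}

#' Construct a dihedral-angle trajectory
#'
#' The universal input container: a snapshots-by-torsions matrix of dihedral
#' angles in degrees, optionally carrying a per-snapshot potential energy (in
#' kT). Angles are canonically wrapped to `(-180, 180]` on construction.
#'
#' @param angles numeric matrix, `n_snapshots x n_torsions`, degrees.
#' @param torsion_labels optional character vector of unique torsion names;
#'   defaults to existing column names or `phi1, phi2, ...`.
#' @param energies optional numeric vector of per-snapshot potential energies
#'   (kT), length `n_snapshots`.
#' @param source provenance string recorded with the object.
#' @return an object of class `dihedral_trajectory` with elements `angles`,
#'   `torsion_labels`, `energies` (possibly `NULL`) and `source`.
#' @examples
#' traj <- dihedral_trajectory(matrix(c(10, 540, -200, 180), 2, 2))
#' traj$angles
#' @export
dihedral_trajectory <- function(angles, torsion_labels = NULL, energies = NULL,
                                source = "in-memory") {
  if (is.data.frame(angles)) angles <- as.matrix(angles)
  if (!is.matrix(angles) || !is.numeric(angles)) {
    stop("`angles` must be a numeric matrix (snapshots x torsions)")
  }
  if (nrow(angles) < 1L) stop("trajectory must contain at least one snapshot")
  if (is.null(torsion_labels)) {
    torsion_labels <- colnames(angles)
    if (is.null(torsion_labels)) torsion_labels <- paste0("phi", seq_len(ncol(angles)))
  }
  if (length(torsion_labels) != ncol(angles)) {
    stop("`torsion_labels` must name every torsion column")
  }
  if (anyDuplicated(torsion_labels)) stop("torsion labels must be unique")
  if (!is.null(energies)) {
    energies <- as.numeric(energies)
    if (length(energies) != nrow(angles)) {
      stop("`energies` must have one value per snapshot")
    }
    if (any(!is.finite(energies))) stop("`energies` must be finite")
  }
  wrapped <- matrix(wrap_angle(as.numeric(angles)), nrow(angles), ncol(angles))
  colnames(wrapped) <- torsion_labels
  structure(
    list(angles = wrapped, torsion_labels = torsion_labels,
         energies = energies, source = source),
    class = "dihedral_trajectory"
  )
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat("<dihedral_trajectory> ", n_snapshots(x), " snapshots x ",
      n_torsions(x), " torsions", sep = "")
  if (!is.null(x$energies)) cat(" (+energies)")
  cat("\n  source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Number of snapshots in a trajectory
#' @param traj a `dihedral_trajectory`.
#' @return integer count.
#' @export
n_snapshots <- function(traj) nrow(traj$angles)

#' Number of torsions in a trajectory
#' @param traj a `dihedral_trajectory`.
#' @return integer count.
#' @export
n_torsions <- function(traj) ncol(traj$angles)

#' Dihedral angle from four atom positions
#'
#' Standard signed torsion about the 2-3 bond, computed from two plane normals
#' with the atan2 formulation; 0 degrees for a cis (eclipsed) arrangement and
#' 180 degrees for trans.
#'
#' @param p1,p2,p3,p4 numeric length-3 position vectors, or matrices with one
#'   row per frame and columns x, y, z.
#' @return dihedral angle(s) in degrees, wrapped to `(-180, 180]`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2hat <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2hat)
  wrap_angle(atan2(y, x) * 180 / pi)
}
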