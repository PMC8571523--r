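#' Contact featurization settings
#'
#' @param cutoff contact distance cutoff in nm (default 0.5). A residue is
#'   in contact when its minimum heavy-atom distance to the ligand is
#'   strictly below the cutoff.
#' @param heavy_only restrict to heavy atoms when reading real structures.
#' @param residue_indices optional subset of residue indices to featurize.
#' @return Object of class `contact_spec`.
#' @export
contact_spec <- function(cutoff = 0.5, heavy_only = TRUE,
                         residue_indices = NULL) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff, heavy_only = heavy_only,
                 residue_indices = residue_indices),
            class = "contact_spec")
}

#' Bound-pose detection thresholds
#'
#' A frame counts toward the bound pose when the superposition RMSD to the
#' reference pose and the pocket-ligand center-of-mass distance are both
#' strictly below their thresholds; a bound interval must persist for at
#' least `min_dwell_ns`.
#'
#' @param rmsd_max RMSD threshold (nm), default 0.2.
#' @param pocket_distance_max pocket-ligand distance threshold (nm),
#'   default 0.5.
#' @param min_dwell_ns minimum continuous dwell (ns), default 100.
#' @return Object of class `bound_pose_criterion`.
#' @export
bound_pose_criterion <- function(rmsd_max = 0.2, pocket_distance_max = 0.5,
                                 min_dwell_ns = 100) {
  stopifnot(rmsd_max > 0, pocket_distance_max > 0, min_dwell_ns > 0)
  structure(list(rmsd_max = rmsd_max,
                 pocket_distance_max = pocket_distance_max,
                 min_dwell_ns = min_dwell_ns),
            class = "bound_pose_criterion")
}

.min_dist <- function(a, b) {
  # minimum pairwise Euclidean distance between two coordinate matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Binary residue-ligand contact vector for one frame
#'
#' Entry r is 1 iff the minimum distance over atom pairs between the
#' ligand and residue r is strictly below the cutoff (nearest-neighbor
#' contact definition).
#'
#' @param ligand_coords ligand atom coordinates (atoms x d, nm).
#' @param residue_coords list of residue atom coordinate matrices (nm).
#' @param spec a [contact_spec()].
#' @return Integer vector of 0/1 contacts, one entry per residue.
#' @export
contact_vector <- function(ligand_coords, residue_coords,
                           spec = contact_spec()) {
  if (!is.matrix(ligand_coords)) ligand_coords <- matrix(ligand_coords, nrow = 1)
  if (nrow(ligand_coords) < 1) stop("ligand has no atoms")
  out <- integer(length(residue_coords))
  for (r in seq_along(residue_coords)) {
    rc <- residue_coords[[r]]
    if (!is.matrix(rc)) rc <- matrix(rc, nrow = 1)
    if (nrow(rc) < 1) stop(sprintf("residue %d has no atoms", r))
    out[r] <- as.integer(.min_dist(ligand_coords, rc) < spec$cutoff)
  }
  out
}

#' Feature trajectory container
#'
#' @param mat frames x features matrix (binary contacts or real CVs).
#' @param dt_ns time per frame in ns.
#' @param labels feature labels (defaults to column names or `f1..fn`).
#' @param meta optional named list of provenance metadata.
#' @return Object of class `feature_trajectory`.
#' @export
feature_trajectory <- function(mat, dt_ns, labels = NULL, meta = list()) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("feature matrix contains missing values")
  if (is.null(labels)) labels <- colnames(mat) %||% paste0("f", seq_len(ncol(mat)))
  colnames(mat) <- labels
  stopifnot(dt_ns > 0)
  structure(list(mat = mat, dt_ns = dt_ns, labels = labels, meta = meta),
            class = "feature_trajectory")
}

#' Contact featurization of a positional trajectory
#'
#' Converts a ligand trajectory (one ligand position or several ligand
#' atoms per frame) plus fixed residue coordinates into a binary contact
#' feature trajectory.
#'
#' @param traj a `binding_trajectory` from [brownian_binding_sim()], or a
#'   frames x d matrix of ligand positions.
#' @param residues list of residue coordinate matrices; taken from the
#'   trajectory when it carries pseudo-residues.
#' @param spec a [contact_spec()].
#' @param dt_ns frame spacing in ns (required for a bare matrix).
#' @return A [feature_trajectory()] of 0/1 contacts.
#' @export
contact_features <- function(traj, residues = NULL, spec = contact_spec(),
                             dt_ns = NULL) {
  if (inherits(traj, "binding_trajectory")) {
    residues <- residues %||% traj$residues
    dt_ns <- dt_ns %||% traj$dt_ns
    pos <- traj$positions
  } else {
    pos <- as.matrix(traj)
    if (is.null(residues) || is.null(dt_ns))
      stop("residues and dt_ns are required for a bare position matrix")
  }
  if (!is.null(spec$residue_indices)) residues <- residues[spec$residue_indices]
  n <- nrow(pos)
  mat <- matrix(0L, n, length(residues))
  for (r in seq_along(residues)) {
    rc <- residues[[r]]
    if (!is.matrix(rc)) rc <- matrix(rc, nrow = 1)
    if (nrow(rc) < 1) stop(sprintf("residue %d has no atoms", r))
    # per-frame min distance to this residue's atoms, vectorized over frames
    d2min <- rep(Inf, n)
    for (i in seq_len(nrow(rc))) {
      d2 <- rowSums(sweep(pos, 2, rc[i, ])^2)
      d2min <- pmin(d2min, d2)
    }
    mat[, r] <- as.integer(sqrt(d2min) < spec$cutoff)
  }
  labs <- names(residues) %||% sprintf("res%02d", seq_along(residues))
  feature_trajectory(mat, dt_ns, labels = labs,
                     meta = list(cutoff = spec$cutoff))
}

#' Center-of-mass distance between ligand and binding pocket
#'
#' @param ligand_coords ligand atom coordinates (atoms x d, nm).
#' @param pocket_coords pocket atom coordinates (atoms x d, nm).
#' @param ligand_masses,pocket_masses optional atomic masses; unit masses
#'   by default (appropriate for toy data).
#' @return Euclidean distance between the two centers of mass (nm).
#' @export
pocket_ligand_distance <- function(ligand_coords, pocket_coords,
                                   ligand_masses = NULL,
                                   pocket_masses = NULL) {
  com <- function(x, m) {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1)
    if (nrow(x) < 1) stop("empty selection")
    if (is.null(m)) m <- rep(1, nrow(x))
    if (sum(m) <= 0) stop("zero total mass")
    colSums(x * m) / sum(m)
  }
  sqrt(sum((com(ligand_coords, ligand_masses) -
              com(pocket_coords, pocket_masses))^2))
}

#' RMSD after optimal rigid-body superposition
#'
#' Kabsch superposition: the weighted squared deviation is minimized over
#' rotations and translations before the RMSD is evaluated. Reflections
#' are excluded (proper rotations only).
#'
#' @param coords_a,coords_b corresponding coordinate matrices (atoms x d).
#' @param weights optional per-atom weights (e.g. masses); unit by default.
#' @return RMSD in the input length unit.
#' @export
rmsd_after_superposition <- function(coords_a, coords_b, weights = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must match in size")
  n <- nrow(a)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  ca <- sweep(a, 2, colSums(a * w))
  cb <- sweep(b, 2, colSums(b * w))
  if (n < 3 || qr(ca)$rank < 2)
    stop("underdetermined rotation: need >= 3 non-collinear atoms")
  h <- t(ca * w) %*% cb
  s <- svd(h)
  dsign <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(rep(1, ncol(a) - 1), dsign)) %*% t(s$u)
  diffs <- ca %*% t(rot) - cb
  sqrt(sum(w * rowSums(diffs^2)))
}

#' Detect bound-pose intervals in an RMSD / pocket-distance series
#'
#' Returns the maximal intervals during which the superposition RMSD and
#' the pocket-ligand distance are both continuously below their thresholds
#' for at least the minimum dwell time.
#'
#' @param rmsd numeric vector of per-frame RMSD values (nm).
#' @param pocket_distance numeric vector of per-frame pocket distances (nm).
#' @param dt_ns frame spacing (ns).
#' @param criterion a [bound_pose_criterion()].
#' @return data.frame with columns `start`, `end` (frame indices, 1-based)
#'   and `duration_ns`; zero rows when no interval qualifies. Intervals
#'   are disjoint and sorted.
#' @export
detect_bound_state <- function(rmsd, pocket_distance, dt_ns,
                               criterion = bound_pose_criterion()) {
  stopifnot(length(rmsd) == length(pocket_distance), dt_ns > 0)
  ok <- rmsd < criterion$rmsd_max &
    pocket_distance < criterion$pocket_distance_max
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * dt_ns >= criterion$min_dwell_ns)
  data.frame(start = starts[keep], end = ends[keep],
             duration_ns = r$lengths[keep] * dt_ns)
}
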