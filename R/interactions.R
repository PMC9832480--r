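#' Per-frame contact/descriptor series
#'
#' @param times frame times, ps.
#' @param values per-frame values (Angstrom for distances, degrees for
#'   angles/dihedrals).
#' @param flags optional per-frame logical (descriptor inside its window).
#' @return object of class `"contact_series"` with `frequency =
#'   mean(flags)`.
#' @export
contact_series <- function(times, values, flags = NULL) {
  if (length(times) != length(values))
    stop("times and values differ in length")
  if (is.null(flags)) flags <- rep(NA, length(values))
  if (length(flags) != length(values))
    stop("flags and values differ in length")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 flags = as.logical(flags),
                 frequency = if (all(is.na(flags))) NA_real_
                             else mean(flags, na.rm = TRUE)),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> %d frames, frequency %s\n",
              length(x$values),
              ifelse(is.na(x$frequency), "NA", sprintf("%.3f", x$frequency))))
  invisible(x)
}

#' Size of the largest small ring of a bond graph
#'
#' For every non-bridge edge the smallest cycle through it is the
#' shortest path between its endpoints with the edge removed, plus one;
#' the reported ring size is the maximum of these smallest cycles (the
#' largest ring in the smallest-set-of-smallest-rings sense for the
#' macrocyclic chemistry handled here). Acyclic graphs return 0.
#'
#' @param bonds two-column integer matrix of bonded atom index pairs, or
#'   an igraph object.
#' @param n_atoms number of atoms; inferred from `bonds` if missing.
#' @return integer ring size (0 if acyclic).
#' @export
largest_ring_size <- function(bonds, n_atoms = NULL) {
  if (inherits(bonds, "igraph")) {
    g <- bonds
  } else {
    bonds <- as.matrix(bonds)
    if (is.null(n_atoms)) n_atoms <- max(bonds)
    g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
    if (igraph::vcount(g) < n_atoms)
      g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  best <- 0L
  for (e in seq_len(nrow(el))) {
    g2 <- igraph::delete_edges(g, e)
    d <- igraph::distances(g2, v = el[e, 1], to = el[e, 2])[1, 1]
    if (is.finite(d)) best <- max(best, as.integer(d) + 1L)
  }
  best
}

frame_dist <- function(fr, i, j) sqrt(sum((fr[i, ] - fr[j, ])^2))

#' Intramolecular hydrogen-bond time series
#'
#' A frame is flagged as hydrogen-bonded when the H-to-acceptor distance
#' falls inside `distance_window` (default 1.5-2.5 Angstrom, the
#' non-negligible IMHB range) and the donor-H-acceptor angle is at least
#' `angle_min` (the window is defined on the H...A distance, for which
#' that range is physical; the angle cutoff excludes strained
#' near-contacts).
#'
#' @param traj trajectory.
#' @param donor_h atom index of the donor hydrogen (element must be H).
#' @param acceptor atom index of the acceptor heavy atom.
#' @param donor atom index of the donor heavy atom; if `NULL`, the
#'   heavy atom covalently nearest to `donor_h` in the first frame
#'   (within 1.3 Angstrom) is used.
#' @param distance_window H...acceptor window, Angstrom.
#' @param angle_min minimum D-H...A angle, degrees (default 120).
#' @return [contact_series()] of H...acceptor distances with per-frame
#'   flags and overall frequency.
#' @export
hbond_series <- function(traj, donor_h, acceptor, donor = NULL,
                         distance_window = c(1.5, 2.5), angle_min = 120) {
  elem <- toupper(trimws(traj$topology$element))
  if (elem[donor_h] != "H")
    stop("atom ", donor_h, " (", traj$topology$name[donor_h],
         ") is not a hydrogen")
  if (is.null(donor)) {
    fr1 <- traj$frames[[1]]
    heavy <- which(elem != "H")
    d <- sqrt(colSums((t(fr1[heavy, , drop = FALSE]) - fr1[donor_h, ])^2))
    if (min(d) > 1.3)
      stop("no heavy atom within 1.3 A of donor hydrogen ", donor_h,
           " in frame 1; pass `donor` explicitly")
    donor <- heavy[which.min(d)]
  }
  vals <- numeric(length(traj$frames))
  flags <- logical(length(traj$frames))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    dHA <- frame_dist(fr, donor_h, acceptor)
    v1 <- fr[donor, ] - fr[donor_h, ]
    v2 <- fr[acceptor, ] - fr[donor_h, ]
    ang <- angle_deg(v1, v2)
    vals[f] <- dHA
    flags[f] <- dHA >= distance_window[1] && dHA <= distance_window[2] &&
      ang >= angle_min
  }
  contact_series(frame_times(traj), vals, flags)
}

angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' NH-pi contact time series (N to aromatic-ring centroid)
#'
#' Per-frame distance from the amide nitrogen to the unweighted centroid
#' of the aromatic ring atoms; flagged inside the shielding-effective
#' window (default 2.9-3.6 Angstrom).
#'
#' @param traj trajectory.
#' @param n_atom atom index of the amide nitrogen.
#' @param ring_atoms atom indices of the aromatic ring (>= 3).
#' @param window distance window, Angstrom.
#' @return [contact_series()].
#' @export
nh_pi_series <- function(traj, n_atom, ring_atoms, window = c(2.9, 3.6)) {
  nat <- nrow(traj$topology)
  if (length(ring_atoms) < 3L) stop("need >= 3 ring atoms")
  if (any(c(n_atom, ring_atoms) < 1L) || any(c(n_atom, ring_atoms) > nat))
    stop("atom index outside topology (1..", nat, ")")
  vals <- vapply(traj$frames, function(fr) {
    cen <- colMeans(fr[ring_atoms, , drop = FALSE])
    sqrt(sum((fr[n_atom, ] - cen)^2))
  }, numeric(1))
  contact_series(frame_times(traj), vals,
                 vals >= window[1] & vals <= window[2])
}

dihedral_one <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18) return(NA_real_)
  ang <- atan2(sqrt(sum(b2^2)) * sum(b1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral-angle time series
#'
#' Signed IUPAC dihedral a-b-c-d per frame, right-handed convention,
#' reported in degrees in (-180, 180]. A 0-degree dihedral is the cis
#' (eclipsed) arrangement, 180 the trans. Typical use: the backbone
#' phi/psi angles of the dipeptide fragment within a macrocyclic ring,
#' with the four atoms declared by the user.
#'
#' @param traj trajectory.
#' @param a,b,c,d four distinct atom indices.
#' @return [contact_series()] in degrees (no flags).
#' @export
dihedral_series <- function(traj, a, b, c, d) {
  idx <- c(a, b, c, d)
  if (anyDuplicated(idx)) stop("dihedral atoms must be distinct")
  vals <- numeric(length(traj$frames))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    v <- dihedral_one(fr[a, ], fr[b, ], fr[c, ], fr[d, ])
    if (is.na(v))
      stop("dihedral undefined at frame ", f, ": collinear atom triple")
    vals[f] <- v
  }
  contact_series(frame_times(traj), vals)
}

#' RMSD time series against a reference structure
#'
#' Per-frame least-squares superposed RMSD (via [superpose()]) with
#' respect to a reference geometry, typically the initial structure, over
#' a declared atom selection (e.g. the heavy atoms of the macrocyclic
#' ring).
#'
#' @param traj trajectory.
#' @param reference conformer (or `n x 3` matrix) to superpose onto.
#' @param selection atom indices used for fitting and RMSD; default all.
#' @return [contact_series()] of RMSD values, Angstrom (no flags).
#' @export
rmsd_series <- function(traj, reference, selection = NULL) {
  vals <- vapply(traj$frames, function(fr) {
    superpose(reference, fr, selection = selection)$rmsd
  }, numeric(1))
  contact_series(frame_times(traj), vals)
}

#' Two-state classification of a descriptor series
#'
#' Splits a 1-D descriptor series (typically the ring-RMSD series of a
#' switching trajectory) into two conformational states with a two-means
#' fit (deterministic min/max initialization; the decision boundary is
#' the midpoint of the fitted centers). State 1 is the cluster closer to
#' the reference geometry (lower values). The series is accepted as
#' two-state only when the split explains at least `min_explained` of
#' the series variance: an optimal two-means split of any unimodal
#' distribution explains markedly less (about 0.64 for a Gaussian, 0.75
#' for a uniform), whereas well-separated conformational states approach
#' 1. Below the cutoff a single-state assignment with populations (1, 0)
#' is returned with a warning.
#'
#' @param series [contact_series()] or numeric vector (>= 2 frames).
#' @param min_explained minimum variance fraction the two-cluster split
#'   must explain for a two-state call (default 0.8).
#' @return object of class `"state_assignment"`: `labels` (integer 1/2
#'   per frame), `populations` (length-2, sums to 1), `boundary` (list
#'   with the fitted centers and threshold).
#' @export
classify_states <- function(series, min_explained = 0.8) {
  x <- if (inherits(series, "contact_series")) series$values else
    as.numeric(series)
  if (length(x) < 2L) stop("need >= 2 frames to classify states")
  if (diff(range(x)) == 0) {
    warning("constant series: single conformational state")
    return(state_assignment(rep(1L, length(x)),
                            boundary = list(centers = c(x[1], NA),
                                            threshold = NA_real_)))
  }
  centers <- c(min(x), max(x))
  for (it in 1:100) {
    lab <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
    new <- c(mean(x[lab == 1L]), mean(x[lab == 2L]))
    if (anyNA(new) || max(abs(new - centers)) < 1e-12) break
    centers <- new
  }
  lab <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
  explained <- 1 - sum((x - centers[lab])^2) / sum((x - mean(x))^2)
  if (explained < min_explained) {
    warning("series looks unimodal (two-cluster split explains ",
            round(explained, 3), " of the variance): ",
            "single conformational state")
    return(state_assignment(rep(1L, length(x)),
                            boundary = list(centers = centers,
                                            threshold = NA_real_,
                                            explained = explained)))
  }
  state_assignment(lab, boundary = list(centers = centers,
                                        threshold = mean(centers),
                                        explained = explained))
}

state_assignment <- function(labels, boundary = list()) {
  p <- c(mean(labels == 1L), mean(labels == 2L))
  structure(list(labels = labels, populations = p, boundary = boundary),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("<state_assignment> %d frames: state1 %.3f / state2 %.3f\n",
              length(x$labels), x$populations[1], x$populations[2]))
  invisible(x)
}

#' Two-state classification by amide-face geometry
#'
#' Geometric classifier: fits the mean plane of the macrocycle ring
#' atoms per frame (least squares; the plane normal is the smallest
#' principal direction of the centered ring coordinates) and takes the
#' sign of the out-of-plane component of each N-H vector. The two N-H
#' groups on opposite faces of the ring is state 1; on the same face,
#' state 2 (interconversion corresponds to an in-plane amide rotation).
#'
#' @param traj trajectory.
#' @param ring_atoms atom indices of the macrocycle ring (>= 3).
#' @param nh1,nh2 length-2 integer vectors `c(N_index, H_index)` for the
#'   two amide N-H groups.
#' @return `"state_assignment"` as in [classify_states()].
#' @export
classify_states_faces <- function(traj, ring_atoms, nh1, nh2) {
  if (length(traj$frames) < 2L) stop("need >= 2 frames to classify states")
  lab <- integer(length(traj$frames))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    ring <- fr[ring_atoms, , drop = FALSE]
    cen <- colMeans(ring)
    normal <- svd(sweep(ring, 2, cen))$v[, 3]  # least-squares plane normal
    s1 <- sign(sum((fr[nh1[2], ] - fr[nh1[1], ]) * normal))
    s2 <- sign(sum((fr[nh2[2], ] - fr[nh2[1], ]) * normal))
    lab[f] <- if (s1 * s2 < 0) 1L else 2L
  }
  state_assignment(lab, boundary = list(method = "face-sign"))
}
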