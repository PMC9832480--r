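#' Least-squares (Kabsch) superposition of two conformers
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms of `mob` onto `ref`. The result is invariant to any
#' rigid pre-transformation of `mob`.
#'
#' @param ref,mob conformers with identical atom ordering (or bare
#'   `n x 3` coordinate matrices).
#' @param selection integer atom indices to superpose on (>= 3,
#'   non-collinear). Default: all atoms.
#' @return list of class `"superposition"`: `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom), `rmsd` (Angstrom, over the
#'   selection). The fitted mobile coordinates are
#'   `xyz %*% t(rotation) + translation` (rows).
#' @export
superpose <- function(ref, mob, selection = NULL) {
  X <- if (inherits(ref, "conformer")) ref$xyz else as.matrix(ref)
  Y <- if (inherits(mob, "conformer")) mob$xyz else as.matrix(mob)
  if (nrow(X) != nrow(Y))
    stop("conformers differ in atom count (", nrow(X), " vs ", nrow(Y), ")")
  if (is.null(selection)) selection <- seq_len(nrow(X))
  if (length(selection) < 3L)
    stop("superposition needs >= 3 selected atoms")
  x <- X[selection, , drop = FALSE]
  y <- Y[selection, , drop = FALSE]
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  sv <- svd(xc)  # degenerate selections have < 2 spread directions
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) atom selection: superposition undefined")
  s <- svd(crossprod(yc, xc))          # 3x3 covariance, Kabsch
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)            # maps mobile -> reference frame
  fit <- yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - xc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cx - R %*% cy),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param xyz `n x 3` matrix.
#' @param sp superposition from [superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(xyz, sp) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, `+`)
}

heavy_atom_indices <- function(cf) {
  which(toupper(trimws(cf$atoms$element)) != "H")
}

#' Eliminate duplicate conformers, assigning a degeneracy index
#'
#' Greedy in input order: each conformer is compared (superposed RMSD
#' over heavy atoms by default) against the representatives retained so
#' far; at RMSD <= `rmsd_threshold` it is absorbed and the
#' representative's degeneracy index is incremented by the duplicate's
#' degeneracy. The degeneracy index thus counts how many times each
#' conformation was found in the sampling; total degeneracy mass is
#' conserved.
#'
#' @param ens ensemble with uniform atom ordering.
#' @param rmsd_threshold duplicate-elimination RMSD cutoff, Angstrom
#'   (default 0.75).
#' @param heavy_only compare heavy atoms only (default `TRUE`; hydrogen
#'   placement is noisy).
#' @return ensemble of unique conformers; pairwise RMSD between retained
#'   conformers exceeds the threshold; `sum(degeneracy)` equals the input
#'   total.
#' @export
deduplicate <- function(ens, rmsd_threshold = 0.75, heavy_only = TRUE) {
  if (!inherits(ens, "ensemble")) stop("`ens` must be an ensemble")
  sel <- if (heavy_only) heavy_atom_indices(ens$conformers[[1]])
         else seq_len(n_atoms(ens$conformers[[1]]))
  if (length(sel) < 3L) sel <- seq_len(n_atoms(ens$conformers[[1]]))
  keep <- integer(0)
  deg <- integer(0)
  for (i in seq_along(ens$conformers)) {
    absorbed <- FALSE
    for (k in seq_along(keep)) {
      r <- superpose(ens$conformers[[keep[k]]], ens$conformers[[i]],
                     selection = sel)$rmsd
      if (r <= rmsd_threshold) {
        deg[k] <- deg[k] + ens$degeneracy[i]
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      keep <- c(keep, i)
      deg <- c(deg, ens$degeneracy[i])
    }
  }
  out <- ensemble_subset(ens, keep)
  out$degeneracy <- deg
  out
}

#' Select the conformers with the highest degeneracy index
#'
#' Ties are broken by lower energy, then input order, so repeated runs
#' are deterministic. Missing energies rank equal (input order decides).
#'
#' @param ens ensemble with degeneracies assigned (see [deduplicate()]).
#' @param n number of conformers to keep (default 10).
#' @return ensemble of the `n` most-degenerate conformers, in selection
#'   order. When `n` exceeds the ensemble size all conformers are
#'   returned with a warning.
#' @export
select_top_degeneracy <- function(ens, n = 10) {
  if (n > length(ens$conformers)) {
    warning("requested ", n, " conformers but ensemble has only ",
            length(ens$conformers), "; returning all")
    n <- length(ens$conformers)
  }
  e <- ensemble_energies(ens)
  e[is.na(e)] <- 0  # no energies yet (pre-DFT): fall through to input order
  ord <- order(-ens$degeneracy, e, seq_along(ens$conformers))
  ensemble_subset(ens, ord[seq_len(n)])
}

#' Retain conformers within an energy window of the minimum
#'
#' Keeps conformers with `E - min(E) <= window`; the minimum-energy
#' conformer is always retained. Monotone: a larger window retains a
#' superset.
#'
#' @param ens ensemble with energies.
#' @param window energy window, kcal/mol (default 10).
#' @return filtered ensemble.
#' @export
energy_window_filter <- function(ens, window = 10) {
  e <- ensemble_energies(ens, require = TRUE)
  ensemble_subset(ens, which(e - min(e) <= window))
}

#' Minimum-energy conformer (MEC) of an ensemble
#'
#' The MEC is used as the representative conformation in single-structure
#' protocols. Ties go to the first conformer in input order (logged).
#'
#' @param ens ensemble with energies.
#' @return the lowest-energy [conformer()].
#' @export
minimum_energy_conformer <- function(ens) {
  e <- ensemble_energies(ens, require = TRUE)
  i <- which.min(e)
  if (sum(e == e[i]) > 1L)
    message("MEC tie at ", e[i], " kcal/mol; keeping first in input order (",
            conformer_ids(ens)[i], ")")
  ens$conformers[[i]]
}

#' Boltzmann weights from conformer energies
#'
#' Weights proportional to `exp(-(E - min(E)) / (R*T))` with the gas
#' constant R = 1.98720425e-3 kcal/(mol K), normalized to sum to 1.
#'
#' @param energies numeric vector, kcal/mol.
#' @param temperature absolute temperature, K (default 300, the usual
#'   simulation thermostat setting).
#' @return numeric weight vector summing to 1.
#' @export
boltzmann_weights <- function(energies, temperature = 300) {
  if (length(energies) == 0L) stop("no energies given")
  if (anyNA(energies)) stop("missing energies")
  if (temperature <= 0) stop("temperature must be > 0 K")
  R <- 1.98720425e-3
  w <- exp(-(energies - min(energies)) / (R * temperature))
  w / sum(w)
}

#' Subsample a trajectory at a fixed stride
#'
#' Unbiased every-`stride`-th frame selection, tail-aligned: frames
#' `stride, 2*stride, ...` are kept, giving `floor(N / stride)`
#' conformers (5000 frames at stride 500 give 10).
#'
#' @param traj trajectory.
#' @param stride frame stride (>= 1).
#' @param compound_id id attached to the resulting ensemble.
#' @return [ensemble()] of the selected frames, conformer ids
#'   `frame<index>`.
#' @export
subsample_every <- function(traj, stride, compound_id = "trajectory") {
  if (stride < 1L) stop("stride must be >= 1")
  n <- length(traj$frames)
  if (stride > n)
    stop("stride ", stride, " exceeds trajectory length ", n,
         ": no frames selected")
  idx <- seq.int(stride, n, by = stride)
  confs <- lapply(idx, function(i) {
    conformer(traj$topology, traj$frames[[i]],
              conformer_id = paste0("frame", i))
  })
  ensemble(confs, compound_id = compound_id)
}
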