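#' Construct a conformer
#'
#' A conformer is one 3D structure of a compound: an atom table plus an
#' `n x 3` coordinate matrix in Angstrom, optionally carrying a potential
#' energy in kcal/mol. Atom indices are the R-native 1-based row positions
#' of `atoms`.
#'
#' @param atoms data.frame with columns `name` (atom label) and `element`
#'   (element symbol). Row order defines atom order.
#' @param xyz numeric matrix, `nrow(atoms)` x 3, coordinates in Angstrom.
#' @param energy optional potential energy, kcal/mol. `NA` when unknown
#'   (e.g. raw MCMM geometries before any energy evaluation).
#' @param conformer_id character scalar identifying the conformer; joins
#'   against shielding tables are done on this id, never on position.
#' @return object of class `"conformer"`.
#' @export
conformer <- function(atoms, xyz, energy = NA_real_, conformer_id = "conf1") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(c("name", "element") %in% names(atoms)))
    stop("`atoms` must have columns 'name' and 'element'")
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L)
    stop("`xyz` must have 3 columns")
  if (nrow(xyz) != nrow(atoms))
    stop("atom table (", nrow(atoms), ") and coordinates (", nrow(xyz),
         ") disagree on atom count")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates")
  structure(
    list(atoms = atoms, xyz = xyz,
         energy = as.numeric(energy)[1],
         conformer_id = as.character(conformer_id)[1]),
    class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %s: %d atoms, energy %s kcal/mol\n",
              x$conformer_id, nrow(x$atoms),
              ifelse(is.na(x$energy), "NA", format(x$energy))))
  invisible(x)
}

n_atoms <- function(x) nrow(x$atoms)

#' Construct a conformer ensemble
#'
#' An ordered collection of conformers of one compound, sharing atom count
#' and atom ordering, each with a degeneracy count (how many times that
#' conformation recurred during iterative sampling; 1 for conformers that
#' have not passed through [deduplicate()]).
#'
#' @param conformers list of [conformer()] objects with identical atom
#'   count and ordering.
#' @param compound_id character scalar.
#' @param solvent solvent descriptor, see [solvent_spec()].
#' @param degeneracy integer vector of per-conformer degeneracies (>= 1);
#'   recycled from 1 if omitted.
#' @return object of class `"ensemble"`.
#' @export
ensemble <- function(conformers, compound_id = "compound",
                     solvent = solvent_spec("other"), degeneracy = NULL) {
  if (length(conformers) == 0L) stop("empty ensemble")
  if (!all(vapply(conformers, inherits, logical(1), "conformer")))
    stop("`conformers` must be a list of conformer objects")
  na <- vapply(conformers, n_atoms, integer(1))
  if (length(unique(na)) != 1L)
    stop("all conformers of an ensemble must share one atom count; got ",
         paste(unique(na), collapse = ", "))
  if (is.null(degeneracy)) degeneracy <- rep(1L, length(conformers))
  degeneracy <- as.integer(degeneracy)
  if (length(degeneracy) != length(conformers) || any(degeneracy < 1L))
    stop("`degeneracy` must give a positive count per conformer")
  structure(
    list(compound_id = as.character(compound_id)[1], solvent = solvent,
         conformers = conformers, degeneracy = degeneracy),
    class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %s in %s: %d conformers (%d atoms), total degeneracy %d\n",
              x$compound_id, x$solvent$name, length(x$conformers),
              n_atoms(x$conformers[[1]]), sum(x$degeneracy)))
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$conformers)

#' Solvent descriptor
#'
#' Names the environment a conformer ensemble was sampled in. The two
#' solvents of interest for chameleonicity contrast an apolar medium
#' (chloroform, dielectric constant 4.8) with a polar one (DMSO, 46.7);
#' any other medium is declared by its dielectric constant.
#'
#' @param name one of `"CHCl3"`, `"DMSO"`, `"other"`.
#' @param epsilon relative dielectric constant; required for `"other"`,
#'   filled in for the two named solvents.
#' @return list with elements `name` and `epsilon`.
#' @export
solvent_spec <- function(name = c("CHCl3", "DMSO", "other"), epsilon = NULL) {
  name <- match.arg(name)
  eps <- switch(name, CHCl3 = 4.8, DMSO = 46.7, other = epsilon)
  if (is.null(eps)) eps <- NA_real_
  list(name = name, epsilon = as.numeric(eps))
}

#' Extract per-conformer energies from an ensemble
#'
#' @param x ensemble.
#' @param require logical; error (rather than return `NA`s) when any
#'   energy is missing. Operations defined on energies (window filtering,
#'   MEC selection, Boltzmann weighting) require them.
#' @return numeric vector, kcal/mol.
#' @export
ensemble_energies <- function(x, require = FALSE) {
  e <- vapply(x$conformers, function(cf) cf$energy, numeric(1))
  if (require && anyNA(e))
    stop("ensemble '", x$compound_id, "' is missing energies for conformer(s): ",
         paste(conformer_ids(x)[is.na(e)], collapse = ", "),
         ". Attach energies before energy-dependent operations.")
  e
}

#' Conformer ids of an ensemble
#' @param x ensemble.
#' @return character vector.
#' @export
conformer_ids <- function(x) {
  vapply(x$conformers, function(cf) cf$conformer_id, character(1))
}

#' Subset an ensemble by conformer index
#'
#' Keeps compound/solvent metadata and the corresponding degeneracies.
#'
#' @param x ensemble.
#' @param idx integer indices of the conformers to retain, in order.
#' @return ensemble.
#' @export
ensemble_subset <- function(x, idx) {
  ensemble(x$conformers[idx], compound_id = x$compound_id,
           solvent = x$solvent, degeneracy = x$degeneracy[idx])
}

#' Attach energies to an ensemble by conformer id
#'
#' @param x ensemble.
#' @param energies named numeric vector, kcal/mol, names = conformer ids.
#' @return ensemble with energies set; unmatched conformers keep theirs.
#' @export
set_energies <- function(x, energies) {
  ids <- conformer_ids(x)
  for (i in seq_along(x$conformers)) {
    if (ids[i] %in% names(energies))
      x$conformers[[i]]$energy <- as.numeric(energies[[ids[i]]])
  }
  x
}

#' Construct a trajectory
#'
#' Time-ordered coordinate frames over one fixed topology, with a frame
#' spacing `dt` in picoseconds.
#'
#' @param topology data.frame of atoms (columns `name`, `element`).
#' @param frames list of `n_atoms` x 3 coordinate matrices, Angstrom.
#' @param dt frame spacing, ps (> 0).
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(topology, frames, dt) {
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  if (length(frames) == 0L) stop("empty trajectory")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a positive frame spacing in ps")
  nat <- nrow(topology)
  for (i in seq_along(frames)) {
    fr <- as.matrix(frames[[i]])
    if (nrow(fr) != nat || ncol(fr) != 3L)
      stop("frame ", i, " has ", nrow(fr), " atoms; topology has ", nat)
    frames[[i]] <- fr
  }
  structure(list(topology = topology, frames = frames, dt = as.numeric(dt)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, dt = %g ps (%g ns total)\n",
              length(x$frames), nrow(x$topology), x$dt,
              length(x$frames) * x$dt / 1000))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Frame times of a trajectory
#' @param x trajectory.
#' @return numeric vector of times in ps (dt, 2*dt, ...).
#' @export
frame_times <- function(x) seq_along(x$frames) * x$dt

#' Construct a shielding table
#'
#' Per-conformer, per-atom isotropic shieldings (sigma, ppm) plus the
#' reference shielding sigma_ref of the shift standard (TMS for 1H) at the
#' same level of theory. sigma_ref is level-of-theory dependent and must
#' be supplied by the user; no default is shipped.
#'
#' @param entries data.frame with columns `conformer_id`, `atom_label`,
#'   `sigma` (ppm). (conformer_id, atom_label) pairs must be unique.
#' @param sigma_ref reference shielding, ppm.
#' @return object of class `"shielding_table"`.
#' @export
shielding_table <- function(entries, sigma_ref) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("conformer_id", "atom_label", "sigma")
  if (!all(need %in% names(entries)))
    stop("shielding entries need columns: ", paste(need, collapse = ", "))
  key <- paste(entries$conformer_id, entries$atom_label, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (conformer_id, atom_label) keys: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  if (!is.numeric(sigma_ref) || length(sigma_ref) != 1L || !is.finite(sigma_ref))
    stop("`sigma_ref` must be a single finite shielding in ppm")
  structure(list(entries = entries[need], sigma_ref = as.numeric(sigma_ref)),
            class = "shielding_table")
}

#' Construct a chemical-shift table
#'
#' Chemical shifts delta (ppm) keyed by (compound, proton label, solvent).
#' Holds either experimental shifts or back-calculated predictions.
#'
#' @param entries data.frame with columns `compound_id`, `proton_label`,
#'   `solvent`, `delta` (ppm); keys must be unique.
#' @param label_set optional character vector of allowed proton labels
#'   (e.g. `c("NH-I","NH-II","NH-III")`); labels outside it are an error.
#' @return object of class `"shift_table"`.
#' @export
shift_table <- function(entries, label_set = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("compound_id", "proton_label", "solvent", "delta")
  if (!all(need %in% names(entries)))
    stop("shift entries need columns: ", paste(need, collapse = ", "))
  key <- paste(entries$compound_id, entries$proton_label, entries$solvent,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (compound, proton, solvent) keys: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  if (!is.null(label_set)) {
    bad <- setdiff(unique(entries$proton_label), label_set)
    if (length(bad))
      stop("proton labels outside the declared label set: ",
           paste(bad, collapse = ", "))
  }
  structure(list(entries = entries[need], label_set = label_set),
            class = "shift_table")
}

#' Construct a NOESY integral table
#'
#' Absolute cross- and diagonal-peak integrals across a series of mixing
#' times. At least four mixing times are required for initial-rate
#' build-up fitting.
#'
#' @param cross data.frame with columns `proton_i`, `proton_j`,
#'   `mixing_time_ms`, `integral` (>= 0).
#' @param diagonal data.frame with columns `proton`, `mixing_time_ms`,
#'   `integral` (>= 0).
#' @return object of class `"noesy_table"` with element `mixing_times`
#'   (sorted unique mixing times, ms).
#' @export
noesy_table <- function(cross, diagonal) {
  cross <- as.data.frame(cross, stringsAsFactors = FALSE)
  diagonal <- as.data.frame(diagonal, stringsAsFactors = FALSE)
  needc <- c("proton_i", "proton_j", "mixing_time_ms", "integral")
  needd <- c("proton", "mixing_time_ms", "integral")
  if (!all(needc %in% names(cross)))
    stop("cross table needs columns: ", paste(needc, collapse = ", "))
  if (!all(needd %in% names(diagonal)))
    stop("diagonal table needs columns: ", paste(needd, collapse = ", "))
  # normalize storage so files round-trip bit-exactly
  cross$proton_i <- as.character(cross$proton_i)
  cross$proton_j <- as.character(cross$proton_j)
  cross$mixing_time_ms <- as.numeric(cross$mixing_time_ms)
  cross$integral <- as.numeric(cross$integral)
  diagonal$proton <- as.character(diagonal$proton)
  diagonal$mixing_time_ms <- as.numeric(diagonal$mixing_time_ms)
  diagonal$integral <- as.numeric(diagonal$integral)
  if (any(cross$integral < 0) || any(diagonal$integral < 0))
    stop("NOESY integrals are absolute values and must be >= 0")
  kc <- paste(cross$proton_i, cross$proton_j, cross$mixing_time_ms, sep = "\r")
  kd <- paste(diagonal$proton, diagonal$mixing_time_ms, sep = "\r")
  if (anyDuplicated(kc) || anyDuplicated(kd))
    stop("duplicate keys in NOESY table: ",
         paste(unique(gsub("\r", "/", c(kc[duplicated(kc)], kd[duplicated(kd)]))),
               collapse = ", "))
  mt <- sort(unique(c(cross$mixing_time_ms, diagonal$mixing_time_ms)))
  structure(list(mixing_times = mt, cross = cross[needc],
                 diagonal = diagonal[needd]),
            class = "noesy_table")
}

#' @export
print.noesy_table <- function(x, ...) {
  cat(sprintf("<noesy_table> %d mixing times (%g-%g ms), %d cross / %d diagonal integrals\n",
              length(x$mixing_times), min(x$mixing_times), max(x$mixing_times),
              nrow(x$cross), nrow(x$diagonal)))
  invisible(x)
}
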