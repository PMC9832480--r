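#' Read a conformer ensemble from a structure file
#'
#' Supported formats: multi-model PDB (`MODEL`/`ENDMDL` records, one model
#' per conformer; parsed via bio3d), SDF V2000 (one record per conformer;
#' parsed via ChemmineR, with per-record energies read from a declared
#' datablock property tag), and multi-frame XYZ (concatenated XYZ blocks).
#' Atom order in the file is preserved exactly.
#'
#' @param path file path.
#' @param format one of `"pdb_multimodel"`, `"sdf"`, `"xyz_multi"`.
#' @param compound_id compound identifier attached to the ensemble.
#' @param solvent [solvent_spec()] attached to the ensemble.
#' @param energies optional named numeric vector (kcal/mol) keyed by
#'   conformer id, attached after reading (energies usually travel in a
#'   separate table, see [read_energy_table()]).
#' @param energy_tag SDF datablock field holding the conformer energy in
#'   kcal/mol (default `"energy"`); ignored for other formats.
#' @return [ensemble()] with conformer ids `conf1`, `conf2`, ...
#' @export
read_conformers <- function(path,
                            format = c("pdb_multimodel", "sdf", "xyz_multi"),
                            compound_id = "compound",
                            solvent = solvent_spec("other"),
                            energies = NULL, energy_tag = "energy") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  confs <- switch(format,
                  pdb_multimodel = read_pdb_models(path),
                  sdf = read_sdf_records(path, energy_tag),
                  xyz_multi = read_xyz_frames(path))
  na <- vapply(confs, n_atoms, integer(1))
  if (length(unique(na)) != 1L)
    stop("atom counts differ across models of ", path, ": model ",
         which(na != na[1])[1], " has ", na[which(na != na[1])[1]],
         " atoms, model 1 has ", na[1])
  ens <- ensemble(confs, compound_id = compound_id, solvent = solvent)
  if (!is.null(energies)) ens <- set_energies(ens, energies)
  ens
}

read_pdb_models <- function(path) {
  # pre-scan model atom counts so a mismatch names the offending model
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- grep("^MODEL", rec)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (length(model_starts) > 1L) {
    ends <- c(model_starts[-1] - 1L, length(lines))
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, ends)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stop("atom counts differ across models of ", path, ": model ", bad,
           " has ", counts[bad], " atoms, model 1 has ", counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(pdb$atom$elety), 1, 1)
  atoms <- data.frame(name = trimws(pdb$atom$elety),
                      element = trimws(elem), stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    conformer(atoms, matrix(xyz[m, ], ncol = 3, byrow = TRUE),
              conformer_id = paste0("conf", m))
  })
}

read_sdf_records <- function(path, energy_tag) {
  sdf <- ChemmineR::read.SDFset(path)
  lapply(seq_along(sdf), function(m) {
    rec <- sdf[[m]]
    ab <- ChemmineR::atomblock(rec)
    elem <- gsub("_.*$", "", rownames(ab))
    atoms <- data.frame(name = rownames(ab), element = elem,
                        stringsAsFactors = FALSE)
    db <- ChemmineR::datablock(rec)
    energy <- NA_real_
    if (length(db) && energy_tag %in% names(db))
      energy <- suppressWarnings(as.numeric(db[[energy_tag]]))
    conformer(atoms, ab[, 1:3, drop = FALSE], energy = energy,
              conformer_id = paste0("conf", m))
  })
}

# Multi-frame XYZ: repeated blocks of (natoms line, comment line, atom lines).
read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  confs <- list()
  i <- 1L
  m <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("malformed XYZ at line ", i, " of ", path,
           ": expected an atom count, got '", lines[i], "'")
    m <- m + 1L
    if (i + 1L + nat > length(lines))
      stop("truncated XYZ frame ", m, " in ", path)
    body <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(tok) < 4L))
      stop("malformed atom line in XYZ frame ", m, " of ", path)
    elem <- vapply(tok, `[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    confs[[m]] <- conformer(
      data.frame(name = paste0(elem, seq_len(nat)), element = elem,
                 stringsAsFactors = FALSE),
      xyz, conformer_id = paste0("conf", m))
    i <- i + 2L + nat
  }
  if (length(confs) == 0L) stop("no XYZ frames found in ", path)
  confs
}

#' Write conformers as a multi-frame XYZ file
#'
#' @param x ensemble or trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  if (inherits(x, "trajectory")) {
    atoms <- x$topology; coords <- x$frames
    ids <- paste0("frame", seq_along(coords))
  } else {
    atoms <- x$conformers[[1]]$atoms
    coords <- lapply(x$conformers, `[[`, "xyz")
    ids <- conformer_ids(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(coords)) {
    writeLines(c(as.character(nrow(atoms)), ids[m]), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", atoms$element,
                       coords[[m]][, 1], coords[[m]][, 2], coords[[m]][, 3]),
               con)
  }
  invisible(path)
}

#' Read a trajectory
#'
#' Frames come from a multi-frame structure file; the topology (atom
#' names/elements) from a separate single-structure file, or from the
#' first frame when `topology_path` is `NULL`.
#'
#' @param path multi-frame file with the coordinates.
#' @param topology_path optional single-structure file defining the atoms.
#' @param dt frame spacing, ps.
#' @param format,topology_format formats as in [read_conformers()].
#' @return [trajectory()]; frame order is preserved.
#' @export
read_trajectory <- function(path, topology_path = NULL, dt,
                            format = c("xyz_multi", "pdb_multimodel", "sdf"),
                            topology_format = format) {
  format <- match.arg(format)
  ens <- read_conformers(path, format = format)
  topo <- ens$conformers[[1]]$atoms
  if (!is.null(topology_path)) {
    tens <- read_conformers(topology_path, format = topology_format)
    topo <- tens$conformers[[1]]$atoms
    if (nrow(topo) != n_atoms(ens$conformers[[1]]))
      stop("topology has ", nrow(topo), " atoms but frames have ",
           n_atoms(ens$conformers[[1]]))
  }
  trajectory(topo, lapply(ens$conformers, `[[`, "xyz"), dt = dt)
}

read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, dec = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, " is missing required column(s): ", paste(miss, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", dec = ".", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write isotropic shielding tables
#'
#' TSV with one header row and columns `conformer_id`, `atom_label`,
#' `sigma` (ppm). The reference shielding of the shift standard is passed
#' separately: it depends on the level of theory and is never defaulted.
#'
#' @param path TSV path.
#' @param sigma_ref reference shielding, ppm (e.g. TMS 1H at the same
#'   level of theory as the table).
#' @return [shielding_table()].
#' @export
read_shielding_table <- function(path, sigma_ref) {
  shielding_table(read_tsv(path, c("conformer_id", "atom_label", "sigma")),
                  sigma_ref = sigma_ref)
}

#' @rdname read_shielding_table
#' @param x shielding_table.
#' @export
write_shielding_table <- function(x, path) write_tsv(x$entries, path)

#' Read/write chemical-shift tables
#'
#' TSV with columns `compound_id`, `proton_label`, `solvent`, `delta`
#' (ppm).
#'
#' @param path TSV path.
#' @param label_set optional allowed proton labels (see [shift_table()]).
#' @return [shift_table()].
#' @export
read_shift_table <- function(path, label_set = NULL) {
  shift_table(read_tsv(path, c("compound_id", "proton_label", "solvent",
                               "delta")),
              label_set = label_set)
}

#' @rdname read_shift_table
#' @param x shift_table.
#' @export
write_shift_table <- function(x, path) write_tsv(x$entries, path)

#' Read/write NOESY integral tables
#'
#' Long-format TSV with columns `type` (`cross` or `diagonal`),
#' `proton_i`, `proton_j` (empty for diagonal rows), `mixing_time_ms`,
#' `integral`.
#'
#' @param path TSV path.
#' @return [noesy_table()].
#' @export
read_noesy_table <- function(path) {
  df <- read_tsv(path, c("type", "proton_i", "proton_j", "mixing_time_ms",
                         "integral"))
  cr <- df[df$type == "cross", ]
  di <- df[df$type == "diagonal", ]
  noesy_table(
    cross = data.frame(proton_i = cr$proton_i, proton_j = cr$proton_j,
                       mixing_time_ms = cr$mixing_time_ms,
                       integral = cr$integral, stringsAsFactors = FALSE),
    diagonal = data.frame(proton = di$proton_i,
                          mixing_time_ms = di$mixing_time_ms,
                          integral = di$integral, stringsAsFactors = FALSE))
}

#' @rdname read_noesy_table
#' @param x noesy_table.
#' @export
write_noesy_table <- function(x, path) {
  df <- rbind(
    data.frame(type = "cross", proton_i = x$cross$proton_i,
               proton_j = x$cross$proton_j,
               mixing_time_ms = x$cross$mixing_time_ms,
               integral = x$cross$integral, stringsAsFactors = FALSE),
    data.frame(type = "diagonal", proton_i = x$diagonal$proton,
               proton_j = "",
               mixing_time_ms = x$diagonal$mixing_time_ms,
               integral = x$diagonal$integral, stringsAsFactors = FALSE))
  write_tsv(df, path)
}

#' Read a per-conformer energy table
#'
#' TSV with columns `conformer_id`, `energy` (kcal/mol).
#'
#' @param path TSV path.
#' @return named numeric vector suitable for [set_energies()].
#' @export
read_energy_table <- function(path) {
  df <- read_tsv(path, c("conformer_id", "energy"))
  if (anyDuplicated(df$conformer_id))
    stop("duplicate conformer_id in ", path, ": ",
         paste(unique(df$conformer_id[duplicated(df$conformer_id)]),
               collapse = ", "))
  stats::setNames(as.numeric(df$energy), df$conformer_id)
}
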