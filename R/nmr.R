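#' Chemical shift from isotropic shielding
#'
#' delta = sigma_ref - sigma (ppm), referencing the shielding of the
#' shift standard (TMS for 1H) computed at the same level of theory.
#' Negative shifts (sigma > sigma_ref) are permitted.
#'
#' @param sigma isotropic shielding(s), ppm.
#' @param sigma_ref reference shielding, ppm.
#' @return chemical shift(s), ppm.
#' @export
shift_from_shielding <- function(sigma, sigma_ref) {
  if (!all(is.finite(sigma)) || !all(is.finite(sigma_ref)))
    stop("shieldings must be finite")
  sigma_ref - sigma
}

#' Per-conformer chemical shifts from a shielding table
#'
#' @param st [shielding_table()].
#' @return data.frame with columns `conformer_id`, `atom_label`, `delta`.
#' @export
shifts_by_conformer <- function(st) {
  data.frame(conformer_id = st$entries$conformer_id,
             atom_label = st$entries$atom_label,
             delta = shift_from_shielding(st$entries$sigma, st$sigma_ref),
             stringsAsFactors = FALSE)
}

#' Ensemble-averaged chemical shifts
#'
#' Filters the ensemble to conformers within `window` kcal/mol of the
#' MEC (via [energy_window_filter()]), then averages each proton's shift
#' across the retained conformers: an unweighted mean by default, or a
#' Boltzmann-weighted mean at temperature `temperature`. With one
#' conformer the averaging is the identity.
#'
#' @param shifts per-conformer shifts: data.frame with columns
#'   `conformer_id`, `atom_label`, `delta` (see [shifts_by_conformer()]).
#' @param ens ensemble with energies; joined on conformer id.
#' @param window energy window, kcal/mol (default 10). `Inf` retains all.
#' @param mode `"simple"` (default) or `"boltzmann"`.
#' @param temperature K, used in boltzmann mode (default 300).
#' @param proton_labels protons to average; default all labels present.
#' @param solvent solvent string recorded in the output (default the
#'   ensemble's solvent name).
#' @return [shift_table()] with one row per proton, compound id taken
#'   from the ensemble.
#' @export
ensemble_average_shifts <- function(shifts, ens, window = 10,
                                    mode = c("simple", "boltzmann"),
                                    temperature = 300,
                                    proton_labels = NULL, solvent = NULL) {
  mode <- match.arg(mode)
  kept <- energy_window_filter(ens, window)
  ids <- conformer_ids(kept)
  if (is.null(proton_labels))
    proton_labels <- unique(shifts$atom_label[shifts$conformer_id %in% ids])
  if (is.null(solvent)) solvent <- ens$solvent$name
  w <- if (mode == "boltzmann")
    boltzmann_weights(ensemble_energies(kept, require = TRUE), temperature)
  else rep(1 / length(ids), length(ids))
  delta <- vapply(proton_labels, function(p) {
    d <- numeric(length(ids))
    for (k in seq_along(ids)) {
      hit <- shifts$conformer_id == ids[k] & shifts$atom_label == p
      if (sum(hit) != 1L)
        stop("missing shift for (", ids[k], ", ", p, ")")
      d[k] <- shifts$delta[hit]
    }
    sum(w * d)
  }, numeric(1))
  shift_table(data.frame(compound_id = ens$compound_id,
                         proton_label = proton_labels,
                         solvent = solvent, delta = as.numeric(delta),
                         stringsAsFactors = FALSE))
}

#' Karplus coefficient set
#'
#' Coefficients of the three-bond scalar-coupling relation
#' `J(theta) = A*cos^2(theta) + B*cos(theta) + C` (Hz). Coefficient sets
#' are configuration, not truth: a provenance string naming their
#' literature source is mandatory.
#'
#' @param A,B,C coefficients, Hz.
#' @param provenance literature source of the coefficients.
#' @return object of class `"karplus_coefficients"`.
#' @export
karplus_coefficients <- function(A, B, C, provenance) {
  if (missing(provenance) || !nzchar(provenance))
    stop("Karplus coefficients require a documented provenance string")
  if (!all(is.finite(c(A, B, C)))) stop("coefficients must be finite")
  structure(list(A = A, B = B, C = C, provenance = provenance),
            class = "karplus_coefficients")
}

#' Default HN-Halpha Karplus coefficients
#'
#' The package's one shipped default set, for backbone H-N-Calpha-H
#' couplings: A = 6.51, B = -1.76, C = 1.60 Hz (Vuister & Bax, J. Am.
#' Chem. Soc. 115:7772, 1993). Treat as configuration; substitute the
#' set appropriate to your fragment.
#'
#' @return [karplus_coefficients()].
#' @export
default_karplus_hn_ha <- function() {
  karplus_coefficients(6.51, -1.76, 1.60,
                       provenance = "Vuister & Bax 1993 JACS 115:7772 (3J HN-Halpha)")
}

#' Karplus three-bond coupling constant
#'
#' @param theta dihedral angle(s), degrees.
#' @param coeffs [karplus_coefficients()].
#' @return J, Hz.
#' @export
karplus_j <- function(theta, coeffs = default_karplus_hn_ha()) {
  ct <- cos(theta * pi / 180)
  coeffs$A * ct^2 + coeffs$B * ct + coeffs$C
}

#' NOE-effective interproton distance
#'
#' r^-6 ensemble averaging: `r_eff = mean(r^-6)^(-1/6)`. Short-distance
#' excursions dominate, so r_eff never exceeds the arithmetic mean; this
#' is the distance an initial-rate NOE senses for a fluctuating pair.
#'
#' @param distances per-frame interproton distances, Angstrom (> 0).
#' @param weights optional frame weights (normalized internally).
#' @return effective distance, Angstrom.
#' @export
effective_noe_distance <- function(distances, weights = NULL) {
  if (length(distances) == 0L) stop("no distances given")
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("distances must be positive and finite")
  if (is.null(weights)) weights <- rep(1 / length(distances), length(distances))
  weights <- weights / sum(weights)
  sum(weights * distances^-6)^(-1 / 6)
}
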