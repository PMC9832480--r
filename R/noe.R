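#' Normalize NOESY cross-peak intensities
#'
#' Initial-rate normalization per mixing time. Default (geminal-diagonal)
#' convention: `eta(i,j,tau) = I_cross(i,j,tau) /
#' sqrt(I_diag(i,tau) * I_diag(j,tau))`; the alternative single-diagonal
#' convention `I_cross / I_diag(i)` is selectable. Calibration against a
#' reference pair cancels convention-dependent constants, so the choice
#' does not propagate into distances.
#'
#' @param table [noesy_table()].
#' @param convention `"geminal"` (default) or `"single"`.
#' @return data.frame with columns `proton_i`, `proton_j`,
#'   `mixing_time_ms`, `eta`.
#' @export
normalize_intensities <- function(table, convention = c("geminal", "single")) {
  convention <- match.arg(convention)
  cr <- table$cross
  di <- table$diagonal
  dkey <- paste(di$proton, di$mixing_time_ms, sep = "\r")
  dval <- stats::setNames(di$integral, dkey)
  get_diag <- function(p, tau) {
    v <- dval[paste(p, tau, sep = "\r")]
    if (is.na(v))
      stop("missing diagonal integral for (", p, ", ", tau, " ms)")
    if (v <= 0)
      stop("nonpositive diagonal integral for (", p, ", ", tau,
           " ms): cannot normalize")
    unname(v)
  }
  eta <- numeric(nrow(cr))
  for (r in seq_len(nrow(cr))) {
    tau <- cr$mixing_time_ms[r]
    di_i <- get_diag(cr$proton_i[r], tau)
    eta[r] <- if (convention == "geminal")
      cr$integral[r] / sqrt(di_i * get_diag(cr$proton_j[r], tau))
    else cr$integral[r] / di_i
  }
  data.frame(proton_i = cr$proton_i, proton_j = cr$proton_j,
             mixing_time_ms = cr$mixing_time_ms, eta = eta,
             stringsAsFactors = FALSE)
}

#' Fit an initial-rate NOESY build-up
#'
#' Least-squares lines are fitted to consecutive windows of normalized
#' intensities in sorted mixing-time order, always starting at the
#' shortest mixing time (the initial build-up). Among windows of at
#' least `min_points` points, the longest with R^2 >= `r2_min` is
#' selected; its slope is the build-up rate sigma_ij (1/ms). When no
#' window qualifies the pair is flagged unquantifiable (`accepted =
#' FALSE`), not an error: weak or spin-diffused peaks are expected
#' casualties.
#'
#' @param mixing_times mixing times, ms (>= `min_points` values).
#' @param eta normalized intensities at those mixing times.
#' @param min_points minimum window length (default 4).
#' @param r2_min minimum R^2 of the linear fit (default 0.95).
#' @param zero_intercept force the line through the origin; by default an
#'   intercept absorbs experimental baseline offsets.
#' @return list of class `"buildup_fit"`: `sigma` (1/ms), `intercept`,
#'   `r2_fit`, `points_used` (indices into sorted mixing times),
#'   `accepted`.
#' @export
fit_buildup <- function(mixing_times, eta, min_points = 4, r2_min = 0.95,
                        zero_intercept = FALSE) {
  if (length(mixing_times) != length(eta))
    stop("mixing_times and eta differ in length")
  if (length(mixing_times) < min_points)
    stop("need >= ", min_points, " mixing times; got ", length(mixing_times))
  ord <- order(mixing_times)
  tau <- mixing_times[ord]
  y <- eta[ord]
  best <- NULL
  for (k in seq(min_points, length(tau))) {
    df <- data.frame(tau = tau[1:k], y = y[1:k])
    fit <- stats::lm(if (zero_intercept) y ~ tau + 0 else y ~ tau, data = df)
    ss_tot <- sum((df$y - mean(df$y))^2)
    if (ss_tot == 0) next  # flat window carries no rate information
    r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
    if (r2 >= r2_min)
      best <- list(sigma = unname(stats::coef(fit)[["tau"]]),
                   intercept = if (zero_intercept) 0
                               else unname(stats::coef(fit)[[1]]),
                   r2_fit = r2, points_used = 1:k, accepted = TRUE)
  }
  if (is.null(best))
    best <- list(sigma = NA_real_, intercept = NA_real_, r2_fit = NA_real_,
                 points_used = integer(0), accepted = FALSE)
  structure(best, class = "buildup_fit")
}

#' @export
print.buildup_fit <- function(x, ...) {
  if (x$accepted)
    cat(sprintf("<buildup_fit> sigma = %.4g /ms over %d points (R2 = %.4f)\n",
                x$sigma, length(x$points_used), x$r2_fit))
  else cat("<buildup_fit> rejected: no consecutive window reached R2 cutoff\n")
  invisible(x)
}

#' Calibrate an interproton distance from build-up rates
#'
#' `r_ij = r_ref * (sigma_ref / sigma_ij)^(1/6)` against a
#' locked-in-distance reference pair (default geminal protons,
#' r_ref = 1.78 Angstrom). Scale-invariant in the rates: only the ratio
#' sigma_ref/sigma_ij enters.
#'
#' @param sigma_ij build-up rate of the pair of interest (> 0).
#' @param sigma_ref build-up rate of the reference pair (> 0).
#' @param r_ref fixed reference distance, Angstrom (default 1.78).
#' @return distance, Angstrom.
#' @export
calibrate_distance <- function(sigma_ij, sigma_ref, r_ref = 1.78) {
  if (any(!is.finite(c(sigma_ij, sigma_ref))) ||
      any(c(sigma_ij, sigma_ref) <= 0))
    stop("build-up rates must be positive for distance calibration")
  r_ref * (sigma_ref / sigma_ij)^(1 / 6)
}

#' Full NOESY build-up analysis of an integral table
#'
#' Normalizes (see [normalize_intensities()]), fits every proton pair's
#' build-up (see [fit_buildup()]), and calibrates distances against a
#' declared reference pair (see [calibrate_distance()]).
#'
#' @param table [noesy_table()].
#' @param reference_pair character length-2: the locked-in-distance
#'   reference protons (e.g. a geminal pair).
#' @param r_ref reference distance, Angstrom (default 1.78).
#' @param convention normalization convention, see
#'   [normalize_intensities()].
#' @param min_points,r2_min,zero_intercept passed to [fit_buildup()].
#' @return data.frame with one row per pair: `proton_i`, `proton_j`,
#'   `sigma_per_ms`, `sigma_per_s`, `r2_fit`, `n_points`, `accepted`,
#'   `distance` (Angstrom; `NA` for rejected pairs).
#' @export
noesy_distances <- function(table, reference_pair, r_ref = 1.78,
                            convention = "geminal", min_points = 4,
                            r2_min = 0.95, zero_intercept = FALSE) {
  eta <- normalize_intensities(table, convention = convention)
  pair_key <- paste(eta$proton_i, eta$proton_j, sep = "\r")
  pairs <- unique(pair_key)
  fits <- lapply(pairs, function(k) {
    sub <- eta[pair_key == k, ]
    fit_buildup(sub$mixing_time_ms, sub$eta, min_points = min_points,
                r2_min = r2_min, zero_intercept = zero_intercept)
  })
  names(fits) <- pairs
  rkey <- paste(reference_pair[1], reference_pair[2], sep = "\r")
  if (!rkey %in% pairs)
    rkey <- paste(reference_pair[2], reference_pair[1], sep = "\r")
  if (!rkey %in% pairs)
    stop("reference pair (", paste(reference_pair, collapse = ", "),
         ") not present in the cross-peak table")
  ref_fit <- fits[[rkey]]
  if (!ref_fit$accepted)
    stop("reference pair build-up rejected (no linear initial window); ",
         "cannot calibrate distances")
  out <- do.call(rbind, lapply(pairs, function(k) {
    f <- fits[[k]]
    ij <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(proton_i = ij[1], proton_j = ij[2],
               sigma_per_ms = f$sigma, sigma_per_s = f$sigma * 1000,
               r2_fit = f$r2_fit, n_points = length(f$points_used),
               accepted = f$accepted,
               distance = if (f$accepted && f$sigma > 0)
                 calibrate_distance(f$sigma, ref_fit$sigma, r_ref)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
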