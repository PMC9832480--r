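#' Coefficient of determination about the identity line
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`: the fraction of
#' observed variance explained by taking the predictions at face value
#' (no refitting). Unlike a squared correlation this is negative whenever
#' the predictions do worse than the observed mean, which is exactly the
#' regime a failed conformational-sampling protocol lands in; it is
#' therefore the headline accuracy column, reported alongside
#' [pearson_r2()].
#'
#' @param pred predicted values.
#' @param obs observed values (not all equal).
#' @return dimensionless, <= 1; 1 iff `pred == obs` elementwise.
#' @export
r2_identity <- function(pred, obs) {
  check_paired(pred, obs, min_n = 2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    stop("observed values are constant: identity-line R2 undefined")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Squared Pearson correlation
#'
#' In [0, 1]; invariant under affine rescaling of either vector, so it
#' measures linear association only, not accuracy.
#'
#' @param pred predicted values.
#' @param obs observed values.
#' @return squared sample Pearson correlation coefficient.
#' @export
pearson_r2 <- function(pred, obs) {
  check_paired(pred, obs, min_n = 2)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("zero variance: Pearson correlation undefined")
  stats::cor(pred, obs)^2
}

#' Root-mean-square error
#'
#' @param pred predicted values (ppm for shifts).
#' @param obs observed values.
#' @return `sqrt(mean((pred - obs)^2))`, same units as the inputs.
#' @export
rmse <- function(pred, obs) {
  check_paired(pred, obs, min_n = 1)
  sqrt(mean((pred - obs)^2))
}

check_paired <- function(pred, obs, min_n) {
  if (length(pred) != length(obs))
    stop("pred and obs differ in length")
  if (length(obs) < min_n)
    stop("need at least ", min_n, " paired values")
  invisible(TRUE)
}

#' Score predicted against experimental chemical shifts
#'
#' Joins each protocol's predicted [shift_table()] with the experimental
#' one on (compound, proton, solvent) and reports, per (protocol,
#' solvent), both R^2 conventions, the RMSE (ppm) and the pair count,
#' pooling all compounds and protons within a solvent. Experimental keys
#' with no matching prediction are listed, not silently dropped.
#'
#' @param predictions named list of shift_tables, one per protocol.
#' @param experimental experimental shift_table.
#' @return list of class `"evaluation_report"`: `metrics` (data.frame
#'   with columns `protocol`, `solvent`, `r2_identity`, `pearson_r2`,
#'   `rmse`, `n`), `residuals` (per-point data.frame with column
#'   `residual = pred - obs`), `missing` (unmatched experimental keys
#'   per protocol).
#' @export
protocol_report <- function(predictions, experimental) {
  if (is.null(names(predictions)) || any(!nzchar(names(predictions))))
    stop("`predictions` must be a named list (one shift_table per protocol)")
  exp_df <- experimental$entries
  metrics <- list(); resids <- list(); missing <- list()
  for (prot in names(predictions)) {
    pred_df <- predictions[[prot]]$entries
    m <- merge(exp_df, pred_df,
               by = c("compound_id", "proton_label", "solvent"),
               suffixes = c("_obs", "_pred"))
    if (nrow(m) == 0L)
      stop("protocol '", prot, "' shares no (compound, proton, solvent) ",
           "keys with the experimental table")
    ek <- paste(exp_df$compound_id, exp_df$proton_label, exp_df$solvent)
    mk <- paste(m$compound_id, m$proton_label, m$solvent)
    missing[[prot]] <- exp_df[!(ek %in% mk),
                              c("compound_id", "proton_label", "solvent"),
                              drop = FALSE]
    for (sv in unique(m$solvent)) {
      ms <- m[m$solvent == sv, ]
      metrics[[length(metrics) + 1L]] <- data.frame(
        protocol = prot, solvent = sv,
        r2_identity = if (nrow(ms) >= 2 && stats::sd(ms$delta_obs) > 0)
          r2_identity(ms$delta_pred, ms$delta_obs) else NA_real_,
        pearson_r2 = if (nrow(ms) >= 2 && stats::sd(ms$delta_obs) > 0 &&
                         stats::sd(ms$delta_pred) > 0)
          pearson_r2(ms$delta_pred, ms$delta_obs) else NA_real_,
        rmse = rmse(ms$delta_pred, ms$delta_obs),
        n = nrow(ms), stringsAsFactors = FALSE)
      resids[[length(resids) + 1L]] <- data.frame(
        protocol = prot, compound_id = ms$compound_id,
        proton_label = ms$proton_label, solvent = sv,
        delta_obs = ms$delta_obs, delta_pred = ms$delta_pred,
        residual = ms$delta_pred - ms$delta_obs, stringsAsFactors = FALSE)
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 residuals = do.call(rbind, resids),
                 missing = missing),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$metrics, row.names = FALSE)
  nmiss <- sum(vapply(x$missing, nrow, integer(1)))
  if (nmiss > 0) cat(nmiss, "experimental point(s) had no prediction\n")
  invisible(x)
}
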