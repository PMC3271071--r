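## Prediction quality metrics: Pearson correlation, mean absolute error
## and root-mean-square error on the raw (degrees) and normalized
## scales, at residue and chain level, stratified by amino acid,
## secondary structure, solvent accessibility and observed-angle bin.

#' Pearson correlation between observed and predicted angles
#'
#' Computed on the raw angle values (no wrap correction), i.e. the
#' ordinary product-moment correlation.  A circular alternative is
#' available via `circular = TRUE` (correlation of sines/cosines is
#' deliberately *not* used; the circular variant ranks by the
#' Fisher-Lee circular correlation) and is labelled as such in reports.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2
#'   after pairwise NA removal).
#' @param circular use the Fisher-Lee circular correlation instead of
#'   the product-moment correlation.
#' @return correlation in `[-1, 1]`, or `NaN` (with a warning) when a
#'   vector has zero variance.
#' @export
pearson_cc <- function(observed, predicted, circular = FALSE) {
  ok <- !is.na(observed) & !is.na(predicted)
  x <- observed[ok]
  y <- predicted[ok]
  if (length(x) < 2) {
    warn("fewer than two paired values; correlation undefined")
    return(NaN)
  }
  if (circular) {
    xr <- x * pi / 180
    yr <- y * pi / 180
    num <- sum(sin(outer(xr, xr, "-")) * sin(outer(yr, yr, "-"))) / 2
    den <- sqrt(sum(sin(outer(xr, xr, "-"))^2) / 2 *
                sum(sin(outer(yr, yr, "-"))^2) / 2)
    if (den == 0) {
      warn("zero circular variance; correlation undefined")
      return(NaN)
    }
    return(num / den)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance; correlation undefined")
    return(NaN)
  }
  cor(x, y)
}

#' Mean absolute error between angle vectors
#'
#' @param observed,predicted angle vectors in degrees.
#' @param mode `"circular"` (wrap-aware, default) or `"linear"`.
#' @return MAE in degrees.
#' @export
angle_mae <- function(observed, predicted, mode = c("circular", "linear")) {
  mode <- match.arg(mode)
  ok <- !is.na(observed) & !is.na(predicted)
  if (!any(ok)) {
    abort("no defined observation/prediction pairs",
          class = "phipsi_config_error")
  }
  mean(angular_difference(observed[ok], predicted[ok], mode))
}

#' Root-mean-square error between angle vectors
#'
#' `scale = "raw"` works in degrees on the stated difference mode;
#' `scale = "norm"` first maps both vectors through the normalizer.
#'
#' @inheritParams angle_mae
#' @param scale `"raw"` (degrees) or `"norm"` (unitless).
#' @param norm an [fit_angle_normalizer()] (required for
#'   `scale = "norm"`).
#' @param which angle type, required for `scale = "norm"`.
#' @return RMSE in degrees (`raw`) or unitless (`norm`).
#' @export
angle_rmse <- function(observed, predicted, scale = c("raw", "norm"),
                       mode = c("circular", "linear"), norm = NULL,
                       which = NULL) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  ok <- !is.na(observed) & !is.na(predicted)
  if (!any(ok)) {
    abort("no defined observation/prediction pairs",
          class = "phipsi_config_error")
  }
  if (scale == "norm") {
    if (is.null(norm) || is.null(which)) {
      abort("normalized-scale RMSE needs `norm` and `which`",
            class = "phipsi_config_error")
    }
    d <- normalize_angle(observed[ok], which, norm) -
      normalize_angle(predicted[ok], which, norm)
    return(sqrt(mean(d^2)))
  }
  sqrt(mean(angular_difference(observed[ok], predicted[ok], mode)^2))
}

metric_row <- function(observed, predicted, mode, norm = NULL, which = NULL) {
  ok <- !is.na(observed) & !is.na(predicted)
  n <- sum(ok)
  if (n == 0) {
    return(tibble(n = 0L, cc = NA_real_, mae = NA_real_,
                  rmse_raw = NA_real_, rmse_norm = NA_real_))
  }
  cc <- if (n >= 2) suppressWarnings(pearson_cc(observed[ok], predicted[ok]))
        else NA_real_
  tibble(
    n = as.integer(n),
    cc = cc,
    mae = angle_mae(observed[ok], predicted[ok], mode),
    rmse_raw = angle_rmse(observed[ok], predicted[ok], "raw", mode),
    rmse_norm = if (is.null(norm)) NA_real_ else
      angle_rmse(observed[ok], predicted[ok], "norm", norm = norm,
                 which = which))
}

#' Evaluate predictions with stratified metrics
#'
#' Residue-level evaluation pools all residues; metrics are additionally
#' stratified by amino acid, secondary structure (H/E/C), two-state
#' solvent accessibility (E/B), 20-degree observed-angle bin and chain.
#' The chain-level summary reports the distribution of per-chain metrics
#' including the fractions of chains with CC of at least 0.5 and 0.6.
#'
#' @param data per-residue tibble with columns `observed` and
#'   `predicted` (degrees) and optionally `chain`, `aa`, `ss`, `sa`.
#' @param mode angle-difference mode for MAE/RMSE.
#' @param norm optional [fit_angle_normalizer()] for normalized-scale
#'   RMSE.
#' @param which angle type (`"phi"`/`"psi"`), needed with `norm` and
#'   used to label the report.
#' @return a `torsion_report` object; `tidy()` gives the per-stratum
#'   table, `glance()` the overall row.
#' @export
evaluate_predictions <- function(data, mode = c("circular", "linear"),
                                 norm = NULL, which = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("observed", "predicted") %in% names(data)))
  data <- filter(data, !is.na(.data$observed), !is.na(.data$predicted))
  if (nrow(data) == 0) {
    abort("no defined observation/prediction pairs",
          class = "phipsi_config_error")
  }
  strat <- function(df, var, label) {
    df |>
      group_by(stratum = as.character(.data[[var]])) |>
      summarise(metric_row(.data$observed, .data$predicted, mode, norm,
                           which),
                .groups = "drop") |>
      mutate(stratification = label, .before = 1)
  }
  out <- bind_rows(
    bind_cols(tibble(stratification = "overall", stratum = "all"),
              metric_row(data$observed, data$predicted, mode, norm, which)),
    if ("aa" %in% names(data)) strat(data, "aa", "amino_acid"),
    if ("ss" %in% names(data)) strat(data, "ss", "secondary_structure"),
    if ("sa" %in% names(data)) strat(data, "sa", "solvent_accessibility"),
    strat(mutate(data, bin = angle_bin(.data$observed)), "bin", "angle_bin"),
    if ("chain" %in% names(data)) strat(data, "chain", "chain"))

  chain_summary <- NULL
  if ("chain" %in% names(data)) {
    per_chain <- filter(out, .data$stratification == "chain")
    few <- per_chain$n < 2
    if (any(few)) {
      warn(sprintf("%d chain(s) with fewer than 2 pairs skipped from %s",
                   sum(few), "chain-level CC summaries"))
    }
    cc <- per_chain$cc[!few & !is.na(per_chain$cc)]
    chain_summary <- tibble(
      n_chains = nrow(per_chain),
      mean_mae = mean(per_chain$mae),
      median_mae = median(per_chain$mae),
      mean_cc = if (length(cc)) mean(cc) else NA_real_,
      median_cc = if (length(cc)) median(cc) else NA_real_,
      frac_cc_ge_0.5 = if (length(cc)) mean(cc >= 0.5) else NA_real_,
      frac_cc_ge_0.6 = if (length(cc)) mean(cc >= 0.6) else NA_real_,
      # pooled-vs-averaged chain RMSE, both reported
      mean_chain_rmse_raw = mean(per_chain$rmse_raw),
      pooled_rmse_raw = out$rmse_raw[out$stratification == "overall"])
  }
  structure(list(strata = out, chain_summary = chain_summary,
                 mode = mode, angle = which %||% NA_character_),
            class = "torsion_report")
}

# 18 bins of 20 degrees covering [-180, 180); labels are bin midpoints.
angle_bin <- function(theta) {
  theta <- wrap_angle(theta)
  theta[theta == 180] <- -180      # fold the closed endpoint into [-180,180)
  lo <- 20 * floor(theta / 20)
  sprintf("%g", lo + 10)
}

#' @export
print.torsion_report <- function(x, ...) {
  overall <- filter(x$strata, .data$stratification == "overall")
  cat(sprintf("<torsion_report> angle: %s, mode: %s\n", x$angle, x$mode))
  cat(sprintf("  overall: n = %d, CC = %.3f, MAE = %.2f, RMSE = %.2f\n",
              overall$n, overall$cc, overall$mae, overall$rmse_raw))
  if (!is.null(x$chain_summary)) {
    cat(sprintf("  chains: %d, median CC = %.3f, CC >= 0.5: %.0f%%\n",
                x$chain_summary$n_chains, x$chain_summary$median_cc,
                100 * x$chain_summary$frac_cc_ge_0.5))
  }
  invisible(x)
}

#' @method tidy torsion_report
#' @export
tidy.torsion_report <- function(x, ...) x$strata

#' @method glance torsion_report
#' @export
glance.torsion_report <- function(x, ...) {
  overall <- filter(x$strata, .data$stratification == "overall")
  out <- select(overall, -"stratification", -"stratum")
  if (!is.null(x$chain_summary)) {
    out <- bind_cols(out, select(x$chain_summary, "n_chains",
                                 "frac_cc_ge_0.5", "frac_cc_ge_0.6"))
  }
  mutate(out, angle = x$angle, mode = x$mode)
}

#' Paired Wilcoxon signed-rank test between per-chain MAEs
#'
#' Two-sided comparison of two methods evaluated on the same chains;
#' the exact null distribution is used for n <= 25 chains and the normal
#' approximation beyond that.
#'
#' @param mae_a,mae_b per-chain MAE vectors, same chain order.
#' @return one-row tibble with the statistic, p-value, n and method.
#' @export
compare_paired_mae <- function(mae_a, mae_b) {
  stopifnot(length(mae_a) == length(mae_b))
  ok <- !is.na(mae_a) & !is.na(mae_b)
  n <- sum(ok)
  ht <- suppressWarnings(
    wilcox.test(mae_a[ok], mae_b[ok], paired = TRUE,
                alternative = "two.sided", exact = n <= 25))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n = as.integer(n),
         method = if (n <= 25) "exact" else "normal approximation")
}
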