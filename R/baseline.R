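## Amino-acid-specific random-angle null model: each test residue is
## assigned a training-set angle drawn uniformly from the pool of its
## own amino-acid type (or from the global pool), and the MAE of this
## assignment is averaged over many repeats.  An exact-expectation
## oracle is provided for verification.

#' Random-angle baseline MAE
#'
#' For each of `repeats` rounds, every test residue receives an angle
#' drawn uniformly (with replacement) from the training pool of its
#' amino-acid type (`granularity = "amino_acid"`) or from all training
#' angles (`"global"`); the MAE of each round is computed and the mean
#' over rounds returned, overall and per stratum.  Test amino acids
#' absent from the pool fall back to the global pool with a warning.
#'
#' @param pool tibble of training angles with columns `aa` and `angle`
#'   (degrees).
#' @param test tibble of test residues with columns `aa` and `observed`
#'   (degrees), optionally `ss` and `sa` for stratified output.
#' @param repeats number of randomization rounds (default 10000).
#' @param granularity `"amino_acid"` or `"global"`.
#' @param mode angle-difference mode.
#' @param seed integer seed.
#' @return a tibble of per-stratum mean MAEs: columns `stratification`,
#'   `stratum`, `n`, `mae`; the first row is the overall value.
#' @export
random_baseline_mae <- function(pool, test, repeats = 10000,
                                granularity = c("amino_acid", "global"),
                                mode = c("circular", "linear"),
                                seed = 1) {
  granularity <- match.arg(granularity)
  mode <- match.arg(mode)
  stopifnot(all(c("aa", "angle") %in% names(pool)),
            all(c("aa", "observed") %in% names(test)))
  pool <- filter(pool, !is.na(.data$angle))
  test <- filter(test, !is.na(.data$observed))
  if (nrow(pool) == 0) {
    abort("empty training angle pool", class = "phipsi_config_error")
  }
  if (nrow(test) == 0) {
    abort("no defined test residues", class = "phipsi_config_error")
  }
  missing_aa <- setdiff(unique(test$aa), unique(pool$aa))
  if (granularity == "amino_acid" && length(missing_aa) > 0) {
    warn(sprintf("amino acid(s) %s absent from the pool; using global pool",
                 paste(missing_aa, collapse = ",")))
  }
  set.seed(seed)
  n <- nrow(test)
  # diff_sums[i] accumulates, per repeat, the summed differences of the
  # residues handled so far; per-stratum sums are kept alongside.
  overall <- numeric(repeats)
  strata_vars <- intersect(c("aa", "ss", "sa"), names(test))
  strata_sums <- list()
  strata_n <- list()
  groups <- if (granularity == "global") list(all = seq_len(n))
            else split(seq_len(n), test$aa)
  for (g in names(groups)) {
    idx <- groups[[g]]
    pg <- if (granularity == "global" || g %in% missing_aa) pool$angle
          else pool$angle[pool$aa == g]
    draws <- matrix(pg[sample.int(length(pg), length(idx) * repeats,
                                  replace = TRUE)],
                    nrow = length(idx))
    d <- angular_difference(test$observed[idx], draws, mode)
    d <- matrix(d, nrow = length(idx))
    overall <- overall + .colSums(d, length(idx), repeats)
    for (v in strata_vars) {
      for (s in unique(test[[v]][idx])) {
        key <- paste(v, s, sep = "\r")
        rows <- which(test[[v]][idx] == s)
        add <- if (length(rows) == 1) d[rows, ]
               else .colSums(d[rows, , drop = FALSE], length(rows), repeats)
        strata_sums[[key]] <- (strata_sums[[key]] %||% numeric(repeats)) + add
        strata_n[[key]] <- (strata_n[[key]] %||% 0L) + length(rows)
      }
    }
  }
  labels <- c(overall = "overall", aa = "amino_acid",
              ss = "secondary_structure", sa = "solvent_accessibility")
  out <- tibble(stratification = "overall", stratum = "all",
                n = as.integer(n), mae = mean(overall / n))
  if (length(strata_sums) > 0) {
    keys <- do.call(rbind, strsplit(names(strata_sums), "\r", fixed = TRUE))
    out <- bind_rows(out, tibble(
      stratification = unname(labels[keys[, 1]]),
      stratum = keys[, 2],
      n = unlist(strata_n, use.names = FALSE),
      mae = vapply(names(strata_sums), function(k) {
        mean(strata_sums[[k]] / strata_n[[k]])
      }, numeric(1), USE.NAMES = FALSE)))
  }
  arrange(out, .data$stratification != "overall", .data$stratification,
          .data$stratum)
}

#' Exact expectation of the random-angle baseline MAE
#'
#' The expectation of [random_baseline_mae()] in the limit of infinitely
#' many repeats: the average, over test residues, of the mean absolute
#' angular difference between the observation and every pool angle.
#'
#' @param pool numeric vector of pool angles (degrees).
#' @param observed numeric vector of observed test angles (degrees).
#' @param mode angle-difference mode.
#' @return expected MAE in degrees.
#' @export
expected_random_mae <- function(pool, observed,
                                mode = c("circular", "linear")) {
  mode <- match.arg(mode)
  pool <- pool[!is.na(pool)]
  observed <- observed[!is.na(observed)]
  stopifnot(length(pool) >= 1, length(observed) >= 1)
  per_obs <- vapply(observed, function(o) {
    mean(angular_difference(o, pool, mode))
  }, numeric(1))
  mean(per_obs)
}

#' Exact amino-acid-specific baseline expectation
#'
#' Convenience wrapper applying [expected_random_mae()] with the
#' per-amino-acid (or global) pools of [random_baseline_mae()].
#'
#' @inheritParams random_baseline_mae
#' @return expected overall MAE in degrees.
#' @export
expected_random_baseline <- function(pool, test,
                                     granularity = c("amino_acid", "global"),
                                     mode = c("circular", "linear")) {
  granularity <- match.arg(granularity)
  mode <- match.arg(mode)
  pool <- filter(pool, !is.na(.data$angle))
  test <- filter(test, !is.na(.data$observed))
  if (granularity == "global") {
    return(expected_random_mae(pool$angle, test$observed, mode))
  }
  groups <- split(test$observed, test$aa)
  total <- 0
  for (g in names(groups)) {
    pg <- pool$angle[pool$aa == g]
    if (length(pg) == 0) pg <- pool$angle
    total <- total + length(groups[[g]]) *
      expected_random_mae(pg, groups[[g]], mode)
  }
  total / nrow(test)
}
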