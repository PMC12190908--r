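#' Normalize raw viability readings to the DMSO control
#'
#' Divides every raw measurement by the mean of the DMSO control readings.
#' Values above 1 (super-viability) are retained.
#'
#' @param raw numeric vector of raw viability readings.
#' @param dmso numeric vector of DMSO control readings; mean must be > 0.
#' @return numeric vector of viability fractions.
#' @export
normalize_viability <- function(raw, dmso) {
  m <- mean(dmso, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) .stopf("DMSO control mean must be positive")
  raw / m
}

#' @noRd
.check_curve <- function(curve) {
  .require_columns(curve, c("dose", "viability"), "dose-response curve")
  if (any(curve$dose <= 0)) .stopf("doses must be strictly positive")
  if (any(curve$viability < 0)) .stopf("viability must be >= 0")
  curve
}

#' Fit a variable-slope logistic dose-response model
#'
#' Least-squares fit of `v(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)`
#' to DMSO-normalized viability on log dose, matching the usual
#' "log(inhibitor) vs normalized response, variable slope" model. A
#' deterministic multi-start grid (hill in \{0.5, 1, 2\}, ic50 at the dose
#' quartiles) guards against local minima; the reported `ic50` is the
#' relative IC50, the dose halfway between the fitted asymptotes (50% of the
#' maximal inhibitory response).
#'
#' @param curve data.frame with columns `dose` (> 0) and `viability`
#'   (fraction of control; replicate rows allowed).
#' @return list of class `logistic_fit`: `top`, `bottom`, `hill`, `ic50`,
#'   `rss`, `n_points`.
#' @export
fit_logistic <- function(curve) {
  curve <- .check_curve(curve)
  d <- curve$dose
  v <- curve$viability
  if (length(unique(d)) < 4) .stopf("need >= 4 distinct doses")
  if (diff(range(v)) < 1e-4) {
    .stopf("no inhibition observed: viability is flat")
  }
  starts <- expand.grid(hill = c(0.5, 1, 2),
                        ic50 = unname(quantile(unique(d), c(0.25, 0.5, 0.75))))
  lower <- c(top = 0, bottom = -0.5, hill = 0.05, ic50 = min(d) / 1e3)
  upper <- c(top = 3, bottom = 1.5, hill = 20, ic50 = max(d) * 1e3)
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + (d / ic50)^hill),
        start = list(top = max(v), bottom = min(v),
                     hill = starts$hill[i], ic50 = starts$ic50[i]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (rss < best_rss) {
      best <- coef(fit)
      best_rss <- rss
    }
  }
  if (is.null(best)) .stopf("logistic fit did not converge")
  if (best[["top"]] - best[["bottom"]] < 0.05) {
    .stopf("logistic fit did not converge to an inhibitory response (best rss %.4g)",
           best_rss)
  }
  structure(list(top = unname(best[["top"]]), bottom = unname(best[["bottom"]]),
                 hill = unname(best[["hill"]]), ic50 = unname(best[["ic50"]]),
                 rss = best_rss, n_points = length(v)),
            class = "logistic_fit")
}

#' Fit the median-effect (Chou) model to a dose-response curve
#'
#' The median-effect equation `fa/fu = (D/Dm)^m` linearizes to
#' `log10(fa/(1-fa)) = m log10(D) - m log10(Dm)` with `fa = 1 - viability`.
#' Replicates are averaged per dose before fitting; wells with fa outside
#' (`fa_min`, `fa_max`) are excluded (log-odds blow-up), and viability above
#' 1 maps to fa <= 0 and is likewise excluded.
#'
#' @param curve data.frame with columns `dose` (> 0) and `viability`.
#' @param fa_min,fa_max usable fraction-affected window (default 0.01/0.99).
#' @return list of class `median_effect_fit`: `m` (slope), `dm`
#'   (median-effect dose), `r2`, `n_points`.
#' @export
fit_median_effect <- function(curve, fa_min = 0.01, fa_max = 0.99) {
  curve <- .check_curve(curve)
  v <- tapply(curve$viability, curve$dose, mean)
  d <- as.numeric(names(v))
  fa <- 1 - as.numeric(v)
  usable <- fa > fa_min & fa < fa_max
  if (sum(usable) < 2 || length(unique(d[usable])) < 2) {
    .stopf("fewer than 2 usable dose points in the fa window (%g, %g)",
           fa_min, fa_max)
  }
  x <- log10(d[usable])
  y <- log10(fa[usable] / (1 - fa[usable]))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  b0 <- unname(coef(fit)[1])
  if (!is.finite(m) || m <= 0) {
    .stopf("median-effect slope is not positive; dose-response is not inhibitory")
  }
  dm <- 10^(-b0 / m)
  ssr <- sum(resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(list(m = m, dm = dm, r2 = r2, n_points = sum(usable)),
            class = "median_effect_fit")
}

#' Construct a median-effect fit from known parameters
#'
#' Convenience constructor (used by the simulators and for sham tests).
#'
#' @param m median-effect slope (> 0).
#' @param dm median-effect dose (> 0).
#' @return a `median_effect_fit`.
#' @export
median_effect_fit <- function(m, dm) {
  stopifnot(m > 0, dm > 0)
  structure(list(m = m, dm = dm, r2 = NA_real_, n_points = NA_integer_),
            class = "median_effect_fit")
}

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param fit a `median_effect_fit`.
#' @param fa fraction affected, strictly in (0, 1); vectorized.
#' @return numeric vector of doses.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) .stopf("fa must be strictly in (0, 1)")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' The mutually exclusive (Loewe) form: `CI = d1/DxA(fa) + d2/DxB(fa)`,
#' where DxA and DxB are the single-agent doses producing the observed
#' fraction affected `fa`. CI < 1 indicates synergy, 1 additivity, > 1
#' antagonism.
#'
#' @param d1,d2 doses of drugs A and B in the combination (>= 0, not both 0);
#'   vectorized.
#' @param fa observed fraction affected, strictly in (0, 1).
#' @param fit_a,fit_b `median_effect_fit` objects for the single agents.
#' @return numeric vector of combination indices.
#' @export
combination_index <- function(d1, d2, fa, fit_a, fit_b) {
  if (any(d1 < 0 | d2 < 0)) .stopf("doses must be >= 0")
  if (any(d1 + d2 <= 0)) .stopf("at least one dose must be positive")
  if (any(fa <= 0 | fa >= 1)) .stopf("fa must be strictly in (0, 1)")
  d1 / dose_for_effect(fit_a, fa) + d2 / dose_for_effect(fit_b, fa)
}

#' Construct a checkerboard viability object
#'
#' @param doses_a numeric vector of descending doses of drug A (grid rows).
#' @param doses_b numeric vector of descending doses of drug B (grid
#'   columns).
#' @param viability matrix of DMSO-normalized viability fractions,
#'   `length(doses_a)` x `length(doses_b)`.
#' @param drug_a,drug_b drug names.
#' @param dilution_factor declared serial-dilution factor; consecutive dose
#'   ratios are checked against it (warning on mismatch).
#' @return list of class `checkerboard`.
#' @export
checkerboard <- function(doses_a, doses_b, viability, drug_a = "drugA",
                         drug_b = "drugB", dilution_factor = 3) {
  viability <- as.matrix(viability)
  stopifnot(nrow(viability) == length(doses_a),
            ncol(viability) == length(doses_b))
  if (any(doses_a <= 0) || any(doses_b <= 0)) .stopf("doses must be positive")
  if (any(viability < 0)) .stopf("viability must be >= 0")
  for (dd in list(doses_a, doses_b)) {
    if (length(dd) > 1) {
      ratio <- dd[-length(dd)] / dd[-1]
      if (any(abs(ratio - dilution_factor) > 1e-6 * dilution_factor)) {
        .warnf("dose grid is not a %g-fold serial dilution", dilution_factor)
      }
    }
  }
  structure(list(doses_a = doses_a, doses_b = doses_b, viability = viability,
                 drug_a = drug_a, drug_b = drug_b,
                 dilution_factor = dilution_factor),
            class = "checkerboard")
}

#' Summarize a checkerboard by per-well combination indices
#'
#' Computes the CI for every well whose observed fraction affected lies in
#' `fa_window` (the stable mid-effect range) and reports their arithmetic
#' mean as the summary CI. `synergy_call` is `synergistic` when the summary
#' CI < 1, `antagonistic` when > 1, `additive` when exactly 1.
#'
#' @param board a [checkerboard()].
#' @param fit_a,fit_b single-agent `median_effect_fit` objects.
#' @param fa_window numeric length-2, inclusive fa window (default
#'   `c(0.2, 0.8)`).
#' @return list of class `ci_result`: `per_well` (data.frame `dose_a`,
#'   `dose_b`, `fa`, `ci`), `summary_ci`, `n_wells_used`, `n_excluded`,
#'   `synergy_call`.
#' @export
summarize_checkerboard <- function(board, fit_a, fit_b,
                                   fa_window = c(0.2, 0.8)) {
  stopifnot(inherits(board, "checkerboard"))
  grid <- expand.grid(i = seq_along(board$doses_a),
                      j = seq_along(board$doses_b))
  fa <- 1 - board$viability[cbind(grid$i, grid$j)]
  keep <- fa >= fa_window[1] & fa <= fa_window[2]
  if (!any(keep)) .stopf("no wells in effect window [%g, %g]",
                         fa_window[1], fa_window[2])
  d1 <- board$doses_a[grid$i[keep]]
  d2 <- board$doses_b[grid$j[keep]]
  ci <- combination_index(d1, d2, fa[keep], fit_a, fit_b)
  per_well <- data.frame(dose_a = d1, dose_b = d2, fa = fa[keep], ci = ci,
                         stringsAsFactors = FALSE, row.names = NULL)
  s <- mean(ci)
  call <- if (s < 1) "synergistic" else if (s > 1) "antagonistic" else "additive"
  structure(list(per_well = per_well, summary_ci = s,
                 n_wells_used = sum(keep), n_excluded = sum(!keep),
                 synergy_call = call),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("summary CI = %.3f over %d wells (%s)\n", x$summary_ci,
              x$n_wells_used, x$synergy_call))
  invisible(x)
}

#' Read single-drug dose-response tables
#'
#' Long TSV with columns `drug`, `dose_uM`, `replicate`, `viability_raw`;
#' rows with dose 0 are the DMSO controls used for normalization (shared
#' across drugs in the file).
#'
#' @param path path to the TSV.
#' @return named list of data.frames (`dose`, `viability`), one per drug,
#'   replicate rows preserved.
#' @export
read_dose_response <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("drug", "dose_uM", "replicate", "viability_raw"),
                   "dose-response table")
  dmso <- df$viability_raw[df$dose_uM == 0]
  if (length(dmso) == 0) .stopf("no DMSO (dose 0) rows in %s", path)
  df <- df[df$dose_uM > 0, , drop = FALSE]
  df$viability <- normalize_viability(df$viability_raw, dmso)
  drugs <- sort(unique(df$drug))
  setNames(lapply(drugs, function(dr) {
    sub <- df[df$drug == dr, , drop = FALSE]
    data.frame(dose = sub$dose_uM, viability = sub$viability,
               stringsAsFactors = FALSE, row.names = NULL)
  }), drugs)
}

#' Read a checkerboard viability grid
#'
#' Long TSV with columns `drug_A`, `dose_A_uM`, `drug_B`, `dose_B_uM`,
#' `replicate`, `viability_raw`. Rows with both doses 0 are the DMSO
#' controls; rows with exactly one zero dose are single-agent wells and are
#' returned as separate curves. Replicates are averaged after DMSO
#' normalization.
#'
#' @param path path to the TSV.
#' @return list: `board` (a [checkerboard()]), `single_a`, `single_b`
#'   (data.frames `dose`, `viability`, or `NULL` when absent).
#' @export
read_checkerboard <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("drug_A", "dose_A_uM", "drug_B", "dose_B_uM",
                         "replicate", "viability_raw"), "checkerboard table")
  dmso <- df$viability_raw[df$dose_A_uM == 0 & df$dose_B_uM == 0]
  if (length(dmso) == 0) .stopf("no DMSO (both doses 0) rows in %s", path)
  df$viability <- normalize_viability(df$viability_raw, dmso)
  single_curve <- function(sub, dose_col) {
    if (nrow(sub) == 0) return(NULL)
    data.frame(dose = sub[[dose_col]], viability = sub$viability,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  single_a <- single_curve(df[df$dose_A_uM > 0 & df$dose_B_uM == 0, ],
                           "dose_A_uM")
  single_b <- single_curve(df[df$dose_A_uM == 0 & df$dose_B_uM > 0, ],
                           "dose_B_uM")
  combo <- df[df$dose_A_uM > 0 & df$dose_B_uM > 0, , drop = FALSE]
  if (nrow(combo) == 0) .stopf("no combination wells in %s", path)
  v <- tapply(combo$viability, list(combo$dose_A_uM, combo$dose_B_uM), mean)
  ord_a <- order(as.numeric(rownames(v)), decreasing = TRUE)
  ord_b <- order(as.numeric(colnames(v)), decreasing = TRUE)
  v <- v[ord_a, ord_b, drop = FALSE]
  doses_a <- as.numeric(rownames(v))
  doses_b <- as.numeric(colnames(v))
  if (any(is.na(v))) .stopf("incomplete checkerboard grid in %s", path)
  board <- checkerboard(doses_a, doses_b, unname(v),
                        drug_a = combo$drug_A[1], drug_b = combo$drug_B[1])
  list(board = board, single_a = single_a, single_b = single_b)
}
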