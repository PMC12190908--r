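#' Thresholds for classifying differential protein responses
#'
#' Defaults follow the study design this package implements: a strong
#' response requires |log2ratio| >= 0.5 together with a nominal t-test
#' p < 0.05 and a Benjamini-Hochberg q < 0.2; network seed lists use the
#' stricter nominal p < 0.01; a protein is "frequently responsive" when it
#' responds strongly in at least 4 conditions.
#'
#' @param log2ratio_min minimum absolute log2 expression ratio.
#' @param p_max nominal two-sided p-value cutoff for a strong response.
#' @param fdr_max BH-adjusted q-value cutoff for a strong response.
#' @param seed_p_max nominal p-value cutoff used by [seed_list()].
#' @param frequent_min_conditions minimum number of conditions with a strong
#'   response for [frequently_responsive()].
#' @return list of class `response_thresholds`.
#' @export
response_thresholds <- function(log2ratio_min = 0.5, p_max = 0.05,
                                fdr_max = 0.2, seed_p_max = 0.01,
                                frequent_min_conditions = 4L) {
  stopifnot(log2ratio_min > 0, p_max > 0, p_max <= 1, fdr_max > 0,
            fdr_max <= 1, seed_p_max > 0, seed_p_max <= 1,
            frequent_min_conditions >= 1)
  structure(list(log2ratio_min = log2ratio_min, p_max = p_max,
                 fdr_max = fdr_max, seed_p_max = seed_p_max,
                 frequent_min_conditions = as.integer(frequent_min_conditions)),
            class = "response_thresholds")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (capped at 1, monotone), delegating to
#' [stats::p.adjust()] after input validation.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) .stopf("p-values must be numeric")
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) .stopf("p-values outside [0, 1]: %s",
                       paste(utils::head(p[!ok], 3), collapse = ", "))
  p.adjust(p, method = "BH")
}

#' @noRd
.row_group_stats <- function(values, cols) {
  m <- values[, cols, drop = FALSE]
  n <- rowSums(!is.na(m))
  mean <- rowMeans(m, na.rm = TRUE)
  mean[n == 0] <- NA_real_
  ss <- rowSums(m * m, na.rm = TRUE)
  v <- (ss - n * mean^2) / (n - 1)
  v[n < 2] <- NA_real_
  v[!is.na(v) & v < 0] <- 0  # numerical guard
  list(n = n, mean = mean, var = v)
}

#' Per-protein differential response versus batch-matched controls
#'
#' For every (protein, drug condition) pair, compares the drug-treated
#' replicates against the DMSO control replicates of the same batch with a
#' two-sided unpaired t-test on log2 intensities. The default is the pooled
#' (equal-variance, Student) test: with balanced triplicate groups measured
#' under one protocol, pooling is appropriate and retains markedly more
#' power at n = 3 than the Welch test (which is available via
#' `var_equal = FALSE`). The effect size is the log2 expression ratio
#' (difference of group means on the log2 scale). q-values are BH-adjusted
#' within each condition across all testable proteins. Proteins with fewer
#' than 2 present values in either group are `untestable`. When the pooled
#' variance is zero the test is degenerate: a nonzero mean difference is
#' treated as decisive (p set to the smallest positive double), an exactly
#' zero difference as constant (p = 1).
#'
#' @param x an [expression_matrix()].
#' @param design design data.frame (`sample_id`, `condition`, `batch`,
#'   `replicate`) covering all samples.
#' @param thresholds a [response_thresholds()] object.
#' @param control condition label of the vehicle control (default "DMSO").
#' @param var_equal logical; pooled-variance Student t-test (default) or
#'   Welch when `FALSE`.
#' @return data.frame of class `response_table` with columns `protein_id`,
#'   `gene_symbol`, `condition`, `log2ratio`, `p_value`, `q_value`,
#'   `n_perturbed`, `n_control`, `response_class` (one of `strong_up`,
#'   `strong_down`, `constant`, `untestable`).
#' @export
differential_response <- function(x, design, thresholds = response_thresholds(),
                                  control = "DMSO", var_equal = TRUE) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(thresholds, "response_thresholds"))
  design <- .check_design(x, design, control)
  conditions <- setdiff(unique(design$condition), control)
  if (length(conditions) == 0) .stopf("no non-control condition in design")
  res <- lapply(conditions, function(cc) {
    drug_rows <- design$condition == cc
    batches <- unique(design$batch[drug_rows])
    ctrl_rows <- design$condition == control & design$batch %in% batches
    if (!any(ctrl_rows)) {
      .stopf("condition '%s' has no %s control in batch '%s'",
             cc, control, paste(batches, collapse = "/"))
    }
    trt <- .row_group_stats(x$values, design$sample_id[drug_rows])
    ctl <- .row_group_stats(x$values, design$sample_id[ctrl_rows])
    lfc <- trt$mean - ctl$mean
    testable <- trt$n >= 2 & ctl$n >= 2
    # unpaired t-test, vectorized
    if (var_equal) {
      sp2 <- ((trt$n - 1) * trt$var + (ctl$n - 1) * ctl$var) /
        (trt$n + ctl$n - 2)
      se2 <- sp2 * (1 / trt$n + 1 / ctl$n)
    } else {
      se2 <- trt$var / trt$n + ctl$var / ctl$n
    }
    p <- rep(NA_real_, length(lfc))
    degen <- testable & se2 == 0
    p[degen & lfc != 0] <- .Machine$double.xmin
    p[degen & lfc == 0] <- 1
    reg <- testable & se2 > 0
    if (any(reg)) {
      tstat <- lfc[reg] / sqrt(se2[reg])
      df <- if (var_equal) {
        trt$n[reg] + ctl$n[reg] - 2
      } else {
        se2[reg]^2 / ((trt$var[reg] / trt$n[reg])^2 / (trt$n[reg] - 1) +
                      (ctl$var[reg] / ctl$n[reg])^2 / (ctl$n[reg] - 1))
      }
      p[reg] <- 2 * pt(-abs(tstat), df)
    }
    q <- rep(NA_real_, length(p))
    q[testable] <- adjust_bh(p[testable])
    cls <- rep("constant", length(p))
    cls[!testable] <- "untestable"
    strong <- testable & !is.na(p) &
      abs(lfc) >= thresholds$log2ratio_min &
      p < thresholds$p_max & q < thresholds$fdr_max
    cls[strong & lfc > 0] <- "strong_up"
    cls[strong & lfc < 0] <- "strong_down"
    data.frame(protein_id = x$protein_ids, gene_symbol = x$gene_symbols,
               condition = cc, log2ratio = lfc, p_value = p, q_value = q,
               n_perturbed = trt$n, n_control = ctl$n, response_class = cls,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("response_table", "data.frame")
  out
}

#' Proteins responding strongly in many conditions
#'
#' Returns the proteins classified `strong_up` or `strong_down` in at least
#' `thresholds$frequent_min_conditions` conditions, together with a signed
#' per-condition response matrix (+1 up, -1 down, 0 not strong).
#'
#' @param table a `response_table` from [differential_response()].
#' @param thresholds a [response_thresholds()] object.
#' @return data.frame with `protein_id`, `gene_symbol`, `n_strong`, and one
#'   signed column per condition; zero rows if no protein qualifies.
#' @export
frequently_responsive <- function(table, thresholds = response_thresholds()) {
  stopifnot(inherits(table, "response_table") || is.data.frame(table))
  conditions <- sort(unique(table$condition))
  sign_of <- ifelse(table$response_class == "strong_up", 1L,
                    ifelse(table$response_class == "strong_down", -1L, 0L))
  wide <- sapply(conditions, function(cc) {
    v <- integer(length(unique(table$protein_id)))
    idx <- table$condition == cc
    v[match(table$protein_id[idx], unique(table$protein_id))] <- sign_of[idx]
    v
  })
  proteins <- unique(table$protein_id)
  wide <- matrix(wide, nrow = length(proteins),
                 dimnames = list(proteins, conditions))
  n_strong <- rowSums(wide != 0)
  keep <- n_strong >= thresholds$frequent_min_conditions
  genes <- table$gene_symbol[match(proteins, table$protein_id)]
  out <- data.frame(protein_id = proteins[keep], gene_symbol = genes[keep],
                    n_strong = n_strong[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  cbind(out, as.data.frame(wide[keep, , drop = FALSE], row.names = FALSE))
}

#' Seed gene list for network module detection
#'
#' Genes whose protein response to one drug satisfies |log2ratio| > 0.5 and
#' nominal t-test p < 0.01 (deduplicated symbols), the input list for
#' NetBox-style module detection and for preranked GSEA.
#'
#' @param table a `response_table`.
#' @param condition condition label present in `table`.
#' @param thresholds a [response_thresholds()] object (`seed_p_max`,
#'   `log2ratio_min`).
#' @return character vector of gene symbols, sorted.
#' @export
seed_list <- function(table, condition, thresholds = response_thresholds()) {
  if (!condition %in% table$condition) {
    .stopf("unknown condition '%s'", condition)
  }
  rows <- table[table$condition == condition & !is.na(table$p_value), ]
  keep <- abs(rows$log2ratio) > thresholds$log2ratio_min &
    rows$p_value < thresholds$seed_p_max
  genes <- rows$gene_symbol[keep]
  sort(unique(genes[!is.na(genes) & genes != ""]))
}

#' Write a response table to TSV
#' @param table a `response_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  .write_tsv(table, path)
}

#' Read a response table written by [write_response_table()]
#' @param path path to the TSV.
#' @return a `response_table` data.frame.
#' @export
read_response_table <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("protein_id", "gene_symbol", "condition",
                         "log2ratio", "p_value", "q_value", "response_class"),
                   "response table")
  class(df) <- c("response_table", "data.frame")
  df
}
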