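#' Read a cancer-gene role table
#'
#' TSV with columns `gene`, `role`; role is one of `oncogene`, `TSG`,
#' `both` (a COSMIC-census-like table). One role per gene.
#'
#' @param path path to the TSV.
#' @return named character vector, gene -> role.
#' @export
read_cancer_gene_roles <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  .require_columns(df, c("gene", "role"), "cancer gene roles")
  if (anyDuplicated(df$gene)) .stopf("duplicate gene in role table")
  ok <- df$role %in% c("oncogene", "TSG", "both")
  if (!all(ok)) {
    .stopf("unknown role '%s' (expected oncogene/TSG/both)",
           df$role[!ok][1])
  }
  setNames(df$role, df$gene)
}

#' Read a drug-annotation table
#'
#' TSV with columns `drug`, `target` (gene symbol or pathway tag) and
#' `clinical_stage_rank` (1 = FDA-approved, 2 = clinical trial,
#' 3 = preclinical).
#'
#' @param path path to the TSV.
#' @return data.frame with the three columns.
#' @export
read_drug_annotations <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  .require_columns(df, c("drug", "target", "clinical_stage_rank"),
                   "drug annotations")
  df$clinical_stage_rank <- as.integer(df$clinical_stage_rank)
  if (any(is.na(df$clinical_stage_rank)) ||
      !all(df$clinical_stage_rank %in% 1:3)) {
    .stopf("clinical_stage_rank must be 1, 2 or 3")
  }
  df
}

#' Functional score of genes from their cancer role
#'
#' +1 (pro-proliferative) for oncogenes, -1 (anti-proliferative) for tumor
#' suppressors; `NA` (undefined) for dual-role genes and genes absent from
#' the role table.
#'
#' @param genes character vector of gene symbols.
#' @param roles named character vector from [read_cancer_gene_roles()].
#' @return numeric vector in \{+1, -1, NA\}, same length as `genes`.
#' @export
functional_score <- function(genes, roles) {
  r <- unname(roles[genes])
  ifelse(is.na(r) | r == "both", NA_real_,
         ifelse(r == "oncogene", 1, -1))
}

#' Mean functional score of a gene collection
#'
#' The mean of the defined (+1/-1) gene scores; genes with an undefined
#' score are excluded from the mean (not counted as 0). Undefined when no
#' member has a defined score.
#'
#' @param genes nonempty character vector of gene symbols.
#' @param roles named character vector of cancer roles.
#' @return list: `score` (in \[-1, 1\] or NA) and `n_scored`.
#' @export
aggregate_score <- function(genes, roles) {
  if (length(genes) == 0) .stopf("empty gene list")
  sc <- functional_score(genes, roles)
  defined <- sc[!is.na(sc)]
  list(score = if (length(defined) > 0) mean(defined) else NA_real_,
       n_scored = length(defined))
}

#' @noRd
.flag_rule <- function(score, direction) {
  !is.na(score) & !is.na(direction) &
    ((score > 0 & direction == "up") | (score < 0 & direction == "down"))
}

#' Flag candidate resistance mechanisms for one drug condition
#'
#' A mechanism is flagged when it is pro-proliferative (positive functional
#' score) with increased expression, or anti-proliferative (negative score)
#' with decreased expression. Three evidence kinds are evaluated:
#' * `netbox_module`: modules whose |mean log2ratio| >=
#'   `thresholds$log2ratio_min` and whose aggregate score satisfies the rule;
#' * `gsea_process`: GSEA results with q < `gsea_q_max`, direction from the
#'   sign of the enrichment score, scored over the set members measured in
#'   the condition, same magnitude rule;
#' * `individual_protein`: strongly up proteins with score +1 and strongly
#'   down proteins with score -1.
#'
#' @param condition condition label.
#' @param module_summaries named list of `module_summary` objects, one per
#'   background network source (may be empty).
#' @param gsea_results data.frame from [gsea_preranked()] (may be `NULL`).
#' @param collection the `gene_set_collection` used for GSEA (needed for
#'   process membership; may be `NULL` when `gsea_results` is).
#' @param table a `response_table`.
#' @param roles named character vector of cancer roles.
#' @param thresholds a [response_thresholds()] object.
#' @param gsea_q_max q-value cutoff for GSEA processes (default 0.25).
#' @return data.frame of class `candidate_mechanisms`: `condition`,
#'   `evidence_kind`, `source`, `entity`, `direction`, `score`, `n_scored`,
#'   `mean_log2ratio`, `magnitude`, `members` (comma-separated), `flagged`.
#' @export
flag_mechanisms <- function(condition, module_summaries = list(),
                            gsea_results = NULL, collection = NULL,
                            table, roles,
                            thresholds = response_thresholds(),
                            gsea_q_max = 0.25) {
  rows_cond <- table[table$condition == condition, ]
  lfc_by_gene <- tapply(rows_cond$log2ratio, rows_cond$gene_symbol,
                        function(v) mean(v, na.rm = TRUE))
  out <- list()

  for (src in names(module_summaries)) {
    ms <- module_summaries[[src]]
    for (i in seq_len(nrow(ms$modules))) {
      mod <- ms$modules[i, ]
      members <- ms$members$gene[ms$members$module_id == mod$module_id]
      agg <- aggregate_score(members, roles)
      flagged <- .flag_rule(agg$score, mod$direction) &&
        !is.na(mod$mean_log2ratio) &&
        abs(mod$mean_log2ratio) >= thresholds$log2ratio_min
      out[[length(out) + 1]] <- data.frame(
        condition = condition, evidence_kind = "netbox_module", source = src,
        entity = paste0("module_", mod$module_id),
        direction = mod$direction, score = agg$score,
        n_scored = agg$n_scored, mean_log2ratio = mod$mean_log2ratio,
        magnitude = abs(agg$score * mod$mean_log2ratio),
        members = paste(sort(members), collapse = ","), flagged = flagged,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }

  if (!is.null(gsea_results) && nrow(gsea_results) > 0) {
    if (is.null(collection)) .stopf("collection required with gsea_results")
    sig <- gsea_results[!is.na(gsea_results$q_value) &
                        gsea_results$q_value < gsea_q_max, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      id <- sig$set_id[i]
      members <- intersect(collection$sets[[id]], names(lfc_by_gene))
      if (length(members) == 0) next
      agg <- aggregate_score(members, roles)
      mean_lfc <- mean(lfc_by_gene[members], na.rm = TRUE)
      direction <- if (sig$es[i] >= 0) "up" else "down"
      flagged <- .flag_rule(agg$score, direction) &&
        abs(mean_lfc) >= thresholds$log2ratio_min
      out[[length(out) + 1]] <- data.frame(
        condition = condition, evidence_kind = "gsea_process",
        source = "gsea", entity = id, direction = direction,
        score = agg$score, n_scored = agg$n_scored,
        mean_log2ratio = mean_lfc,
        magnitude = abs(agg$score * mean_lfc),
        members = paste(sort(members), collapse = ","), flagged = flagged,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }

  strong <- rows_cond[rows_cond$response_class %in%
                        c("strong_up", "strong_down"), , drop = FALSE]
  if (nrow(strong) > 0) {
    sc <- functional_score(strong$gene_symbol, roles)
    keep <- !is.na(sc)
    strong <- strong[keep, , drop = FALSE]
    sc <- sc[keep]
    for (i in seq_len(nrow(strong))) {
      direction <- if (strong$response_class[i] == "strong_up") "up" else "down"
      out[[length(out) + 1]] <- data.frame(
        condition = condition, evidence_kind = "individual_protein",
        source = "response", entity = strong$gene_symbol[i],
        direction = direction, score = sc[i], n_scored = 1L,
        mean_log2ratio = strong$log2ratio[i],
        magnitude = abs(strong$log2ratio[i]),
        members = strong$gene_symbol[i],
        flagged = .flag_rule(sc[i], direction),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }

  if (length(out) == 0) {
    res <- data.frame(condition = character(), evidence_kind = character(),
                      source = character(), entity = character(),
                      direction = character(), score = numeric(),
                      n_scored = integer(), mean_log2ratio = numeric(),
                      magnitude = numeric(), members = character(),
                      flagged = logical())
  } else {
    res <- do.call(rbind, out)
  }
  class(res) <- c("candidate_mechanisms", "data.frame")
  res
}

#' Nominate ranked drug-combination candidates
#'
#' For each flagged mechanism, every annotated drug whose target matches the
#' mechanism's entity or one of its member genes becomes a combination
#' partner for the profiled drug. Candidates are ordered by clinical stage
#' (1 = FDA-approved first), then decreasing evidence magnitude, then partner
#' drug name and entity (a deterministic total order). A flagged mechanism
#' with no matching drug is emitted with an empty partner and a
#' "no inhibitor available" note.
#'
#' @param mechanisms a `candidate_mechanisms` data.frame.
#' @param drug_annotations data.frame from [read_drug_annotations()].
#' @param primary_drug name of the profiled drug (the tested inhibitor).
#' @return data.frame of class `combination_candidates`: `tested_drug`,
#'   `partner`, `target_of_partner`, `clinical_stage`, `analysis_evidence`,
#'   `evidence_magnitude`, `note`.
#' @export
nominate <- function(mechanisms, drug_annotations, primary_drug) {
  if (nrow(drug_annotations) == 0) .stopf("empty drug annotation table")
  flagged <- mechanisms[mechanisms$flagged, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(flagged))) {
    mech <- flagged[i, ]
    targets <- unique(c(mech$entity, strsplit(mech$members, ",")[[1]]))
    hits <- drug_annotations[drug_annotations$target %in% targets, ,
                             drop = FALSE]
    evidence <- sprintf("%s:%s:%s", mech$evidence_kind, mech$source,
                        mech$entity)
    if (nrow(hits) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        tested_drug = primary_drug, partner = "",
        target_of_partner = "", clinical_stage = NA_integer_,
        analysis_evidence = evidence,
        evidence_magnitude = mech$magnitude,
        note = "no inhibitor available",
        stringsAsFactors = FALSE, row.names = NULL)
    } else {
      for (j in seq_len(nrow(hits))) {
        rows[[length(rows) + 1]] <- data.frame(
          tested_drug = primary_drug, partner = hits$drug[j],
          target_of_partner = hits$target[j],
          clinical_stage = hits$clinical_stage_rank[j],
          analysis_evidence = evidence,
          evidence_magnitude = mech$magnitude, note = "",
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(tested_drug = character(), partner = character(),
                      target_of_partner = character(),
                      clinical_stage = integer(),
                      analysis_evidence = character(),
                      evidence_magnitude = numeric(), note = character())
  } else {
    out <- do.call(rbind, rows)
    out <- unique(out)
    rank_key <- ifelse(is.na(out$clinical_stage), Inf, out$clinical_stage)
    out <- out[order(rank_key, -out$evidence_magnitude, out$partner,
                     out$target_of_partner, out$analysis_evidence), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("combination_candidates", "data.frame")
  out
}
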