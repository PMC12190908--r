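#' Read a pipeline configuration file
#'
#' A single YAML key-value file naming the input paths and analysis
#' settings. Recognized keys: `matrix`, `design`, `networks` (named map of
#' source -> path), `gmt`, `roles`, `drugs`, `dose_response`,
#' `checkerboard_dir`, `output_dir`, `control` (default "DMSO"),
#' `thresholds` (map overriding [response_thresholds()] fields),
#' `linker_q_max` (default 0.005), `gsea` (map: `weight`, `n_perm`, `seed`,
#' `min_size`, `max_size`, `q_max`), `ci_window` (length-2 fa window).
#' Relative paths are resolved against the config file's directory.
#'
#' @param path path to the YAML config.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("matrix", "design", "gmt", "roles", "drugs",
                "dose_response", "checkerboard_dir", "output_dir")) {
    cfg[[key]] <- resolve(cfg[[key]])
  }
  if (!is.null(cfg$networks)) cfg$networks <- lapply(cfg$networks, resolve)
  cfg$control <- cfg$control %||% "DMSO"
  cfg$linker_q_max <- cfg$linker_q_max %||% 0.005
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- do.call(response_thresholds, th)
  gs <- cfg$gsea %||% list()
  cfg$gsea <- list(weight = gs$weight %||% 1, n_perm = gs$n_perm %||% 1000,
                   seed = gs$seed %||% 1, min_size = gs$min_size %||% 3,
                   max_size = gs$max_size %||% 500,
                   q_max = gs$q_max %||% 0.25)
  cfg$ci_window <- cfg$ci_window %||% c(0.2, 0.8)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
.as_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    return(read_pipeline_config(config))
  }
  .stopf("expected a pipeline_config or a path to one")
}

#' @noRd
.check_paths <- function(paths) {
  paths <- unlist(paths)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    .stopf("input path(s) do not exist: %s", paste(absent, collapse = ", "))
  }
}

#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' @noRd
.write_manifest <- function(out_dir, config, inputs, counts) {
  inputs <- unlist(inputs)
  manifest <- list(
    tool = "pertcombi",
    version = as.character(packageVersion("pertcombi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), NULL)],
    input_checksums = as.list(tools::md5sum(inputs)),
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Differential-response stage
#'
#' Reads the expression matrix and design named by the config, runs
#' [differential_response()] and writes `response.tsv` and the MDS QC
#' coordinates `mds.tsv` to the output directory.
#'
#' @param config a `pipeline_config` or a path to one.
#' @param out_dir output directory (default `config$output_dir`).
#' @return the response table, invisibly.
#' @export
stage_respond <- function(config, out_dir = NULL) {
  config <- .as_config(config)
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .check_paths(list(config$matrix, config$design))
  tab <- .stage("respond", {
    x <- read_expression_matrix(config$matrix)
    design <- read_sample_annotation(config$design)
    mds <- mds_projection(x)
    .write_tsv(data.frame(sample_id = rownames(mds), mds,
                          stringsAsFactors = FALSE),
               file.path(out_dir, "mds.tsv"))
    differential_response(x, design, config$thresholds, config$control)
  })
  write_response_table(tab, file.path(out_dir, "response.tsv"))
  invisible(tab)
}

#' Module-detection stage
#'
#' Reads `response.tsv` from the output directory and each configured
#' background network, builds seed lists per condition, admits linkers,
#' detects modules and writes one `modules_<source>.tsv` per network.
#'
#' @inheritParams stage_respond
#' @return named list (per network source) of per-condition module tables,
#'   invisibly.
#' @export
stage_modules <- function(config, out_dir = NULL) {
  config <- .as_config(config)
  out_dir <- out_dir %||% config$output_dir
  .check_paths(config$networks)
  tab <- read_response_table(file.path(out_dir, "response.tsv"))
  conditions <- sort(unique(tab$condition))
  res <- .stage("modules", {
    lapply(config$networks, function(net_path) {
      network <- read_network(net_path)
      do.call(rbind, lapply(conditions, function(cc) {
        seeds <- seed_list(tab, cc, config$thresholds)
        if (length(intersect(seeds, igraph::V(network)$name)) == 0) {
          return(NULL)
        }
        mg <- build_module_graph(network, seeds, config$linker_q_max)
        part <- detect_modules(mg)
        write_modules(module_summary(part, tab, cc), cc,
                      network_source = NA_character_)
      }))
    })
  })
  for (src in names(res)) {
    if (is.null(res[[src]])) next
    res[[src]]$network_source <- src
    .write_tsv(res[[src]], file.path(out_dir, sprintf("modules_%s.tsv", src)))
  }
  invisible(res)
}

#' Enrichment stage
#'
#' Reads `response.tsv` and the module tables from the output directory.
#' Runs preranked GSEA per condition on the seed-list genes ranked by
#' decreasing log2ratio, and hypergeometric ORA per detected module against
#' the universe of genes quantified in the condition. Writes `gsea.tsv` and
#' `ora.tsv`.
#'
#' @inheritParams stage_respond
#' @return list with `gsea` and `ora` data.frames, invisibly.
#' @export
stage_enrich <- function(config, out_dir = NULL) {
  config <- .as_config(config)
  out_dir <- out_dir %||% config$output_dir
  .check_paths(list(config$gmt))
  tab <- read_response_table(file.path(out_dir, "response.tsv"))
  collection <- read_gmt(config$gmt)
  conditions <- sort(unique(tab$condition))
  res <- .stage("enrich", {
    gsea <- do.call(rbind, lapply(conditions, function(cc) {
      seeds <- seed_list(tab, cc, config$thresholds)
      if (length(seeds) < config$gsea$min_size) return(NULL)
      rows <- tab[tab$condition == cc & tab$gene_symbol %in% seeds, ]
      ranked <- tapply(rows$log2ratio, rows$gene_symbol, mean)
      ranked <- setNames(as.numeric(ranked), toupper(names(ranked)))
      g <- suppressWarnings(
        gsea_preranked(ranked, collection, weight = config$gsea$weight,
                       n_perm = config$gsea$n_perm, seed = config$gsea$seed,
                       min_size = config$gsea$min_size,
                       max_size = config$gsea$max_size))
      if (nrow(g) == 0) return(NULL)
      cbind(condition = cc, g, stringsAsFactors = FALSE)
    }))
    ora <- do.call(rbind, lapply(names(config$networks), function(src) {
      mpath <- file.path(out_dir, sprintf("modules_%s.tsv", src))
      if (!file.exists(mpath)) return(NULL)
      mods <- .read_tsv(mpath)
      do.call(rbind, lapply(split(mods, mods[, c("condition", "module_id")],
                                  drop = TRUE), function(d) {
        if (nrow(d) < 3) return(NULL)
        cc <- d$condition[1]
        universe <- toupper(unique(tab$gene_symbol[tab$condition == cc &
                                                     !is.na(tab$p_value)]))
        genes <- intersect(toupper(d$gene), universe)
        if (length(genes) == 0) return(NULL)
        o <- ora_hypergeometric(genes, universe, collection)
        cbind(condition = cc, network_source = src,
              module_id = d$module_id[1], o, stringsAsFactors = FALSE)
      }))
    }))
    list(gsea = gsea, ora = ora)
  })
  if (!is.null(res$gsea)) .write_tsv(res$gsea, file.path(out_dir, "gsea.tsv"))
  if (!is.null(res$ora)) .write_tsv(res$ora, file.path(out_dir, "ora.tsv"))
  invisible(res)
}

#' Nomination stage
#'
#' Reads the persisted response, module and GSEA tables, flags candidate
#' resistance mechanisms per condition and writes the ranked combination
#' candidates to `candidates.tsv`.
#'
#' @inheritParams stage_respond
#' @return the candidate data.frame, invisibly.
#' @export
stage_nominate <- function(config, out_dir = NULL) {
  config <- .as_config(config)
  out_dir <- out_dir %||% config$output_dir
  .check_paths(list(config$roles, config$drugs, config$gmt))
  tab <- read_response_table(file.path(out_dir, "response.tsv"))
  roles <- read_cancer_gene_roles(config$roles)
  drugs <- read_drug_annotations(config$drugs)
  collection <- read_gmt(config$gmt)
  gsea_path <- file.path(out_dir, "gsea.tsv")
  gsea_all <- if (file.exists(gsea_path)) .read_tsv(gsea_path) else NULL
  conditions <- sort(unique(tab$condition))
  out <- .stage("nominate", {
    do.call(rbind, lapply(conditions, function(cc) {
      summaries <- list()
      for (src in names(config$networks)) {
        mpath <- file.path(out_dir, sprintf("modules_%s.tsv", src))
        if (!file.exists(mpath)) next
        mods <- .read_tsv(mpath)
        mods <- mods[mods$condition == cc, , drop = FALSE]
        if (nrow(mods) == 0) next
        members <- data.frame(module_id = mods$module_id, gene = mods$gene,
                              role = mods$role, log2ratio = mods$log2ratio,
                              stringsAsFactors = FALSE)
        modules <- unique(data.frame(module_id = mods$module_id,
                                     mean_log2ratio = mods$module_mean_log2ratio,
                                     stringsAsFactors = FALSE))
        modules$size <- as.integer(table(members$module_id)[
          as.character(modules$module_id)])
        modules$n_measured <- as.integer(tapply(
          !is.na(members$log2ratio), members$module_id,
          sum)[as.character(modules$module_id)])
        modules$direction <- ifelse(is.na(modules$mean_log2ratio), NA,
                                    ifelse(modules$mean_log2ratio > 0,
                                           "up", "down"))
        summaries[[src]] <- structure(list(modules = modules,
                                           members = members),
                                      class = "module_summary")
      }
      g <- if (!is.null(gsea_all)) {
        gsea_all[gsea_all$condition == cc, , drop = FALSE]
      } else NULL
      mech <- flag_mechanisms(cc, summaries, g, collection, tab, roles,
                              config$thresholds, config$gsea$q_max)
      cand <- nominate(mech, drugs, primary_drug = cc)
      if (nrow(cand) == 0) return(NULL)
      cand
    }))
  })
  if (is.null(out)) {
    out <- data.frame(tested_drug = character(), partner = character(),
                      target_of_partner = character(),
                      clinical_stage = integer(),
                      analysis_evidence = character(),
                      evidence_magnitude = numeric(), note = character())
  }
  .write_tsv(out, file.path(out_dir, "candidates.tsv"))
  invisible(out)
}

#' Run the full response-to-nomination pipeline
#'
#' Executes the four analysis stages in order (differential response,
#' module detection on each background network, enrichment, nomination),
#' persisting every intermediate TSV plus a JSON run manifest. Identical
#' config and inputs give identical outputs (all randomness is seeded by the
#' config).
#'
#' @param config a `pipeline_config` or a path to a YAML config file.
#' @param out_dir output directory (default `config$output_dir`).
#' @return the output directory, invisibly.
#' @export
run_response_to_nomination <- function(config, out_dir = NULL) {
  config <- .as_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) .stopf("output_dir is not set")
  .check_paths(c(list(config$matrix, config$design, config$gmt,
                      config$roles, config$drugs), config$networks))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_respond(config, out_dir)
  stage_modules(config, out_dir)
  stage_enrich(config, out_dir)
  stage_nominate(config, out_dir)
  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  counts <- lapply(setNames(outputs, basename(outputs)), function(p) {
    length(readLines(p)) - 1L
  })
  .write_manifest(out_dir, unclass(config),
                  c(list(config$matrix, config$design, config$gmt,
                         config$roles, config$drugs), config$networks),
                  counts)
  invisible(out_dir)
}

#' Run the synergy (combination-index) pipeline
#'
#' Fits median-effect models to the single-drug curves, then computes a
#' summary combination index for every checkerboard TSV in
#' `config$checkerboard_dir`. Single-agent fits come from the dedicated
#' dose-response table when the drug is present there, otherwise from the
#' checkerboard's own single-agent wells. Writes `ci_summary.tsv`,
#' `ci_wells.tsv` and a manifest.
#'
#' @inheritParams run_response_to_nomination
#' @return the summary data.frame, invisibly.
#' @export
run_synergy <- function(config, out_dir = NULL) {
  config <- .as_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) .stopf("output_dir is not set")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .check_paths(list(config$checkerboard_dir))
  boards <- sort(list.files(config$checkerboard_dir, pattern = "\\.tsv$",
                            full.names = TRUE))
  if (length(boards) == 0) {
    .stopf("no checkerboard TSV found in %s", config$checkerboard_dir)
  }
  curves <- if (!is.null(config$dose_response)) {
    .check_paths(list(config$dose_response))
    read_dose_response(config$dose_response)
  } else list()
  res <- .stage("synergy", {
    lapply(boards, function(bp) {
      cb <- tryCatch(read_checkerboard(bp), error = function(e) {
        .stopf("checkerboard '%s': %s", basename(bp), conditionMessage(e))
      })
      fit_for <- function(drug, single) {
        if (drug %in% names(curves)) return(fit_median_effect(curves[[drug]]))
        if (!is.null(single)) return(fit_median_effect(single))
        .stopf("no single-agent data for drug '%s' (%s)", drug, basename(bp))
      }
      fit_a <- fit_for(cb$board$drug_a, cb$single_a)
      fit_b <- fit_for(cb$board$drug_b, cb$single_b)
      ci <- summarize_checkerboard(cb$board, fit_a, fit_b,
                                   fa_window = config$ci_window)
      dataset <- sub("\\.tsv$", "", basename(bp))
      list(summary = data.frame(
             combination = paste(cb$board$drug_a, cb$board$drug_b, sep = "+"),
             dataset = dataset, summary_CI = ci$summary_ci,
             n_wells_used = ci$n_wells_used, call = ci$synergy_call,
             stringsAsFactors = FALSE),
           wells = cbind(dataset = dataset, ci$per_well,
                         stringsAsFactors = FALSE))
    })
  })
  summary <- do.call(rbind, lapply(res, `[[`, "summary"))
  wells <- do.call(rbind, lapply(res, `[[`, "wells"))
  .write_tsv(summary, file.path(out_dir, "ci_summary.tsv"))
  .write_tsv(wells, file.path(out_dir, "ci_wells.tsv"))
  inputs <- c(boards, if (!is.null(config$dose_response)) config$dose_response)
  .write_manifest(out_dir, unclass(config), inputs,
                  list(ci_summary = nrow(summary), ci_wells = nrow(wells)))
  invisible(summary)
}
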