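#' Simulate a drug-perturbation proteome with planted effects
#'
#' Emulates a label-free perturbation-proteomics experiment: per-protein
#' baseline log2 intensities ~ Normal(`baseline_mean`, `baseline_sd`); each
#' sample adds the planted condition-specific effect (if any) plus replicate
#' noise ~ Normal(0, `replicate_sd`); entries are then masked missing
#' completely at random at `missing_rate`. Each drug condition has
#' `n_replicates` biological replicates, and the DMSO control appears once
#' per batch (drugs are split over two batches, as in a two-batch design
#' with its own control replicates per batch).
#'
#' @param n_proteins number of simulated protein groups.
#' @param drugs character vector of drug condition labels.
#' @param n_replicates biological replicates per condition (default 3).
#' @param planted_effects data.frame with columns `gene`, `condition`,
#'   `effect` (log2 units); genes must be among the simulated symbols
#'   `sprintf("G%05d", 1:n_proteins)` (or `genes` when supplied).
#' @param replicate_sd replicate noise SD in log2 units (default 0.25).
#' @param missing_rate completely-at-random missingness rate (default 0.05).
#' @param baseline_mean,baseline_sd baseline log2-intensity distribution
#'   (defaults 25 and 2, a typical DIA log2 range).
#' @param genes optional character vector of gene symbols (length
#'   `n_proteins`).
#' @param seed mandatory integer seed; identical inputs give bit-identical
#'   output.
#' @return list: `matrix` (an [expression_matrix()]), `design` (data.frame
#'   `sample_id`, `condition`, `batch`, `replicate`), `truth` (the planted
#'   effects actually applied).
#' @export
simulate_proteome <- function(n_proteins = 1000,
                              drugs = sprintf("drug%02d", 1:6),
                              n_replicates = 3,
                              planted_effects = NULL,
                              replicate_sd = 0.25, missing_rate = 0.05,
                              baseline_mean = 25, baseline_sd = 2,
                              genes = NULL, seed) {
  if (missing(seed)) .stopf("seed is mandatory")
  stopifnot(missing_rate >= 0, missing_rate < 1, n_replicates >= 2)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_proteins))
  stopifnot(length(genes) == n_proteins)
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(gene = character(), condition = character(),
                                  effect = numeric())
  }
  .require_columns(planted_effects, c("gene", "condition", "effect"),
                   "planted effects")
  unknown <- setdiff(planted_effects$gene, genes)
  if (length(unknown) > 0) {
    .stopf("planted genes not simulated: %s",
           paste(utils::head(unknown, 3), collapse = ", "))
  }
  batches <- rep(c("b1", "b2"), length.out = length(drugs))
  design <- do.call(rbind, lapply(seq_along(drugs), function(i) {
    data.frame(sample_id = sprintf("%s_r%d", drugs[i], seq_len(n_replicates)),
               condition = drugs[i], batch = batches[i],
               replicate = seq_len(n_replicates), stringsAsFactors = FALSE)
  }))
  for (b in unique(batches)) {
    design <- rbind(design, data.frame(
      sample_id = sprintf("DMSO_%s_r%d", b, seq_len(n_replicates)),
      condition = "DMSO", batch = b, replicate = seq_len(n_replicates),
      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  baseline <- rnorm(n_proteins, baseline_mean, baseline_sd)
  vals <- matrix(rnorm(n_proteins * nrow(design), 0, replicate_sd),
                 nrow = n_proteins) + baseline
  for (k in seq_len(nrow(planted_effects))) {
    i <- match(planted_effects$gene[k], genes)
    j <- which(design$condition == planted_effects$condition[k])
    vals[i, j] <- vals[i, j] + planted_effects$effect[k]
  }
  if (missing_rate > 0) {
    vals[runif(length(vals)) < missing_rate] <- NA_real_
  }
  protein_ids <- sprintf("P%05d", seq_len(n_proteins))
  list(matrix = expression_matrix(vals, protein_ids, genes, design$sample_id),
       design = design, truth = planted_effects)
}

#' Simulate a background interaction network with planted communities
#'
#' Stochastic-block-model communities (edge probability `p_in` within,
#' `p_out` between and to/among background nodes) plus designated linker
#' nodes, each wired to `linker_degree` members of its community (at least
#' 3). Node names default to the gene universe `sprintf("G%05d", ...)` so the
#' network aligns with [simulate_proteome()].
#'
#' @param community_sizes integer vector of community sizes (each >= 3).
#' @param p_in,p_out intra- and inter-community edge probabilities.
#' @param n_linkers_per_community planted linkers per community (default 1).
#' @param linker_degree community neighbors per linker (default 10, capped
#'   at the community size).
#' @param n_background number of extra background nodes.
#' @param genes optional node names (communities first, then linkers, then
#'   background).
#' @param seed mandatory integer seed.
#' @return list: `network` (igraph), `truth` (data.frame `gene`,
#'   `community` (NA for background), `role` in member/linker/background).
#' @export
simulate_network <- function(community_sizes = c(12, 12), p_in = 0.6,
                             p_out = 0.02, n_linkers_per_community = 1,
                             linker_degree = 10, n_background = 30,
                             genes = NULL, seed) {
  if (missing(seed)) .stopf("seed is mandatory")
  stopifnot(all(community_sizes >= 3), p_in >= 0, p_in <= 1, p_out >= 0,
            p_out <= 1, n_linkers_per_community >= 0, linker_degree >= 3)
  n_comm <- length(community_sizes)
  n_members <- sum(community_sizes)
  n_link <- n_comm * n_linkers_per_community
  n_total <- n_members + n_link + n_background
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_total))
  stopifnot(length(genes) == n_total)
  community <- rep(NA_integer_, n_total)
  community[seq_len(n_members)] <- rep(seq_len(n_comm), community_sizes)
  role <- rep("background", n_total)
  role[seq_len(n_members)] <- "member"
  link_idx <- if (n_link > 0) n_members + seq_len(n_link) else integer()
  if (n_link > 0) {
    role[link_idx] <- "linker"
    community[link_idx] <- rep(seq_len(n_comm), each = n_linkers_per_community)
  }
  set.seed(seed)
  edges <- list()
  # all unordered pairs among members + background (linkers wired separately)
  free_idx <- c(seq_len(n_members),
                if (n_background > 0) n_members + n_link + seq_len(n_background))
  pairs <- utils::combn(free_idx, 2)
  c1 <- community[pairs[1, ]]
  c2 <- community[pairs[2, ]]
  same_comm <- (!is.na(c1) & !is.na(c2)) & (c1 == c2)
  same_comm[is.na(same_comm)] <- FALSE
  prob <- ifelse(same_comm, p_in, p_out)
  keep <- runif(ncol(pairs)) < prob
  edges[[1]] <- cbind(pairs[1, keep], pairs[2, keep])
  for (li in link_idx) {
    members <- which(community == community[li] & role == "member")
    k <- min(linker_degree, length(members))
    nbrs <- sort(sample(members, k))
    edges[[length(edges) + 1]] <- cbind(nbrs, rep(li, k))
  }
  em <- do.call(rbind, edges)
  from <- pmin(genes[em[, 1]], genes[em[, 2]])
  to <- pmax(genes[em[, 1]], genes[em[, 2]])
  ed <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  network <- igraph::graph_from_data_frame(
    ed, directed = FALSE, vertices = data.frame(name = sort(genes)))
  truth <- data.frame(gene = genes, community = community, role = role,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(network = network, truth = truth)
}

#' Simulate a gene-set collection matched to planted communities
#'
#' One set per planted community (its members plus linkers) and
#' `n_decoy_sets` decoys of matched sizes drawn from the remaining genes.
#'
#' @param truth the truth data.frame from [simulate_network()].
#' @param n_decoy_sets number of decoy sets (default 3).
#' @param universe optional character vector to draw decoys from (default:
#'   all genes in `truth`).
#' @param seed mandatory integer seed.
#' @return a `gene_set_collection`.
#' @export
simulate_gene_sets <- function(truth, n_decoy_sets = 3, universe = NULL,
                               seed) {
  if (missing(seed)) .stopf("seed is mandatory")
  comms <- sort(unique(truth$community[!is.na(truth$community)]))
  if (length(comms) == 0) .stopf("truth has no planted community")
  if (is.null(universe)) universe <- truth$gene
  set.seed(seed)
  sets <- list()
  descriptions <- character()
  for (cc in comms) {
    id <- sprintf("PLANTED_SET_%d", cc)
    sets[[id]] <- sort(truth$gene[!is.na(truth$community) &
                                    truth$community == cc])
    descriptions[id] <- sprintf("planted community %d", cc)
  }
  size_pool <- lengths(sets)
  planted_genes <- unique(unlist(sets))
  decoy_pool <- setdiff(universe, planted_genes)
  for (k in seq_len(n_decoy_sets)) {
    id <- sprintf("DECOY_SET_%d", k)
    size <- size_pool[((k - 1) %% length(size_pool)) + 1]
    sets[[id]] <- sort(sample(decoy_pool, min(size, length(decoy_pool))))
    descriptions[id] <- "decoy set"
  }
  structure(list(sets = lapply(sets, toupper),
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' Simulate cancer-gene roles and a drug-annotation table
#'
#' Designates one planted community as oncogene-rich (`frac_onco` of its
#' members are oncogenes, the rest TSG) and the other communities as
#' TSG-rich; provides a rank-1 (FDA-approved-like) inhibitor targeting one
#' oncogene of the oncogene-rich community, plus decoy drugs at ranks 2-3
#' targeting genes outside it.
#'
#' @param truth the truth data.frame from [simulate_network()].
#' @param onco_community which community is oncogene-rich (default 1).
#' @param frac_onco fraction of oncogenes in the oncogene-rich community
#'   (default 0.9, i.e. >= 80%).
#' @param n_decoy_drugs number of decoy drugs (default 3).
#' @param seed mandatory integer seed.
#' @return list: `roles` (named character vector), `drugs` (data.frame
#'   `drug`, `target`, `clinical_stage_rank`), `planted_drug` (name of the
#'   rank-1 inhibitor), `planted_target`.
#' @export
simulate_roles_and_drugs <- function(truth, onco_community = 1,
                                     frac_onco = 0.9, n_decoy_drugs = 3,
                                     seed) {
  if (missing(seed)) .stopf("seed is mandatory")
  onco_members <- truth$gene[!is.na(truth$community) &
                               truth$community == onco_community &
                               truth$role == "member"]
  if (length(onco_members) == 0) .stopf("community %d has no members",
                                        onco_community)
  other_members <- truth$gene[!is.na(truth$community) &
                                truth$community != onco_community &
                                truth$role == "member"]
  set.seed(seed)
  n_onco <- max(1, round(frac_onco * length(onco_members)))
  onco_genes <- sort(sample(onco_members, n_onco))
  roles <- setNames(rep("TSG", length(c(onco_members, other_members))),
                    c(onco_members, other_members))
  roles[onco_genes] <- "oncogene"
  planted_target <- sample(onco_genes, 1)
  planted_drug <- "inhibitor_rank1"
  drugs <- data.frame(drug = planted_drug, target = planted_target,
                      clinical_stage_rank = 1L, stringsAsFactors = FALSE)
  decoy_pool <- c(other_members,
                  truth$gene[truth$role == "background"])
  for (k in seq_len(n_decoy_drugs)) {
    drugs <- rbind(drugs, data.frame(
      drug = sprintf("decoy_drug_%d", k),
      target = sample(decoy_pool, 1),
      clinical_stage_rank = ((k - 1L) %% 2L) + 2L,
      stringsAsFactors = FALSE))
  }
  list(roles = roles, drugs = drugs, planted_drug = planted_drug,
       planted_target = planted_target)
}

#' Simulate a checkerboard with a known combination-index level
#'
#' Ground truth is defined directly on the CI scale: for each well (d1, d2)
#' the fraction affected solves `d1/DxA(fa) + d2/DxB(fa) = alpha` (monotone
#' one-dimensional root finding), so a correct CI computation recovers
#' `alpha` exactly in the noise-free case. Viability is `(1 - fa)` times
#' multiplicative log-normal noise with coefficient of variation `noise_cv`.
#' Single-agent curves are generated from the median-effect fits directly.
#'
#' @param fit_a,fit_b ground-truth `median_effect_fit` objects.
#' @param alpha target combination index (1 = Loewe additive, < 1 synergy).
#' @param doses_a,doses_b dose grids (default 6 and 9 three-fold dilutions
#'   spanning each drug's Dm).
#' @param noise_cv multiplicative noise CV (default 0).
#' @param n_replicates replicates per well (default 1).
#' @param drug_a,drug_b drug names.
#' @param seed mandatory integer seed.
#' @return list: `board` (a [checkerboard()], replicate-averaged),
#'   `curve_a`, `curve_b` (replicate-level single-agent data.frames `dose`,
#'   `viability`), `alpha`, `fit_a`, `fit_b`.
#' @export
simulate_checkerboard <- function(fit_a, fit_b, alpha = 1,
                                  doses_a = NULL, doses_b = NULL,
                                  noise_cv = 0, n_replicates = 1,
                                  drug_a = "drugA", drug_b = "drugB", seed) {
  if (missing(seed)) .stopf("seed is mandatory")
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"), alpha > 0, noise_cv >= 0)
  if (is.null(doses_a)) doses_a <- fit_a$dm * 9 / 3^(0:5)
  if (is.null(doses_b)) doses_b <- fit_b$dm * 27 / 3^(0:8)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) {
    if (noise_cv == 0) rep(1, n) else rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  fa_for_well <- function(d1, d2) {
    if (d1 <= 0 && d2 <= 0) return(0)
    f <- function(fa) d1 / dose_for_effect(fit_a, fa) +
      d2 / dose_for_effect(fit_b, fa) - alpha
    uniroot(f, lower = 1e-12, upper = 1 - 1e-12, tol = 1e-12)$root
  }
  fa_true <- outer(doses_a, doses_b, Vectorize(fa_for_well))
  reps <- lapply(seq_len(n_replicates), function(r) {
    (1 - fa_true) * matrix(noise(length(fa_true)), nrow = nrow(fa_true))
  })
  v <- Reduce(`+`, reps) / n_replicates
  board <- checkerboard(doses_a, doses_b, v, drug_a, drug_b)
  single <- function(fit, doses) {
    fa <- (doses / fit$dm)^fit$m / (1 + (doses / fit$dm)^fit$m)
    do.call(rbind, lapply(seq_len(max(3, n_replicates)), function(r) {
      data.frame(dose = doses, viability = (1 - fa) * noise(length(doses)),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  list(board = board, curve_a = single(fit_a, doses_a),
       curve_b = single(fit_b, doses_b), alpha = alpha,
       fit_a = fit_a, fit_b = fit_b)
}

#' Write a simulated checkerboard (and single-agent wells) as a long TSV
#'
#' Produces the raw-viability long format read by [read_checkerboard()]:
#' combination wells, single-agent wells and `n_dmso` DMSO control rows, all
#' scaled by an arbitrary plate signal.
#'
#' @param sim output of [simulate_checkerboard()].
#' @param path output path.
#' @param n_dmso number of DMSO control rows (default 6).
#' @param signal raw-signal scale factor (default 10000).
#' @return `path`, invisibly.
#' @export
write_checkerboard_tsv <- function(sim, path, n_dmso = 6, signal = 10000) {
  board <- sim$board
  grid <- expand.grid(i = seq_along(board$doses_a),
                      j = seq_along(board$doses_b))
  rows <- data.frame(
    drug_A = board$drug_a, dose_A_uM = board$doses_a[grid$i],
    drug_B = board$drug_b, dose_B_uM = board$doses_b[grid$j],
    replicate = 1L,
    viability_raw = signal * board$viability[cbind(grid$i, grid$j)],
    stringsAsFactors = FALSE)
  add_single <- function(curve, is_a) {
    reps <- as.integer(ave(curve$dose, curve$dose, FUN = seq_along))
    data.frame(
      drug_A = board$drug_a,
      dose_A_uM = if (is_a) curve$dose else 0,
      drug_B = board$drug_b,
      dose_B_uM = if (is_a) 0 else curve$dose,
      replicate = reps, viability_raw = signal * curve$viability,
      stringsAsFactors = FALSE)
  }
  rows <- rbind(rows, add_single(sim$curve_a, TRUE),
                add_single(sim$curve_b, FALSE))
  rows <- rbind(rows, data.frame(
    drug_A = board$drug_a, dose_A_uM = 0, drug_B = board$drug_b,
    dose_B_uM = 0, replicate = seq_len(n_dmso), viability_raw = signal,
    stringsAsFactors = FALSE))
  .write_tsv(rows, path)
}

#' Generate and persist a complete synthetic input bundle
#'
#' Writes every pipeline input with known ground truth to `dir`: expression
#' matrix + design (community 1 of the interaction network is planted up
#' +1 log2 and community 2 down -1 log2 in the first drug condition, plus a
#' frequently-responsive gene set planted up in every condition), two
#' independent background networks over the same communities (emulating two
#' interaction sources), a GMT collection, cancer-gene roles, drug
#' annotations (one rank-1 inhibitor of an up-regulated oncogene), a
#' single-drug dose-response table and two checkerboards (one synergistic,
#' one additive), and a `truth/` directory.
#'
#' @param dir output directory (created if needed).
#' @param seed mandatory integer seed.
#' @param n_proteins proteins in the simulated matrix (default 1000).
#' @param effect planted log2 effect size (default 1.0).
#' @param n_frequent number of frequently responsive genes (default 12).
#' @param responsive_fraction fraction of the proteome planted as additional
#'   drug-specific responders per condition, half up and half down (default
#'   0.1, emulating the sizable responsive fraction of an IC50-dose
#'   perturbation screen; capped by the available genes).
#' @return list with all file paths (`paths`) and ground truth (`truth`).
#' @export
simulate_bundle <- function(dir, seed, n_proteins = 1000, effect = 1.0,
                            n_frequent = 12, responsive_fraction = 0.1) {
  if (missing(seed)) .stopf("seed is mandatory")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  drugs <- sprintf("drug%02d", 1:6)
  net1 <- simulate_network(seed = seed)
  net2 <- simulate_network(seed = seed + 1)
  truth <- net1$truth
  comm1 <- truth$gene[!is.na(truth$community) & truth$community == 1 &
                        truth$role == "member"]
  comm2 <- truth$gene[!is.na(truth$community) & truth$community == 2 &
                        truth$role == "member"]
  n_net <- nrow(truth)
  frequent <- sprintf("G%05d", (n_net + 1):(n_net + n_frequent))
  n_free <- n_proteins - n_net - n_frequent
  n_resp <- min(round(responsive_fraction * n_proteins),
                floor(n_free / length(drugs)))
  per_drug <- lapply(seq_along(drugs), function(i) {
    if (n_resp <= 0) return(NULL)
    start <- n_net + n_frequent + (i - 1) * n_resp
    genes <- sprintf("G%05d", (start + 1):(start + n_resp))
    data.frame(gene = genes, condition = drugs[i],
               effect = effect * rep_len(c(1, -1), n_resp))
  })
  planted <- rbind(
    data.frame(gene = comm1, condition = drugs[1], effect = effect),
    data.frame(gene = comm2, condition = drugs[1], effect = -effect),
    do.call(rbind, lapply(drugs, function(dd) {
      data.frame(gene = frequent, condition = dd, effect = effect)
    })),
    do.call(rbind, per_drug))
  sim <- simulate_proteome(n_proteins = n_proteins, drugs = drugs,
                           planted_effects = planted, seed = seed + 2)
  gsc <- simulate_gene_sets(truth, seed = seed + 3)
  rd <- simulate_roles_and_drugs(truth, seed = seed + 4)
  fit_a <- median_effect_fit(m = 1.5, dm = 2)
  fit_b <- median_effect_fit(m = 1, dm = 10)
  cb_syn <- simulate_checkerboard(fit_a, fit_b, alpha = 0.5, noise_cv = 0.05,
                                  n_replicates = 3, drug_a = drugs[1],
                                  drug_b = rd$planted_drug, seed = seed + 5)
  cb_add <- simulate_checkerboard(fit_a, fit_b, alpha = 1.5, noise_cv = 0.05,
                                  n_replicates = 3, drug_a = drugs[1],
                                  drug_b = "decoy_drug_1", seed = seed + 6)
  paths <- list(
    matrix = file.path(dir, "expression_matrix.tsv"),
    design = file.path(dir, "design.tsv"),
    network_fi = file.path(dir, "network_fi.sif"),
    network_indra = file.path(dir, "network_indra.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    roles = file.path(dir, "cancer_gene_roles.tsv"),
    drugs = file.path(dir, "drug_annotations.tsv"),
    dose_response = file.path(dir, "single_drug.tsv"),
    checkerboard_dir = file.path(dir, "checkerboards"))
  dir.create(paths$checkerboard_dir, showWarnings = FALSE)
  write_expression_matrix(sim$matrix, paths$matrix)
  .write_tsv(sim$design, paths$design)
  write_network(net1$network, paths$network_fi, format = "sif")
  write_network(net2$network, paths$network_indra, format = "edgelist")
  write_gmt(gsc, paths$gmt)
  .write_tsv(data.frame(gene = names(rd$roles), role = unname(rd$roles)),
             paths$roles)
  .write_tsv(rd$drugs, paths$drugs)
  # single-drug table for the two checkerboard agents
  sd_rows <- do.call(rbind, lapply(
    list(list(d = drugs[1], cv = cb_syn$curve_a),
         list(d = rd$planted_drug, cv = cb_syn$curve_b)),
    function(e) {
      reps <- as.integer(ave(e$cv$dose, e$cv$dose, FUN = seq_along))
      data.frame(drug = e$d, dose_uM = e$cv$dose, replicate = reps,
                 viability_raw = 10000 * e$cv$viability,
                 stringsAsFactors = FALSE)
    }))
  sd_rows <- rbind(sd_rows, data.frame(
    drug = "DMSO", dose_uM = 0, replicate = 1:6, viability_raw = 10000,
    stringsAsFactors = FALSE))
  .write_tsv(sd_rows, paths$dose_response)
  write_checkerboard_tsv(cb_syn, file.path(paths$checkerboard_dir,
                                           "combo_synergistic.tsv"))
  write_checkerboard_tsv(cb_add, file.path(paths$checkerboard_dir,
                                           "combo_antagonistic.tsv"))
  .write_tsv(sim$truth, file.path(dir, "truth", "planted_effects.tsv"))
  .write_tsv(truth, file.path(dir, "truth", "network_communities.tsv"))
  .write_tsv(data.frame(board = c("combo_synergistic", "combo_antagonistic"),
                        alpha = c(0.5, 1.5)),
             file.path(dir, "truth", "checkerboard_alpha.tsv"))
  list(paths = paths,
       truth = list(planted_effects = sim$truth, network = truth,
                    frequent = frequent,
                    planted_drug = rd$planted_drug,
                    planted_target = rd$planted_target,
                    roles = rd$roles, drugs = rd$drugs,
                    alpha = c(combo_synergistic = 0.5,
                              combo_antagonistic = 1.5),
                    primary_drug = drugs[1]))
}
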