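#' Read a GMT gene-set collection
#'
#' GMT rows are `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols
#' are uppercased and deduplicated within each set.
#'
#' @param path path to a GMT file (gzip transparent).
#' @return list of class `gene_set_collection`: `sets` (named list of
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- .text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    .stopf("GMT row with fewer than 3 fields at line %d", bad[1])
  }
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) .stopf("duplicate set id in GMT")
  descriptions <- setNames(vapply(parts, `[[`, "", 2), ids)
  sets <- setNames(lapply(parts, function(p) {
    g <- unique(toupper(p[-(1:2)]))
    g[nzchar(g)]
  }), ids)
  if (any(lengths(sets) == 0)) .stopf("empty gene set in GMT")
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Over-representation analysis by the hypergeometric upper tail
#'
#' For each gene set, the p-value of observing at least the witnessed
#' overlap between `genes` and the set when |genes| items are drawn from the
#' universe. Sets are first intersected with the universe; q-values are BH
#' over all sets tested.
#'
#' @param genes character vector of query genes (e.g. one module), must be a
#'   subset of `universe`.
#' @param universe character vector of all testable genes (e.g. all genes
#'   quantified in the condition).
#' @param collection a `gene_set_collection`.
#' @return data.frame `set_id`, `overlap`, `set_size`, `n_genes`,
#'   `universe_size`, `p_value`, `q_value`, sorted by p-value.
#' @export
ora_hypergeometric <- function(genes, universe, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- unique(toupper(genes))
  universe <- unique(toupper(universe))
  if (length(genes) == 0) .stopf("empty gene list")
  out_univ <- setdiff(genes, universe)
  if (length(out_univ) > 0) {
    .stopf("query genes not in universe: %s",
           paste(utils::head(out_univ, 3), collapse = ", "))
  }
  N <- length(universe)
  n <- length(genes)
  res <- do.call(rbind, lapply(names(collection$sets), function(id) {
    set <- intersect(collection$sets[[id]], universe)
    K <- length(set)
    x <- length(intersect(set, genes))
    p <- if (K == 0) NA_real_ else phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, overlap = x, set_size = K, n_genes = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  res <- res[!is.na(res$p_value), , drop = FALSE]
  res$q_value <- adjust_bh(res$p_value)
  res[order(res$p_value, res$set_id), , drop = FALSE]
}

#' Weighted Kolmogorov-Smirnov enrichment score for one gene set
#'
#' Running-sum statistic on a ranked gene list: genes are ordered by
#' decreasing score (ties broken by gene symbol); hits increment the sum
#' proportionally to |score|^`weight` (normalized to 1 over the set's hits),
#' misses decrement it by 1/(n - n_hits). The enrichment score is the
#' running-sum value of maximal absolute deviation from zero.
#'
#' @param scores named numeric vector (gene -> ranking score), any order;
#'   names must be unique.
#' @param set character vector of gene symbols; at least one must appear in
#'   `scores`.
#' @param weight exponent on |score| for hit increments (0 = classic KS,
#'   1 = default weighting).
#' @return list: `es`, `n_hits`, `leading_edge` (character vector).
#' @export
gsea_es <- function(scores, set, weight = 1) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    .stopf("scores must be uniquely named by gene")
  }
  if (any(!is.finite(scores))) .stopf("scores must be finite")
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  genes <- names(s)
  hit <- genes %in% set
  if (!any(hit)) .stopf("no member of the set is in the ranking")
  es <- .es_stat(unname(s), hit, weight)
  run <- .es_running(unname(s), hit, weight)
  i <- which.max(abs(run))
  le <- if (run[i] >= 0) genes[seq_len(i)][hit[seq_len(i)]]
        else genes[i:length(genes)][hit[i:length(genes)]]
  list(es = es, n_hits = sum(hit), leading_edge = le)
}

#' @noRd
.es_running <- function(s, hit, weight) {
  n <- length(hit)
  nh <- sum(hit)
  w <- abs(s[hit])^weight
  tot <- sum(w)
  steps <- numeric(n)
  steps[hit] <- if (tot > 0) w / tot else 1 / nh
  if (n > nh) steps[!hit] <- -1 / (n - nh)
  cumsum(steps)
}

#' @noRd
.es_stat <- function(s, hit, weight) {
  run <- .es_running(s, hit, weight)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Enrichment scores per [gsea_es()]; significance by gene-label
#' permutation: for each set, `n_perm` random same-size gene subsets are
#' scored, the nominal p compares the observed ES against permuted ES of the
#' same sign, and NES = ES / mean(|permuted ES| of the same sign). q-values
#' are BH across the sets tested. Sets with fewer than `min_size` or more
#' than `max_size` members in the ranking are skipped with a warning.
#' Results are reproducible bit-for-bit for a fixed `seed`.
#'
#' @param ranked named numeric vector (gene -> score); ranking is by
#'   decreasing score, ties broken by gene symbol.
#' @param collection a `gene_set_collection`.
#' @param weight hit-increment exponent (default 1).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param min_size,max_size gene-set size bounds after intersection with the
#'   ranking.
#' @return data.frame `set_id`, `size`, `es`, `nes`, `p_value`, `q_value`,
#'   `leading_edge` (comma-separated), sorted by p-value.
#' @export
gsea_preranked <- function(ranked, collection, weight = 1, n_perm = 1000,
                           seed = 1, min_size = 3, max_size = 500) {
  stopifnot(inherits(collection, "gene_set_collection"), n_perm >= 100)
  if (is.null(names(ranked)) || anyDuplicated(names(ranked))) {
    .stopf("ranked scores must be uniquely named by gene")
  }
  if (any(!is.finite(ranked))) .stopf("scores must be finite")
  ord <- order(-ranked, names(ranked))
  s <- unname(ranked[ord])
  genes <- names(ranked)[ord]
  n <- length(s)
  set.seed(seed)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], genes)
    size <- length(members)
    if (size < min_size || size > max_size) {
      .warnf("set '%s' skipped: %d member(s) in ranking", id, size)
      return(NULL)
    }
    hit <- genes %in% members
    run <- .es_running(s, hit, weight)
    i <- which.max(abs(run))
    es <- run[i]
    le <- if (es >= 0) genes[seq_len(i)][hit[seq_len(i)]]
          else genes[i:n][hit[i:n]]
    perm <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, size)] <- TRUE
      .es_stat(s, h, weight)
    }, 0)
    same <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
    if (length(same) == 0) {
      p <- 1 / (n_perm + 1)
      nes <- NA_real_
    } else {
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- es / mean(abs(same))
    }
    data.frame(set_id = id, size = size, es = es, nes = nes, p_value = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(set_id = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_value = numeric(),
                      q_value = numeric(), leading_edge = character()))
  }
  out <- do.call(rbind, rows)
  out$q_value <- adjust_bh(out$p_value)
  out <- out[order(out$p_value, out$set_id),
             c("set_id", "size", "es", "nes", "p_value", "q_value",
               "leading_edge")]
  rownames(out) <- NULL
  out
}
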