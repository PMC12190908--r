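# shared fixtures and independent oracles, built in code at test time

# brute-force BH step-up: adjusted_(i) = min_{j >= i} p_(j) * n / j, capped at 1
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exhaustive hypergeometric: P(>= s seeds among k draws from the other N-1 nodes)
linker_oracle <- function(n_nodes, n_seeds_in, k, s) {
  others <- seq_len(n_nodes - 1)
  is_seed <- others <= n_seeds_in
  hits <- utils::combn(others, k, function(idx) sum(is_seed[idx]) >= s)
  mean(hits)
}

# literal running-sum ES, loop form
es_oracle <- function(scores, set, weight) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  genes <- names(s)
  hit <- genes %in% set
  nh <- sum(hit)
  n <- length(s)
  tot <- sum(abs(s[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (tot > 0) abs(s[i])^weight / tot else 1 / nh
    } else {
      -1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# exhaustive set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recur <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (g in seq_len(k + 1)) recur(c(assign, g), max(k, g))
  }
  recur(integer(), 0)
  out
}

make_collection <- function(sets) {
  structure(list(sets = lapply(sets, toupper),
                 descriptions = setNames(rep("", length(sets)), names(sets))),
            class = "gene_set_collection")
}

# tiny expression fixture: values are log2 intensities, one NA
tiny_matrix <- function() {
  vals <- matrix(c(20, 21, 20.5, 19.9,
                   25, NA, 25.2, 25.1,
                   18, 18.1, 17.9, 18.2), nrow = 3, byrow = TRUE)
  expression_matrix(vals, c("P1", "P2", "P3"), c("GA", "GB", "GC"),
                    c("s1", "s2", "s3", "s4"))
}

# balanced two-condition design for a 3v3 contrast on 6 samples
design_3v3 <- function(condition = "drugX") {
  data.frame(
    sample_id = c(paste0("t", 1:3), paste0("c", 1:3)),
    condition = rep(c(condition, "DMSO"), each = 3),
    batch = "b1", replicate = rep(1:3, 2), stringsAsFactors = FALSE)
}

matrix_3v3 <- function(trt, ctl, protein = "P1", gene = "G1") {
  vals <- matrix(c(trt, ctl), nrow = 1)
  expression_matrix(vals, protein, gene, c(paste0("t", 1:3), paste0("c", 1:3)))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
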