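test_that("network files are parsed, deduplicated and self-loop free", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tinteracts\tB", "B\tinteracts\tA", "A\tinteracts\tC",
               "A\tinteracts\tA"), path)
  expect_message(g <- read_network(path), "self-loop")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))

  writeLines(c("A\tB", "A\tB\tC\tD"), path)
  expect_error(read_network(path), "line 2")
})

test_that("simulated networks round-trip through SIF and edge-list formats", {
  net <- simulate_network(community_sizes = c(5, 5), n_background = 5,
                          linker_degree = 3, seed = 8)
  for (fmt in c("sif", "edgelist")) {
    path <- withr::local_tempfile()
    write_network(net$network, path, format = fmt)
    back <- read_network(path)
    ed <- function(g) {
      el <- igraph::as_edgelist(g)
      sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    }
    expect_identical(ed(back), ed(net$network))
  }
})

test_that("linker p-value matches the closed form and the degenerate case", {
  # star: candidate L adjacent to exactly the 3 seeds among 6 nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("L", "L", "L", "X"), to = c("A", "B", "C", "Y")),
    directed = FALSE)
  st <- linker_test(g, c("A", "B", "C"), "L")
  expect_equal(st$p_value, choose(3, 3) * choose(2, 0) / choose(5, 3))
  expect_equal(st$p_value, 0.1)

  # zero seed neighbors -> p = 1
  st2 <- linker_test(g, c("A", "B", "C"), "X")
  expect_equal(st2$p_value, 1)

  expect_error(linker_test(g, c("A", "L"), "L"), "is a seed")
  expect_error(linker_test(g, "A", "Z"), "not in network")
})

test_that("linker p-value equals exhaustive enumeration on small graphs", {
  set.seed(17)
  checked <- 0
  while (checked < 40) {
    n <- sample(5:10, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.7))
    igraph::V(g)$name <- LETTERS[seq_len(n)]
    n_seeds <- sample(2:4, 1)
    seeds <- LETTERS[seq_len(n_seeds)]
    cand <- setdiff(LETTERS[seq_len(n)], seeds)
    cand <- cand[igraph::degree(g, cand) >= 1]
    if (length(cand) == 0) next
    cand <- cand[1]
    st <- linker_test(g, seeds, cand)
    p_brute <- linker_oracle(n, n_seeds, st$global_degree, st$seed_neighbors)
    expect_equal(st$p_value, p_brute, tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("connecting a candidate to one more seed never increases its p", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 10
    g <- igraph::sample_gnp(n, 0.3)
    igraph::V(g)$name <- LETTERS[1:n]
    seeds <- LETTERS[1:4]
    cand <- "J"
    free_seed <- seeds[!seeds %in% igraph::neighbors(g, cand)$name]
    if (igraph::degree(g, cand) < 1 || length(free_seed) == 0) next
    p0 <- linker_test(g, seeds, cand)$p_value
    g2 <- igraph::add_edges(g, c(cand, free_seed[1]))
    p1 <- linker_test(g2, seeds, cand)$p_value
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("module graph keeps seeds and admits linkers per the BH rule", {
  # connected seed triangle, no candidate qualifies
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C", "C"), to = c("B", "C", "A", "D")),
    directed = FALSE)
  mg <- build_module_graph(g, c("A", "B", "C"))
  expect_setequal(igraph::V(mg$graph)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(mg$graph), 3)
  expect_false(any(mg$linker_stats$accepted))

  # candidate pool of size 1 with p < 0.005: BH on one test equals raw p.
  # L adjacent to all 7 seeds in a 14-node graph:
  # p = C(7,7)/C(13,7) = 1/1716 < 0.005
  seeds <- paste0("S", 1:7)
  pad <- paste0("Z", 1:6)  # degree-0 padding (never candidates)
  edges <- data.frame(from = rep("L", 7), to = seeds)
  g2 <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(seeds, "L", pad)))
  mg2 <- build_module_graph(g2, seeds)
  expect_equal(nrow(mg2$linker_stats), 1)
  expect_equal(mg2$linker_stats$p_value, 1 / choose(13, 7))
  expect_true(mg2$linker_stats$accepted)
  expect_true("L" %in% igraph::V(mg2$graph)$name)
  expect_equal(unname(mg2$roles["L"]), "linker")

  # degenerate threshold admits nothing
  mg3 <- build_module_graph(g2, seeds, linker_q_max = 0)
  expect_false(any(mg3$linker_stats$accepted))
  expect_false("L" %in% igraph::V(mg3$graph)$name)

  # seeds absent from the network are reported, not dropped silently
  mg4 <- build_module_graph(g, c("A", "B", "NOPE"))
  expect_equal(mg4$missing_seeds, "NOPE")
  expect_error(build_module_graph(g, "NOPE"), "no seed maps")
})

test_that("divisive clustering finds the max-modularity partition", {
  # two 4-cliques joined by one bridge; verify against exhaustive search
  mk_clique <- function(v) t(utils::combn(v, 2))
  el <- rbind(mk_clique(paste0("a", 1:4)), mk_clique(paste0("b", 1:4)),
              c("a1", "b1"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  part <- detect_modules(g)
  mods <- split(names(part$membership), part$membership)
  expect_equal(length(mods), 2)
  expect_setequal(vapply(mods, function(m) paste(sort(m), collapse = ","), ""),
                  c("a1,a2,a3,a4", "b1,b2,b3,b4"))
  # exhaustive max modularity over all partitions of the 8 nodes
  nodes <- igraph::V(g)$name
  qs <- vapply(all_partitions(8), function(asg) {
    igraph::modularity(g, setNames(asg, nodes))
  }, 0)
  expect_equal(part$modularity, max(qs), tolerance = 1e-12)

  # single clique stays one module
  g1 <- igraph::graph_from_edgelist(mk_clique(paste0("c", 1:5)),
                                    directed = FALSE)
  expect_equal(length(unique(detect_modules(g1)$membership)), 1)

  # edgeless graph: singleton modules, Q = 0 by convention
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- paste0("n", 1:5)
  p0 <- detect_modules(g0)
  expect_equal(length(unique(p0$membership)), 5)
  expect_equal(p0$modularity, 0)
})

test_that("partitions are disjoint, exhaustive and input-order invariant", {
  net <- simulate_network(seed = 4)
  seeds <- net$truth$gene[net$truth$role == "member"]
  path <- withr::local_tempfile()
  write_network(net$network, path, format = "edgelist")
  g1 <- read_network(path)
  mg <- build_module_graph(g1, seeds)
  part <- detect_modules(mg)
  expect_setequal(names(part$membership), igraph::V(mg$graph)$name)
  expect_false(anyNA(part$membership))

  # shuffle the edge-list row order on disk; partition must be identical
  lines <- readLines(path)
  set.seed(99)
  writeLines(sample(lines), path)
  part2 <- detect_modules(build_module_graph(read_network(path), seeds))
  expect_identical(part$membership[sort(names(part$membership))],
                   part2$membership[sort(names(part2$membership))])
})

test_that("module summaries average measured members only", {
  membership <- setNames(c(1L, 1L, 2L, 2L), c("g1", "g2", "h1", "h2"))
  part <- structure(list(membership = membership, modularity = 0.1,
                         roles = setNames(rep("seed", 4), names(membership))),
                    class = "module_partition")
  tab <- data.frame(protein_id = c("p1", "p2", "p3"),
                    gene_symbol = c("g1", "g2", "h1"),
                    condition = "d1",
                    log2ratio = c(0.99, 0.99, -1),
                    p_value = 0.01, q_value = 0.05, n_perturbed = 3,
                    n_control = 3, response_class = "constant",
                    stringsAsFactors = FALSE)
  ms <- module_summary(part, tab, "d1")
  m1 <- ms$modules[ms$modules$module_id == 1, ]
  expect_equal(m1$mean_log2ratio, 0.99)
  expect_equal(m1$direction, "up")
  m2 <- ms$modules[ms$modules$module_id == 2, ]
  expect_equal(m2$n_measured, 1)  # h2 unmeasured, excluded from mean
  expect_equal(m2$mean_log2ratio, -1)

  # symmetric members cancel
  tab2 <- tab
  tab2$log2ratio <- c(1, -1, 0)
  ms2 <- module_summary(part, tab2, "d1")
  expect_equal(ms2$modules$mean_log2ratio[ms2$modules$module_id == 1], 0)
})
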