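.cats <- function(vars, cat = "MRG") stats::setNames(rep(cat, length(vars)), vars)

test_that("a table with no strong pairs yields all nodes and zero edges", {
  set.seed(51)
  m <- matrix(stats::rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("v", 1:4)))
  net <- build_network(m, .cats(colnames(m)), rho_threshold = 0.99)
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 0)
})

test_that("the rho threshold is strict: rho exactly at the cutoff is no edge", {
  # ranks engineered so Spearman rho is exactly 0.6 at n = 6
  x <- 1:6
  yy <- c(2, 1, 3, 4, 6, 5)
  r <- cor(x, yy, method = "spearman")  # exactly 1 - 24/210
  net <- build_network(cbind(a = x, b = yy), .cats(c("a", "b")),
                       rho_threshold = r, p_threshold = 0.9)
  expect_equal(igraph::ecount(net), 0)
  net2 <- build_network(cbind(a = x, b = yy), .cats(c("a", "b")),
                        rho_threshold = r - 1e-9, p_threshold = 0.9)
  expect_equal(igraph::ecount(net2), 1)
})

test_that("untagged variables error and constant variables are excluded", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 5), k = rep(1, 5))
  expect_error(build_network(m, .cats(c("a", "b"))), "k")
  expect_warning(net <- build_network(m, .cats(c("a", "b", "k"))), "constant")
  expect_equal(sort(igraph::V(net)$name), c("a", "b"))
  expect_equal(igraph::graph_attr(net, "excluded"), "k")
})

test_that("edge sets match brute-force pair enumeration on random tables", {
  set.seed(52)
  for (i in 1:20) {
    m <- matrix(stats::rnorm(12 * 10), 12, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    # plant a few correlated pairs so edges actually occur
    m[, 2] <- m[, 1] + stats::rnorm(12, sd = 0.4)
    m[, 5] <- -m[, 4] + stats::rnorm(12, sd = 0.4)
    net <- build_network(m, .cats(colnames(m)))
    expect_equal(edge_keys(net), oracle_edges(m))
  }
})

test_that("edges carry rho, p, sign and degrees count incident edges", {
  set.seed(53)
  m <- matrix(stats::rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("v", 1:5)))
  m[, 2] <- m[, 1] + stats::rnorm(20, sd = 0.3)
  m[, 3] <- -m[, 1] + stats::rnorm(20, sd = 0.3)
  net <- build_network(m, .cats(colnames(m)))
  expect_true(all(abs(igraph::E(net)$rho) > 0.6))
  expect_true(all(igraph::E(net)$p < 0.05))
  expect_equal(igraph::E(net)$sign,
               ifelse(igraph::E(net)$rho >= 0, "positive", "negative"))
  expect_equal(igraph::V(net)$degree,
               unname(igraph::degree(net)))
  expect_true(any(igraph::E(net)$sign == "negative"))
})

test_that("tightening either threshold never adds edges", {
  set.seed(54)
  m <- matrix(stats::rnorm(15 * 8), 15, 8, dimnames = list(NULL, paste0("v", 1:8)))
  m[, 2] <- m[, 1] + stats::rnorm(15, sd = 0.5)
  m[, 6] <- m[, 5] + stats::rnorm(15, sd = 0.5)
  loose <- edge_keys(build_network(m, .cats(colnames(m)), 0.3, 0.1))
  for (thr in list(c(0.5, 0.1), c(0.3, 0.02), c(0.7, 0.01))) {
    tight <- edge_keys(build_network(m, .cats(colnames(m)), thr[1], thr[2]))
    expect_true(all(tight %in% loose))
  }
})

test_that("the network is invariant under monotone transforms of the data", {
  set.seed(55)
  m <- matrix(stats::rlnorm(18 * 6), 18, 6, dimnames = list(NULL, paste0("v", 1:6)))
  m[, 2] <- m[, 1] * stats::rlnorm(18, 0, 0.2)
  a <- build_network(m, .cats(colnames(m)))
  b <- build_network(log(m), .cats(colnames(m)))
  expect_equal(edge_keys(a), edge_keys(b))
  expect_equal(igraph::E(a)$rho, igraph::E(b)$rho, tolerance = 1e-12)
})

test_that("module detection separates disjoint cliques and isolates singletons", {
  edges <- data.frame(from = c("a", "b", "c", "x", "y", "z"),
                      to = c("b", "c", "a", "y", "z", "x"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$rho <- 0.9
  g <- detect_modules(g, seed = 1)
  mods <- igraph::V(g)$module
  expect_equal(length(unique(mods)), 2)
  expect_equal(length(unique(mods[1:3])), 1)
  expect_equal(length(unique(mods[4:6])), 1)
  # empty graph: every node its own module
  e <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(e)$name <- paste0("n", 1:5)
  e <- detect_modules(e, seed = 1)
  expect_equal(sort(unique(igraph::V(e)$module)), 1:5)
})

test_that("module detection is deterministic for a fixed seed", {
  set.seed(56)
  pg <- planted_block_graph()
  m1 <- igraph::V(detect_modules(pg$graph, seed = 9))$module
  m2 <- igraph::V(detect_modules(pg$graph, seed = 9))$module
  expect_identical(m1, m2)
})

test_that("returned partition beats the one-module partition on modularity", {
  set.seed(57)
  pg <- planted_block_graph()
  g <- detect_modules(pg$graph, seed = 1)
  w <- abs(igraph::E(g)$rho)
  trivial <- igraph::modularity(g, rep(1, igraph::vcount(g)), weights = w)
  expect_gte(igraph::graph_attr(g, "modularity"), trivial)
})

test_that("hub is the most densely connected node in each module", {
  # star of 5: the center
  star <- igraph::graph_from_data_frame(
    data.frame(from = "c", to = paste0("l", 1:4)), directed = FALSE)
  igraph::E(star)$rho <- 0.8
  igraph::V(star)$module <- 1L
  igraph::V(star)$degree <- igraph::degree(star)
  h <- find_hubs(star)
  expect_equal(igraph::graph_attr(h, "hubs")$hub, "c")
  expect_equal(igraph::V(h)$name[igraph::V(h)$hub], "c")
  expect_error(find_hubs(igraph::make_ring(3)), "modules")
})

test_that("degree ties break by larger sum of |rho|, then lexicographic id", {
  # square a-b-c-d-a: all degree 2; edge weights favour b
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a")),
    directed = FALSE)
  igraph::E(g)$rho <- c(0.9, 0.9, 0.61, 0.61)  # b touches the two big ones
  igraph::V(g)$module <- 1L
  igraph::V(g)$degree <- igraph::degree(g)
  h <- igraph::graph_attr(find_hubs(g), "hubs")
  expect_equal(h$hub, "b")
  expect_equal(h$tie_break, "strength")
  # all weights equal: lexicographic
  igraph::E(g)$rho <- 0.7
  h2 <- igraph::graph_attr(find_hubs(g), "hubs")
  expect_equal(h2$hub, "a")
  expect_equal(h2$tie_break, "lexicographic")
})

test_that("hubs match an exhaustive within-module degree scan on random graphs", {
  set.seed(58)
  for (i in 1:10) {
    pg <- planted_block_graph(block_size = 6, p_within = 0.7, p_between = 0.1)
    g <- detect_modules(pg$graph, seed = i)
    g <- find_hubs(g)
    hubs <- igraph::graph_attr(g, "hubs")
    for (r in seq_len(nrow(hubs))) {
      members <- igraph::V(g)$name[igraph::V(g)$module == hubs$module[r]]
      sub <- igraph::induced_subgraph(g, members)
      expect_equal(max(igraph::degree(sub)),
                   unname(igraph::degree(sub)[hubs$hub[r]]))
    }
    # exactly one hub per non-singleton module
    non_singleton <- names(which(table(igraph::V(g)$module) > 1))
    expect_setequal(as.character(hubs$module), non_singleton)
  }
})

.toy_net <- function(seed = 59) {
  set.seed(seed)
  m <- matrix(stats::rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("v", 1:6)))
  m[, 2] <- m[, 1] + stats::rnorm(20, sd = 0.3)
  m[, 4] <- -m[, 3] + stats::rnorm(20, sd = 0.3)
  net <- build_network(m, stats::setNames(c("RI", "MRG", "ARG", "ARG", "MGE", "MRG"),
                                          colnames(m)))
  find_hubs(detect_modules(net, seed = 1))
}

test_that("exports round-trip nodes, edges and attributes in every format", {
  net <- .toy_net()
  for (fmt in c("graphml", "gexf", "edgelist")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_equal(sort(igraph::V(back)$name), sort(igraph::V(net)$name))
    expect_equal(edge_keys(back), edge_keys(net))
    ord <- match(igraph::V(net)$name, igraph::V(back)$name)
    expect_equal(igraph::V(back)$category[ord], igraph::V(net)$category)
    expect_equal(igraph::V(back)$module[ord], igraph::V(net)$module)
    expect_equal(igraph::V(back)$degree[ord], igraph::V(net)$degree)
    expect_equal(igraph::V(back)$hub[ord], igraph::V(net)$hub)
    # edge weights preserved to 1e-12 (matched through canonical edge keys)
    key_rho <- function(g) {
      ends <- igraph::ends(g, igraph::E(g))
      keys <- apply(ends, 1, function(e) paste(sort(e), collapse = "|"))
      stats::setNames(igraph::E(g)$rho, keys)[sort(keys)]
    }
    expect_equal(key_rho(back), key_rho(net), tolerance = 1e-12)
    expect_equal(sort(table(igraph::V(back)$category)),
                 sort(table(igraph::V(net)$category)))
  }
  expect_error(export_network(net, tempfile(), "dot"), "format")
  expect_error(read_network(tempfile(), "dot"), "format")
})

test_that("an edgeless network still exports valid files with all nodes", {
  set.seed(60)
  m <- matrix(stats::rnorm(25 * 3), 25, 3, dimnames = list(NULL, c("a", "b", "c")))
  net <- detect_modules(build_network(m, .cats(c("a", "b", "c")),
                                      rho_threshold = 0.99), seed = 1)
  net <- find_hubs(net)
  for (fmt in c("graphml", "gexf", "edgelist")) {
    path <- tempfile()
    export_network(net, path, fmt)
    back <- read_network(path, fmt)
    expect_equal(igraph::vcount(back), 3)
    expect_equal(igraph::ecount(back), 0)
  }
})
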