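# Independent brute-force oracles used across the test files. These
# deliberately re-derive results from first principles (or from a different
# library routine) rather than reusing package internals.

# two-pass mean / sd
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  s <- if (length(x) < 2) NA_real_ else sqrt(sum((x - m)^2) / (length(x) - 1))
  c(mean = m, sd = s)
}

# textbook one-way ANOVA from sums of squares
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       mse = ssw / df2)
}

# protected stepwise multiple range procedure, evaluated pair by pair with
# memoized recursion: a pair is significant iff its own ranked range exceeds
# the Duncan critical value AND every containing range is significant
oracle_duncan_matrix <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  k <- length(means)
  ns <- table(groups)[names(means)]
  nh <- k / sum(1 / as.numeric(ns))
  oa <- oracle_anova(values, groups)
  df2 <- length(values) - k
  se <- sqrt(oa$mse / nh)
  memo <- matrix(NA, k, k)
  sig <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    span <- j - i + 1
    crit <- stats::qtukey(1 - (1 - (1 - alpha)^(span - 1)),
                          nmeans = span, df = df2) * se
    own <- abs(means[i] - means[j]) > crit
    parents_ok <- TRUE
    if (i > 1) parents_ok <- parents_ok && sig(i - 1, j)
    if (j < k) parents_ok <- parents_ok && sig(i, j + 1)
    res <- own && parents_ok
    memo[i, j] <<- res
    res
  }
  out <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    out[i, j] <- out[j, i] <- sig(i, j)
  out
}

# brute-force co-occurrence edge enumeration via stats::cor.test
oracle_edges <- function(m, rho_threshold = 0.6, p_threshold = 0.05) {
  vars <- colnames(m)
  out <- list()
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      ct <- suppressWarnings(stats::cor.test(m[, i], m[, j],
                                             method = "spearman",
                                             exact = FALSE))
      if (abs(ct$estimate) > rho_threshold && ct$p.value < p_threshold)
        out[[length(out) + 1]] <- sort(c(vars[i], vars[j]))
    }
  }
  if (length(out) == 0) character(0)
  else sort(vapply(out, paste, "", collapse = "|"))
}

edge_keys <- function(net) {
  if (igraph::ecount(net) == 0) return(character(0))
  ends <- igraph::ends(net, igraph::E(net))
  sort(apply(ends, 1, function(e) paste(sort(e), collapse = "|")))
}

# small random sample table builder
random_conc_table <- function(n_sites = 3, n_per_site = 4, metals = c("A", "B", "C")) {
  site <- rep(paste0("S", seq_len(n_sites)), each = n_per_site)
  df <- data.frame(sample_id = paste0("s", seq_along(site)), site = site,
                   stringsAsFactors = FALSE)
  for (m in metals) df[[m]] <- stats::rlnorm(length(site), 1, 0.5)
  df
}

random_reference <- function(metals) {
  metal_reference(metals, background_value = stats::runif(length(metals), 0.5, 50),
                  toxic_response = sample(c(1, 2, 5, 10, 30), length(metals),
                                          replace = TRUE))
}

# planted 3-block weighted graph for module-recovery experiments
planted_block_graph <- function(block_size = 10, p_within = 0.9,
                                p_between = 0.05) {
  n <- 3 * block_size
  membership <- rep(1:3, each = block_size)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (membership[i] == membership[j]) p_within else p_between
    if (stats::runif(1) < p) edges <- rbind(edges, c(i, j))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("v", edges[, 1]), to = paste0("v", edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = paste0("v", 1:n)))
  igraph::E(g)$rho <- stats::runif(igraph::ecount(g), 0.6, 1)
  igraph::E(g)$p <- 0.01
  igraph::E(g)$sign <- "positive"
  list(graph = g, membership = membership)
}
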