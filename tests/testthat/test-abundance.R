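test_that("standard-curve quantification inverts the curve", {
  expect_equal(standard_curve_quantify(37, -3.3219, 37), 1)
  expect_equal(amplification_efficiency(-3.3219), 1, tolerance = 1e-4)
  expect_error(standard_curve_quantify(30, 3.3, 37), "negative")
  set.seed(21)
  for (i in 1:20) {
    slope <- -stats::runif(1, 2.8, 3.8)
    intercept <- stats::runif(1, 30, 40)
    copies <- 10^stats::runif(1, 0, 8)
    ct <- standard_curve_ct(copies, slope, intercept)
    expect_equal(standard_curve_quantify(ct, slope, intercept), copies,
                 tolerance = 1e-9)
  }
})

.random_measurements <- function(n_samples = 4, genes = c("g1", "g2"),
                                 p_detect = 0.8) {
  grid <- expand.grid(sample_id = paste0("s", seq_len(n_samples)),
                      gene = genes, replicate = 1:3,
                      stringsAsFactors = FALSE)
  grid$site <- rep(c("S1", "S2"), length.out = n_samples)[
    match(grid$sample_id, paste0("s", seq_len(n_samples)))]
  grid$detected <- stats::runif(nrow(grid)) < p_detect
  grid$copies <- ifelse(grid$detected, stats::rlnorm(nrow(grid), 5, 1), 0)
  grid
}

test_that("replicate collapse averages detected replicates with a min-detect rule", {
  m <- data.frame(sample_id = "s1", site = "S1", gene = "g",
                  replicate = 1:3, copies = c(100, 110, 90), detected = TRUE)
  out <- collapse_replicates(m)
  expect_equal(out$g, 100)
  expect_true(attr(out, "detect")["s1", "g"])
  # one of three amplifying falls below the default min-detect of 2
  m$detected <- c(TRUE, FALSE, FALSE)
  out1 <- collapse_replicates(m)
  expect_equal(out1$g, 0)
  expect_false(attr(out1, "detect")["s1", "g"])
  expect_equal(collapse_replicates(m, min_detect = 1)$g, 100)
})

test_that("replicate collapse matches an independent group-by mean", {
  set.seed(22)
  meas <- .random_measurements(n_samples = 5, genes = c("g1", "g2", "g3"))
  out <- collapse_replicates(meas, min_detect = 2)
  for (s in unique(meas$sample_id)) {
    for (g in c("g1", "g2", "g3")) {
      sub <- meas[meas$sample_id == s & meas$gene == g, ]
      want <- if (sum(sub$detected) >= 2) mean(sub$copies[sub$detected]) else 0
      expect_equal(out[out$sample_id == s, g], want, tolerance = 1e-12)
    }
  }
})

test_that("detected-gene count never grows as the min-detect threshold rises", {
  set.seed(23)
  meas <- .random_measurements(n_samples = 6, genes = paste0("g", 1:4),
                               p_detect = 0.6)
  counts <- vapply(1:3, function(k)
    sum(attr(collapse_replicates(meas, min_detect = k), "detect")), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("16S normalization divides by the sample's 16S copies", {
  tab <- data.frame(sample_id = c("a", "b"), site = "S1",
                    `16S` = c(1e5, 2e5), g = c(500, 500), check.names = FALSE)
  rel <- normalize_to_16S(tab)
  expect_equal(rel$g, c(5e-3, 2.5e-3))
  expect_false("16S" %in% names(rel))
  # invariant under uniform per-sample rescaling of absolute values
  tab10 <- tab
  tab10[c("16S", "g")] <- tab10[c("16S", "g")] * 10
  expect_equal(normalize_to_16S(tab10)$g, rel$g)
  bad <- tab
  bad$`16S`[2] <- 0
  expect_error(normalize_to_16S(bad), "b")
})

test_that("16S normalization matches element-wise division on random tables", {
  set.seed(24)
  tab <- data.frame(sample_id = paste0("s", 1:8), site = "S1",
                    `16S` = stats::rlnorm(8, 12, 1), check.names = FALSE)
  for (g in paste0("g", 1:5)) tab[[g]] <- stats::rlnorm(8, 6, 2)
  rel <- normalize_to_16S(tab)
  for (g in paste0("g", 1:5))
    expect_equal(rel[[g]], tab[[g]] / tab$`16S`, tolerance = 1e-12)
})

test_that("transforms are monotone and the log pseudocount rule applies", {
  expect_equal(transform_abundance(4, "sqrt"), 2)
  x <- c(1, 2.5, 9)
  expect_equal(exp(transform_abundance(x, "log")), x)  # no zeros: no pseudocount
  withz <- c(0, 4, 10)
  expect_message(tz <- transform_abundance(withz, "log"), "pseudocount")
  expect_equal(tz, log(withz + 2))  # half the smallest nonzero value
  expect_error(transform_abundance(c(0, 0), "log"), "all-zero")
  set.seed(25)
  r <- stats::rlnorm(50, 2, 1.5)
  for (m in c("sqrt", "log"))
    expect_equal(order(transform_abundance(r, m)), order(r))
})

test_that("class aggregation sums per class and compositions close at 100%", {
  panel <- gene_panel(c("16S", "m1", "m2", "a1"),
                      c("16S", "MRG", "MRG", "ARG"),
                      c("ribosomal", "copper", "arsenic", "tet"))
  tab <- data.frame(sample_id = c("x", "y"), site = c("S1", "S1"),
                    `16S` = c(1e5, 1e5), m1 = c(10, 30), m2 = c(90, 70),
                    a1 = c(5, 5), check.names = FALSE)
  agg <- aggregate_by_class(tab, panel)
  expect_equal(agg$totals$MRG, c(100, 100))
  expect_equal(agg$totals$ARG, c(5, 5))
  comp <- agg$composition
  expect_equal(sum(comp$percent[comp$class == "MRG"]), 100)
  expect_equal(comp$percent[comp$gene == "a1"], 100)  # single-gene class
  expect_equal(comp$percent[comp$gene == "m1"], 100 * 40 / 200)
  tab$extra <- 1
  expect_error(aggregate_by_class(tab, panel), "extra")
})

test_that("class totals add up to the sum over all non-16S genes", {
  set.seed(26)
  sim <- default_study_fixture(seed = 7)
  agg <- aggregate_by_class(sim$abundance, sim$panel)
  genes <- setdiff(names(sim$abundance), c("sample_id", "site", "16S"))
  expect_equal(agg$totals$MRG + agg$totals$ARG + agg$totals$MGE,
               rowSums(as.matrix(sim$abundance[genes])), tolerance = 1e-9)
})

test_that("aggregation matches a brute-force group-by on random tables", {
  set.seed(27)
  panel <- gene_panel(c("16S", paste0("g", 1:6)),
                      c("16S", rep(c("MRG", "ARG"), each = 3)),
                      rep("x", 7))
  tab <- data.frame(sample_id = paste0("s", 1:9),
                    site = rep(c("S1", "S2", "S3"), 3),
                    `16S` = stats::rlnorm(9, 10), check.names = FALSE)
  for (g in paste0("g", 1:6)) tab[[g]] <- stats::rlnorm(9, 4, 1)
  agg <- aggregate_by_class(tab, panel)
  for (s in c("S1", "S2", "S3")) {
    sub <- tab[tab$site == s, ]
    mrg_sum <- sum(sub[paste0("g", 1:3)])
    for (g in paste0("g", 1:3)) {
      got <- agg$composition$percent[agg$composition$site == s &
                                       agg$composition$gene == g]
      expect_equal(got, 100 * sum(sub[[g]]) / mrg_sum, tolerance = 1e-12)
    }
  }
})

test_that("a gene is detected at a site when any sample of the site detects it", {
  tab <- data.frame(sample_id = paste0("s", 1:4),
                    site = rep(c("S1", "S2"), each = 2),
                    g1 = c(0, 5, 0, 0), g2 = c(1, 1, 1, 1))
  det <- detected_by_site(tab)
  expect_true(det["S1", "g1"])
  expect_false(det["S2", "g1"])
  expect_true(all(det[, "g2"]))
})

test_that("the built-in panel has the study's class structure", {
  panel <- default_gene_panel()
  expect_equal(as.integer(table(panel$class)[c("MRG", "ARG", "MGE", "16S")]),
               c(10L, 17L, 2L, 1L))
  expect_error(gene_panel(c("a", "a"), c("MRG", "ARG"), c("x", "y")),
               "duplicated")
  expect_error(gene_panel("a", "MRG", "x"), "16S")
})
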