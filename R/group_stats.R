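#' One-way analysis of variance
#'
#' Classical between/within decomposition for a single grouping factor,
#' fitted through `stats::lm`/`stats::anova`. Degenerate layouts are given
#' explicit conventions: zero variance both between and within groups yields
#' F = 0, p = 1; zero within-group variance with distinct group means yields
#' F = Inf, p = 0.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @return object of class `anova_result`: list with `f`, `df1`, `df2`, `p`,
#'   `group_means`, `group_n`, `mse` (residual mean square).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop_validation("values and groups differ in length")
  if (nlevels(groups) < 2) stop_validation("need at least 2 groups")
  if (any(tabulate(groups) < 1)) stop_validation("empty group")
  df2 <- length(values) - nlevels(groups)
  if (df2 < 1) stop_validation("no residual degrees of freedom")
  fit <- stats::lm(values ~ groups)
  # perfect fits are handled by the explicit conventions below
  an <- suppressWarnings(stats::anova(fit))
  ssb <- an$`Sum Sq`[1]; ssw <- an$`Sum Sq`[2]
  msb <- ssb / an$Df[1]; mse <- ssw / an$Df[2]
  tot_var <- stats::var(values)
  if (isTRUE(all.equal(tot_var, 0)) || (ssb < 1e-12 && ssw < 1e-12)) {
    f <- 0; p <- 1
  } else if (mse < 1e-12 * max(msb, 1)) {
    f <- Inf; p <- 0
  } else {
    f <- msb / mse
    p <- stats::pf(f, an$Df[1], an$Df[2], lower.tail = FALSE)
  }
  structure(list(f = f, df1 = an$Df[1], df2 = an$Df[2], p = p,
                 group_means = tapply(values, groups, mean),
                 group_n = as.vector(table(groups)),
                 mse = mse),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$f, x$p))
  invisible(x)
}

# critical range for a span of p ranked means at Duncan's protection level
.duncan_crit <- function(p_span, alpha, df_error, se) {
  level <- 1 - (1 - alpha)^(p_span - 1)
  stats::qtukey(1 - level, nmeans = p_span, df = df_error) * se
}

#' Duncan's multiple range test with compact letter display
#'
#' Protected stepwise range procedure on group means ranked in descending
#' order: the range spanning p consecutive ranked means is declared
#' significant when it exceeds q(1-(1-alpha)^(p-1), p, df_e) * sqrt(MSE/n_h),
#' and subranges of a non-significant range are not pursued (declared
#' non-significant). Unequal group sizes are handled through the harmonic
#' mean n_h. Letters are assigned by insert-and-absorb over the maximal
#' non-significant runs, "a" on the largest mean.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha protection level per comparison step (default 0.05).
#' @param anova optional precomputed [one_way_anova()] result (for MSE/df).
#' @return object of class `duncan_result`: list with `means` (descending),
#'   `n`, `harmonic_n`, `mse`, `df_error`, `significant` (logical group x
#'   group matrix), `letters` (named character), `alpha`.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05, anova = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must lie strictly between 0 and 1")
  groups <- factor(groups)
  if (is.null(anova)) anova <- one_way_anova(values, groups)
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  k <- length(means)
  ns <- table(groups)[names(means)]
  n_h <- k / sum(1 / as.numeric(ns))
  se <- sqrt(anova$mse / n_h)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  tested_ns <- matrix(FALSE, k, k)  # ranges already fixed non-significant
  if (se == 0) {
    # zero residual variance: any difference in means is significant
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > 1e-12
  } else {
    for (span in k:2) {
      crit <- .duncan_crit(span, alpha, anova$df2, se)
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        if (tested_ns[i, j]) next
        if (abs(means[i] - means[j]) > crit) {
          sig[i, j] <- sig[j, i] <- TRUE
        } else {
          # protect: every subrange is non-significant
          for (a in i:(j - 1)) for (b in (a + 1):j) {
            tested_ns[a, b] <- tested_ns[b, a] <- TRUE
          }
        }
      }
    }
  }
  letters <- .letter_display(sig)
  structure(list(means = means, n = as.numeric(ns), harmonic_n = n_h,
                 mse = anova$mse, df_error = anova$df2,
                 significant = sig, letters = letters, alpha = alpha),
            class = "duncan_result")
}

# compact letter display from a significance matrix whose non-significant
# relation is a union of intervals in mean-rank order (guaranteed by the
# protected stepwise procedure); "a" goes to the largest mean
.letter_display <- function(sig) {
  k <- nrow(sig)
  ids <- rownames(sig)
  # maximal runs [i, j] of mutually non-significant groups
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !sig[i, j + 1]) j <- j + 1
    runs[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (m in seq_len(k)) {
      if (m != i && runs[[m]][1] <= runs[[i]][1] && runs[[m]][2] >= runs[[i]][2]) {
        keep[i] <- FALSE; break
      }
    }
  }
  runs <- runs[keep]
  runs <- runs[order(vapply(runs, `[`, 0, 1))]
  lab <- character(k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    lab[idx] <- paste0(lab[idx], letters[r])
  }
  stats::setNames(lab, ids)
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, df_e = %d)\n",
              x$alpha, x$df_error))
  print(data.frame(mean = x$means, n = x$n, letters = x$letters))
  invisible(x)
}

# Spearman rho via the product-moment formula on average ranks
.spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(x) - 1) * sx * sy)
}

# all permutations of 1..n (n small), rows of a matrix
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

.spearman_p_exact <- function(x, y, rho_obs) {
  n <- length(x)
  P <- .perms(n)
  ry <- rank(y, ties.method = "average")
  rho_null <- apply(P, 1, function(idx) .spearman_rho(x, ry[idx]))
  mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
}

.spearman_p_t <- function(rho, n) {
  if (abs(rho) >= 1 - 1e-12) return(2 / factorial(n))  # permutation bound
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Pairwise Spearman correlation matrix with two-tailed significance
#'
#' Rank correlations over all column pairs of a samples x variables matrix.
#' Ties receive average ranks; rho is the product-moment correlation of the
#' ranks. Two-tailed p-values come from the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) by default, with perfect correlations
#' reported at the permutation bound 2/n!; `p_method = "exact"` enumerates
#' all n! orderings (n <= 9) for an exact permutation p. Constant variables
#' have undefined rank correlation and are reported as `NA`, not 0.
#'
#' @param table numeric matrix/data.frame of samples x variables (a sample
#'   table with `sample_id`/`site` columns is accepted; they are dropped).
#' @param p_method `"t"` or `"exact"`.
#' @return object of class `correlation_result`: list with matrices `rho`,
#'   `p`, scalar `n`, and `variables`.
#' @export
spearman_matrix <- function(table, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  if (is.data.frame(table) && all(.id_cols %in% names(table)))
    table <- table[.value_cols(table)]
  m <- as.matrix(table)
  if (!is.numeric(m)) stop_validation("table must be numeric")
  n <- nrow(m)
  if (n < 4) stop_validation("need at least 4 observations")
  if (p_method == "exact" && n > 9)
    stop_validation("exact permutation p only supported for n <= 9")
  v <- ncol(m)
  vars <- colnames(m) %||% paste0("V", seq_len(v))
  rho <- matrix(NA_real_, v, v, dimnames = list(vars, vars))
  p <- matrix(NA_real_, v, v, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(v - 1)) {
    for (j in (i + 1):v) {
      r <- .spearman_rho(m[, i], m[, j])
      rho[i, j] <- rho[j, i] <- r
      if (is.na(r)) next
      pv <- if (p_method == "exact") .spearman_p_exact(m[, i], m[, j], r)
            else .spearman_p_t(r, n)
      p[i, j] <- p[j, i] <- pv
    }
  }
  structure(list(rho = rho, p = p, n = n, variables = vars),
            class = "correlation_result")
}

#' Significance stars for display
#'
#' @param p numeric p-values.
#' @return character vector: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Long-format correlation table
#'
#' @param cor a [spearman_matrix()] result.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching the unadjusted pairwise practice;
#'   `"BH"` available).
#' @return data.frame `var1`, `var2`, `rho`, `p`, `stars` for all pairs.
#' @export
correlation_long <- function(cor, adjust = "none") {
  stopifnot(inherits(cor, "correlation_result"))
  idx <- which(upper.tri(cor$rho), arr.ind = TRUE)
  out <- data.frame(var1 = cor$variables[idx[, 1]],
                    var2 = cor$variables[idx[, 2]],
                    rho = cor$rho[idx], p = cor$p[idx],
                    stringsAsFactors = FALSE)
  out$p <- stats::p.adjust(out$p, method = adjust)
  out$stars <- significance_stars(out$p)
  out
}

#' Per-variable site comparison table (mean, sd, Duncan letters)
#'
#' Summarises each value column per site and attaches compact letters from
#' Duncan's test, the layout of publication summary tables.
#'
#' @param df sample table (`sample_id`, `site`, value columns).
#' @param alpha significance level for the letter display.
#' @return data.frame `variable`, `site`, `n`, `mean`, `sd`, `letters`.
#' @export
site_comparison_table <- function(df, alpha = 0.05) {
  .check_sample_table(df, "value table")
  cols <- .value_cols(df)
  out <- do.call(rbind, lapply(cols, function(v) {
    s <- site_summary(df, v)
    lt <- tryCatch(duncan_mrt(df[[v]], df$site, alpha = alpha)$letters,
                   error = function(e) stats::setNames(rep(NA_character_,
                     length(unique(df$site))), unique(df$site)))
    s$letters <- lt[s$site]
    s
  }))
  rownames(out) <- NULL
  out
}
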