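#' Gene panel definition
#'
#' A gene panel classifies every assayed gene as a metal resistance gene
#' (MRG), antibiotic resistance gene (ARG), mobile genetic element marker
#' (MGE) or the 16S rRNA gene used for normalization, together with its
#' resistance subclass (the target metal for MRGs, the antibiotic class for
#' ARGs).
#'
#' @param gene character vector of unique gene identifiers.
#' @param class one of `"MRG"`, `"ARG"`, `"MGE"`, `"16S"` per gene.
#' @param subclass resistance target per gene.
#' @return validated panel `data.frame`.
#' @export
gene_panel <- function(gene, class, subclass) {
  panel <- data.frame(gene = as.character(gene), class = as.character(class),
                      subclass = as.character(subclass),
                      stringsAsFactors = FALSE)
  validate_gene_panel(panel)
}

#' @rdname gene_panel
#' @param panel data.frame with columns `gene`, `class`, `subclass`.
#' @export
validate_gene_panel <- function(panel) {
  need <- c("gene", "class", "subclass")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0)
    stop_validation("gene panel lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$gene))
    stop_validation("duplicated gene identifiers in panel")
  bad <- setdiff(unique(panel$class), c("MRG", "ARG", "MGE", "16S"))
  if (length(bad) > 0)
    stop_validation("unknown gene class(es): ", paste(bad, collapse = ", "))
  if (sum(panel$class == "16S") != 1)
    stop_validation("panel must carry exactly one 16S gene")
  panel
}

#' Built-in gene panel of the copper-tailings resistome study design
#'
#' 10 MRGs, 17 ARGs, 2 MGE markers (intI1, tnpA) plus 16S.
#'
#' @return gene panel data.frame.
#' @export
default_gene_panel <- function() {
  validate_gene_panel(utils::read.csv(
    system.file("extdata", "gene_panel.csv", package = "resistrisk",
                mustWork = TRUE),
    stringsAsFactors = FALSE, check.names = FALSE))
}

#' Absolute quantification from a qPCR standard curve
#'
#' Converts threshold cycles to copy numbers through the fitted standard
#' curve Ct = slope * log10(copies) + intercept, so
#' copies = 10^((Ct - intercept) / slope). The amplification efficiency
#' implied by the slope is 10^(-1/slope) - 1 (1.0 = 100% doubling).
#'
#' @param ct numeric Ct values.
#' @param slope standard-curve slope (must be negative).
#' @param intercept standard-curve intercept (Ct at 1 copy).
#' @return numeric copy numbers.
#' @export
standard_curve_quantify <- function(ct, slope, intercept) {
  if (!is.finite(slope) || slope >= 0)
    stop_validation("standard-curve slope must be negative")
  10^((ct - intercept) / slope)
}

#' @rdname standard_curve_quantify
#' @param copies copy numbers to convert back to Ct (inverse transform).
#' @export
standard_curve_ct <- function(copies, slope, intercept) {
  if (!is.finite(slope) || slope >= 0)
    stop_validation("standard-curve slope must be negative")
  slope * log10(copies) + intercept
}

#' @rdname standard_curve_quantify
#' @export
amplification_efficiency <- function(slope) {
  if (!is.finite(slope) || slope >= 0)
    stop_validation("standard-curve slope must be negative")
  10^(-1 / slope) - 1
}

#' Collapse qPCR replicates into one abundance per sample and gene
#'
#' Technical replicates (typically triplicates) are averaged over the
#' replicates that amplified. A sample-gene combination with fewer than
#' `min_detect` amplified replicates is called a non-detect and stored as an
#' explicit zero, with the detection status kept in a parallel logical matrix
#' (attribute `"detect"`), so downstream rank statistics stay computable.
#'
#' @param measurements long data.frame with columns `sample_id`, `site`,
#'   `gene`, `replicate`, `copies`, `detected` (logical).
#' @param min_detect minimum number of amplified replicates for a detect
#'   (default 2).
#' @return wide abundance data.frame (`sample_id`, `site`, gene columns) with
#'   a logical `"detect"` attribute of matching shape.
#' @export
collapse_replicates <- function(measurements, min_detect = 2) {
  need <- c("sample_id", "site", "gene", "replicate", "copies", "detected")
  miss <- setdiff(need, names(measurements))
  if (length(miss) > 0)
    stop_validation("measurements lack column(s): ", paste(miss, collapse = ", "))
  reps <- stats::aggregate(replicate ~ sample_id + gene, measurements, length)
  if (any(reps$replicate > 3))
    stop_validation("more than 3 replicates for a sample-gene combination")
  key <- unique(measurements[c("sample_id", "site")])
  if (anyDuplicated(key$sample_id))
    stop_validation("a sample_id maps to more than one site")
  genes <- unique(measurements$gene)
  samples <- key$sample_id
  vals <- matrix(0, nrow = length(samples), ncol = length(genes),
                 dimnames = list(samples, genes))
  det <- matrix(FALSE, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  for (i in seq_along(samples)) {
    sub <- measurements[measurements$sample_id == samples[i], , drop = FALSE]
    for (g in unique(sub$gene)) {
      gg <- sub[sub$gene == g, , drop = FALSE]
      hit <- gg$detected
      if (sum(hit) >= min_detect) {
        vals[i, g] <- mean(gg$copies[hit])
        det[i, g] <- TRUE
      }
    }
  }
  out <- data.frame(sample_id = samples, site = key$site,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[genes] <- as.data.frame(vals, check.names = FALSE)
  attr(out, "detect") <- det
  out
}

#' Normalize gene abundances to the 16S rRNA gene
#'
#' Each gene's absolute copies are divided by the 16S copies of the same
#' sample, yielding the approximate fraction of bacteria carrying the gene.
#' The 16S column is removed from the output; relative abundances are
#' invariant under any per-sample rescaling of the absolute values.
#'
#' @param table wide abundance data.frame containing a 16S column.
#' @param gene_16s name of the 16S column (default `"16S"`).
#' @return relative abundance data.frame without the 16S column; the detect
#'   mask attribute, if present, is carried along.
#' @export
normalize_to_16S <- function(table, gene_16s = "16S") {
  .check_sample_table(table, "abundance table")
  if (!gene_16s %in% names(table))
    stop_validation("no 16S column ('", gene_16s, "') in abundance table")
  s16 <- table[[gene_16s]]
  bad <- which(!is.finite(s16) | s16 <= 0)
  if (length(bad) > 0)
    stop_validation("non-positive 16S copies in sample(s): ",
                    paste(table$sample_id[bad], collapse = ", "))
  genes <- setdiff(.value_cols(table), gene_16s)
  out <- table[c(.id_cols, genes)]
  out[genes] <- as.data.frame(sweep(as.matrix(table[genes]), 1, s16, `/`),
                              check.names = FALSE)
  det <- attr(table, "detect")
  if (!is.null(det)) attr(out, "detect") <- det[, genes, drop = FALSE]
  out
}

#' Square-root or log transform of abundance values
#'
#' Variance-stabilising transforms applied before parametric site testing.
#' For the log transform a pseudocount is required when zeros (non-detects)
#' are present; the default is half the smallest nonzero value in the data,
#' applied only if zeros exist, and reported via a message.
#'
#' @param x numeric vector, matrix, or sample table (value columns only are
#'   transformed).
#' @param method `"sqrt"` or `"log"` (natural log).
#' @param pseudocount pseudocount for the log transform; `NULL` = automatic
#'   rule above.
#' @return transformed object of the same shape.
#' @export
transform_abundance <- function(x, method = c("sqrt", "log"),
                                pseudocount = NULL) {
  method <- match.arg(method)
  if (is.data.frame(x) && all(.id_cols %in% names(x))) {
    cols <- .value_cols(x)
    x[cols] <- transform_abundance(as.matrix(x[cols]), method, pseudocount)
    return(x)
  }
  v <- as.numeric(x)
  if (any(!is.finite(v)) || any(v < 0))
    stop_validation("values must be finite and non-negative")
  if (method == "sqrt") {
    out <- sqrt(x)
  } else {
    if (is.null(pseudocount)) {
      if (any(v == 0)) {
        nz <- v[v > 0]
        if (length(nz) == 0)
          stop_validation("log transform of all-zero data is undefined")
        pseudocount <- min(nz) / 2
        message("log transform: zeros present, using pseudocount ",
                format(pseudocount))
      } else pseudocount <- 0
    }
    if (any(v + pseudocount <= 0))
      stop_validation("log transform requires positive values after pseudocount")
    out <- log(x + pseudocount)
  }
  out
}

#' Class totals and within-class composition
#'
#' Sums abundances per gene class (MRG / ARG / MGE) per sample, and computes
#' each gene's percentage of its class total per site (site-summed
#' abundances), the quantities behind stacked composition bar charts.
#'
#' @param table wide abundance (absolute or relative) data.frame; a 16S
#'   column, if present, is ignored for totals.
#' @param panel gene panel classifying every gene column.
#' @return list with `totals` (sample table with one column per class) and
#'   `composition` (data.frame `site`, `class`, `gene`, `percent`).
#' @export
aggregate_by_class <- function(table, panel) {
  .check_sample_table(table, "abundance table")
  panel <- validate_gene_panel(panel)
  genes <- .value_cols(table)
  miss <- setdiff(genes, panel$gene)
  if (length(miss) > 0)
    stop_validation("gene(s) not classified in panel: ",
                    paste(miss, collapse = ", "))
  cls <- panel$class[match(genes, panel$gene)]
  keep <- cls != "16S"
  classes <- unique(cls[keep])
  totals <- table[.id_cols]
  for (cl in classes)
    totals[[cl]] <- rowSums(as.matrix(table[, genes[keep & cls == cl], drop = FALSE]))
  sites <- unique(table$site)
  comp <- do.call(rbind, lapply(sites, function(s) {
    sub <- table[table$site == s, , drop = FALSE]
    do.call(rbind, lapply(classes, function(cl) {
      gs <- genes[keep & cls == cl]
      sums <- colSums(as.matrix(sub[, gs, drop = FALSE]))
      tot <- sum(sums)
      data.frame(site = s, class = cl, gene = gs,
                 percent = if (tot > 0) 100 * sums / tot else NA_real_,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
  rownames(comp) <- NULL
  list(totals = totals, composition = comp)
}

#' Gene detection status per site
#'
#' A gene counts as detected at a site when it was detected in at least one
#' sample of that site.
#'
#' @param table abundance table with a `"detect"` attribute (or zeros taken
#'   as non-detects if absent).
#' @return logical matrix sites x genes.
#' @export
detected_by_site <- function(table) {
  .check_sample_table(table, "abundance table")
  genes <- .value_cols(table)
  det <- attr(table, "detect")
  if (is.null(det)) det <- as.matrix(table[genes]) > 0
  sites <- unique(table$site)
  out <- t(vapply(sites, function(s)
    apply(det[table$site == s, genes, drop = FALSE], 2, any),
    logical(length(genes))))
  dimnames(out) <- list(sites, genes)
  out
}
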