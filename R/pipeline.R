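#' Per-sample risk components for network analysis
#'
#' The co-occurrence network includes eight risk variables: the seven
#' per-metal monomial risk factors (named `RI-<metal>`) plus the integrated
#' index `RI`, all as per-sample series.
#'
#' @inheritParams compute_risk
#' @return sample table with columns `RI-<metal>` ... and `RI`.
#' @export
risk_components <- function(conc, ref) {
  res <- compute_risk(conc, ref)
  metals <- .value_cols(res$er)
  out <- res$er
  names(out)[match(metals, names(out))] <- paste0("RI-", metals)
  out$RI <- res$ri$RI
  out
}

#' Assemble the variable table and categories for network inference
#'
#' Joins per-sample relative gene abundances with the per-sample risk
#' components on `sample_id`, and tags every variable with its category
#' (RI for risk components, MRG/ARG/MGE from the gene panel).
#'
#' @param rel relative abundance table (no 16S column).
#' @param conc concentration table for the same samples.
#' @param ref metal reference table.
#' @param panel gene panel.
#' @return list with `table` (sample table of all variables) and
#'   `categories` (named character vector).
#' @export
assemble_network_table <- function(rel, conc, ref, panel) {
  .check_sample_table(rel, "relative abundance table")
  risk <- risk_components(conc, ref)
  if (!setequal(rel$sample_id, risk$sample_id))
    stop_validation("abundance and concentration tables cover different samples")
  risk <- risk[match(rel$sample_id, risk$sample_id), ]
  genes <- .value_cols(rel)
  rvars <- .value_cols(risk)
  tab <- cbind(rel[c(.id_cols, genes)], risk[rvars])
  cats <- c(stats::setNames(rep("RI", length(rvars)), rvars),
            stats::setNames(panel$class[match(genes, panel$gene)], genes))
  if (any(is.na(cats)))
    stop_validation("gene(s) missing from panel: ",
                    paste(genes[is.na(cats[genes])], collapse = ", "))
  list(table = tab, categories = cats)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param concentrations path to the concentration CSV, or a data.frame.
#' @param abundance path to the wide abundance CSV (absolute copies incl. a
#'   16S column), or a data.frame.
#' @param panel path to the gene panel CSV, or a data.frame; default built-in.
#' @param reference_profile `"default"` or `"table2-compat"` (or a reference
#'   data.frame).
#' @param alpha significance level for site tests (default 0.05).
#' @param rho_threshold network correlation threshold (default 0.6).
#' @param p_threshold network significance threshold (default 0.05).
#' @param transform `"sqrt"` or `"log"` for site testing.
#' @param seed integer seed (module detection; simulation when used).
#' @param outdir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(concentrations = NULL, abundance = NULL, panel = NULL,
                       reference_profile = "default", alpha = 0.05,
                       rho_threshold = 0.6, p_threshold = 0.05,
                       transform = "sqrt", seed = 1L, outdir = "resistrisk-out") {
  if (!alpha > 0 || !alpha < 1) stop_validation("alpha must be in (0, 1)")
  if (rho_threshold < 0 || rho_threshold >= 1)
    stop_validation("rho_threshold must be in [0, 1)")
  if (p_threshold <= 0 || p_threshold > 1)
    stop_validation("p_threshold must be in (0, 1]")
  for (f in list(concentrations, abundance, panel))
    if (is.character(f) && length(f) == 1 && !file.exists(f))
      stop_validation("input file does not exist: ", f)
  structure(list(concentrations = concentrations, abundance = abundance,
                 panel = panel, reference_profile = reference_profile,
                 alpha = alpha, rho_threshold = rho_threshold,
                 p_threshold = p_threshold, transform = transform,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

.load_table <- function(x, validator = identity) {
  if (is.character(x))
    x <- utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
  validator(x)
}

.resolve_reference <- function(ref) {
  if (is.data.frame(ref)) validate_metal_reference(ref)
  else hakanson_reference(ref)
}

.write_output <- function(df, outdir, name, manifest) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(manifest, stats::setNames(list(nrow(df)), name))
}

#' Run the risk stage
#'
#' Computes per-sample Cf/Er/RI and the per-site summary table from a
#' concentration table and reference profile, writing tidy CSVs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the computed objects and the manifest of
#'   written files.
#' @export
run_risk <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$concentrations))
    stop_validation("no concentration input configured")
  conc <- .load_table(config$concentrations, validate_concentrations)
  if (nrow(conc) == 0) stop_validation("empty concentration table")
  ref <- .resolve_reference(config$reference_profile)
  message("risk stage: reference profile ",
          if (is.data.frame(config$reference_profile)) "(custom)"
          else config$reference_profile)
  res <- compute_risk(conc, ref)
  tab <- risk_site_table(conc, ref)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  per_sample <- cbind(res$er, RI = res$ri$RI)
  manifest <- .write_output(per_sample, config$outdir, "risk_per_sample.csv",
                            manifest)
  manifest <- .write_output(tab$er_summary, config$outdir,
                            "risk_site_summary.csv", manifest)
  site_table <- cbind(row = rownames(tab$formatted), tab$formatted)
  manifest <- .write_output(site_table, config$outdir, "risk_site_table.csv",
                            manifest)
  invisible(list(risk = res, site_table = tab, manifest = manifest))
}

#' Run the abundance stage
#'
#' @param config a [run_config()].
#' @return invisibly, list with absolute and relative tables, class
#'   aggregates and the manifest.
#' @export
run_abundance <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$abundance)) stop_validation("no abundance input configured")
  abund <- .load_table(config$abundance, function(x)
    .check_sample_table(x, "abundance table"))
  panel <- if (is.null(config$panel)) default_gene_panel()
           else .load_table(config$panel, validate_gene_panel)
  rel <- normalize_to_16S(abund)
  agg <- aggregate_by_class(rel, panel)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  manifest <- .write_output(abund, config$outdir, "abundance_absolute.csv",
                            manifest)
  manifest <- .write_output(rel, config$outdir, "abundance_relative.csv",
                            manifest)
  manifest <- .write_output(agg$totals, config$outdir, "class_totals.csv",
                            manifest)
  manifest <- .write_output(agg$composition, config$outdir,
                            "class_composition.csv", manifest)
  invisible(list(absolute = abund, relative = rel, panel = panel,
                 aggregates = agg, manifest = manifest))
}

#' Run the group-statistics stage
#'
#' Site-comparison tables (mean, sd, Duncan letters) for transformed
#' relative abundances and for the risk components, plus the Spearman
#' correlation long table.
#'
#' @param config a [run_config()].
#' @param rel relative abundance table (from [run_abundance()]).
#' @param risk risk components table (from [risk_components()]).
#' @return invisibly, list with the tables and the manifest.
#' @export
run_stats <- function(config, rel, risk) {
  stopifnot(inherits(config, "run_config"))
  trans <- transform_abundance(rel, method = config$transform)
  comparison <- rbind(site_comparison_table(trans, alpha = config$alpha),
                      site_comparison_table(risk, alpha = config$alpha))
  combined <- cbind(rel[.id_cols], rel[.value_cols(rel)],
                    risk[match(rel$sample_id, risk$sample_id),
                         .value_cols(risk)])
  cor <- spearman_matrix(combined)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  manifest <- .write_output(comparison, config$outdir, "site_comparison.csv",
                            manifest)
  manifest <- .write_output(correlation_long(cor), config$outdir,
                            "correlations.csv", manifest)
  invisible(list(comparison = comparison, correlation = cor,
                 manifest = manifest))
}

#' Run the network stage
#'
#' @param config a [run_config()].
#' @param table variable table from [assemble_network_table()].
#' @param categories category tags from [assemble_network_table()].
#' @return invisibly, list with the annotated graph and the manifest.
#' @export
run_network <- function(config, table, categories) {
  stopifnot(inherits(config, "run_config"))
  net <- build_network(table, categories,
                       rho_threshold = config$rho_threshold,
                       p_threshold = config$p_threshold)
  net <- detect_modules(net, seed = config$seed)
  net <- find_hubs(net)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  export_network(net, file.path(config$outdir, "network.graphml"), "graphml")
  export_network(net, file.path(config$outdir, "network.gexf"), "gexf")
  export_network(net, file.path(config$outdir, "network_edges.tsv"), "edgelist")
  manifest <- list("network.graphml" = igraph::vcount(net),
                   "network.gexf" = igraph::vcount(net),
                   "network_edges.tsv" = igraph::ecount(net),
                   "network_edges.tsv.nodes.tsv" = igraph::vcount(net))
  invisible(list(network = net, manifest = manifest))
}

# canonical config hash: serialize to sorted key=value text, md5 the file
.config_hash <- function(config) {
  flat <- unlist(config[order(names(config))])
  txt <- paste(names(flat), vapply(flat, format, ""), sep = "=",
               collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' abundance -> risk -> statistics -> network, writing every declared output
#' plus a JSON manifest (package version, seed, config hash, per-file row or
#' element counts).
#'
#' @param config a [run_config()].
#' @return invisibly, list with all stage results and the manifest path.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "abundance"
  res <- tryCatch({
    ab <- run_abundance(config)
    stage <- "risk"
    rk <- run_risk(config)
    conc <- .load_table(config$concentrations, validate_concentrations)
    ref <- .resolve_reference(config$reference_profile)
    risk <- risk_components(conc, ref)
    stage <- "stats"
    st <- run_stats(config, ab$relative, risk)
    stage <- "network"
    asm <- assemble_network_table(ab$relative, conc, ref, ab$panel)
    nw <- run_network(config, asm$table, asm$categories)
    list(abundance = ab, risk = rk, stats = st, network = nw)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(
    package = "resistrisk",
    version = as.character(utils::packageVersion("resistrisk")),
    seed = config$seed,
    config_hash = .config_hash(config),
    outputs = c(res$abundance$manifest, res$risk$manifest,
                res$stats$manifest, res$network$manifest))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest_path <- manifest_path
  res$manifest <- manifest
  invisible(res)
}

#' Write a simulated study to CSV inputs
#'
#' Convenience driver: simulate the default fixture (or a custom config) and
#' write the concentration and abundance CSVs in the schemas the pipeline
#' consumes.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param config optional [sim_config()]; default [default_study_fixture()].
#' @return invisibly, the simulation result with file paths attached.
#' @export
run_simulate <- function(outdir, seed = 1L, config = NULL) {
  sim <- if (is.null(config)) default_study_fixture(seed = seed)
         else simulate_study(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(outdir, "concentrations.csv")
  apath <- file.path(outdir, "abundance.csv")
  utils::write.csv(sim$concentrations, cpath, row.names = FALSE)
  utils::write.csv(sim$abundance, apath, row.names = FALSE)
  sim$paths <- c(concentrations = cpath, abundance = apath)
  invisible(sim)
}
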