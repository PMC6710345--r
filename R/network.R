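#' Build a Spearman co-occurrence network
#'
#' Nodes are variables (per-sample relative gene abundances plus the
#' per-metal risk factors and the integrated risk index); an edge joins two
#' variables whose Spearman correlation is both strong (|rho| strictly above
#' `rho_threshold`) and significant (p strictly below `p_threshold`). The
#' edge keeps the correlation as weight, its sign (positive / negative) and
#' its p-value. Constant variables have no defined rank correlation and are
#' excluded with a warning; their names are recorded in the graph attribute
#' `excluded`.
#'
#' @param table samples x variables numeric table (sample-table columns
#'   `sample_id`/`site` are dropped if present).
#' @param categories named character vector mapping every variable to its
#'   category (e.g. `"RI"`, `"MRG"`, `"ARG"`, `"MGE"`).
#' @param rho_threshold minimum |rho|, exclusive (default 0.6).
#' @param p_threshold maximum p, exclusive (default 0.05).
#' @param p_method p-value method passed to [spearman_matrix()].
#' @return an `igraph` object (class also `cooc_network`) with vertex
#'   attributes `name`, `category`, `degree` and edge attributes `rho`,
#'   `p`, `sign`.
#' @export
build_network <- function(table, categories, rho_threshold = 0.6,
                          p_threshold = 0.05, p_method = "t") {
  if (is.data.frame(table) && all(.id_cols %in% names(table)))
    table <- table[.value_cols(table)]
  m <- as.matrix(table)
  vars <- colnames(m)
  if (is.null(vars)) stop_validation("variables must be named")
  untagged <- setdiff(vars, names(categories))
  if (length(untagged) > 0)
    stop_validation("variable(s) without a category: ",
                    paste(untagged, collapse = ", "))
  if (rho_threshold < 0 || rho_threshold >= 1)
    stop_validation("rho_threshold must lie in [0, 1)")
  if (p_threshold <= 0 || p_threshold > 1)
    stop_validation("p_threshold must lie in (0, 1]")
  constant <- vars[apply(m, 2, function(x) stats::sd(rank(x)) == 0)]
  if (length(constant) > 0) {
    warning("excluding constant variable(s): ", paste(constant, collapse = ", "))
    m <- m[, setdiff(vars, constant), drop = FALSE]
    vars <- colnames(m)
  }
  cor <- spearman_matrix(m, p_method = p_method)
  idx <- which(upper.tri(cor$rho), arr.ind = TRUE)
  keep <- !is.na(cor$rho[idx]) &
    abs(cor$rho[idx]) > rho_threshold & cor$p[idx] < p_threshold
  edges <- data.frame(from = vars[idx[keep, 1]], to = vars[idx[keep, 2]],
                      rho = cor$rho[idx][keep], p = cor$p[idx][keep],
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = vars,
                          category = unname(categories[vars]),
                          stringsAsFactors = FALSE))
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  igraph::V(g)$degree <- igraph::degree(g)
  g <- igraph::set_graph_attr(g, "rho_threshold", rho_threshold)
  g <- igraph::set_graph_attr(g, "p_threshold", p_threshold)
  g <- igraph::set_graph_attr(g, "excluded", constant)
  class(g) <- c("cooc_network", class(g))
  g
}

#' Detect modules by modularity maximization
#'
#' Louvain multi-level modularity optimization on |rho| edge weights, seeded
#' for reproducibility; `method = "greedy"` selects the deterministic
#' fast-greedy agglomeration instead. Degree-0 nodes always end up in their
#' own singleton modules.
#'
#' @param net a [build_network()] graph.
#' @param seed integer seed controlling the Louvain vertex ordering.
#' @param method `"louvain"` or `"greedy"`.
#' @return the graph with a vertex attribute `module` (integer labels) and a
#'   graph attribute `modularity`.
#' @export
detect_modules <- function(net, seed = 1L, method = c("louvain", "greedy")) {
  method <- match.arg(method)
  w <- if (igraph::ecount(net) > 0) abs(igraph::E(net)$rho) else NULL
  if (igraph::ecount(net) == 0) {
    membership <- seq_len(igraph::vcount(net))
    mod <- 0
  } else if (method == "louvain") {
    set.seed(seed)
    cl <- igraph::cluster_louvain(net, weights = w)
    membership <- igraph::membership(cl)
    mod <- max(cl$modularity)
  } else {
    cl <- igraph::cluster_fast_greedy(net, weights = w)
    membership <- igraph::membership(cl)
    mod <- igraph::modularity(net, membership, weights = w)
  }
  igraph::V(net)$module <- as.integer(membership)
  igraph::set_graph_attr(net, "modularity", mod)
}

#' Identify the hub of each module
#'
#' The hub is the most densely connected node within its module: maximum
#' within-module degree, ties broken by the larger sum of |rho| over
#' within-module edges, then by lexicographic node id. Singleton (degree-0)
#' modules carry no hub.
#'
#' @param net graph with a `module` vertex attribute.
#' @return the graph with a logical vertex attribute `hub`; the per-module
#'   hub table is attached as graph attribute `hubs` (data.frame `module`,
#'   `hub`, `within_degree`, `tie_break`).
#' @export
find_hubs <- function(net) {
  if (is.null(igraph::V(net)$module))
    stop_validation("modules not assigned; run detect_modules() first")
  mods <- sort(unique(igraph::V(net)$module))
  names <- igraph::V(net)$name
  hub_flag <- rep(FALSE, igraph::vcount(net))
  rows <- list()
  for (m in mods) {
    members <- which(igraph::V(net)$module == m)
    sub <- igraph::induced_subgraph(net, members)
    if (igraph::ecount(sub) == 0) next  # singleton or edgeless module: no hub
    deg <- igraph::degree(sub)
    strength <- igraph::strength(sub, weights = abs(igraph::E(sub)$rho))
    ord <- order(-deg, -strength, igraph::V(sub)$name)
    best <- ord[1]
    tie <- sum(deg == deg[best]) > 1
    hub_name <- igraph::V(sub)$name[best]
    hub_flag[match(hub_name, names)] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      module = m, hub = hub_name, within_degree = deg[best],
      tie_break = if (!tie) "degree" else
        if (sum(deg == deg[best] & abs(strength - strength[best]) < 1e-12) > 1)
          "lexicographic" else "strength",
      stringsAsFactors = FALSE)
  }
  igraph::V(net)$hub <- hub_flag
  igraph::set_graph_attr(net, "hubs",
                         if (length(rows)) do.call(rbind, rows)
                         else data.frame(module = integer(), hub = character(),
                                         within_degree = integer(),
                                         tie_break = character()))
}

#' Export a co-occurrence network
#'
#' Writes GraphML (via igraph), GEXF 1.2, or a pair of TSV tables
#' (`<path>` edge list + `<path>.nodes.tsv` node table). Node attributes
#' exported: category, module, degree, hub; edge attributes: rho, p, sign.
#' Exports are round-trip safe through [read_network()].
#'
#' @param net the network graph.
#' @param path output file path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "gexf", "edgelist")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_validation("unknown format"))
  if (is.null(igraph::V(net)$module)) igraph::V(net)$module <- NA_integer_
  if (is.null(igraph::V(net)$hub)) igraph::V(net)$hub <- FALSE
  if (format == "graphml") {
    g <- net
    class(g) <- "igraph"
    for (at in intersect(c("hubs", "excluded"), igraph::graph_attr_names(g)))
      g <- igraph::delete_graph_attr(g, at)
    igraph::V(g)$hub <- as.integer(igraph::V(g)$hub)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "gexf") {
    .write_gexf(net, path)
  } else {
    edges <- .edge_table(net)
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(.node_table(net), paste0(path, ".nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.node_table <- function(net) {
  data.frame(id = igraph::V(net)$name,
             category = igraph::V(net)$category,
             module = igraph::V(net)$module,
             degree = igraph::V(net)$degree,
             hub = igraph::V(net)$hub,
             stringsAsFactors = FALSE)
}

.edge_table <- function(net) {
  if (igraph::ecount(net) == 0)
    return(data.frame(source = character(), target = character(),
                      rho = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  ends <- igraph::ends(net, igraph::E(net))
  data.frame(source = ends[, 1], target = ends[, 2],
             rho = igraph::E(net)$rho, p = igraph::E(net)$p,
             sign = igraph::E(net)$sign, stringsAsFactors = FALSE)
}

.num17 <- function(x) formatC(x, digits = 17, format = "g")

.write_gexf <- function(net, path) {
  doc <- xml2::xml_new_root("gexf", version = "1.2",
                            xmlns = "http://www.gexf.net/1.2draft")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  natts <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (a in list(c("0", "category", "string"), c("1", "module", "integer"),
                 c("2", "degree", "integer"), c("3", "hub", "boolean")))
    xml2::xml_add_child(natts, "attribute", id = a[1], title = a[2], type = a[3])
  eatts <- xml2::xml_add_child(graph, "attributes", class = "edge")
  for (a in list(c("0", "rho", "double"), c("1", "p", "double"),
                 c("2", "sign", "string")))
    xml2::xml_add_child(eatts, "attribute", id = a[1], title = a[2], type = a[3])
  nodes <- xml2::xml_add_child(graph, "nodes")
  nt <- .node_table(net)
  for (i in seq_len(nrow(nt))) {
    nd <- xml2::xml_add_child(nodes, "node", id = nt$id[i], label = nt$id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = nt$category[i])
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = as.character(nt$module[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "2",
                        value = as.character(nt$degree[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "3",
                        value = tolower(as.character(nt$hub[i])))
  }
  edges <- xml2::xml_add_child(graph, "edges")
  et <- .edge_table(net)
  for (i in seq_len(nrow(et))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                              source = et$source[i], target = et$target[i],
                              weight = .num17(abs(et$rho[i])))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = .num17(et$rho[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "1", value = .num17(et$p[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "2", value = et$sign[i])
  }
  xml2::write_xml(doc, path)
}

#' Read back an exported network
#'
#' @param path file written by [export_network()].
#' @param format the format it was written in.
#' @return an igraph object with the exported attributes.
#' @export
read_network <- function(path, format = c("graphml", "gexf", "edgelist")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_validation("unknown format"))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!is.null(igraph::V(g)$hub)) igraph::V(g)$hub <- igraph::V(g)$hub > 0
    return(g)
  }
  if (format == "edgelist") {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    nodes <- utils::read.table(paste0(path, ".nodes.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    names(nodes)[names(nodes) == "id"] <- "name"
    return(igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = nodes))
  }
  .read_gexf(path)
}

.read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  get_att <- function(el, id) {
    v <- xml2::xml_find_first(el, sprintf(".//g:attvalue[@for='%s']", id), ns)
    xml2::xml_attr(v, "value")
  }
  nodes <- data.frame(
    name = xml2::xml_attr(node_els, "id"),
    category = vapply(node_els, get_att, "", "0"),
    module = as.integer(vapply(node_els, get_att, "", "1")),
    degree = as.integer(vapply(node_els, get_att, "", "2")),
    hub = vapply(node_els, get_att, "", "3") == "true",
    stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    rho = as.numeric(vapply(edge_els, get_att, "", "0")),
    p = as.numeric(vapply(edge_els, get_att, "", "1")),
    sign = vapply(edge_els, get_att, "", "2"),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
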