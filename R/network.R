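#' Build an attribute-annotated association network
#'
#' Assembles nodes and undirected edges from a PCIT edge list and overlays
#' external evidence (DEG status per trait, TF, cis/trans eQTL), RIF
#' significance and pathway membership as node attributes.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `role_a`,
#'   `role_b`, `r`, and optionally `significant`, `source_run` (as produced
#'   by [pcit_edges()]). Self-loops and duplicate unordered pairs are an
#'   error.
#' @param attributes optional attribute data.frame (`feature_id`, `kind`,
#'   `trait_id`, `direction`); rows for features absent from the network are
#'   ignored with a message.
#' @param rif optional named list of `rif_table`s (names = trait ids or
#'   `"overall"`); significant candidates get `rif_significant = TRUE` and
#'   the trait labels recorded.
#' @param pathway_members optional character vector of feature ids that are
#'   part of enriched pathways (external enrichment results).
#' @param nodes optional data.frame (`node_id`, `role`) of nodes to include
#'   even when they have no incident edge (isolated nodes count in degree
#'   statistics).
#' @return an `association_network`: list with data.frames `nodes` (id,
#'   role, deg/TF/eQTL/RIF/hub/pathway flags) and `edges`.
#' @export
build_network <- function(edges, attributes = NULL, rif = NULL,
                          pathway_members = NULL, nodes = NULL) {
  if (nrow(edges)) {
    if (any(edges$node_a == edges$node_b)) stop("self-loops are not allowed")
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b))
    if (anyDuplicated(key)) stop("duplicate unordered edge pairs")
  }
  ids <- c(edges$node_a, edges$node_b)
  roles <- c(edges$role_a, edges$role_b)
  if (!is.null(nodes)) {
    extra <- !(nodes$node_id %in% ids)
    ids <- c(ids, nodes$node_id[extra])
    roles <- c(roles, nodes$role[extra])
  }
  if (length(ids)) {
    first <- !duplicated(ids)
    node_id <- ids[first]
    node_role <- roles[first]
    conflict <- tapply(roles, ids, function(r) length(unique(r)) > 1L)
    if (any(conflict))
      stop("conflicting roles for node(s): ",
           paste(names(conflict)[conflict], collapse = ", "))
    bad <- setdiff(unique(node_role), c("gene", "mirna", "trait"))
    if (length(bad)) stop("unknown node role(s): ", paste(bad, collapse = ", "))
  } else {
    node_id <- character(0)
    node_role <- character(0)
  }

  k <- length(node_id)
  nodes <- data.frame(
    node_id = node_id, role = node_role,
    deg = rep(FALSE, k), deg_traits = rep("", k),
    deg_direction = rep("", k),
    tf = rep(FALSE, k), cis_eqtl = rep(FALSE, k),
    trans_eqtl = rep(FALSE, k),
    rif_significant = rep(FALSE, k), rif_traits = rep("", k),
    hub = rep(FALSE, k), in_enriched_pathway = rep(FALSE, k),
    stringsAsFactors = FALSE)
  rownames(nodes) <- nodes$node_id

  if (!is.null(attributes) && nrow(attributes)) {
    unmatched <- setdiff(unique(attributes$feature_id), nodes$node_id)
    if (length(unmatched))
      message(length(unmatched),
              " attribute feature(s) absent from the network; ignored")
    att <- attributes[attributes$feature_id %in% nodes$node_id, , drop = FALSE]
    for (i in seq_len(nrow(att))) {
      id <- att$feature_id[i]
      kind <- att$kind[i]
      if (kind == "DEG") {
        nodes[id, "deg"] <- TRUE
        nodes[id, "deg_traits"] <-
          .append_label(nodes[id, "deg_traits"], att$trait_id[i])
        nodes[id, "deg_direction"] <-
          .append_label(nodes[id, "deg_direction"],
                        paste0(att$trait_id[i], ":", att$direction[i]))
      } else if (kind == "TF") nodes[id, "tf"] <- TRUE
      else if (kind == "cis_eqtl") nodes[id, "cis_eqtl"] <- TRUE
      else if (kind == "trans_eqtl") nodes[id, "trans_eqtl"] <- TRUE
    }
  }

  if (!is.null(rif)) {
    for (label in names(rif)) {
      tab <- rif[[label]]
      sig <- tab$candidate_id[tab$significant]
      sig <- intersect(sig, nodes$node_id)
      nodes[sig, "rif_significant"] <- TRUE
      for (id in sig)
        nodes[id, "rif_traits"] <- .append_label(nodes[id, "rif_traits"], label)
    }
  }

  if (!is.null(pathway_members)) {
    hit <- intersect(pathway_members, nodes$node_id)
    nodes[hit, "in_enriched_pathway"] <- TRUE
  }

  keep <- c("node_a", "node_b", "r",
            intersect(c("significant", "source_run"), names(edges)))
  structure(list(nodes = nodes, edges = edges[, keep, drop = FALSE]),
            class = "association_network")
}

.append_label <- function(cur, lab) {
  if (is.na(cur) || cur == "") lab else paste(cur, lab, sep = ";")
}

#' @export
print.association_network <- function(x, ...) {
  cat("Association network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges;", sum(x$nodes$hub), "hubs,",
      sum(x$nodes$rif_significant), "RIF-significant nodes\n")
  invisible(x)
}

#' Detect network hubs by connectivity degree
#'
#' A node is a hub when its degree strictly exceeds the network's mean degree
#' plus `sd_multiplier` times the population standard deviation of the degree
#' sequence (computed over all nodes of the analysed network). With a
#' degenerate (constant) degree sequence the threshold equals the mean and no
#' node is a hub.
#'
#' @param net an `association_network`.
#' @param sd_multiplier multiplier on the degree standard deviation
#'   (default 2).
#' @return data.frame `node_id`, `degree`, `hub`, with the mean, sd and
#'   threshold attached as attributes `mean_degree`, `sd_degree`,
#'   `hub_threshold`, `sd_type = "population"`.
#' @export
detect_hubs <- function(net, sd_multiplier = 2) {
  stopifnot(inherits(net, "association_network"))
  if (nrow(net$nodes) == 0L) stop("network has no nodes")
  deg <- stats::setNames(rep(0L, nrow(net$nodes)), net$nodes$node_id)
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$node_a, net$edges$node_b))
    deg[names(tab)] <- as.integer(tab)
  }
  mu <- mean(deg)
  sdp <- sqrt(mean((deg - mu)^2))        # population sd
  thr <- mu + sd_multiplier * sdp
  out <- data.frame(node_id = names(deg), degree = as.integer(deg),
                    hub = deg > thr, stringsAsFactors = FALSE)
  attr(out, "mean_degree") <- mu
  attr(out, "sd_degree") <- sdp
  attr(out, "hub_threshold") <- thr
  attr(out, "sd_type") <- "population"
  out
}

#' Flag hub nodes on a network
#'
#' Convenience wrapper: runs [detect_hubs()] and writes the result into the
#' network's `hub` node column.
#'
#' @inheritParams detect_hubs
#' @return the network with `nodes$hub` updated and the degree summary stored
#'   as attribute `degree_summary`.
#' @export
flag_hubs <- function(net, sd_multiplier = 2) {
  ds <- detect_hubs(net, sd_multiplier)
  net$nodes$hub <- ds$hub[match(net$nodes$node_id, ds$node_id)]
  attr(net, "degree_summary") <- ds
  net
}

#' PCIT integration of trait-correlated features with the trait's DEGs
#'
#' Runs PCIT in its original, expression-only form over the union of a
#' trait's correlated features and its differentially expressed genes, then
#' builds the attribute network and flags hubs.
#'
#' @param trait trait id (used for labels only).
#' @param correlated_features character vector of feature ids correlated to
#'   the trait.
#' @param deg_list character vector of DEG ids for the trait (may be empty).
#' @param expr numeric matrix, features x samples, covering every listed id.
#' @param roles named character vector of roles for the features in `expr`
#'   (default: all `"gene"`, miRNA ids must be supplied by the caller).
#' @param attributes,rif passed to [build_network()].
#' @param sd_multiplier hub rule multiplier (default 2).
#' @return an `association_network` with hubs flagged.
#' @export
integrate_with_degs <- function(trait, correlated_features, deg_list, expr,
                                roles = NULL, attributes = NULL, rif = NULL,
                                sd_multiplier = 2) {
  expr <- as.matrix(expr)
  feats <- unique(c(correlated_features, deg_list))
  missing <- setdiff(feats, rownames(expr))
  if (length(missing))
    stop("expression missing for feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (length(feats) < 3L)
    stop("trait '", trait, "': need at least 3 features for PCIT, got ",
         length(feats))
  if (is.null(roles))
    roles <- stats::setNames(rep("gene", length(feats)), feats)
  res <- pcit(expr[feats, , drop = FALSE], roles = unname(roles[feats]))
  e <- pcit_edges(res, significant_only = TRUE,
                  source_run = paste0("deg_integration_", trait))
  net <- build_network(e, attributes = attributes, rif = rif)
  flag_hubs(net, sd_multiplier)
}

#' Keep only edges carrying regulatory evidence
#'
#' Retains the edges with at least one endpoint flagged `hub` or
#' `rif_significant`; the endpoints of the kept edges form the candidate set
#' handed to external functional enrichment.
#'
#' @param net an `association_network` with hub and RIF flags populated.
#' @return list with `edges` (the kept subset) and `candidates` (character
#'   vector of endpoint node ids).
#' @export
select_regulatory_edges <- function(net) {
  stopifnot(inherits(net, "association_network"))
  flagged <- net$nodes$node_id[net$nodes$hub | net$nodes$rif_significant]
  keep <- net$edges$node_a %in% flagged | net$edges$node_b %in% flagged
  edges <- net$edges[keep, , drop = FALSE]
  list(edges = edges,
       candidates = unique(c(edges$node_a, edges$node_b)))
}

#' Final putative-regulator network
#'
#' One more PCIT round over the expression of the selected elements (pathway
#' members, hubs, TFs, miRNAs and RIF-significant features). Edges incident
#' to a RIF-significant node are marked (`rif_marked`), mirroring the usual
#' highlighting of regulatory correlations in network figures.
#'
#' @param selected character vector of feature ids entering the final round.
#' @param expr numeric matrix, features x samples.
#' @param roles optional named role vector (defaults to `"gene"`).
#' @param attributes,rif,pathway_members passed to [build_network()].
#' @param sd_multiplier hub rule multiplier (default 2).
#' @param source_run edge label (default `"final"`).
#' @return an `association_network`; its edges carry a logical `rif_marked`
#'   column.
#' @export
final_regulator_network <- function(selected, expr, roles = NULL,
                                    attributes = NULL, rif = NULL,
                                    pathway_members = NULL,
                                    sd_multiplier = 2, source_run = "final") {
  expr <- as.matrix(expr)
  selected <- unique(selected)
  selected <- intersect(selected, rownames(expr))
  if (length(selected) < 3L)
    stop("need at least 3 selected elements with expression, got ",
         length(selected))
  if (is.null(roles))
    roles <- stats::setNames(rep("gene", length(selected)), selected)
  res <- pcit(expr[selected, , drop = FALSE], roles = unname(roles[selected]))
  e <- pcit_edges(res, significant_only = TRUE, source_run = source_run)
  net <- build_network(e, attributes = attributes, rif = rif,
                       pathway_members = pathway_members)
  net <- flag_hubs(net, sd_multiplier)
  rif_nodes <- net$nodes$node_id[net$nodes$rif_significant]
  net$edges$rif_marked <- net$edges$node_a %in% rif_nodes |
    net$edges$node_b %in% rif_nodes
  net
}

#' Write a network as edge and node-attribute TSVs
#'
#' The two tables import directly into standard graph-visualisation tools.
#'
#' @param net an `association_network`.
#' @param edge_path path for the edge table.
#' @param node_path path for the node-attribute table.
#' @export
write_network_tsv <- function(net, edge_path, node_path) {
  stopifnot(inherits(net, "association_network"))
  write_tsv(net$edges, edge_path)
  write_tsv(net$nodes, node_path)
  invisible(edge_path)
}

#' Read a network back from its edge and node-attribute TSVs
#'
#' Round-trip companion of [write_network_tsv()].
#'
#' @param edge_path,node_path paths written by [write_network_tsv()].
#' @return an `association_network`.
#' @export
read_network_tsv <- function(edge_path, node_path) {
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                             na.strings = NULL)
  for (col in c("deg_traits", "deg_direction", "rif_traits"))
    if (col %in% names(nodes)) nodes[[col]][is.na(nodes[[col]])] <- ""
  rownames(nodes) <- nodes$node_id
  structure(list(nodes = nodes, edges = edges),
            class = "association_network")
}

#' Export a network to GraphML (requires igraph)
#'
#' @param net an `association_network`.
#' @param path output `.graphml` path.
#' @export
write_network_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for GraphML export")
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = net$nodes[, c("node_id",
                             setdiff(names(net$nodes), "node_id"))])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
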