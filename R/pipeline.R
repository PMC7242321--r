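#' Pipeline configuration
#'
#' Builds (and validates) the configuration for [run_pipeline()]. Defaults
#' are the method's standard constants: low-expression cut at 22 samples,
#' contrast groups of 15, RIF significance at |z| >= 1.96, hub rule
#' mean + 2 sd. Trait names are never hard-coded; the pipeline applies to any
#' set of quantitative traits.
#'
#' @param genes,mirnas,gebv paths to the expression and GEBV TSVs (`mirnas`
#'   may be `NULL`).
#' @param gene_counts,mirna_counts optional raw count TSVs; when given, the
#'   low-expression filter restricts the corresponding expression matrix.
#' @param attributes optional attribute TSV (DEG/TF/eQTL lists; DEG rows
#'   carry the trait and direction).
#' @param pathway_members optional TSV with columns `feature_id` and
#'   optionally `trait_id`, listing genes in enriched pathways (external
#'   enrichment results; enrichment is never computed here).
#' @param out_dir output directory.
#' @param group_size contrast-group size (default 15).
#' @param min_samples low-expression filter threshold (default 22).
#' @param z_cutoff RIF significance cutoff (default 1.96).
#' @param hub_sd_multiplier hub rule sd multiplier (default 2).
#' @param pca_weight_mode `"proportion"` or `"eigenvalue"`.
#' @param seed integer seed recorded with the run.
#' @param resume reuse existing stage outputs when config and input checksums
#'   are unchanged (default `TRUE`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genes, gebv, mirnas = NULL,
                            gene_counts = NULL, mirna_counts = NULL,
                            attributes = NULL, pathway_members = NULL,
                            out_dir = "pcitrif_run",
                            group_size = 15L, min_samples = 22L,
                            z_cutoff = 1.96, hub_sd_multiplier = 2,
                            pca_weight_mode = "proportion", seed = 1L,
                            resume = TRUE) {
  cfg <- list(genes = genes, mirnas = mirnas, gebv = gebv,
              gene_counts = gene_counts, mirna_counts = mirna_counts,
              attributes = attributes, pathway_members = pathway_members,
              out_dir = out_dir, group_size = as.integer(group_size),
              min_samples = as.integer(min_samples), z_cutoff = z_cutoff,
              hub_sd_multiplier = hub_sd_multiplier,
              pca_weight_mode = match.arg(pca_weight_mode,
                                          c("proportion", "eigenvalue")),
              seed = as.integer(seed), resume = isTRUE(resume))
  for (k in c("genes", "mirnas", "gebv", "gene_counts", "mirna_counts",
              "attributes", "pathway_members")) {
    p <- cfg[[k]]
    if (!is.null(p) && !file.exists(p))
      stop("config input '", k, "' not found: ", p)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value schema; keys match the arguments of [pipeline_config()].
#' Relative input paths are resolved against the config file's directory.
#'
#' @param path YAML config path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("genes", "mirnas", "gebv", "gene_counts", "mirna_counts",
              "attributes", "pathway_members"))
    if (!is.null(raw[[k]]) && !grepl("^(/|[A-Za-z]:)", raw[[k]]))
      raw[[k]] <- file.path(base, raw[[k]])
  do.call(pipeline_config, raw)
}

# deterministic fingerprint of the resolved config + input file contents
.config_hash <- function(cfg) {
  inputs <- c("genes", "mirnas", "gebv", "gene_counts", "mirna_counts",
              "attributes", "pathway_members")
  sums <- vapply(inputs, function(k) {
    if (is.null(cfg[[k]])) "-" else unname(tools::md5sum(cfg[[k]]))
  }, character(1))
  params <- cfg[c("group_size", "min_samples", "z_cutoff",
                  "hub_sd_multiplier", "pca_weight_mode", "seed")]
  paste(paste(inputs, sums, collapse = ";"),
        paste(names(params), unlist(params), collapse = ";"), sep = "|")
}

.log <- function(log_path, ...) {
  msg <- paste0(...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
}

# cached stage execution: reuse outputs written by a previous run with the
# same config hash, otherwise compute and write
.stage <- function(state, name, files, compute, read) {
  cached <- state$resume &&
    identical(state$prev_manifest$config_hash, state$hash) &&
    name %in% names(state$prev_manifest$stages) &&
    all(file.exists(file.path(state$out_dir, files)))
  if (cached) {
    .log(state$log, "[", name, "] reusing cached outputs")
    read(file.path(state$out_dir, files))
  } else {
    compute(file.path(state$out_dir, files))
  }
}

# edges (with endpoint roles) + node table from a pcit_result, the
# disk-round-trippable summary the downstream stages consume
.pcit_summary <- function(res, run) {
  edges <- pcit_edges(res, significant_only = TRUE, source_run = run)
  nodes <- data.frame(node_id = res$node_ids, role = unname(res$roles),
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

.read_pcit_summary <- function(paths) {
  edges <- utils::read.delim(paths[1L], stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paths[2L], stringsAsFactors = FALSE)
  role <- stats::setNames(nodes$role, nodes$node_id)
  edges$role_a <- unname(role[edges$node_a])
  edges$role_b <- unname(role[edges$node_b])
  list(edges = edges, nodes = nodes)
}

.write_pcit_summary <- function(sm, paths) {
  write_tsv(sm$edges[, c("node_a", "node_b", "r", "significant",
                         "source_run")], paths[1L])
  write_tsv(sm$nodes, paths[2L])
}

# feature-trait union from edge summaries (role-aware), same semantics as
# combine_feature_trait_edges() but operating on the disk representation
.combine_from_summaries <- function(general, mirna_only) {
  ft <- function(sm, run) {
    if (is.null(sm)) return(NULL)
    e <- sm$edges
    is_ft <- xor(e$role_a == "trait", e$role_b == "trait")
    e <- e[is_ft, , drop = FALSE]
    if (!nrow(e))
      return(data.frame(trait = character(0), feature_id = character(0),
                        feature_role = character(0), r = numeric(0),
                        source = character(0), stringsAsFactors = FALSE))
    data.frame(
      trait = ifelse(e$role_a == "trait", e$node_a, e$node_b),
      feature_id = ifelse(e$role_a == "trait", e$node_b, e$node_a),
      feature_role = ifelse(e$role_a == "trait", e$role_b, e$role_a),
      r = e$r, source = run, stringsAsFactors = FALSE)
  }
  g <- ft(general, "general")
  m <- ft(mirna_only, "mirna")
  if (!is.null(g) && !is.null(m)) {
    shared <- intersect(paste(g$trait, g$feature_id),
                        paste(m$trait, m$feature_id))
    g$source[paste(g$trait, g$feature_id) %in% shared] <- "both"
    m <- m[!(paste(m$trait, m$feature_id) %in% shared), , drop = FALSE]
  }
  out <- rbind(g, m)
  rownames(out) <- NULL
  out[order(out$trait, out$feature_id), , drop = FALSE]
}

#' Run the full PCIT + RIF pipeline
#'
#' Executes, in order: low-expression filtering (when counts are supplied),
#' sample alignment, PCIT general and PCIT miRNA, combination of the
#' feature-trait edges, per-trait RIF and overall RIF with PCA-score
#' contrasts, the attribute-annotated correlation network, per-trait
#' DEG-integration PCIT rounds with hub detection and regulatory-edge
#' selection, and the final putative-regulator networks (per trait and
#' overall). Every stage writes TSVs under `out_dir`; a manifest records
#' outputs, counts and input checksums, and unchanged reruns reuse cached
#' stage outputs.
#'
#' @param cfg a `pipeline_config` (or path to a YAML config).
#' @return the run manifest (invisibly): list with `stages`, `config_hash`,
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)  # fresh log

  hash <- .config_hash(cfg)
  prev_manifest <- NULL
  manifest_path <- file.path(cfg$out_dir, "manifest.yaml")
  if (cfg$resume && file.exists(manifest_path))
    prev_manifest <- tryCatch(yaml::read_yaml(manifest_path),
                              error = function(e) NULL)
  state <- list(out_dir = cfg$out_dir, log = log_path, hash = hash,
                resume = cfg$resume, prev_manifest = prev_manifest)
  manifest <- list(config_hash = hash, out_dir = cfg$out_dir,
                   stages = list())
  note <- function(stage, files, ...) {
    manifest$stages[[stage]] <<- c(list(outputs = as.list(files)), list(...))
  }

  # resolved config for provenance / reruns
  cfg_out <- unclass(cfg)
  yaml::write_yaml(cfg_out[!vapply(cfg_out, is.null, logical(1))],
                   file.path(cfg$out_dir, "config_resolved.yaml"))

  ## stage: load (+ filter) + align -----------------------------------------
  genes <- read_matrix_tsv(cfg$genes)
  mirnas <- if (!is.null(cfg$mirnas)) read_matrix_tsv(cfg$mirnas) else
    matrix(numeric(0), 0L, ncol(genes), dimnames = list(NULL, colnames(genes)))
  gebv <- read_gebv_tsv(cfg$gebv)
  if (!is.null(cfg$gene_counts)) {
    kept <- filter_low_expression(read_matrix_tsv(cfg$gene_counts),
                                  min_samples = cfg$min_samples)
    genes <- genes[intersect(rownames(genes), kept), , drop = FALSE]
    .log(log_path, "[filter] genes retained: ", nrow(genes))
  }
  if (!is.null(cfg$mirna_counts) && nrow(mirnas)) {
    kept <- filter_low_expression(read_matrix_tsv(cfg$mirna_counts),
                                  min_samples = cfg$min_samples)
    mirnas <- mirnas[intersect(rownames(mirnas), kept), , drop = FALSE]
    .log(log_path, "[filter] miRNAs retained: ", nrow(mirnas))
  }
  al <- align_samples(rbind(genes, mirnas), gebv)
  gebv <- al$gebv
  genes <- al$expr[rownames(genes), , drop = FALSE]
  mirnas <- al$expr[rownames(mirnas), , drop = FALSE]
  expr <- al$expr
  roles <- stats::setNames(rep(c("gene", "mirna"),
                               c(nrow(genes), nrow(mirnas))), rownames(expr))
  attributes <- if (!is.null(cfg$attributes))
    read_attributes_tsv(cfg$attributes) else NULL
  pathways <- if (!is.null(cfg$pathway_members)) {
    pw <- utils::read.delim(cfg$pathway_members, stringsAsFactors = FALSE)
    if (!"feature_id" %in% names(pw))
      stop("pathway_members needs a feature_id column")
    if (!"trait_id" %in% names(pw)) pw$trait_id <- ""
    pw
  } else NULL
  .log(log_path, "[load] ", nrow(genes), " genes, ", nrow(mirnas),
       " miRNAs, ", ncol(gebv), " traits, ", ncol(expr), " samples")

  ## stage: PCIT general ----------------------------------------------------
  general <- .stage(state, "pcit_general",
                    c("pcit_general_edges.tsv", "pcit_general_nodes.tsv"),
    compute = function(paths) {
      res <- run_pcit_general(genes, mirnas, gebv)
      sm <- .pcit_summary(res, "general")
      .write_pcit_summary(sm, paths)
      sm
    },
    read = .read_pcit_summary)
  note("pcit_general", c("pcit_general_edges.tsv", "pcit_general_nodes.tsv"),
       nodes = nrow(general$nodes), edges = nrow(general$edges))
  .log(log_path, "[pcit_general] ", nrow(general$nodes), " nodes, ",
       nrow(general$edges), " significant edges")

  ## stage: PCIT miRNA ------------------------------------------------------
  mirna_sm <- NULL
  if (nrow(mirnas) + ncol(gebv) >= 3L && nrow(mirnas) > 0L) {
    mirna_sm <- .stage(state, "pcit_mirna",
                       c("pcit_mirna_edges.tsv", "pcit_mirna_nodes.tsv"),
      compute = function(paths) {
        res <- run_pcit_mirna(mirnas, gebv)
        sm <- .pcit_summary(res, "mirna")
        .write_pcit_summary(sm, paths)
        sm
      },
      read = .read_pcit_summary)
    note("pcit_mirna", c("pcit_mirna_edges.tsv", "pcit_mirna_nodes.tsv"),
         nodes = nrow(mirna_sm$nodes), edges = nrow(mirna_sm$edges))
    .log(log_path, "[pcit_mirna] ", nrow(mirna_sm$nodes), " nodes, ",
         nrow(mirna_sm$edges), " significant edges")
  } else {
    .log(log_path, "[pcit_mirna] skipped (no miRNAs)")
  }

  ## stage: combine ---------------------------------------------------------
  correlated <- .combine_from_summaries(general, mirna_sm)
  write_tsv(correlated, file.path(cfg$out_dir, "correlated_features.tsv"))
  note("combine", "correlated_features.tsv", records = nrow(correlated))
  .log(log_path, "[combine] ", length(unique(correlated$feature_id)),
       " features correlated to >=1 trait (", nrow(correlated),
       " feature-trait records)")

  ## stage: RIF -------------------------------------------------------------
  per_trait <- rif_per_trait(correlated, expr, gebv,
                             group_size = cfg$group_size,
                             z_cutoff = cfg$z_cutoff)
  overall <- rif_overall(correlated, expr, gebv, group_size = cfg$group_size,
                         z_cutoff = cfg$z_cutoff,
                         weight_mode = cfg$pca_weight_mode)
  rif_all <- c(per_trait, list(overall = overall$rif))
  rif_long <- do.call(rbind, lapply(names(rif_all), function(nm) {
    t <- rif_all[[nm]]
    if (!nrow(t)) return(NULL)
    cbind(analysis = nm, t)
  }))
  if (is.null(rif_long))
    rif_long <- data.frame(analysis = character(0),
                           candidate_id = character(0))
  write_tsv(rif_long, file.path(cfg$out_dir, "rif.tsv"))
  write_tsv(overall$scores, file.path(cfg$out_dir, "pca_scores.tsv"))
  contrasts <- do.call(rbind, lapply(colnames(gebv), function(tr) {
    d <- select_contrast_by_trait(gebv, tr, cfg$group_size)
    cbind(label = tr, contrast_table(d))
  }))
  contrasts <- rbind(contrasts,
                     cbind(label = "pca_score",
                           contrast_table(overall$design)))
  write_tsv(contrasts, file.path(cfg$out_dir, "contrasts.tsv"))
  n_sig_rif <- sum(rif_long$significant)
  note("rif", c("rif.tsv", "pca_scores.tsv", "contrasts.tsv"),
       significant = n_sig_rif)
  .log(log_path, "[rif] ", n_sig_rif,
       " significant (candidate, analysis) pairs; overall: ",
       sum(overall$rif$significant), " significant candidates")

  ## stage: correlation network with attributes ------------------------------
  corr_feats <- unique(correlated$feature_id)
  net_nodes <- c(corr_feats, colnames(gebv))
  keep_e <- general$edges$node_a %in% net_nodes &
    general$edges$node_b %in% net_nodes
  net_edges <- general$edges[keep_e, , drop = FALSE]
  if (!is.null(mirna_sm)) {
    me <- mirna_sm$edges[mirna_sm$edges$node_a %in% net_nodes &
                           mirna_sm$edges$node_b %in% net_nodes, ,
                         drop = FALSE]
    key <- paste(pmin(net_edges$node_a, net_edges$node_b),
                 pmax(net_edges$node_a, net_edges$node_b))
    mkey <- paste(pmin(me$node_a, me$node_b), pmax(me$node_a, me$node_b))
    net_edges <- rbind(net_edges, me[!(mkey %in% key), , drop = FALSE])
  }
  net1 <- build_network(net_edges, attributes = attributes, rif = rif_all,
                        pathway_members = pathways$feature_id)
  net1 <- flag_hubs(net1, cfg$hub_sd_multiplier)
  write_network_tsv(net1, file.path(cfg$out_dir, "network_edges.tsv"),
                    file.path(cfg$out_dir, "network_nodes.tsv"))
  note("network", c("network_edges.tsv", "network_nodes.tsv"),
       nodes = nrow(net1$nodes), edges = nrow(net1$edges))
  .log(log_path, "[network] ", nrow(net1$nodes), " nodes, ",
       nrow(net1$edges), " edges")

  ## stage: per-trait DEG integration + hub/RIF selection --------------------
  deg_by_trait <- list()
  if (!is.null(attributes)) {
    degs <- attributes[attributes$kind == "DEG", , drop = FALSE]
    deg_by_trait <- split(degs$feature_id, degs$trait_id)
  }
  if (!length(deg_by_trait))
    .log(log_path, "[integration] no DEG lists configured; ",
         "using correlated features only")
  selected_by_trait <- list()
  for (tr in colnames(gebv)) {
    feats <- unique(correlated$feature_id[correlated$trait == tr])
    degs_tr <- intersect(deg_by_trait[[tr]], rownames(expr))
    union_feats <- unique(c(feats, degs_tr))
    if (length(union_feats) < 3L) {
      .log(log_path, "[integration:", tr, "] skipped (",
           length(union_feats), " features)")
      next
    }
    net_tr <- integrate_with_degs(tr, feats, degs_tr, expr, roles = roles,
                                  attributes = attributes,
                                  rif = rif_all[c(tr, "overall")],
                                  sd_multiplier = cfg$hub_sd_multiplier)
    write_network_tsv(net_tr,
                      file.path(cfg$out_dir,
                                paste0("integration_", tr, "_edges.tsv")),
                      file.path(cfg$out_dir,
                                paste0("integration_", tr, "_nodes.tsv")))
    sel <- select_regulatory_edges(net_tr)
    selected_by_trait[[tr]] <- sel$candidates
    .log(log_path, "[integration:", tr, "] ", nrow(net_tr$nodes),
         " nodes, ", nrow(net_tr$edges), " edges, ",
         sum(net_tr$nodes$hub), " hubs, ", length(sel$candidates),
         " selected candidates")
  }
  sel_tab <- do.call(rbind, lapply(names(selected_by_trait), function(tr)
    data.frame(trait = tr, node_id = selected_by_trait[[tr]],
               stringsAsFactors = FALSE)))
  if (is.null(sel_tab))
    sel_tab <- data.frame(trait = character(0), node_id = character(0))
  write_tsv(sel_tab, file.path(cfg$out_dir, "selected_candidates.tsv"))
  note("integration", "selected_candidates.tsv",
       candidates = nrow(sel_tab))

  ## stage: final regulator networks -----------------------------------------
  tf_ids <- if (!is.null(attributes))
    unique(attributes$feature_id[attributes$kind == "TF"]) else character(0)
  final_files <- character(0)
  for (tr in colnames(gebv)) {
    sel <- selected_by_trait[[tr]]
    if (is.null(sel)) next
    feats_tr <- unique(correlated$feature_id[correlated$trait == tr])
    pw_tr <- if (!is.null(pathways))
      pathways$feature_id[pathways$trait_id %in% c(tr, "")] else character(0)
    rif_tr <- rif_all[[tr]]
    rif_sig <- if (!is.null(rif_tr)) rif_tr$candidate_id[rif_tr$significant]
      else character(0)
    inputs <- unique(c(intersect(pw_tr, rownames(expr)),
                       sel,
                       intersect(tf_ids, rownames(expr)),
                       feats_tr[roles[feats_tr] == "mirna"],
                       rif_sig))
    if (!length(intersect(pw_tr, rownames(expr)))) {
      # fallback: no pathway members -> DEGs correlated to hub/RIF elements
      inputs <- unique(c(sel, intersect(deg_by_trait[[tr]], rownames(expr)),
                         feats_tr[roles[feats_tr] == "mirna"], rif_sig))
    }
    inputs <- intersect(inputs, rownames(expr))
    if (length(inputs) < 3L) {
      .log(log_path, "[final:", tr, "] skipped (", length(inputs),
           " elements)")
      next
    }
    fin <- final_regulator_network(inputs, expr, roles = roles,
                                   attributes = attributes,
                                   rif = rif_all[c(tr, "overall")],
                                   pathway_members = pw_tr,
                                   sd_multiplier = cfg$hub_sd_multiplier,
                                   source_run = paste0("final_", tr))
    f1 <- paste0("final_", tr, "_edges.tsv")
    f2 <- paste0("final_", tr, "_nodes.tsv")
    write_network_tsv(fin, file.path(cfg$out_dir, f1),
                      file.path(cfg$out_dir, f2))
    final_files <- c(final_files, f1, f2)
    .log(log_path, "[final:", tr, "] ", nrow(fin$nodes), " nodes, ",
         nrow(fin$edges), " edges")
  }

  # overall final network: every hub/RIF/TF/miRNA/pathway element
  overall_inputs <- unique(c(
    unlist(selected_by_trait, use.names = FALSE),
    overall$rif$candidate_id[overall$rif$significant],
    intersect(tf_ids, rownames(expr)),
    corr_feats[roles[corr_feats] == "mirna"],
    if (!is.null(pathways)) intersect(pathways$feature_id, rownames(expr))))
  overall_inputs <- intersect(overall_inputs, rownames(expr))
  if (length(overall_inputs) >= 3L) {
    fin <- final_regulator_network(overall_inputs, expr, roles = roles,
                                   attributes = attributes, rif = rif_all,
                                   pathway_members = pathways$feature_id,
                                   sd_multiplier = cfg$hub_sd_multiplier,
                                   source_run = "final_overall")
    write_network_tsv(fin, file.path(cfg$out_dir, "final_overall_edges.tsv"),
                      file.path(cfg$out_dir, "final_overall_nodes.tsv"))
    final_files <- c(final_files, "final_overall_edges.tsv",
                     "final_overall_nodes.tsv")
    .log(log_path, "[final:overall] ", nrow(fin$nodes), " nodes, ",
         nrow(fin$edges), " edges, ",
         sum(fin$nodes$rif_significant), " RIF-significant nodes")
  } else {
    .log(log_path, "[final:overall] skipped (", length(overall_inputs),
         " elements)")
  }
  note("final", final_files)

  yaml::write_yaml(manifest, manifest_path)
  .log(log_path, "[done] manifest written to ", manifest_path)
  invisible(manifest)
}
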