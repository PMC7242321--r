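# Network assembly, attribute overlay, hub detection, regulatory-edge
# selection and round-trip I/O.

star_edges <- function(k = 12) {
  data.frame(node_a = "hub0", node_b = sprintf("leaf%02d", 1:k),
             role_a = "gene", role_b = "gene", r = 0.9,
             significant = TRUE, source_run = "test",
             stringsAsFactors = FALSE)
}

test_that("build_network assembles nodes, attributes and RIF flags", {
  e <- star_edges(3)
  att <- data.frame(
    feature_id = c("leaf01", "leaf01", "hub0", "leaf02", "leaf03"),
    kind = c("DEG", "TF", "trans_eqtl", "cis_eqtl", "DEG"),
    trait_id = c("tFe", "", "", "", "tZn"),
    direction = c("up", "none", "none", "none", "down"))
  rif <- list(tFe = data.frame(candidate_id = c("leaf01", "hub0"),
                               significant = c(TRUE, FALSE)))
  net <- build_network(e, attributes = att, rif = rif,
                       pathway_members = "leaf02")

  n <- net$nodes
  expect_setequal(n$node_id, c("hub0", sprintf("leaf%02d", 1:3)))
  expect_true(n["leaf01", "deg"])
  expect_identical(n["leaf01", "deg_traits"], "tFe")
  expect_identical(n["leaf01", "deg_direction"], "tFe:up")
  expect_identical(n["leaf03", "deg_direction"], "tZn:down")
  expect_true(n["leaf01", "tf"])
  expect_true(n["hub0", "trans_eqtl"])
  expect_true(n["leaf02", "cis_eqtl"])
  expect_true(n["leaf02", "in_enriched_pathway"])
  expect_true(n["leaf01", "rif_significant"])
  expect_identical(n["leaf01", "rif_traits"], "tFe")
  expect_false(n["hub0", "rif_significant"])

  # every flag independently queryable on a node holding all of them
  att_all <- data.frame(feature_id = "hub0",
                        kind = c("DEG", "TF", "cis_eqtl", "trans_eqtl"),
                        trait_id = c("tA", "", "", ""),
                        direction = c("up", "none", "none", "none"))
  net2 <- build_network(e, attributes = att_all,
                        rif = list(overall = data.frame(
                          candidate_id = "hub0", significant = TRUE)),
                        pathway_members = "hub0")
  h <- net2$nodes["hub0", ]
  expect_true(all(unlist(h[c("deg", "tf", "cis_eqtl", "trans_eqtl",
                             "rif_significant", "in_enriched_pathway")])))

  # unmatched attribute rows are ignored with a message
  att_miss <- data.frame(feature_id = "ghost", kind = "TF", trait_id = "",
                         direction = "none")
  expect_message(build_network(e, attributes = att_miss), "ignored")
})

test_that("build_network rejects malformed edge sets", {
  e <- star_edges(2)
  loop <- e; loop$node_b[1] <- "hub0"
  expect_error(build_network(loop), "self-loops")
  dup <- rbind(e, data.frame(node_a = "leaf01", node_b = "hub0",
                             role_a = "gene", role_b = "gene", r = 0.5,
                             significant = TRUE, source_run = "test"))
  expect_error(build_network(dup), "duplicate")
  badrole <- e; badrole$role_a <- "planet"
  expect_error(build_network(badrole), "unknown node role")
  conflict <- rbind(e, data.frame(node_a = "hub0", node_b = "leaf09",
                                  role_a = "mirna", role_b = "gene", r = 0.5,
                                  significant = TRUE, source_run = "test"))
  expect_error(build_network(conflict), "conflicting roles")

  empty <- build_network(e[0, ])
  expect_identical(nrow(empty$nodes), 0L)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("hub rule: strictly above mean + 2 population sd", {
  # star K_{1,12}: only the centre is a hub
  net <- build_network(star_edges(12))
  ds <- detect_hubs(net)
  oracle <- hub_oracle(net$edges$node_a, net$edges$node_b, ds$node_id)
  expect_equal(attr(ds, "mean_degree"), 24 / 13, tolerance = 1e-12)
  expect_equal(attr(ds, "hub_threshold"), oracle$threshold, tolerance = 1e-12)
  expect_identical(ds$node_id[ds$hub], "hub0")
  expect_identical(ds$degree[ds$node_id == "hub0"], 12L)

  # complete graph: zero spread, threshold = mean, no hubs
  k5 <- t(combn(paste0("v", 1:5), 2))
  e5 <- data.frame(node_a = k5[, 1], node_b = k5[, 2], role_a = "gene",
                   role_b = "gene", r = 0.5, significant = TRUE,
                   source_run = "test")
  expect_false(any(detect_hubs(build_network(e5))$hub))

  # edgeless network: all degrees zero, no hubs
  iso <- build_network(e5[0, ],
                       nodes = data.frame(node_id = paste0("v", 1:4),
                                          role = "gene"))
  ds0 <- detect_hubs(iso)
  expect_identical(ds0$degree, rep(0L, 4))
  expect_false(any(ds0$hub))
})

test_that("hub detection is invariant under relabeling and edge order", {
  set.seed(20)
  e <- star_edges(8)
  e <- rbind(e, data.frame(node_a = "leaf01", node_b = "leaf02",
                           role_a = "gene", role_b = "gene", r = 0.4,
                           significant = TRUE, source_run = "test"))
  net <- build_network(e)
  ds <- detect_hubs(net)
  shuf <- e[sample(nrow(e)), ]
  ds2 <- detect_hubs(build_network(shuf))
  expect_identical(ds$hub[match(ds2$node_id, ds$node_id)], ds2$hub)
})

test_that("select_regulatory_edges keeps only evidence-bearing edges", {
  e <- star_edges(4)
  e <- rbind(e, data.frame(node_a = "leaf01", node_b = "leaf02",
                           role_a = "gene", role_b = "gene", r = 0.3,
                           significant = TRUE, source_run = "test"))
  net <- build_network(e)

  # no hubs / no RIF flags: nothing selected
  sel0 <- select_regulatory_edges(net)
  expect_identical(nrow(sel0$edges), 0L)
  expect_length(sel0$candidates, 0L)

  net$nodes["leaf01", "rif_significant"] <- TRUE
  sel <- select_regulatory_edges(net)
  # edges touching leaf01 kept (one flagged endpoint suffices), others not
  expect_true(all(sel$edges$node_a == "leaf01" |
                    sel$edges$node_b == "leaf01"))
  expect_identical(nrow(sel$edges), 2L)
  expect_setequal(sel$candidates, c("hub0", "leaf01", "leaf02"))

  # selection is idempotent: selecting from the kept subgraph changes nothing
  net2 <- net; net2$edges <- sel$edges
  expect_identical(select_regulatory_edges(net2)$edges, sel$edges)
})

test_that("integrate_with_degs runs expression-only PCIT over the union", {
  set.seed(21)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  base <- rnorm(n)
  expr <- rbind(corr1 = base + rnorm(n, sd = 0.4),
                corr2 = rnorm(n),
                deg1 = base + rnorm(n, sd = 0.4),   # planted DEG-regulator link
                deg2 = rnorm(n),
                other = rnorm(n))
  colnames(expr) <- ids
  net <- integrate_with_degs("tX", c("corr1", "corr2"), c("deg1", "deg2"),
                             expr)
  expect_true(all(c("corr1", "deg1") %in% net$nodes$node_id))
  expect_false("other" %in% net$nodes$node_id)
  key <- paste(pmin(net$edges$node_a, net$edges$node_b),
               pmax(net$edges$node_a, net$edges$node_b))
  expect_true("corr1 deg1" %in% key)   # planted correlation recovered

  # empty DEG list: union with nothing
  net0 <- integrate_with_degs("tX", c("corr1", "corr2", "deg2"),
                              character(0), expr)
  expect_setequal(unique(c(net0$edges$node_a, net0$edges$node_b)),
                  intersect(c("corr1", "corr2", "deg2"),
                            c(net0$edges$node_a, net0$edges$node_b)))

  expect_error(integrate_with_degs("tX", "corr1", "deg1", expr), "at least 3")
  expect_error(integrate_with_degs("tX", c("corr1", "ghost", "deg1"),
                                   character(0), expr), "ghost")
})

test_that("final_regulator_network marks RIF-incident edges", {
  set.seed(22)
  n <- 50
  ids <- sprintf("s%03d", 1:n)
  base <- rnorm(n)
  expr <- rbind(rsig = base + rnorm(n, sd = 0.3),
                g2 = base + rnorm(n, sd = 0.3),
                g3 = rnorm(n), g4 = rnorm(n))
  colnames(expr) <- ids
  rif <- list(overall = data.frame(candidate_id = "rsig", significant = TRUE))
  fin <- final_regulator_network(rownames(expr), expr, rif = rif,
                                 pathway_members = "g2")
  expect_true(fin$nodes["rsig", "rif_significant"])
  expect_true(fin$nodes["g2", "in_enriched_pathway"])
  touching <- fin$edges$node_a == "rsig" | fin$edges$node_b == "rsig"
  expect_identical(fin$edges$rif_marked, touching)

  # same node set: PCIT decisions identical to a direct integration round
  again <- final_regulator_network(rownames(expr), expr, rif = rif)
  key <- function(net) sort(paste(pmin(net$edges$node_a, net$edges$node_b),
                                  pmax(net$edges$node_a, net$edges$node_b)))
  expect_identical(key(again), key(fin))

  expect_error(final_regulator_network(c("rsig", "g2"), expr), "at least 3")
})

test_that("networks round-trip through their TSV representation", {
  e <- star_edges(5)
  att <- data.frame(feature_id = c("leaf01", "hub0"), kind = c("DEG", "TF"),
                    trait_id = c("tA", ""), direction = c("down", "none"))
  net <- flag_hubs(build_network(e, attributes = att,
                                 rif = list(tA = data.frame(
                                   candidate_id = "leaf02",
                                   significant = TRUE))))
  ep <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  write_network_tsv(net, ep, np)
  back <- read_network_tsv(ep, np)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges, ignore_attr = TRUE)
})

test_that("GraphML export produces a loadable graph", {
  skip_if_not_installed("igraph")
  net <- flag_hubs(build_network(star_edges(4)))
  p <- tempfile(fileext = ".graphml")
  write_network_graphml(net, p)
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 4)
})
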