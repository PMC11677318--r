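# Disease projection: first-neighbor sets, the shared-neighbor matrix
# against the double-loop oracle, dense-group mining.

proj_net <- function() {
  # dA and dB share {p1, DB00001}; dC shares nothing
  toy_net(dp = list(c("dA", "dA", "dB", "dC"), c("p1", "p2", "p1", "p9")),
          dd = list(c("DB00001", "DB00001"), c("dA", "dB")))
}

test_that("first neighbors are the adjacent proteins and drugs", {
  net <- proj_net()
  sub <- first_neighbor_subnetwork(net, "dA")
  expect_equal(sub$neighbor_ids, c("DB00001", "p1", "p2"))
  expect_error(first_neighbor_subnetwork(net, "p1"), "not a disease")
  expect_error(first_neighbor_subnetwork(net, "nope"), "unknown")
  # a disease node without edges has an empty neighbor set
  g <- igraph::make_empty_graph(1, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = "lonely")
  g <- igraph::set_vertex_attr(g, "category", value = "disease")
  expect_equal(first_neighbor_subnetwork(g, "lonely")$neighbor_ids,
               character())
})

test_that("shared-neighbor counts match set intersection", {
  net <- proj_net()
  w <- common_neighbor_matrix(net)
  expect_equal(w[["dA", "dB"]], 2L)
  expect_equal(w[["dA", "dC"]], 0L)
  expect_true(is.na(w[["dA", "dA"]]))
  expect_equal(unclass(w)[upper.tri(w)], t(unclass(w))[upper.tri(w)])
  expect_error(common_neighbor_matrix(net, "dA"), "at least two")
})

test_that("identical neighborhoods give the full weight, disjoint give zero", {
  net <- toy_net(dp = list(rep(c("dX", "dY"), each = 5),
                           rep(sprintf("p%d", 1:5), 2)))
  w <- common_neighbor_matrix(net, c("dX", "dY"))
  expect_equal(w[["dX", "dY"]], 5L)
})

test_that("the sparse cross-product projection equals the double-loop oracle", {
  dir <- synthetic_fixture_dir()
  dp <- read_disease_protein_associations(file.path(dir, "disease_protein.tsv"))
  ppi <- read_ppi_table(file.path(dir, "ppi.tsv"))
  drg <- read_drug_tables(file.path(dir, "drug_targets.tsv"),
                          file.path(dir, "drug_indications.tsv"))
  net <- build_network(dp$edges, ppi, drg$protein_drug, drg$disease_drug)
  w <- common_neighbor_matrix(net)
  oracle <- oracle_common_neighbors(net, rownames(w))
  expect_equal(unclass(w), oracle)
  # bound: w_ij <= min(deg_i, deg_j)
  deg <- igraph::degree(net, rownames(w))
  for (i in seq_len(nrow(w) - 1)) {
    for (j in (i + 1):nrow(w)) {
      expect_lte(w[i, j], min(deg[i], deg[j]))
    }
  }
})

test_that("adding a shared neighbor raises exactly one matrix entry by one", {
  net <- proj_net()
  w0 <- common_neighbor_matrix(net)
  net2 <- igraph::add_vertices(net, 1, name = "p_new",
                               category = "protein", roles = "",
                               display_name = "p_new")
  net2 <- igraph::add_edges(net2, c("dA", "p_new", "dB", "p_new"),
                            attr = list(type = "disease_protein"))
  w1 <- common_neighbor_matrix(net2)
  expect_equal(w1[["dA", "dB"]], w0[["dA", "dB"]] + 1L)
  w1r <- unclass(w1)
  w1r["dA", "dB"] <- w1r["dB", "dA"] <- unclass(w0)["dA", "dB"]
  expect_equal(w1r, unclass(w0))  # no other entry moved
})

test_that("the disease network drops zero weights but keeps all diseases", {
  m <- matrix(c(NA, 34, 16, 34, NA, 14, 16, 14, NA), 3, 3,
              dimnames = list(c("RA", "SA", "SLE"), c("RA", "SA", "SLE")))
  dn <- build_disease_network(m)
  expect_equal(igraph::ecount(dn), 3)
  expect_setequal(igraph::E(dn)$weight, c(34, 16, 14))
  z <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  dz <- build_disease_network(z)
  expect_equal(igraph::ecount(dz), 0)
  expect_equal(igraph::vcount(dz), 3)
  bad <- matrix(c(NA, 1, 2, NA), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(build_disease_network(bad), "symmetric")
  # round trip on positive entries
  back <- igraph::as_data_frame(dn, "edges")
  for (i in seq_len(nrow(back))) {
    expect_equal(back$weight[i], m[back$from[i], back$to[i]])
  }
})

test_that("dense groups are maximal cliques ranked by internal weight", {
  # a heavy triangle and a lighter 4-clique sharing no members
  ids <- c("t1", "t2", "t3", "q1", "q2", "q3", "q4", "leaf")
  m <- matrix(0L, 8, 8, dimnames = list(ids, ids))
  m["t1", "t2"] <- m["t2", "t1"] <- 30L
  m["t1", "t3"] <- m["t3", "t1"] <- 20L
  m["t2", "t3"] <- m["t3", "t2"] <- 25L
  for (i in 1:3) for (j in (i + 1):4) {
    m[paste0("q", i), paste0("q", j)] <- 5L
    m[paste0("q", j), paste0("q", i)] <- 5L
  }
  m["leaf", "t1"] <- m["t1", "leaf"] <- 2L
  diag(m) <- NA_integer_
  dn <- build_disease_network(m)
  groups <- find_dense_groups(dn, min_size = 3)
  expect_equal(length(groups), 2)
  expect_equal(groups[[1]]$members, c("t1", "t2", "t3"))  # min weight 20 > 5
  expect_equal(groups[[1]]$min_internal_weight, 20L)
  expect_equal(groups[[2]]$members, c("q1", "q2", "q3", "q4"))
  expect_equal(groups[[2]]$total_internal_weight, 30L)
})

test_that("clique mining agrees with exhaustive subset enumeration", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:14, 1)
    g <- igraph::sample_gnp(n, 0.45)
    igraph::V(g)$name <- sprintf("d%02d", seq_len(n))
    igraph::E(g)$weight <- sample(1:9, igraph::ecount(g), replace = TRUE)
    class(g) <- c("disease_net", class(g))
    got <- find_dense_groups(g, min_size = 3)
    got_sets <- sort(vapply(got, function(x) paste(x$members, collapse = "|"),
                            character(1)))
    want <- oracle_max_cliques(g, min_size = 3)
    want_sets <- sort(vapply(want, paste, character(1), collapse = "|"))
    expect_equal(got_sets, want_sets)
  }
})

test_that("trees yield no groups and complete graphs yield one", {
  tree <- igraph::make_tree(7, 2, mode = "undirected")
  igraph::V(tree)$name <- letters[1:7]
  igraph::E(tree)$weight <- 1
  expect_equal(length(find_dense_groups(tree, 3)), 0)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  igraph::E(k4)$weight <- 2
  g <- find_dense_groups(k4, 3)
  expect_equal(length(g), 1)
  expect_equal(g[[1]]$members, letters[1:4])
})

test_that("shared-neighbor reports partition common nodes by category and role", {
  dir <- synthetic_fixture_dir()
  gen <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                             simplifyVector = TRUE)
  dp <- read_disease_protein_associations(file.path(dir, "disease_protein.tsv"))
  ppi <- read_ppi_table(file.path(dir, "ppi.tsv"))
  drg <- read_drug_tables(file.path(dir, "drug_targets.tsv"),
                          file.path(dir, "drug_indications.tsv"))
  net <- build_network(dp$edges, ppi, drg$protein_drug, drg$disease_drug)
  pg <- gen$planted_groups
  for (i in seq_len(nrow(pg))) {
    rep <- shared_neighbor_report(net, unlist(pg$members[i]))
    expect_equal(rep$n_drugs, pg$shared_drugs[i])
    expect_equal(rep$n_amyloidogenic, pg$shared_proteins[i])
    expect_equal(rep$n_common, pg$weight[i])
  }
  # disjoint neighborhoods give an empty report
  net2 <- proj_net()
  r <- shared_neighbor_report(net2, c("dA", "dC"))
  expect_equal(r$n_common, 0)
  expect_error(shared_neighbor_report(net2, character()), "empty")
})
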