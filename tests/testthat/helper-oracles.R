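# Brute-force oracles, independent of the package's (igraph-backed)
# implementations: everything here works from a plain adjacency list with
# hand-rolled BFS / enumeration.

# named adjacency list (indices) from any igraph object
adj_of <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(x) sort(unique(x)))
}

oracle_dist_matrix <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

oracle_clustering <- function(g) {
  adj <- adj_of(g)
  local <- vapply(seq_along(adj), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(local)
}

oracle_cpl <- function(g) {
  D <- oracle_dist_matrix(adj_of(g))
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

oracle_diameter <- function(g) {
  D <- oracle_dist_matrix(adj_of(g))
  d <- D[upper.tri(D)]
  max(d[is.finite(d)])
}

# exhaustive enumeration of all shortest paths per pair (tiny graphs only)
oracle_betweenness <- function(g, normalized = TRUE) {
  adj <- adj_of(g)
  n <- length(adj)
  D <- oracle_dist_matrix(adj)
  score <- numeric(n)
  enumerate <- function(v, t) {
    if (v == t) return(list(t))
    out <- list()
    for (w in adj[[v]]) {
      if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1) {
        for (p in enumerate(w, t)) out[[length(out) + 1]] <- c(v, p)
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] == 0) next
      paths <- enumerate(s, t)
      inter <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inter) > 0) {
        tb <- table(inter)
        idx <- as.integer(names(tb))
        score[idx] <- score[idx] + as.numeric(tb) / length(paths)
      }
    }
  }
  if (normalized) score <- score / ((n - 1) * (n - 2) / 2)
  stats::setNames(score, igraph::V(g)$name)
}

# double-loop set-intersection projection oracle
oracle_common_neighbors <- function(net, disease_ids) {
  sets <- lapply(disease_ids, function(d) {
    nb <- igraph::neighbors(net, d)
    nb$name[nb$category != "disease"]
  })
  n <- length(disease_ids)
  W <- matrix(NA_integer_, n, n, dimnames = list(disease_ids, disease_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      W[i, j] <- W[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  W
}

# exhaustive maximal-clique enumeration by subset check (<= 15 nodes)
oracle_max_cliques <- function(g, min_size) {
  ids <- igraph::V(g)$name
  n <- length(ids)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  is_clique <- function(s) all(A[s, s] | diag(length(s)) == 1)
  cliques <- list()
  for (size in seq(min_size, n)) {
    for (comb in utils::combn(n, size, simplify = FALSE)) {
      if (is_clique(comb)) cliques[[length(cliques) + 1]] <- comb
    }
  }
  # keep maximal ones
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  lapply(cliques[keep], function(s) sort(ids[s]))
}

# deterministic random G(n, p) test graph
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}

# -- tiny fixture writers -------------------------------------------------

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

ppi_fixture <- function(a, b, score, organism = "9606",
                        path = tempfile(fileext = ".tsv")) {
  write_tsv_fixture(data.frame(protein_a = a, protein_b = b,
                               combined_score = score,
                               organism_tag = organism,
                               stringsAsFactors = FALSE), path)
}

dp_fixture <- function(disease, protein, role = "amyloidogenic",
                       path = tempfile(fileext = ".tsv")) {
  write_tsv_fixture(data.frame(disease_id = disease, uniprot_ac = protein,
                               role = role, stringsAsFactors = FALSE), path)
}

# a small heterogeneous network built from in-memory edge tables
toy_net <- function(dp = NULL, pp = NULL, pd = NULL, dd = NULL) {
  build_network(
    dp = if (is.null(dp)) NULL else
      data.frame(disease_id = dp[[1]], uniprot_ac = dp[[2]],
                 role = if (length(dp) > 2) dp[[3]] else "amyloidogenic",
                 stringsAsFactors = FALSE),
    pp = if (is.null(pp)) NULL else
      data.frame(protein_a = pp[[1]], protein_b = pp[[2]],
                 combined_score = if (length(pp) > 2) pp[[3]] else 0.95,
                 stringsAsFactors = FALSE),
    pd = if (is.null(pd)) NULL else
      data.frame(drugbank_id = pd[[1]], uniprot_ac = pd[[2]],
                 stringsAsFactors = FALSE),
    dd = if (is.null(dd)) NULL else
      data.frame(drugbank_id = dd[[1]], disease_id = dd[[2]],
                 stringsAsFactors = FALSE))
}

# shared default synthetic fixture, generated once per test run
synthetic_fixture_dir <- local({
  dir <- NULL
  function(seed = 4242) {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), sprintf("amylonet-fixture-%d", seed))
      generate_synthetic(synthetic_config(seed = seed), dir)
    }
    dir
  }
})
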