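# Topology: the parameter suite used to argue the network is biological —
# sparse, small-world, scale-free — plus the Erdos-Renyi null comparison.

#' Network density
#'
#' `2E / (N (N - 1))` for a simple undirected graph. Summaries print it to
#' three decimals; full precision is returned.
#'
#' @param net An igraph graph with at least two nodes.
#' @return Density in `[0, 1]`.
#' @export
net_density <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("density undefined for fewer than 2 nodes", call. = FALSE)
  2 * igraph::ecount(net) / (n * (n - 1))
}

#' Average clustering coefficient
#'
#' Mean of the local clustering coefficients over all nodes; nodes of degree
#' below 2 contribute 0 and are included in the average (NetworkAnalyzer
#' convention — this inclusion lowers the statistic relative to averaging
#' over eligible nodes only).
#'
#' @param net An igraph graph with at least one node.
#' @return Value in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  if (igraph::vcount(net) == 0) {
    stop("clustering undefined for an empty network", call. = FALSE)
  }
  igraph::transitivity(net, type = "localaverage", isolates = "zero")
}

#' Characteristic path length
#'
#' Mean shortest-path length over all connected node pairs; pairs in
#' different components are excluded (the network may legitimately hold
#' isolated components while still reporting a finite path length). Edges
#' are treated as unweighted.
#'
#' @param net An igraph graph with at least one edge.
#' @return Mean finite shortest-path length (>= 1).
#' @export
characteristic_path_length <- function(net) {
  if (igraph::ecount(net) == 0) {
    stop("characteristic path length undefined without edges", call. = FALSE)
  }
  igraph::mean_distance(net, directed = FALSE, unconnected = TRUE,
                        weights = NA)
}

#' Network diameter
#'
#' Longest finite shortest path (unweighted; infinite pairs excluded).
#'
#' @param net An igraph graph with at least one edge.
#' @return Integer diameter.
#' @export
net_diameter <- function(net) {
  if (igraph::ecount(net) == 0) {
    stop("diameter undefined without edges", call. = FALSE)
  }
  as.integer(igraph::diameter(net, directed = FALSE, unconnected = TRUE,
                              weights = NA))
}

#' Degree heterogeneity
#'
#' Coefficient of variation of the degree sequence:
#' `sqrt(population variance(k)) / mean(k)`. Zero for any k-regular graph;
#' large for hub-dominated degree distributions.
#'
#' @param net An igraph graph with at least one edge endpoint.
#' @return Non-negative real.
#' @export
heterogeneity <- function(net) {
  k <- igraph::degree(net)
  if (length(k) == 0 || all(k == 0)) {
    stop("heterogeneity undefined for an all-zero degree sequence",
         call. = FALSE)
  }
  m <- mean(k)
  sqrt(mean((k - m)^2)) / m
}

#' Full topological summary of a network
#'
#' Computes node/edge counts, density, average neighbors, heterogeneity,
#' clustering coefficient, characteristic path length, diameter, and (when
#' `fit = TRUE`) the power-law degree fit of [fit_degree_powerlaw()].
#'
#' @param net An igraph graph.
#' @param fit Fit the degree distribution (skipped for null replicates where
#'   only the geometric statistics are compared).
#' @return List of class `topology_summary`.
#' @export
topology_summary <- function(net, fit = TRUE) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  pl <- NULL
  if (isTRUE(fit)) {
    pl <- tryCatch(suppressWarnings(fit_degree_powerlaw(igraph::degree(net))),
                   error = function(e) NULL)
  }
  structure(list(
    n_nodes = n,
    n_edges = m,
    density = if (n >= 2) net_density(net) else NA_real_,
    avg_neighbors = if (n >= 1) 2 * m / n else NA_real_,
    heterogeneity = tryCatch(heterogeneity(net), error = function(e) NA_real_),
    clustering_coefficient = tryCatch(clustering_coefficient(net),
                                      error = function(e) NA_real_),
    characteristic_path_length = tryCatch(characteristic_path_length(net),
                                          error = function(e) NA_real_),
    diameter = tryCatch(net_diameter(net), error = function(e) NA_integer_),
    degree_exponent = if (!is.null(pl)) pl$gamma else NA_real_,
    powerlaw_coefficient = if (!is.null(pl)) pl$coefficient else NA_real_,
    xmin = if (!is.null(pl)) pl$xmin else NA_integer_,
    powerlaw_fit = pl
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("Topology: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  density                    %.3f\n", x$density))
  cat(sprintf("  avg neighbors              %.3f\n", x$avg_neighbors))
  cat(sprintf("  heterogeneity              %.3f\n", x$heterogeneity))
  cat(sprintf("  clustering coefficient     %.3f\n", x$clustering_coefficient))
  cat(sprintf("  characteristic path length %.3f\n",
              x$characteristic_path_length))
  cat(sprintf("  diameter                   %d\n", x$diameter))
  if (!is.na(x$degree_exponent)) {
    cat(sprintf("  degree exponent (MLE)      %.3f (xmin = %d)\n",
                x$degree_exponent, x$xmin))
    cat(sprintf("  log-log fit constant       %.2f\n",
                x$powerlaw_coefficient))
  }
  invisible(x)
}

#' Erdos-Renyi random reference comparison
#'
#' Generates `n_replicates` G(N, M) random graphs with the observed node and
#' edge counts, summarises each, and reports per-field mean and standard
#' deviation beside the observed summary. Fully reproducible from `seed`;
#' the caller's RNG state is restored on exit.
#'
#' @param net The observed igraph graph.
#' @param n_replicates Number of null replicates (>= 1; default 10).
#' @param seed Integer seed.
#' @param fit_observed Fit the observed degree distribution (default TRUE).
#' @return List of class `random_comparison`: `observed`, `null_mean`,
#'   `null_sd` (named numeric vectors over the geometric fields),
#'   `replicates`, `n_replicates`, `seed`.
#' @export
random_reference <- function(net, n_replicates = 10, seed = 1,
                             fit_observed = TRUE) {
  stopifnot(n_replicates >= 1)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  if (m > n * (n - 1) / 2) {
    stop("infeasible null model: more edges than a simple graph allows",
         call. = FALSE)
  }
  fields <- c("density", "avg_neighbors", "heterogeneity",
              "clustering_coefficient", "characteristic_path_length",
              "diameter")
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      topology_summary(igraph::sample_gnm(n, m), fit = FALSE)
    })
  })
  mat <- vapply(reps, function(s) {
    vapply(fields, function(f) as.numeric(s[[f]]), numeric(1))
  }, numeric(length(fields)))
  mat <- matrix(mat, nrow = length(fields), dimnames = list(fields, NULL))
  structure(list(
    observed = topology_summary(net, fit = fit_observed),
    null_mean = apply(mat, 1, mean),
    null_sd = apply(mat, 1, stats::sd),
    replicates = reps,
    n_replicates = n_replicates,
    seed = seed
  ), class = "random_comparison")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.random_comparison <- function(x, ...) {
  cat(sprintf("Random reference: %d Erdos-Renyi G(N=%d, M=%d) replicates (seed %d)\n",
              x$n_replicates, x$observed$n_nodes, x$observed$n_edges, x$seed))
  for (f in names(x$null_mean)) {
    cat(sprintf("  %-27s obs %.4f | null %.4f +/- %.4f\n", f,
                as.numeric(x$observed[[f]]), x$null_mean[[f]],
                x$null_sd[[f]]))
  }
  invisible(x)
}

#' Degree ranking within a node category
#'
#' Degrees of all nodes of one category, in descending order (ties broken by
#' ascending id), mirroring per-category hub tables (e.g. the best-connected
#' diseases are common, well-studied disorders whose neighbors are mostly
#' drugs).
#'
#' @param net A `hetero_net` graph.
#' @param category One of `"disease"`, `"protein"`, `"drug"`.
#' @return data.frame `id`, `degree`, sorted.
#' @export
degree_ranking <- function(net, category) {
  if (!category %in% c("disease", "protein", "drug")) {
    stop(sprintf("unknown node category '%s'", category), call. = FALSE)
  }
  ids <- node_ids_of(net, category)
  if (length(ids) == 0) {
    return(data.frame(id = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(net, v = ids)
  out <- data.frame(id = ids, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[radix_order(-out$degree, out$id), ]
  rownames(out) <- NULL
  out
}

#' Classify a network as sparse / small-world / scale-free
#'
#' Sparse: density below `sparse_max` (default 0.1). Small-world: observed
#' clustering at least `clustering_ratio_min` times the null-model mean AND
#' observed characteristic path length at most `cpl_ratio_max` times the
#' null mean (Watts-Strogatz style: far more clustered than random at
#' comparable path length). Scale-free: taken from the power-law fit flag of
#' the observed summary.
#'
#' @param summary A [topology_summary()] of the observed network.
#' @param comparison A [random_reference()] computed on the same network.
#' @param sparse_max Density threshold (default 0.1).
#' @param clustering_ratio_min Minimum observed/null clustering ratio
#'   (default 10).
#' @param cpl_ratio_max Maximum observed/null path-length ratio (default 1.5).
#' @return List with logical flags `sparse`, `small_world`, `scale_free`.
#' @export
classify_topology <- function(summary, comparison, sparse_max = 0.1,
                              clustering_ratio_min = 10,
                              cpl_ratio_max = 1.5) {
  stopifnot(inherits(summary, "topology_summary"),
            inherits(comparison, "random_comparison"))
  null_c <- comparison$null_mean[["clustering_coefficient"]]
  null_l <- comparison$null_mean[["characteristic_path_length"]]
  small_world <- isTRUE(
    summary$clustering_coefficient >= clustering_ratio_min * null_c &&
    summary$characteristic_path_length <= cpl_ratio_max * null_l)
  scale_free <- if (is.null(summary$powerlaw_fit)) NA else
    isTRUE(summary$powerlaw_fit$scale_free)
  list(sparse = isTRUE(summary$density < sparse_max),
       small_world = small_world,
       scale_free = scale_free)
}

#' Degree distribution table
#'
#' Empirical degree distribution (k, count, P(k)) over positive degrees,
#' suitable for external plotting of the scale-free fit.
#'
#' @param net An igraph graph.
#' @return data.frame `k`, `count`, `p_k`.
#' @export
degree_distribution_table <- function(net) {
  k <- igraph::degree(net)
  k <- k[k > 0]
  tab <- table(k)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab),
             p_k = as.integer(tab) / length(k))
}
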