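# Disease projection: collapse the heterogeneous network onto a weighted
# disease-disease graph where the weight is the number of shared first
# neighbors (proteins or drugs), then mine densely connected groups.

#' First-neighbor subnetwork of a disease
#'
#' The set of nodes directly adjacent to a disease: proteins via
#' disease-protein edges and drugs via disease-drug (indication) edges.
#' Disease nodes are never neighbors (diseases connect only through
#' protein/drug intermediates).
#'
#' @param net A `hetero_net` graph.
#' @param disease_id Id of a disease node.
#' @return List of class `disease_subnetwork`: `disease_id`, `neighbor_ids`
#'   (sorted character vector).
#' @export
first_neighbor_subnetwork <- function(net, disease_id) {
  idx <- match(disease_id, igraph::V(net)$name)
  if (is.na(idx)) {
    stop(sprintf("unknown node id '%s'", disease_id), call. = FALSE)
  }
  if (igraph::V(net)$category[idx] != "disease") {
    stop(sprintf("node '%s' is not a disease", disease_id), call. = FALSE)
  }
  nb <- igraph::neighbors(net, idx)
  keep <- nb$category != "disease"
  structure(list(disease_id = disease_id,
                 neighbor_ids = sort(nb$name[keep], method = "radix")),
            class = "disease_subnetwork")
}

disease_neighbor_sets <- function(net, disease_ids) {
  lapply(stats::setNames(disease_ids, disease_ids), function(d) {
    first_neighbor_subnetwork(net, d)$neighbor_ids
  })
}

#' Shared-first-neighbor count matrix between diseases
#'
#' The symmetric matrix `w[i, j]` of counts of nodes (proteins or drugs)
#' adjacent to both disease i and disease j. The diagonal is masked with NA
#' to prevent accidental self-edges downstream. Computed as a sparse
#' incidence cross-product over the disease rows of the adjacency matrix.
#'
#' @param net A `hetero_net` graph.
#' @param disease_ids Diseases to include; defaults to all disease nodes
#'   (sorted). At least two required.
#' @return Integer matrix with class `common_neighbor_matrix` and the
#'   disease ids as dimnames; `w[i, j] <= min(deg(i), deg(j))`.
#' @export
common_neighbor_matrix <- function(net, disease_ids = NULL) {
  if (is.null(disease_ids)) {
    disease_ids <- sort(node_ids_of(net, "disease"), method = "radix")
  }
  if (length(disease_ids) < 2) {
    stop("need at least two diseases to build the shared-neighbor matrix",
         call. = FALSE)
  }
  idx <- match(disease_ids, igraph::V(net)$name)
  if (anyNA(idx)) {
    stop(sprintf("unknown disease id(s): %s",
                 paste(disease_ids[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  if (any(igraph::V(net)$category[idx] != "disease")) {
    stop("all requested ids must be disease nodes", call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  non_disease <- igraph::V(net)$name[igraph::V(net)$category != "disease"]
  B <- A[disease_ids, non_disease, drop = FALSE]
  W <- as.matrix(Matrix::tcrossprod(B))
  storage.mode(W) <- "integer"
  dimnames(W) <- list(disease_ids, disease_ids)
  diag(W) <- NA_integer_
  class(W) <- c("common_neighbor_matrix", class(W))
  W
}

#' @export
print.common_neighbor_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("Shared-first-neighbor matrix: %d diseases, %d positive pairs (max weight %s)\n",
              nrow(x), sum(off > 0),
              if (length(off) > 0) max(off) else "-"))
  invisible(x)
}

#' Weighted disease-disease network from a shared-neighbor matrix
#'
#' One undirected edge per disease pair with positive shared-neighbor count;
#' zero-weight pairs are excluded. All diseases remain as nodes, so diseases
#' sharing nothing appear as singletons.
#'
#' @param w A [common_neighbor_matrix()] (or plain symmetric non-negative
#'   matrix with disease ids as dimnames; diagonal ignored).
#' @return igraph graph of class `disease_net` with edge attribute `weight`.
#' @export
build_disease_network <- function(w) {
  m <- unclass(w)
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m))) {
    stop("expected a square matrix with disease ids as dimnames",
         call. = FALSE)
  }
  chk <- m
  diag(chk) <- 0L
  chk[is.na(chk)] <- 0L
  if (!isSymmetric(unname(chk))) {
    stop("shared-neighbor matrix must be symmetric", call. = FALSE)
  }
  ids <- rownames(m)
  ut <- which(upper.tri(chk) & chk > 0, arr.ind = TRUE)
  edges <- data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                      weight = as.integer(chk[ut]),
                      stringsAsFactors = FALSE)
  edges <- edges[radix_order(edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  class(g) <- c("disease_net", class(g))
  g
}

#' @export
print.disease_net <- function(x, ...) {
  cat(sprintf("Weighted disease network: %d diseases, %d positive-weight edges\n",
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}

#' Find densely connected disease groups
#'
#' Enumerates all maximal cliques of at least `min_size` diseases in the
#' weighted disease network and ranks them by minimum internal edge weight
#' (descending), then total internal weight (descending), then member ids.
#' This formalises the visual identification of standout groups (a heavy
#' triangle, a fully interconnected set of six) as clique mining.
#'
#' @param disease_net A [build_disease_network()] graph.
#' @param min_size Minimum group size (default 3).
#' @return List of class `disease_groups`; each element has `members`
#'   (sorted ids), `min_internal_weight`, `total_internal_weight`,
#'   `weights` (named per-pair vector).
#' @export
find_dense_groups <- function(disease_net, min_size = 3) {
  g <- disease_net
  class(g) <- "igraph"
  cl <- igraph::max_cliques(g, min = min_size)
  groups <- lapply(cl, function(vs) {
    members <- sort(vs$name, method = "radix")
    sub <- igraph::induced_subgraph(g, members)
    ed <- igraph::as_data_frame(sub, what = "edges")
    pair <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "|")
    w <- stats::setNames(as.integer(ed$weight), pair)
    w <- w[radix_order(names(w))]
    list(members = members,
         min_internal_weight = min(w),
         total_internal_weight = sum(w),
         weights = w)
  })
  if (length(groups) > 0) {
    ord <- radix_order(
      -vapply(groups, `[[`, numeric(1), "min_internal_weight"),
      -vapply(groups, `[[`, numeric(1), "total_internal_weight"),
      vapply(groups, function(gr) paste(gr$members, collapse = "|"),
             character(1)))
    groups <- groups[ord]
  }
  structure(groups, class = "disease_groups")
}

#' @export
print.disease_groups <- function(x, ...) {
  cat(sprintf("Densely connected disease groups (maximal cliques): %d\n",
              length(x)))
  for (i in seq_along(utils::head(x, 10))) {
    gr <- x[[i]]
    cat(sprintf("  %d. {%s}  min w = %d, total w = %d\n", i,
                paste(gr$members, collapse = ", "),
                gr$min_internal_weight, gr$total_internal_weight))
  }
  invisible(x)
}

#' Categorised shared-neighbor report for a disease group
#'
#' Intersects the first-neighbor sets of all group members and partitions
#' the common nodes by category (drug / protein) and protein role
#' (amyloidogenic, co-deposited).
#'
#' @param net A `hetero_net` graph.
#' @param members Character vector of disease ids (non-empty).
#' @return List of class `shared_neighbor_report`: `members`, `common`
#'   (data.frame `id`, `category`, `roles`), and counts `n_common`,
#'   `n_drugs`, `n_proteins`, `n_amyloidogenic`, `n_co_deposited`.
#' @export
shared_neighbor_report <- function(net, members) {
  if (length(members) == 0) {
    stop("disease group must not be empty", call. = FALSE)
  }
  sets <- disease_neighbor_sets(net, members)
  common <- Reduce(intersect, sets)
  common <- sort(common, method = "radix")
  idx <- match(common, igraph::V(net)$name)
  df <- data.frame(id = common,
                   category = igraph::V(net)$category[idx],
                   roles = igraph::V(net)$roles[idx],
                   stringsAsFactors = FALSE)
  is_prot <- df$category == "protein"
  structure(list(
    members = sort(members, method = "radix"),
    common = df,
    n_common = nrow(df),
    n_drugs = sum(df$category == "drug"),
    n_proteins = sum(is_prot),
    n_amyloidogenic = sum(is_prot & has_role(net, df$id, "amyloidogenic")),
    n_co_deposited = sum(is_prot & has_role(net, df$id, "co_deposited"))
  ), class = "shared_neighbor_report")
}

#' @export
print.shared_neighbor_report <- function(x, ...) {
  cat(sprintf("Shared neighbors of {%s}: %d nodes\n",
              paste(x$members, collapse = ", "), x$n_common))
  cat(sprintf("  drugs: %d | proteins: %d (amyloidogenic %d, co-deposited %d)\n",
              x$n_drugs, x$n_proteins, x$n_amyloidogenic, x$n_co_deposited))
  invisible(x)
}

#' Write a shared-neighbor matrix as square TSV
#'
#' @param w A [common_neighbor_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(w, path) {
  m <- unclass(w)
  df <- data.frame(disease_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
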