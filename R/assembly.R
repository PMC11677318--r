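# Assembly: merge the four typed edge sets into one simple undirected
# heterogeneous graph (igraph backend) and report its components.

EDGE_TYPES <- c("disease_protein", "protein_protein", "protein_drug",
                "disease_drug")

#' Build the heterogeneous disease-protein-drug network
#'
#' Merges disease-protein, protein-protein, protein-drug and disease-drug
#' edge lists into one simple undirected graph. Nodes are created on first
#' sight with their category inferred from the edge slot; an id claimed by
#' two different categories is a hard consistency error (identifier
#' namespaces must never collide). Protein roles are the union of the
#' disease-association role tags plus `interactor` for proteins on PPI edges
#' and `drug_target` for targeted proteins. The result is order-invariant:
#' permuting the input rows yields an identical graph.
#'
#' @param dp data.frame `disease_id`, `uniprot_ac`, `role` (or NULL).
#' @param pp data.frame `protein_a`, `protein_b`, `combined_score` (or NULL).
#' @param pd data.frame `drugbank_id`, `uniprot_ac` (or NULL).
#' @param dd data.frame `drugbank_id`, `disease_id` (or NULL).
#' @return An [igraph][igraph::igraph-package] graph of class `hetero_net`
#'   with vertex attributes `category`, `roles` (comma-joined),
#'   `display_name` and edge attributes `type`, `score` (PPI confidence, NA
#'   elsewhere), `role` (disease-protein role tag, NA elsewhere).
#' @export
build_network <- function(dp = NULL, pp = NULL, pd = NULL, dd = NULL) {
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  ed <- list()
  if (!is.null(dp) && nrow(dp) > 0) {
    ed$dp <- empty(from = dp$disease_id, to = dp$uniprot_ac,
                   type = "disease_protein", score = NA_real_,
                   role = dp$role)
  }
  if (!is.null(pp) && nrow(pp) > 0) {
    a <- pmin(pp$protein_a, pp$protein_b)
    b <- pmax(pp$protein_a, pp$protein_b)
    ed$pp <- empty(from = a, to = b, type = "protein_protein",
                   score = as.numeric(pp$combined_score),
                   role = NA_character_)
  }
  if (!is.null(pd) && nrow(pd) > 0) {
    ed$pd <- empty(from = pd$uniprot_ac, to = pd$drugbank_id,
                   type = "protein_drug", score = NA_real_,
                   role = NA_character_)
  }
  if (!is.null(dd) && nrow(dd) > 0) {
    ed$dd <- empty(from = dd$disease_id, to = dd$drugbank_id,
                   type = "disease_drug", score = NA_real_,
                   role = NA_character_)
  }
  edges <- if (length(ed) > 0) do.call(rbind, ed) else {
    empty(from = character(), to = character(), type = character(),
          score = numeric(), role = character())
  }
  if (any(edges$from == edges$to)) {
    stop("self-edge in input (same id on both endpoints)", call. = FALSE)
  }
  # collapse duplicate (pair, type); endpoint categories determine the type,
  # so pair uniqueness per type is pair uniqueness overall
  key <- paste(edges$from, edges$to, edges$type, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[radix_order(edges$type, edges$from, edges$to), , drop = FALSE]

  # category claims per endpoint slot
  slot <- function(ids, cat) {
    data.frame(id = ids, category = rep(cat, length(ids)),
               stringsAsFactors = FALSE)
  }
  claim <- rbind(
    slot(edges$from[edges$type == "disease_protein"], "disease"),
    slot(edges$to[edges$type == "disease_protein"], "protein"),
    slot(edges$from[edges$type == "protein_protein"], "protein"),
    slot(edges$to[edges$type == "protein_protein"], "protein"),
    slot(edges$from[edges$type == "protein_drug"], "protein"),
    slot(edges$to[edges$type == "protein_drug"], "drug"),
    slot(edges$from[edges$type == "disease_drug"], "disease"),
    slot(edges$to[edges$type == "disease_drug"], "drug"))
  claim <- unique(claim)
  dup <- claim$id[duplicated(claim$id)]
  if (length(dup) > 0) {
    stop(sprintf(
      "node id(s) used under conflicting categories (corrupt input?): %s",
      paste(sort(unique(dup), method = "radix"), collapse = ", ")),
      call. = FALSE)
  }
  claim <- claim[radix_order(claim$id), , drop = FALSE]

  # protein role union: disease-association tags + interactor + drug_target
  role_tags <- list()
  dp_e <- edges[edges$type == "disease_protein", , drop = FALSE]
  if (nrow(dp_e) > 0) {
    role_tags$assoc <- empty(id = dp_e$to, role = dp_e$role)
  }
  pp_ids <- unique(c(edges$from[edges$type == "protein_protein"],
                     edges$to[edges$type == "protein_protein"]))
  if (length(pp_ids) > 0) role_tags$pp <- empty(id = pp_ids, role = "interactor")
  tgt_ids <- unique(edges$from[edges$type == "protein_drug"])
  if (length(tgt_ids) > 0) {
    role_tags$pd <- empty(id = tgt_ids, role = "drug_target")
  }
  roles <- rep("", nrow(claim))
  names(roles) <- claim$id
  if (length(role_tags) > 0) {
    rt <- do.call(rbind, role_tags)
    rt$role <- as.character(rt$role)
    per_id <- vapply(split(rt$role, rt$id), function(r) {
      paste(sort(unique(unlist(strsplit(r, ",", fixed = TRUE))),
                 method = "radix"), collapse = ",")
    }, character(1))
    roles[names(per_id)] <- per_id
  }
  vertices <- empty(name = claim$id, category = claim$category,
                    roles = unname(roles), display_name = claim$id)

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  class(g) <- c("hetero_net", class(g))
  g
}

node_categories <- function(net) {
  stats::setNames(igraph::V(net)$category, igraph::V(net)$name)
}

node_ids_of <- function(net, category) {
  igraph::V(net)$name[igraph::V(net)$category == category]
}

has_role <- function(net, ids, role) {
  roles <- igraph::V(net)$roles[match(ids, igraph::V(net)$name)]
  vapply(strsplit(roles, ",", fixed = TRUE), function(r) role %in% r,
         logical(1))
}

#' @export
print.hetero_net <- function(x, ...) {
  cat <- base::cat
  tab <- table(igraph::V(x)$category)
  etab <- table(igraph::E(x)$type)
  cat(sprintf("Heterogeneous disease-protein-drug network: %d nodes, %d edges\n",
              igraph::vcount(x), igraph::ecount(x)))
  cat("  nodes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  edges:", paste(sprintf("%s=%d", names(etab), etab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Connected components of the heterogeneous network
#'
#' Standard undirected components, with sizes in descending order and the
#' list of diseases falling outside the largest component (diseases that do
#' not share any connection with the main body of the network).
#'
#' @param net A `hetero_net` graph (any igraph works).
#' @return List of class `component_report`: `component_count`,
#'   `component_sizes` (descending), `isolated_disease_ids`.
#' @export
connected_components_report <- function(net) {
  if (igraph::vcount(net) == 0) {
    return(structure(list(component_count = 0L, component_sizes = integer(),
                          isolated_disease_ids = character()),
                     class = "component_report"))
  }
  comp <- igraph::components(net)
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  main <- which.max(comp$csize)
  is_dis <- igraph::V(net)$category == "disease"
  iso <- igraph::V(net)$name[is_dis & comp$membership != main]
  structure(list(component_count = comp$no,
                 component_sizes = sizes,
                 isolated_disease_ids = sort(iso, method = "radix")),
            class = "component_report")
}

#' @export
print.component_report <- function(x, ...) {
  cat(sprintf("Components: %d (sizes: %s)\n", x$component_count,
              paste(utils::head(x$component_sizes, 10), collapse = ", ")))
  if (length(x$isolated_disease_ids) > 0) {
    cat("Diseases outside the largest component:",
        paste(x$isolated_disease_ids, collapse = ", "), "\n")
  } else {
    cat("All diseases lie in the largest component.\n")
  }
  invisible(x)
}

#' Write a network to GraphML (Cytoscape-compatible)
#'
#' @param net An igraph graph.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- net
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a flat edge-list TSV
#'
#' Columns: `from`, `to`, plus every edge attribute present (`type`,
#' `score`, `role`, `weight`).
#'
#' @param net An igraph graph.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edge_tsv <- function(net, path) {
  df <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
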