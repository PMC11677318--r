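# Drug repurposing: betweenness-ranked candidates among drugs that target
# amyloidogenic proteins without an existing indication link to the
# corresponding diseases, plus two-hop context subnetworks.

#' Betweenness centrality table
#'
#' Exact shortest-path betweenness (Brandes algorithm) over the
#' heterogeneous network, all edge types treated as unweighted. Normalised
#' values divide by `(N - 1)(N - 2) / 2` (undirected); with fewer than three
#' nodes the normalised table is all zeros by convention.
#'
#' @param net An igraph graph.
#' @param normalized Normalise to `[0, 1]` (default TRUE).
#' @return data.frame `node_id`, `category` (if present), `betweenness`,
#'   sorted descending (ties by id).
#' @export
betweenness_table <- function(net, normalized = TRUE) {
  n <- igraph::vcount(net)
  if (n == 0) {
    return(data.frame(node_id = character(), betweenness = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (normalized && n < 3) {
    b <- stats::setNames(rep(0, n), igraph::V(net)$name)
  } else {
    b <- igraph::betweenness(net, directed = FALSE, weights = NA,
                             normalized = normalized)
  }
  out <- data.frame(node_id = igraph::V(net)$name,
                    betweenness = as.numeric(b),
                    stringsAsFactors = FALSE)
  if (!is.null(igraph::V(net)$category)) {
    out$category <- igraph::V(net)$category
    out <- out[, c("node_id", "category", "betweenness")]
  }
  out <- out[radix_order(-out$betweenness, out$node_id), ]
  rownames(out) <- NULL
  out
}

#' Filter drugs to repurposing candidates
#'
#' A drug is a candidate when (a) it targets at least one amyloidogenic
#' protein, and (b) at least one disease linked to such a target has no
#' existing indication edge to the drug; `candidate_diseases` lists every
#' (b)-qualifying disease. Filter (c), the stand-in for a manual literature
#' screen, is a user-supplied exclusion list: drugs passing (a) and (b) but
#' listed there are returned with `excluded_by_list = TRUE` as a pass/fail
#' record, and [rank_candidates()] drops them.
#'
#' @param net A `hetero_net` graph built with role tags.
#' @param exclusion_list Character vector of DrugBank ids to screen out.
#' @return data.frame of class `repurposing_candidates`: `drug_id`,
#'   `amyloidogenic_targets` and `candidate_diseases` (comma-joined, sorted),
#'   `excluded_by_list`.
#' @export
candidate_filter <- function(net, exclusion_list = character()) {
  drugs <- node_ids_of(net, "drug")
  rows <- lapply(drugs, function(drug) {
    nb <- igraph::neighbors(net, drug)
    targets <- nb$name[nb$category == "protein"]
    targets <- targets[has_role(net, targets, "amyloidogenic")]
    if (length(targets) == 0) return(NULL)
    linked_dis <- unique(unlist(lapply(targets, function(p) {
      pn <- igraph::neighbors(net, p)
      pn$name[pn$category == "disease"]
    })))
    indicated <- nb$name[nb$category == "disease"]
    cand_dis <- setdiff(linked_dis, indicated)
    if (length(cand_dis) == 0) return(NULL)
    data.frame(
      drug_id = drug,
      amyloidogenic_targets = paste(sort(targets, method = "radix"),
                                    collapse = ","),
      candidate_diseases = paste(sort(cand_dis, method = "radix"),
                                 collapse = ","),
      excluded_by_list = drug %in% exclusion_list,
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(drug_id = character(), amyloidogenic_targets = character(),
               candidate_diseases = character(),
               excluded_by_list = logical(), stringsAsFactors = FALSE)
  }
  out <- out[radix_order(out$drug_id), ]
  rownames(out) <- NULL
  class(out) <- c("repurposing_candidates", class(out))
  out
}

#' Rank repurposing candidates by betweenness centrality
#'
#' Drops candidates flagged by the exclusion list, joins the betweenness
#' table, and sorts by betweenness descending (ties by drug id ascending),
#' recording the rank. A bridging drug — one lying on many shortest paths
#' between otherwise distant parts of the network — ranks first.
#'
#' @param candidates A [candidate_filter()] result.
#' @param centrality A [betweenness_table()] computed on the same network.
#' @return data.frame of class `ranked_candidates` with columns of
#'   `candidates` plus `betweenness` and `rank`.
#' @export
rank_candidates <- function(candidates, centrality) {
  cand <- candidates[!candidates$excluded_by_list, , drop = FALSE]
  miss <- setdiff(cand$drug_id, centrality$node_id)
  if (length(miss) > 0) {
    stop(sprintf("candidate drug(s) missing from the centrality table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cand$betweenness <- centrality$betweenness[
    match(cand$drug_id, centrality$node_id)]
  cand <- cand[radix_order(-cand$betweenness, cand$drug_id), , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  class(cand) <- c("ranked_candidates", "data.frame")
  cand
}

#' @export
print.ranked_candidates <- function(x, ...) {
  cat(sprintf("Repurposing candidates: %d drugs ranked by betweenness\n",
              nrow(x)))
  top <- utils::head(x, 10)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %s  b = %.4g  targets [%s]  diseases [%s]\n",
                top$rank[i], top$drug_id[i], top$betweenness[i],
                top$amyloidogenic_targets[i], top$candidate_diseases[i]))
  }
  invisible(x)
}

#' Two-hop context subnetwork around a drug
#'
#' Induced subgraph on all nodes within two edges of the drug. Optional
#' medium-confidence PPI edges (scores in `[0.700, 0.900)`, below the main
#' network's floor) are layered in first and tagged `tier = "medium"`
#' (edges of the main network are `tier = "high"`), so a medium edge can
#' pull a second disease module into view. Medium edges are display/context
#' only — they never enter centrality or projection, which operate on the
#' main network.
#'
#' @param net A `hetero_net` graph.
#' @param drug_id Id of a drug node.
#' @param medium_ppi Optional data.frame `protein_a`, `protein_b`,
#'   `combined_score` with scores in `[0.700, 0.900)`.
#' @return igraph graph of class `context_subnetwork` with graph attribute
#'   `center` and edge attribute `tier`.
#' @export
context_subnetwork <- function(net, drug_id, medium_ppi = NULL) {
  idx <- match(drug_id, igraph::V(net)$name)
  if (is.na(idx) || igraph::V(net)$category[idx] != "drug") {
    stop(sprintf("'%s' is not a drug node of the network", drug_id),
         call. = FALSE)
  }
  g <- net
  class(g) <- "igraph"
  igraph::E(g)$tier <- "high"
  if (!is.null(medium_ppi) && nrow(medium_ppi) > 0) {
    s <- as.numeric(medium_ppi$combined_score)
    if (any(s < 0.700 | s >= 0.900)) {
      stop("medium-confidence edge score outside [0.700, 0.900)",
           call. = FALSE)
    }
    new_prot <- setdiff(unique(c(medium_ppi$protein_a, medium_ppi$protein_b)),
                        igraph::V(g)$name)
    if (length(new_prot) > 0) {
      g <- igraph::add_vertices(g, length(new_prot), name = new_prot,
                                category = "protein", roles = "interactor",
                                display_name = new_prot)
    }
    g <- igraph::add_edges(
      g, rbind(medium_ppi$protein_a, medium_ppi$protein_b),
      attr = list(type = "protein_protein", score = s, tier = "medium"))
  }
  ctx <- igraph::make_ego_graph(g, order = 2, nodes = drug_id)[[1]]
  ctx <- igraph::set_graph_attr(ctx, "center", drug_id)
  class(ctx) <- c("context_subnetwork", class(ctx))
  ctx
}

#' @export
print.context_subnetwork <- function(x, ...) {
  tiers <- table(igraph::E(x)$tier)
  cat(sprintf("Two-hop context of %s: %d nodes, %d edges (%s)\n",
              igraph::graph_attr(x, "center"), igraph::vcount(x),
              igraph::ecount(x),
              paste(sprintf("%s=%d", names(tiers), tiers), collapse = ", ")))
  invisible(x)
}
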