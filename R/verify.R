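# End-to-end verification of a pipeline run against generator ground truth.

#' Verify the pipeline against synthetic ground truth
#'
#' Runs the full pipeline (ingest, assembly, components, disease projection,
#' dense-group discovery, candidate filtering and ranking) on a generated
#' fixture directory and compares every stage's output with the recorded
#' ground truth: node/edge counts, per-filter drop counts, planted group
#' memberships with exact weights, isolated diseases, and the planted
#' candidate's top rank. Any mismatch is itemised rather than raised.
#'
#' @param dir Fixture directory written by [generate_synthetic()].
#' @param ground_truth Ground-truth list; read from
#'   `dir/ground_truth.json` when NULL.
#' @return data.frame of class `pipeline_verification` with columns
#'   `check`, `expected`, `observed`, `pass`; attribute `pass` is the
#'   overall conjunction.
#' @export
verify_pipeline <- function(dir, ground_truth = NULL) {
  if (is.null(ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    if (!file.exists(gt_path)) {
      return(verification_result(data.frame(
        check = "ground_truth_file", expected = gt_path,
        observed = "missing", pass = FALSE, stringsAsFactors = FALSE)))
    }
    ground_truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  gt <- ground_truth
  rows <- list()
  add <- function(check, expected, observed, pass = NULL) {
    if (is.null(pass)) pass <- identical(as.character(expected),
                                         as.character(observed))
    rows[[length(rows) + 1]] <<- data.frame(
      check = check,
      expected = paste(expected, collapse = ","),
      observed = paste(observed, collapse = ","),
      pass = pass, stringsAsFactors = FALSE)
  }

  dp <- read_disease_protein_associations(
    file.path(dir, "disease_protein.tsv"), dialect = "tsv")
  ppi <- read_ppi_table(file.path(dir, "ppi.tsv"))
  drg <- read_drug_tables(file.path(dir, "drug_targets.tsv"),
                          file.path(dir, "drug_indications.tsv"))

  add("dp_duplicate_drops", gt$ingest_drops$dp$duplicate,
      drop_counts(dp$edges)$duplicate)
  ppi_drops <- drop_counts(ppi)
  for (f in c("self_loop", "score", "organism", "duplicate", "cap")) {
    add(paste0("ppi_", f, "_drops"), gt$ingest_drops$ppi[[f]],
        ppi_drops[[f]])
  }
  add("target_excluded_drops", gt$ingest_drops$targets$excluded,
      drop_counts(drg$protein_drug)$excluded)
  add("target_duplicate_drops", gt$ingest_drops$targets$duplicate,
      drop_counts(drg$protein_drug)$duplicate)
  add("indication_duplicate_drops", gt$ingest_drops$indications$duplicate,
      drop_counts(drg$disease_drug)$duplicate)

  net <- build_network(dp = dp$edges, pp = ppi, pd = drg$protein_drug,
                       dd = drg$disease_drug)
  add("n_nodes", gt$counts$n_nodes, igraph::vcount(net))
  add("n_edges", gt$counts$n_edges, igraph::ecount(net))
  cats <- table(igraph::V(net)$category)
  add("n_diseases", gt$counts$n_diseases, as.integer(cats[["disease"]]))
  add("n_proteins", gt$counts$n_proteins, as.integer(cats[["protein"]]))
  add("n_drugs", gt$counts$n_drugs, as.integer(cats[["drug"]]))
  etab <- table(igraph::E(net)$type)
  add("n_dp_edges", gt$counts$n_dp_edges,
      as.integer(etab[["disease_protein"]]))
  add("n_pp_edges", gt$counts$n_pp_edges,
      as.integer(etab[["protein_protein"]]))
  add("n_pd_edges", gt$counts$n_pd_edges, as.integer(etab[["protein_drug"]]))
  add("n_dd_edges", gt$counts$n_dd_edges, as.integer(etab[["disease_drug"]]))

  comp <- connected_components_report(net)
  add("isolated_diseases",
      sort(unlist(gt$isolated_diseases), method = "radix"),
      comp$isolated_disease_ids,
      pass = setequal(unlist(gt$isolated_diseases),
                      comp$isolated_disease_ids))

  w <- common_neighbor_matrix(net)
  dnet <- build_disease_network(w)
  groups <- find_dense_groups(dnet, min_size = 3)
  group_key <- vapply(groups, function(g) paste(g$members, collapse = "|"),
                      character(1))
  pg <- gt$planted_groups
  if (is.data.frame(pg)) {  # jsonlite simplification
    pg <- lapply(seq_len(nrow(pg)), function(i) {
      list(members = unlist(pg$members[i]), weight = pg$weight[i])
    })
  }
  for (i in seq_along(pg)) {
    members <- sort(unlist(pg[[i]]$members), method = "radix")
    key <- paste(members, collapse = "|")
    hit <- match(key, group_key)
    if (is.na(hit)) {
      add(sprintf("planted_group_%d_recovered", i), key, "absent",
          pass = FALSE)
    } else {
      add(sprintf("planted_group_%d_recovered", i), key, key, pass = TRUE)
      ws <- groups[[hit]]$weights
      add(sprintf("planted_group_%d_weights", i),
          paste(rep(pg[[i]]$weight, length(ws)), collapse = ","),
          paste(unname(ws), collapse = ","),
          pass = all(ws == pg[[i]]$weight))
    }
  }

  cent <- betweenness_table(net)
  cand <- candidate_filter(net)
  ranked <- rank_candidates(cand, cent)
  add("top_candidate", gt$candidate$drug_id,
      if (nrow(ranked) > 0) ranked$drug_id[1] else "none")
  hit <- match(gt$candidate$drug_id, ranked$drug_id)
  if (!is.na(hit)) {
    add("candidate_diseases",
        paste(sort(unlist(gt$candidate$diseases), method = "radix"),
              collapse = ","),
        ranked$candidate_diseases[hit])
    add("candidate_targets",
        paste(sort(unlist(gt$candidate$targets), method = "radix"),
              collapse = ","),
        ranked$amyloidogenic_targets[hit])
  } else {
    add("candidate_present", gt$candidate$drug_id, "absent", pass = FALSE)
  }

  verification_result(do.call(rbind, rows))
}

verification_result <- function(df) {
  rownames(df) <- NULL
  structure(df, pass = all(df$pass),
            class = c("pipeline_verification", "data.frame"))
}

#' @export
print.pipeline_verification <- function(x, ...) {
  ok <- attr(x, "pass")
  cat(sprintf("Pipeline verification: %d/%d checks passed — %s\n",
              sum(x$pass), nrow(x), if (ok) "PASS" else "FAIL"))
  bad <- x[!x$pass, , drop = FALSE]
  for (i in seq_len(nrow(bad))) {
    cat(sprintf("  FAIL %s: expected %s, observed %s\n", bad$check[i],
                bad$expected[i], bad$observed[i]))
  }
  invisible(x)
}
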