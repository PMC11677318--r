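# Orchestration: a validated configuration object and a staged runner that
# chains ingest -> assembly -> topology -> projection -> repurposing,
# writing standard-format artifacts with a reconciling stage log.

#' Pipeline configuration
#'
#' Validates paths and thresholds for [run_pipeline()]. The confidence
#' floors must satisfy `0 <= medium_score < min_score <= 1`: the main
#' network is built at the high-confidence floor and medium-confidence
#' interactions only ever appear as a context layer.
#'
#' @param dp_path,ppi_path,targets_path,indications_path Input files.
#' @param out_dir Output directory for artifacts.
#' @param dialect Disease-protein dialect, `"tsv"` or `"xml"`.
#' @param min_score High-confidence PPI floor (default 0.900).
#' @param medium_score Medium-confidence floor for context layers (default
#'   0.700).
#' @param max_neighbors Per-protein PPI partner cap (default 100).
#' @param human_only Drop non-human PPI rows (default TRUE).
#' @param excluded_drugs Drug-id blocklist (default [metal_drug_ids()]).
#' @param exclusion_list Candidate screen (filter (c)) drug ids.
#' @param null_replicates Random-reference replicates (default 10).
#' @param seed Seed for the null model.
#' @param group_min_size Minimum dense-group size (default 3).
#' @param top_k Candidates reported (default 20).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dp_path, ppi_path, targets_path,
                            indications_path, out_dir,
                            dialect = c("tsv", "xml"),
                            min_score = 0.900, medium_score = 0.700,
                            max_neighbors = 100, human_only = TRUE,
                            excluded_drugs = metal_drug_ids(),
                            exclusion_list = character(),
                            null_replicates = 10, seed = 1,
                            group_min_size = 3, top_k = 20) {
  dialect <- match.arg(dialect)
  if (!(is.numeric(min_score) && is.numeric(medium_score) &&
        medium_score >= 0 && medium_score < min_score && min_score <= 1)) {
    stop("invalid thresholds: need 0 <= medium_score < min_score <= 1",
         call. = FALSE)
  }
  stopifnot(max_neighbors >= 1, null_replicates >= 1, group_min_size >= 2,
            top_k >= 1)
  for (p in c(dp_path, ppi_path, targets_path, indications_path)) {
    if (!file.exists(p)) stop(sprintf("input not found: '%s'", p),
                              call. = FALSE)
  }
  structure(list(dp_path = dp_path, ppi_path = ppi_path,
                 targets_path = targets_path,
                 indications_path = indications_path, out_dir = out_dir,
                 dialect = dialect, min_score = min_score,
                 medium_score = medium_score, max_neighbors = max_neighbors,
                 human_only = human_only, excluded_drugs = excluded_drugs,
                 exclusion_list = exclusion_list,
                 null_replicates = null_replicates, seed = seed,
                 group_min_size = group_min_size, top_k = top_k),
            class = "pipeline_config")
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Chains the stages on the configured inputs and writes artifacts to
#' `config$out_dir`: edge lists and GraphML of the heterogeneous network, a
#' JSON component report, a JSON topology report with null comparison and
#' classification flags, per-category degree tables, the shared-neighbor
#' matrix, the weighted disease network, a JSON dense-group report, and a
#' JSON ranked-candidate report. Each stage logs records in / dropped per
#' rule / records out (the sums reconcile), to stderr and to `run.log`; the
#' resolved configuration and package version are written for provenance.
#'
#' @param config A [pipeline_config()].
#' @param stage One of `"all"`, `"build"`, `"topology"`, `"project"`,
#'   `"repurpose"` (later stages imply the build).
#' @return Invisibly, a list with the computed objects (`net`,
#'   `components`, and stage outputs).
#' @export
run_pipeline <- function(config, stage = c("all", "build", "topology",
                                           "project", "repurpose")) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "at")
  on.exit(close(log_con), add = TRUE)
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    writeLines(line, log_con)
  }
  t0 <- Sys.time()

  # provenance: resolved config + tool version
  cfg_lines <- c(sprintf("amylonet_version = %s",
                         as.character(utils::packageVersion("amylonet"))),
                 vapply(names(config), function(k) {
                   sprintf("%s = %s", k,
                           paste(format(config[[k]]), collapse = ","))
                 }, character(1)))
  write_atomic(function(p) writeLines(cfg_lines, p),
               file.path(config$out_dir, "resolved_config.txt"))

  out <- list()

  # -- ingest + build ----------------------------------------------------
  dp <- read_disease_protein_associations(config$dp_path, config$dialect)
  d <- drop_counts(dp$edges)
  logf("ingest dp: %d records in, %d duplicate dropped, %d out",
       nrow(dp$edges) + d$duplicate, d$duplicate, nrow(dp$edges))
  ppi <- read_ppi_table(config$ppi_path, min_score = config$min_score,
                        max_neighbors = config$max_neighbors,
                        human_only = config$human_only)
  d <- drop_counts(ppi)
  logf(paste("ingest ppi: %d records in, dropped self_loop=%d score=%d",
             "organism=%d duplicate=%d cap=%d, %d out"),
       nrow(ppi) + sum(unlist(d)), d$self_loop, d$score, d$organism,
       d$duplicate, d$cap, nrow(ppi))
  drg <- read_drug_tables(config$targets_path, config$indications_path,
                          excluded_drugs = config$excluded_drugs)
  for (nm in names(drg)) {
    d <- drop_counts(drg[[nm]])
    logf("ingest %s: %d records in, dropped excluded=%d duplicate=%d, %d out",
         nm, nrow(drg[[nm]]) + sum(unlist(d)), d$excluded, d$duplicate,
         nrow(drg[[nm]]))
  }

  net <- build_network(dp = dp$edges, pp = ppi, pd = drg$protein_drug,
                       dd = drg$disease_drug)
  out$net <- net
  comp <- connected_components_report(net)
  out$components <- comp
  logf("assembly: %d nodes, %d edges, %d components",
       igraph::vcount(net), igraph::ecount(net), comp$component_count)
  write_atomic(function(p) write_graphml(net, p),
               file.path(config$out_dir, "network.graphml"))
  write_atomic(function(p) write_edge_tsv(net, p),
               file.path(config$out_dir, "network_edges.tsv"))
  write_atomic(function(p) {
    jsonlite::write_json(unclass(comp), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, file.path(config$out_dir, "components.json"))

  # -- topology ----------------------------------------------------------
  if (stage %in% c("all", "topology")) {
    summ <- topology_summary(net)
    cmpn <- random_reference(net, n_replicates = config$null_replicates,
                             seed = config$seed, fit_observed = FALSE)
    flags <- classify_topology(summ, cmpn)
    report <- list(
      observed = unclass(summ[setdiff(names(summ), "powerlaw_fit")]),
      null_mean = as.list(cmpn$null_mean),
      null_sd = as.list(cmpn$null_sd),
      n_replicates = cmpn$n_replicates, seed = cmpn$seed,
      classification = flags)
    write_atomic(function(p) {
      jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }, file.path(config$out_dir, "topology.json"))
    for (categ in c("disease", "protein", "drug")) {
      write_atomic(function(p) {
        utils::write.table(degree_ranking(net, categ), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }, file.path(config$out_dir, sprintf("degrees_%s.tsv", categ)))
    }
    write_atomic(function(p) {
      utils::write.table(degree_distribution_table(net), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }, file.path(config$out_dir, "degree_distribution.tsv"))
    out$topology <- summ
    out$null_comparison <- cmpn
    out$classification <- flags
    logf("topology: density=%.4f clustering=%.4f cpl=%.3f sparse=%s small_world=%s",
         summ$density, summ$clustering_coefficient,
         summ$characteristic_path_length, flags$sparse, flags$small_world)
  }

  # -- disease projection ------------------------------------------------
  if (stage %in% c("all", "project")) {
    w <- common_neighbor_matrix(net)
    dnet <- build_disease_network(w)
    groups <- find_dense_groups(dnet, min_size = config$group_min_size)
    write_atomic(function(p) write_matrix_tsv(w, p),
                 file.path(config$out_dir, "common_neighbors.tsv"))
    write_atomic(function(p) write_edge_tsv(dnet, p),
                 file.path(config$out_dir, "disease_network.tsv"))
    write_atomic(function(p) write_graphml(dnet, p),
                 file.path(config$out_dir, "disease_network.graphml"))
    grp_json <- lapply(groups, function(g) {
      rep <- shared_neighbor_report(net, g$members)
      list(members = g$members,
           min_internal_weight = g$min_internal_weight,
           total_internal_weight = g$total_internal_weight,
           shared = list(drugs = rep$n_drugs, proteins = rep$n_proteins,
                         amyloidogenic = rep$n_amyloidogenic,
                         co_deposited = rep$n_co_deposited))
    })
    write_atomic(function(p) {
      jsonlite::write_json(grp_json, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }, file.path(config$out_dir, "disease_groups.json"))
    out$common_neighbors <- w
    out$disease_network <- dnet
    out$groups <- groups
    logf("projection: %d diseases, %d positive pairs, %d dense groups (min size %d)",
         igraph::vcount(dnet), igraph::ecount(dnet), length(groups),
         config$group_min_size)
  }

  # -- drug repurposing --------------------------------------------------
  if (stage %in% c("all", "repurpose")) {
    cent <- betweenness_table(net)
    cand <- candidate_filter(net, exclusion_list = config$exclusion_list)
    ranked <- rank_candidates(cand, cent)
    topk <- utils::head(ranked, config$top_k)
    write_atomic(function(p) {
      jsonlite::write_json(as.data.frame(topk), p, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }, file.path(config$out_dir, "candidates.json"))
    out$centrality <- cent
    out$candidates <- ranked
    logf("repurposing: %d drugs pass filters (%d excluded by list), top: %s",
         nrow(ranked), sum(cand$excluded_by_list),
         if (nrow(ranked) > 0) ranked$drug_id[1] else "none")
  }

  logf("done (%s) in %.1f s", stage,
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}
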