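# Synthetic fixture generator. Emits the four ingest input files (plus an
# XML dialect of the disease-protein table) with planted, exactly known
# structure: dense disease groups with exact shared-neighbor weights, a
# bridging repurposing candidate guaranteed to top the drug betweenness
# ranking, isolated diseases, a heavy-tailed interactor degree
# distribution, and noise rows exercising every ingest filter.
#
# Exactness guarantees: planted-group members and isolated diseases draw
# all their neighbors from pools dedicated to them alone, so their pairwise
# shared-neighbor counts equal the planted counts exactly and the planted
# cliques are maximal. The bridge protein module connects to the rest of
# the network only through the candidate drug, so every shortest path from
# that module passes through it.

#' Configuration for the synthetic fixture generator
#'
#' Defaults emulate the magnitudes of a curated amyloidosis
#' disease-protein-drug dataset scaled down about fourfold (19 diseases,
#' ~200 proteins, ~350 drugs) so a full pipeline run stays fast. Two dense
#' disease groups are planted by default: a heavy triangle sharing 12 drugs
#' plus 2 amyloidogenic proteins, and a fully connected group of six sharing
#' 1 drug plus 7 amyloidogenic proteins.
#'
#' @param n_diseases Total diseases (planted groups + isolated + ordinary).
#' @param n_amyloidogenic,n_codeposited,n_interactors Protein pool sizes.
#' @param n_drugs Drug pool size.
#' @param degree_tail_exponent Target power-law exponent of the background
#'   interactor degree distribution.
#' @param max_ppi_degree Truncation of drawn degrees. The default (95)
#'   leaves room for the module-attachment and bridging edges so that no
#'   protein ever exceeds the 100-neighbor ingest cap on clean data.
#' @param p_high_score Probability that a background interaction scores in
#'   the high-confidence band `[0.900, 0.999]`; the rest fall in
#'   `[0.150, 0.899]` and are filtered out on ingest.
#' @param planted_groups List of `list(members = <disease indices>,
#'   shared_drugs = <int>, shared_proteins = <int>)`; member indices must be
#'   disjoint across groups.
#' @param bridge_module_size Proteins in the module reachable only through
#'   the planted candidate drug.
#' @param anchor_module_size Interactors in the dense module around the
#'   candidate's amyloidogenic target.
#' @param isolated_diseases Number of diseases planted as disconnected
#'   components (taken from the top disease indices).
#' @param n_noise Counts of noise rows: `subthreshold`, `nonhuman`, `metal`,
#'   `duplicate` (the duplicate count is applied to each of the four
#'   tables).
#' @param seed Integer seed (mandatory; the generator is byte-deterministic
#'   given `(config, seed)`).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_diseases = 19,
                             n_amyloidogenic = 20,
                             n_codeposited = 10,
                             n_interactors = 180,
                             n_drugs = 350,
                             degree_tail_exponent = 2.5,
                             max_ppi_degree = 95,
                             p_high_score = 0.55,
                             planted_groups = list(
                               list(members = 1:3, shared_drugs = 12,
                                    shared_proteins = 2),
                               list(members = 4:9, shared_drugs = 1,
                                    shared_proteins = 7)),
                             bridge_module_size = 12,
                             anchor_module_size = 5,
                             isolated_diseases = 4,
                             n_noise = list(subthreshold = 40, nonhuman = 15,
                                            metal = 6, duplicate = 10),
                             seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_diseases, cfg$n_amyloidogenic, cfg$n_codeposited,
              cfg$n_interactors, cfg$n_drugs, cfg$isolated_diseases,
              unlist(cfg$n_noise))
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  stopifnot(cfg$degree_tail_exponent > 1, cfg$p_high_score >= 0,
            cfg$p_high_score <= 1)
  gm <- unlist(lapply(cfg$planted_groups, `[[`, "members"))
  if (anyDuplicated(gm) > 0) {
    stop("planted group member indices must be disjoint", call. = FALSE)
  }
  n_group <- length(gm)
  iso_idx <- seq.int(cfg$n_diseases - cfg$isolated_diseases + 1,
                     length.out = cfg$isolated_diseases)
  if (any(gm %in% iso_idx) || any(gm > cfg$n_diseases) || any(gm < 1)) {
    stop("planted group member indices clash with the isolated-disease block or exceed n_diseases",
         call. = FALSE)
  }
  n_ordinary <- cfg$n_diseases - n_group - cfg$isolated_diseases
  if (n_ordinary < 1) {
    stop("infeasible config: no ordinary disease left to anchor the candidate's target",
         call. = FALSE)
  }
  shared_prot <- sum(vapply(cfg$planted_groups, `[[`, numeric(1),
                            "shared_proteins"))
  amyl_needed <- shared_prot + cfg$isolated_diseases + 1  # +1 anchor target
  if (amyl_needed + 1 > cfg$n_amyloidogenic) {
    stop(sprintf(
      "infeasible config: %d amyloidogenic proteins needed for planted structure but only %d available",
      amyl_needed + 1, cfg$n_amyloidogenic), call. = FALSE)
  }
  if (cfg$anchor_module_size + cfg$bridge_module_size + 5 > cfg$n_interactors) {
    stop("infeasible config: interactor pool smaller than the planted modules",
         call. = FALSE)
  }
  shared_drugs <- sum(vapply(cfg$planted_groups, `[[`, numeric(1),
                             "shared_drugs"))
  drugs_needed <- 1 + shared_drugs + 3 * n_group + 20
  if (drugs_needed > cfg$n_drugs) {
    stop(sprintf("infeasible config: at least %d drugs needed, only %d available",
                 drugs_needed, cfg$n_drugs), call. = FALSE)
  }
  invisible(cfg)
}

# Configuration-model wiring: random stub matching with self-loops and
# multi-edges resolved by double-edge swaps against randomly chosen good
# pairs, so the drawn degree sequence is preserved (rare irreparable pairs
# are dropped after the iteration cap).
stub_match <- function(stubs) {
  m <- matrix(sample(stubs), ncol = 2)
  for (iter in seq_len(200)) {
    key <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    bad <- which(m[, 1] == m[, 2] | duplicated(key))
    if (length(bad) == 0) break
    good <- setdiff(seq_len(nrow(m)), bad)
    if (length(good) < length(bad)) break
    partners <- sample(good, length(bad))
    tmp <- m[bad, 2]
    m[bad, 2] <- m[partners, 2]
    m[partners, 2] <- tmp
  }
  a <- pmin(m[, 1], m[, 2])
  b <- pmax(m[, 1], m[, 2])
  keep <- m[, 1] != m[, 2] & !duplicated(paste(a, b))
  data.frame(protein_a = a[keep], protein_b = b[keep],
             stringsAsFactors = FALSE)
}

rand_pair_frame <- function(n, pool) {
  if (n == 0 || length(pool) < 2) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  i <- sample(pool, n, replace = TRUE)
  j <- sample(pool, n, replace = TRUE)
  clash <- i == j
  while (any(clash)) {
    j[clash] <- sample(pool, sum(clash), replace = TRUE)
    clash <- i == j
  }
  data.frame(protein_a = pmin(i, j), protein_b = pmax(i, j),
             stringsAsFactors = FALSE)
}

take <- function(pool, n, what) {
  if (n > length(pool)) {
    stop(sprintf("infeasible config: %s pool exhausted (need %d, have %d)",
                 what, n, length(pool)), call. = FALSE)
  }
  list(ids = pool[seq_len(n)], rest = pool[-seq_len(n)])
}

#' Generate a synthetic fixture file set with ground truth
#'
#' Writes `disease_protein.tsv`, `disease_protein.xml`, `ppi.tsv`,
#' `drug_targets.tsv`, `drug_indications.tsv` and `ground_truth.json` to
#' `dir`. Identical `(config, seed)` produces byte-identical files. The
#' ground truth records the post-filter node/edge counts, per-filter drop
#' counts, planted group memberships and weights, the planted candidate and
#' its qualifying diseases, and the isolated disease ids.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `ground_truth`.
#' @export
generate_synthetic <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- with_seed(config$seed, synth_realize(config))
  paths <- synth_write(res, config, dir)
  jsonlite::write_json(res$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, ground_truth = res$ground_truth))
}

# Draw all clean edge sets and noise rows. Runs under a fixed seed.
synth_realize <- function(cfg) {
  diseases <- sprintf("disease_%02d", seq_len(cfg$n_diseases))
  amyl <- sprintf("P1%04d", seq_len(cfg$n_amyloidogenic))
  codep <- sprintf("P2%04d", seq_len(cfg$n_codeposited))
  inter <- sprintf("P3%04d", seq_len(cfg$n_interactors))
  drugs <- sprintf("DB%05d", 10000 + seq_len(cfg$n_drugs))

  iso_idx <- seq.int(cfg$n_diseases - cfg$isolated_diseases + 1,
                     length.out = cfg$isolated_diseases)
  grp_idx <- lapply(cfg$planted_groups, `[[`, "members")
  ordinary_idx <- setdiff(seq_len(cfg$n_diseases),
                          c(unlist(grp_idx), iso_idx))
  anchor_disease <- diseases[ordinary_idx[1]]

  # -- dedicated protein allocation ------------------------------------
  amyl_pool <- amyl
  grp_prot <- vector("list", length(cfg$planted_groups))
  for (i in seq_along(cfg$planted_groups)) {
    tk <- take(amyl_pool, cfg$planted_groups[[i]]$shared_proteins,
               "amyloidogenic")
    grp_prot[[i]] <- tk$ids; amyl_pool <- tk$rest
  }
  tk <- take(amyl_pool, cfg$isolated_diseases, "amyloidogenic")
  iso_prot <- tk$ids; amyl_pool <- tk$rest
  tk <- take(amyl_pool, 1, "amyloidogenic")
  anchor_target <- tk$ids; amyl_pool <- tk$rest  # the candidate's target

  inter_pool <- inter
  tk <- take(inter_pool, cfg$anchor_module_size, "interactor")
  module_a <- tk$ids; inter_pool <- tk$rest
  tk <- take(inter_pool, cfg$bridge_module_size, "interactor")
  module_b <- tk$ids; inter_pool <- tk$rest
  bg_inter <- inter_pool

  # -- dedicated drug allocation ---------------------------------------
  drug_pool <- drugs
  tk <- take(drug_pool, 1, "drug"); candidate <- tk$ids; drug_pool <- tk$rest
  grp_drugs <- vector("list", length(cfg$planted_groups))
  for (i in seq_along(cfg$planted_groups)) {
    tk <- take(drug_pool, cfg$planted_groups[[i]]$shared_drugs, "drug")
    grp_drugs[[i]] <- tk$ids; drug_pool <- tk$rest
  }
  n_members <- length(unlist(grp_idx))
  tk <- take(drug_pool, 3 * n_members, "drug")
  private_drugs <- tk$ids; drug_pool <- tk$rest
  n_pool_ind <- min(120L, max(20L, length(drug_pool) %/% 3))
  tk <- take(drug_pool, n_pool_ind, "drug")
  ind_pool <- tk$ids; drug_pool <- tk$rest
  target_drugs <- drug_pool

  # -- disease-protein edges -------------------------------------------
  dp <- list()
  for (i in seq_along(cfg$planted_groups)) {
    dp[[length(dp) + 1]] <- expand.grid(
      disease_id = diseases[grp_idx[[i]]], uniprot_ac = grp_prot[[i]],
      stringsAsFactors = FALSE)
  }
  dp[[length(dp) + 1]] <- data.frame(disease_id = diseases[iso_idx],
                                     uniprot_ac = iso_prot,
                                     stringsAsFactors = FALSE)
  dp[[length(dp) + 1]] <- data.frame(disease_id = anchor_disease,
                                     uniprot_ac = anchor_target,
                                     stringsAsFactors = FALSE)
  dp <- do.call(rbind, dp)
  dp$role <- "amyloidogenic"
  ord_rows <- list()
  for (d in diseases[ordinary_idx]) {
    na <- sample(1:2, 1)
    picks <- sample(amyl_pool, min(na, length(amyl_pool)))
    ord_rows[[length(ord_rows) + 1]] <- data.frame(
      disease_id = d, uniprot_ac = picks, role = "amyloidogenic",
      stringsAsFactors = FALSE)
    nc <- sample(0:2, 1)
    if (nc > 0 && length(codep) > 0) {
      picks <- sample(codep, min(nc, length(codep)))
      ord_rows[[length(ord_rows) + 1]] <- data.frame(
        disease_id = d, uniprot_ac = picks, role = "co_deposited",
        stringsAsFactors = FALSE)
    }
  }
  dp <- rbind(dp, do.call(rbind, ord_rows))
  dp <- dp[!duplicated(paste(dp$disease_id, dp$uniprot_ac)), ]
  dp <- dp[radix_order(dp$disease_id, dp$uniprot_ac), ]
  rownames(dp) <- NULL

  # -- PPI edges --------------------------------------------------------
  complete_pairs <- function(ids) {
    cmb <- utils::combn(ids, 2)
    data.frame(protein_a = pmin(cmb[1, ], cmb[2, ]),
               protein_b = pmax(cmb[1, ], cmb[2, ]),
               stringsAsFactors = FALSE)
  }
  mod_a <- complete_pairs(c(anchor_target, module_a))
  mod_b <- complete_pairs(module_b)
  attach_edge <- data.frame(protein_a = pmin(module_a[1], bg_inter[1]),
                            protein_b = pmax(module_a[1], bg_inter[1]),
                            stringsAsFactors = FALSE)
  planted_pp <- rbind(mod_a, mod_b, attach_edge)
  planted_pp$combined_score <- round(stats::runif(nrow(planted_pp),
                                                  0.900, 0.998), 3)

  deg <- sample_power_law(length(bg_inter), cfg$degree_tail_exponent)
  deg <- pmin(deg, cfg$max_ppi_degree, length(bg_inter) - 1)
  stubs <- rep(bg_inter, deg)
  if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
  bg <- stub_match(stubs)
  # the high-confidence graph itself realizes the heavy-tailed degree
  # sequence; low-confidence rows are a separate random layer sized to give
  # the configured high-confidence mass fraction, so the score filter is
  # exercised without thinning the planted degree tail
  bg$combined_score <- round(stats::runif(nrow(bg), 0.900, 0.998), 3)
  n_low <- round(nrow(bg) * (1 - cfg$p_high_score) /
                   max(cfg$p_high_score, 0.05))
  low <- rand_pair_frame(n_low, bg_inter)
  if (nrow(low) > 0) {
    low$combined_score <- round(stats::runif(nrow(low), 0.150, 0.898), 3)
  }
  ppi_all <- rbind(planted_pp, bg, low)   # written rows (human, pre-noise)
  ppi_all$organism_tag <- "9606"
  ppi_clean <- ppi_all[ppi_all$combined_score >= 0.900, , drop = FALSE]
  ppi_clean <- ppi_clean[radix_order(ppi_clean$protein_a,
                                     ppi_clean$protein_b), ]
  rownames(ppi_clean) <- NULL

  # -- drug-target edges ------------------------------------------------
  target_pool <- c(amyl_pool, codep, bg_inter)
  pd <- list(data.frame(drugbank_id = candidate,
                        uniprot_ac = c(anchor_target, module_b[1]),
                        stringsAsFactors = FALSE))
  # every background drug targets exactly one protein: the planted
  # candidate is then the only drug that can bridge protein modules, which
  # is what guarantees its top betweenness rank
  pd[[length(pd) + 1]] <- data.frame(
    drugbank_id = target_drugs,
    uniprot_ac = sample(target_pool, length(target_drugs), replace = TRUE),
    stringsAsFactors = FALSE)
  pd <- do.call(rbind, pd)
  pd <- pd[!duplicated(paste(pd$drugbank_id, pd$uniprot_ac)), ]
  pd <- pd[radix_order(pd$drugbank_id, pd$uniprot_ac), ]
  rownames(pd) <- NULL

  # -- disease-drug indications ----------------------------------------
  dd <- list()
  pv <- private_drugs
  for (i in seq_along(cfg$planted_groups)) {
    for (m in grp_idx[[i]]) {
      tk <- take(pv, 3, "private drug"); pv <- tk$rest
      dd[[length(dd) + 1]] <- data.frame(
        disease_id = diseases[m], drugbank_id = tk$ids,
        stringsAsFactors = FALSE)
    }
    dd[[length(dd) + 1]] <- expand.grid(
      disease_id = diseases[grp_idx[[i]]], drugbank_id = grp_drugs[[i]],
      stringsAsFactors = FALSE)
  }
  for (d in diseases[ordinary_idx]) {
    nd <- sample(2:5, 1)
    dd[[length(dd) + 1]] <- data.frame(
      disease_id = d, drugbank_id = sample(ind_pool, nd),
      stringsAsFactors = FALSE)
  }
  dd <- do.call(rbind, dd)
  dd <- dd[!duplicated(paste(dd$disease_id, dd$drugbank_id)), ]
  dd <- dd[radix_order(dd$disease_id, dd$drugbank_id), ]
  rownames(dd) <- NULL

  # -- connectivity bridging --------------------------------------------
  # Every component other than the planted isolated diseases is tied into
  # the main component by one high-confidence PPI edge from one of its
  # proteins to a background interactor (round-robin, so no interactor
  # approaches the neighbor cap). PPI edges never enter a disease's
  # first-neighbor set, so planted weights and clique maximality are
  # untouched, and the bridge protein module stays reachable only through
  # the candidate drug (its component already contains the main body).
  union_edges <- rbind(cbind(dp$disease_id, dp$uniprot_ac),
                       cbind(ppi_clean$protein_a, ppi_clean$protein_b),
                       cbind(pd$drugbank_id, pd$uniprot_ac),
                       cbind(dd$disease_id, dd$drugbank_id))
  ug <- igraph::graph_from_edgelist(union_edges, directed = FALSE)
  cmp <- igraph::components(ug)
  main_comp <- cmp$membership[[anchor_target]]
  iso_set <- diseases[iso_idx]
  frags <- setdiff(seq_len(cmp$no), main_comp)
  frag_prot <- lapply(frags, function(ci) {
    members <- igraph::V(ug)$name[cmp$membership == ci]
    if (any(members %in% iso_set)) return(NULL)
    # bridge only fragments that carry a disease (so non-planted diseases
    # always reach the main component) or are large enough to rival it;
    # small pure protein/drug fragments stay legitimately disconnected and
    # the planted degree tail is not distorted by bridge edges
    if (!any(grepl("^disease_", members)) && length(members) < 30) {
      return(NULL)
    }
    sort(members[grepl("^P[123]", members)], method = "radix")[1]
  })
  frag_prot <- unlist(frag_prot[!vapply(frag_prot, is.null, logical(1))])
  frag_prot <- sort(frag_prot, method = "radix")
  # daisy chain: each fragment hangs off the previous one, the first off a
  # background interactor already in the main component
  bridge <- NULL
  if (length(frag_prot) > 0) {
    prev <- c(bg_inter[1], frag_prot[-length(frag_prot)])
    bridge <- data.frame(protein_a = pmin(frag_prot, prev),
                         protein_b = pmax(frag_prot, prev),
                         stringsAsFactors = FALSE)
  }
  if (!is.null(bridge) && nrow(bridge) > 0) {
    bridge$combined_score <- round(stats::runif(nrow(bridge), 0.900, 0.998), 3)
    bridge$organism_tag <- "9606"
    ppi_all <- rbind(ppi_all, bridge)
    ppi_clean <- rbind(ppi_clean, bridge)
    ppi_clean <- ppi_clean[radix_order(ppi_clean$protein_a,
                                       ppi_clean$protein_b), ]
    rownames(ppi_clean) <- NULL
  }

  # -- noise rows (dropped on ingest) ----------------------------------
  nz <- cfg$n_noise
  sub_noise <- rand_pair_frame(nz$subthreshold, c(bg_inter, codep))
  if (nrow(sub_noise) > 0) {
    sub_noise$combined_score <- round(stats::runif(nrow(sub_noise),
                                                   0.150, 0.898), 3)
    sub_noise$organism_tag <- "9606"
  }
  nh_noise <- rand_pair_frame(nz$nonhuman, c(bg_inter, codep))
  if (nrow(nh_noise) > 0) {
    nh_noise$combined_score <- round(stats::runif(nrow(nh_noise),
                                                  0.900, 0.998), 3)
    nh_noise$organism_tag <- "10090"
  }
  ndup <- min(nz$duplicate, nrow(ppi_clean))
  dup_rows <- ppi_clean[sample(nrow(ppi_clean), ndup), , drop = FALSE]
  dup_rows <- data.frame(protein_a = dup_rows$protein_b,    # flipped order
                         protein_b = dup_rows$protein_a,
                         combined_score = dup_rows$combined_score,
                         organism_tag = "9606", stringsAsFactors = FALSE)
  ppi_rows <- rbind(ppi_all, sub_noise, nh_noise, dup_rows)
  ppi_rows <- ppi_rows[sample(nrow(ppi_rows)), ]

  ndup_dp <- min(nz$duplicate, nrow(dp))
  dp_rows <- rbind(dp, dp[sample(nrow(dp), ndup_dp), , drop = FALSE])
  dp_rows <- dp_rows[sample(nrow(dp_rows)), ]

  metal_rows <- data.frame(
    drugbank_id = rep_len(unname(metal_drug_ids()), nz$metal),
    uniprot_ac = sample(target_pool, nz$metal, replace = TRUE),
    stringsAsFactors = FALSE)
  ndup_tg <- min(nz$duplicate, nrow(pd))
  tg_rows <- rbind(pd, metal_rows, pd[sample(nrow(pd), ndup_tg), , drop = FALSE])
  tg_rows <- tg_rows[sample(nrow(tg_rows)), ]

  ndup_ind <- min(nz$duplicate, nrow(dd))
  ind_rows <- rbind(dd, dd[sample(nrow(dd), ndup_ind), , drop = FALSE])
  ind_rows <- ind_rows[sample(nrow(ind_rows)), ]

  # -- ground truth ------------------------------------------------------
  n_score_drop <- sum(ppi_all$combined_score < 0.900) + nrow(sub_noise)
  node_ids <- unique(c(dp$disease_id, dp$uniprot_ac,
                       ppi_clean$protein_a, ppi_clean$protein_b,
                       pd$drugbank_id, pd$uniprot_ac,
                       dd$disease_id, dd$drugbank_id))
  is_dis <- grepl("^disease_", node_ids)
  is_drug <- grepl("^DB", node_ids)
  gt <- list(
    seed = cfg$seed,
    counts = list(
      n_nodes = length(node_ids),
      n_edges = nrow(dp) + nrow(ppi_clean) + nrow(pd) + nrow(dd),
      n_diseases = sum(is_dis),
      n_proteins = sum(!is_dis & !is_drug),
      n_drugs = sum(is_drug),
      n_dp_edges = nrow(dp),
      n_pp_edges = nrow(ppi_clean),
      n_pd_edges = nrow(pd),
      n_dd_edges = nrow(dd)),
    ingest_drops = list(
      dp = list(duplicate = ndup_dp),
      ppi = list(self_loop = 0L, score = n_score_drop,
                 organism = nrow(nh_noise), duplicate = ndup, cap = 0L),
      targets = list(excluded = nrow(metal_rows), duplicate = ndup_tg),
      indications = list(excluded = 0L, duplicate = ndup_ind)),
    planted_groups = lapply(seq_along(cfg$planted_groups), function(i) {
      list(members = sort(diseases[grp_idx[[i]]], method = "radix"),
           weight = cfg$planted_groups[[i]]$shared_drugs +
             cfg$planted_groups[[i]]$shared_proteins,
           shared_drugs = cfg$planted_groups[[i]]$shared_drugs,
           shared_proteins = cfg$planted_groups[[i]]$shared_proteins)
    }),
    candidate = list(drug_id = candidate,
                     targets = anchor_target,
                     diseases = anchor_disease),
    isolated_diseases = sort(diseases[iso_idx], method = "radix"))

  list(dp_rows = dp_rows, ppi_rows = ppi_rows, tg_rows = tg_rows,
       ind_rows = ind_rows, ground_truth = gt)
}

synth_write <- function(res, cfg, dir) {
  paths <- c(
    disease_protein_tsv = file.path(dir, "disease_protein.tsv"),
    disease_protein_xml = file.path(dir, "disease_protein.xml"),
    ppi = file.path(dir, "ppi.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    drug_indications = file.path(dir, "drug_indications.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  wt <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
  }
  wt(res$dp_rows[, c("disease_id", "uniprot_ac", "role")],
     paths[["disease_protein_tsv"]])
  wt(res$ppi_rows[, c("protein_a", "protein_b", "combined_score",
                      "organism_tag")], paths[["ppi"]])
  wt(res$tg_rows[, c("drugbank_id", "uniprot_ac")], paths[["drug_targets"]])
  wt(res$ind_rows[, c("disease_id", "drugbank_id")],
     paths[["drug_indications"]])

  # XML dialect of the same disease-protein rows
  dp <- res$dp_rows
  by_dis <- split(dp, dp$disease_id)
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<diseases>")
  for (d in sort(names(by_dis), method = "radix")) {
    lines <- c(lines, sprintf("  <disease name=\"%s\">", d))
    rows <- by_dis[[d]]
    lines <- c(lines, sprintf("    <protein ac=\"%s\" role=\"%s\"/>",
                              rows$uniprot_ac, rows$role))
    lines <- c(lines, "  </disease>")
  }
  lines <- c(lines, "</diseases>")
  con <- file(paths[["disease_protein_xml"]], open = "wb")
  writeLines(lines, con)
  close(con)
  paths
}
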