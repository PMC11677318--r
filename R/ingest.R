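# Ingest: parse the four association datasets and apply the filtering rules.
#
# All tables are tab-delimited UTF-8 with a header row; lines starting with
# `#` are ignored. Identifiers live in disjoint namespaces: disease slugs,
# UniProt accessions, DrugBank ids (DB + 5 digits).

VALID_DP_ROLES <- c("amyloidogenic", "co_deposited")

#' DrugBank identifiers of non-specifically binding metal compounds
#'
#' Default exclusion list for [read_drug_tables()]: zinc, copper and aluminum
#' interact non-specifically with many proteins and are dropped from the
#' drug-target and indication tables.
#'
#' @return Named character vector of DrugBank ids.
#' @export
metal_drug_ids <- function() {
  c(zinc = "DB01593", copper = "DB09130", aluminum = "DB01370")
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: '%s'", what, path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                      colClasses = "character", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("malformed %s TSV '%s': %s", what, path,
                   conditionMessage(e)), call. = FALSE)
    })
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table '%s' is missing column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

radix_order <- function(...) order(..., method = "radix")

#' Read disease-protein associations
#'
#' Parses disease to protein association records in either a 3-column TSV
#' dialect (`disease_id`, `uniprot_ac`, `role`) or a minimal XML dialect
#' (`<disease name="...">` elements holding `<protein ac="..." role="..."/>`
#' children). Roles must be `amyloidogenic` or `co_deposited`. Duplicate
#' (disease, protein) records collapse to one edge; when a pair is recorded
#' under several roles the per-edge tag keeps all of them (comma-joined) and
#' the protein's role set is the union over its edges.
#'
#' @param path Path to the association file.
#' @param dialect `"tsv"` or `"xml"`.
#' @return A list with components
#'   \item{edges}{data.frame `disease_id`, `uniprot_ac`, `role`, one row per
#'     unique pair, canonically sorted; attribute `drop_counts` records
#'     duplicate rows collapsed.}
#'   \item{nodes}{data.frame `id`, `category`, `roles`, `display_name` for
#'     every disease and protein seen.}
#' @export
read_disease_protein_associations <- function(path, dialect = c("tsv", "xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read_tsv_checked(path, c("disease_id", "uniprot_ac", "role"),
                           "disease-protein association")
    recs <- df[, c("disease_id", "uniprot_ac", "role")]
  } else {
    doc <- tryCatch(xml2::read_xml(path), error = function(e) {
      stop(sprintf("malformed association XML '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
    dis_nodes <- xml2::xml_find_all(doc, ".//disease")
    if (length(dis_nodes) == 0) {
      stop(sprintf("association XML '%s' contains no <disease> elements", path),
           call. = FALSE)
    }
    recs <- do.call(rbind, lapply(dis_nodes, function(d) {
      dname <- xml2::xml_attr(d, "name")
      if (is.na(dname)) {
        stop(sprintf("<disease> element without 'name' attribute in '%s'",
                     path), call. = FALSE)
      }
      prots <- xml2::xml_find_all(d, "./protein")
      if (length(prots) == 0) {
        return(data.frame(disease_id = character(), uniprot_ac = character(),
                          role = character(), stringsAsFactors = FALSE))
      }
      data.frame(disease_id = dname,
                 uniprot_ac = xml2::xml_attr(prots, "ac"),
                 role = xml2::xml_attr(prots, "role"),
                 stringsAsFactors = FALSE)
    }))
  }
  if (anyNA(recs$uniprot_ac) || anyNA(recs$role)) {
    stop("disease-protein record missing accession or role attribute",
         call. = FALSE)
  }
  bad <- !(recs$role %in% VALID_DP_ROLES)
  if (any(bad)) {
    stop(sprintf("unknown protein role label(s): %s (expected %s)",
                 paste(unique(recs$role[bad]), collapse = ", "),
                 paste(VALID_DP_ROLES, collapse = "/")), call. = FALSE)
  }
  n_in <- nrow(recs)

  # collapse duplicates; per-pair role tag is the sorted union of roles
  key <- paste(recs$disease_id, recs$uniprot_ac, sep = "\r")
  role_by_pair <- vapply(split(recs$role, key), function(r) {
    paste(sort(unique(r), method = "radix"), collapse = ",")
  }, character(1))
  first <- !duplicated(key)
  edges <- recs[first, c("disease_id", "uniprot_ac")]
  edges$role <- unname(role_by_pair[key[first]])
  edges <- edges[radix_order(edges$disease_id, edges$uniprot_ac), ]
  rownames(edges) <- NULL
  attr(edges, "drop_counts") <- list(duplicate = n_in - nrow(edges))

  prot_roles <- vapply(split(edges$role, edges$uniprot_ac), function(r) {
    paste(sort(unique(unlist(strsplit(r, ",", fixed = TRUE))),
               method = "radix"), collapse = ",")
  }, character(1))
  dis_ids <- sort(unique(edges$disease_id), method = "radix")
  prot_ids <- sort(unique(edges$uniprot_ac), method = "radix")
  nodes <- data.frame(
    id = c(dis_ids, prot_ids),
    category = c(rep("disease", length(dis_ids)),
                 rep("protein", length(prot_ids))),
    roles = c(rep("", length(dis_ids)), unname(prot_roles[prot_ids])),
    display_name = c(dis_ids, prot_ids),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}

#' Read and filter a scored protein-protein interaction table
#'
#' Reads a STRING-style PPI table with columns `protein_a`, `protein_b`,
#' `combined_score`, `organism_tag` and applies, in order: score-scale
#' normalisation (any score > 1 implies a 0-1000 scale; all scores divided by
#' 1000), the confidence floor (`combined_score >= min_score`, inclusive),
#' the organism filter (only rows with `organism_tag == human_tag` kept when
#' `human_only`), the per-protein neighbor cap, and unordered-pair
#' de-duplication (max score kept). The cap is mutual top-K: an interaction
#' survives only if each endpoint ranks the other within its `max_neighbors`
#' highest-scoring partners (ties broken by lexicographic partner id), which
#' guarantees every protein retains at most `max_neighbors` partners.
#'
#' @param path Path to the PPI TSV.
#' @param min_score Confidence floor on the 0-1 scale (default 0.900).
#' @param max_neighbors Per-protein partner cap (default 100).
#' @param human_only Drop rows whose `organism_tag` differs from `human_tag`.
#' @param human_tag NCBI taxon tag marking human rows (default `"9606"`).
#' @return data.frame `protein_a`, `protein_b`, `combined_score` with
#'   canonical unordered pairs (`protein_a < protein_b`), sorted; attribute
#'   `drop_counts` itemises rows removed per rule (`self_loop`, `organism`,
#'   `score`, `duplicate`, `cap`).
#' @export
read_ppi_table <- function(path, min_score = 0.900, max_neighbors = 100,
                           human_only = TRUE, human_tag = "9606") {
  stopifnot(is.numeric(min_score), min_score >= 0, min_score <= 1,
            max_neighbors >= 1)
  df <- read_tsv_checked(
    path, c("protein_a", "protein_b", "combined_score", "organism_tag"),
    "protein-protein interaction")
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    stop(sprintf("non-numeric combined_score at data row(s) %s of '%s'",
                 paste(utils::head(which(is.na(score)), 5), collapse = ", "),
                 path), call. = FALSE)
  }
  if (any(score < 0 | score > 1000)) {
    stop("combined_score outside [0, 1000]", call. = FALSE)
  }
  if (any(score > 1)) score <- score / 1000
  df$combined_score <- score
  drops <- list(self_loop = 0L, organism = 0L, score = 0L,
                duplicate = 0L, cap = 0L)

  keep <- df$protein_a != df$protein_b
  drops$self_loop <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$combined_score >= min_score
  drops$score <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  if (isTRUE(human_only)) {
    keep <- df$organism_tag == human_tag
    drops$organism <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }

  edges <- dedupe_ppi(df[, c("protein_a", "protein_b", "combined_score")])
  drops$duplicate <- nrow(df) - nrow(edges)

  capped <- cap_neighbors(edges, max_neighbors)
  drops$cap <- nrow(edges) - nrow(capped)

  rownames(capped) <- NULL
  attr(capped, "drop_counts") <- drops
  capped
}

# Mutual top-K neighbor cap on a canonical, de-duplicated pair list.
cap_neighbors <- function(edges, k) {
  if (nrow(edges) == 0) return(edges)
  long <- data.frame(
    p = c(edges$protein_a, edges$protein_b),
    q = c(edges$protein_b, edges$protein_a),
    s = rep(edges$combined_score, 2),
    i = rep(seq_len(nrow(edges)), 2),
    stringsAsFactors = FALSE)
  long <- long[radix_order(long$p, -long$s, long$q), ]
  rank_in_p <- stats::ave(seq_len(nrow(long)), long$p, FUN = seq_along)
  kept_dir <- rank_in_p <= k
  both <- tabulate(long$i[kept_dir], nbins = nrow(edges)) == 2L
  edges[both, , drop = FALSE]
}

#' De-duplicate protein-protein interaction edges
#'
#' Collapses a PPI edge list to unique unordered pairs: `(a, b)` and `(b, a)`
#' are the same interaction; when duplicates carry different confidence
#' scores the maximum is kept. Output is in canonical order (`protein_a <
#' protein_b`, rows sorted by pair).
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @return De-duplicated, canonically sorted data.frame of the same columns.
#' @export
dedupe_ppi <- function(edges) {
  stopifnot(all(c("protein_a", "protein_b", "combined_score") %in%
                  names(edges)))
  if (nrow(edges) == 0) {
    out <- edges[, c("protein_a", "protein_b", "combined_score")]
    rownames(out) <- NULL
    return(out)
  }
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(a, b, sep = "\r")
  smax <- vapply(split(as.numeric(edges$combined_score), key), max,
                 numeric(1))
  first <- !duplicated(key)
  out <- data.frame(protein_a = a[first], protein_b = b[first],
                    combined_score = unname(smax[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[radix_order(out$protein_a, out$protein_b), ]
  rownames(out) <- NULL
  out
}

#' Read drug-target and drug-indication tables
#'
#' Reads a drug-target table (`drugbank_id`, `uniprot_ac`) and a
#' drug-indication table (`drugbank_id`, `disease_id`), drops every row
#' touching an excluded drug id (by default the metal compounds from
#' [metal_drug_ids()]), collapses duplicates, and warns (keeping the row) on
#' drug ids that do not match the `DB` + 5 digits pattern.
#'
#' @param targets_path Path to the drug-target TSV.
#' @param indications_path Path to the drug-indication TSV.
#' @param excluded_drugs Character vector of DrugBank ids to drop.
#' @return List with data.frames `protein_drug` (`drugbank_id`,
#'   `uniprot_ac`) and `disease_drug` (`drugbank_id`, `disease_id`), each
#'   carrying a `drop_counts` attribute (`excluded`, `duplicate`).
#' @export
read_drug_tables <- function(targets_path, indications_path,
                             excluded_drugs = metal_drug_ids()) {
  tg <- read_tsv_checked(targets_path, c("drugbank_id", "uniprot_ac"),
                         "drug-target")
  ind <- read_tsv_checked(indications_path, c("drugbank_id", "disease_id"),
                          "drug-indication")
  check_db_ids(unique(c(tg$drugbank_id, ind$drugbank_id)))

  clean_one <- function(df, other_col) {
    n_in <- nrow(df)
    df <- df[!(df$drugbank_id %in% excluded_drugs), , drop = FALSE]
    n_excl <- n_in - nrow(df)
    key <- paste(df$drugbank_id, df[[other_col]], sep = "\r")
    df <- df[!duplicated(key), c("drugbank_id", other_col), drop = FALSE]
    df <- df[radix_order(df$drugbank_id, df[[other_col]]), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "drop_counts") <- list(excluded = n_excl,
                                    duplicate = n_in - n_excl - nrow(df))
    df
  }
  list(protein_drug = clean_one(tg, "uniprot_ac"),
       disease_drug = clean_one(ind, "disease_id"))
}

check_db_ids <- function(ids) {
  bad <- ids[!grepl("^DB[0-9]{5}$", ids)]
  if (length(bad) > 0) {
    warning(sprintf(
      "drug id(s) not matching DrugBank pattern 'DB' + 5 digits (rows kept): %s",
      paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  invisible(length(bad))
}

drop_counts <- function(x) attr(x, "drop_counts")
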