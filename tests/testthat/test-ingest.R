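# Ingest: parsing dialects and the filtering rules (score floor, scale
# auto-detection, organism filter, neighbor cap, metal blocklist, dedup).

test_that("disease-protein associations collapse duplicates and keep role tags", {
  df <- data.frame(
    disease_id = c("d1", "d1", "d2", "d2", "d3", "d3", "d1"),
    uniprot_ac = c("P00001", "P00002", "P00001", "P00003", "P00002",
                   "P00004", "P00001"),
    role = c("amyloidogenic", "co_deposited", "co_deposited",
             "amyloidogenic", "amyloidogenic", "amyloidogenic",
             "amyloidogenic"),
    stringsAsFactors = FALSE)
  res <- read_disease_protein_associations(write_tsv_fixture(df), "tsv")
  expect_equal(nrow(res$edges), 6)  # 3 diseases x 2 proteins, one dup row
  expect_equal(drop_counts <- attr(res$edges, "drop_counts")$duplicate, 1)
  # P00001 is amyloidogenic in d1, co-deposited in d2: per-edge tags kept,
  # node role set is the union
  e <- res$edges
  expect_equal(e$role[e$disease_id == "d1" & e$uniprot_ac == "P00001"],
               "amyloidogenic")
  expect_equal(e$role[e$disease_id == "d2" & e$uniprot_ac == "P00001"],
               "co_deposited")
  nd <- res$nodes
  expect_equal(nd$roles[nd$id == "P00001"], "amyloidogenic,co_deposited")
  expect_setequal(nd$category, c("disease", "protein"))
})

test_that("a pair recorded under two roles keeps both tags on the edge", {
  df <- data.frame(disease_id = c("d1", "d1"),
                   uniprot_ac = c("P00001", "P00001"),
                   role = c("amyloidogenic", "co_deposited"),
                   stringsAsFactors = FALSE)
  res <- read_disease_protein_associations(write_tsv_fixture(df), "tsv")
  expect_equal(nrow(res$edges), 1)
  expect_equal(res$edges$role, "amyloidogenic,co_deposited")
})

test_that("XML and TSV dialects produce identical edge objects", {
  df <- data.frame(disease_id = c("diseaseX", "diseaseX", "diseaseY"),
                   uniprot_ac = c("P02766", "P00002", "P02766"),
                   role = c("amyloidogenic", "co_deposited", "amyloidogenic"),
                   stringsAsFactors = FALSE)
  tsv <- write_tsv_fixture(df)
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<?xml version=\"1.0\"?>", "<diseases>",
    "  <disease name=\"diseaseX\">",
    "    <protein ac=\"P02766\" role=\"amyloidogenic\"/>",
    "    <protein ac=\"P00002\" role=\"co_deposited\"/>",
    "  </disease>",
    "  <disease name=\"diseaseY\">",
    "    <protein ac=\"P02766\" role=\"amyloidogenic\"/>",
    "  </disease>", "</diseases>"), xml)
  rt <- read_disease_protein_associations(tsv, "tsv")
  rx <- read_disease_protein_associations(xml, "xml")
  expect_identical(rt$edges, rx$edges)
  expect_identical(rt$nodes, rx$nodes)
})

test_that("malformed input and unknown roles are rejected with clear errors", {
  bad_role <- write_tsv_fixture(data.frame(
    disease_id = "d1", uniprot_ac = "P1", role = "mystery",
    stringsAsFactors = FALSE))
  expect_error(read_disease_protein_associations(bad_role, "tsv"),
               "unknown protein role")
  missing_col <- write_tsv_fixture(data.frame(disease_id = "d1",
                                              stringsAsFactors = FALSE))
  expect_error(read_disease_protein_associations(missing_col, "tsv"),
               "missing column")
  bad_xml <- tempfile(fileext = ".xml")
  writeLines("<diseases><disease name='x'>", bad_xml)
  expect_error(read_disease_protein_associations(bad_xml, "xml"),
               "malformed")
  expect_error(read_disease_protein_associations(tempfile(), "tsv"),
               "not found")
})

test_that("PPI score floor is inclusive and the 0-1000 scale is auto-detected", {
  p <- ppi_fixture(c("A", "B", "C"), c("B", "C", "A"),
                   c(0.950, 0.899, 0.900))
  out <- read_ppi_table(p)
  expect_equal(nrow(out), 2)  # 0.899 out, 0.900 kept (floor inclusive)
  expect_true(all(out$combined_score >= 0.900))
  # same table on the integer scale gives the same result
  p1000 <- ppi_fixture(c("A", "B", "C"), c("B", "C", "A"), c(950, 899, 900))
  expect_equal(read_ppi_table(p1000), out, ignore_attr = TRUE)
})

test_that("non-human rows are dropped only when human_only is set", {
  p <- ppi_fixture(c("A", "B"), c("B", "C"), c(0.95, 0.95),
                   organism = c("9606", "10090"))
  expect_equal(nrow(read_ppi_table(p)), 1)
  expect_equal(attr(read_ppi_table(p), "drop_counts")$organism, 1)
  expect_equal(nrow(read_ppi_table(p, human_only = FALSE)), 2)
})

test_that("scores outside [0, 1000] and missing columns are schema errors", {
  expect_error(read_ppi_table(ppi_fixture("A", "B", 1001)), "outside")
  expect_error(read_ppi_table(ppi_fixture("A", "B", -2)), "outside")
  bad <- write_tsv_fixture(data.frame(protein_a = "A", protein_b = "B",
                                      stringsAsFactors = FALSE))
  expect_error(read_ppi_table(bad), "missing column")
})

test_that("the neighbor cap keeps the highest-scoring partners with lexicographic ties", {
  partners <- sprintf("Q%03d", sample(150))
  p <- ppi_fixture(rep("SEED0", 150), partners, rep(0.950, 150))
  out <- read_ppi_table(p, max_neighbors = 100)
  expect_equal(nrow(out), 100)
  kept <- setdiff(unique(c(out$protein_a, out$protein_b)), "SEED0")
  expect_equal(sort(kept), sort(sprintf("Q%03d", 1:100)))  # lexicographic
  expect_equal(attr(out, "drop_counts")$cap, 50)
  # score beats id: a low-scoring early id loses to high-scoring later ids
  p2 <- ppi_fixture(rep("S", 3), c("A", "B", "C"), c(0.90, 0.99, 0.95))
  out2 <- read_ppi_table(p2, max_neighbors = 2)
  expect_setequal(setdiff(unique(c(out2$protein_a, out2$protein_b)), "S"),
                  c("B", "C"))
})

test_that("every protein retains at most max_neighbors partners", {
  dir <- synthetic_fixture_dir()
  out <- read_ppi_table(file.path(dir, "ppi.tsv"), max_neighbors = 10)
  deg <- table(c(out$protein_a, out$protein_b))
  expect_lte(max(deg), 10)
})

test_that("the PPI filter chain is idempotent", {
  dir <- synthetic_fixture_dir()
  once <- read_ppi_table(file.path(dir, "ppi.tsv"))
  p2 <- tempfile(fileext = ".tsv")
  once$organism_tag <- "9606"
  write_tsv_fixture(once, p2)
  twice <- read_ppi_table(p2)
  expect_equal(twice, once[, names(twice)], ignore_attr = TRUE)
})

test_that("dedupe_ppi collapses symmetric duplicates keeping the max score", {
  e <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
                  combined_score = c(0.91, 0.95), stringsAsFactors = FALSE)
  out <- dedupe_ppi(e)
  expect_equal(out, data.frame(protein_a = "A", protein_b = "B",
                               combined_score = 0.95,
                               stringsAsFactors = FALSE))
  expect_identical(dedupe_ppi(out), out)  # idempotent
})

test_that("dedupe_ppi output size equals the unordered-pair set cardinality", {
  set.seed(31)
  ids <- sprintf("P%02d", 1:12)
  a <- sample(ids, 300, replace = TRUE)
  b <- sample(ids, 300, replace = TRUE)
  keep <- a != b
  e <- data.frame(protein_a = a[keep], protein_b = b[keep],
                  combined_score = runif(sum(keep), 0.9, 1),
                  stringsAsFactors = FALSE)
  out <- dedupe_ppi(e)
  oracle <- unique(paste(pmin(e$protein_a, e$protein_b),
                         pmax(e$protein_a, e$protein_b)))
  expect_equal(nrow(out), length(oracle))
  # max-score rule against a by-hand split
  for (i in seq_len(nrow(out))) {
    pair_rows <- pmin(e$protein_a, e$protein_b) == out$protein_a[i] &
      pmax(e$protein_a, e$protein_b) == out$protein_b[i]
    expect_equal(out$combined_score[i], max(e$combined_score[pair_rows]))
  }
})

test_that("drug tables drop excluded metals and collapse duplicates", {
  tg <- write_tsv_fixture(data.frame(
    drugbank_id = c("DB09221", "DB01593", "DB09221", "DB00001"),
    uniprot_ac = c("P00441", "P00441", "P00441", "P99999"),
    stringsAsFactors = FALSE))
  ind <- write_tsv_fixture(data.frame(
    drugbank_id = c("DB00001", "DB00001", "DB09130"),
    disease_id = c("als", "als", "als"), stringsAsFactors = FALSE))
  out <- read_drug_tables(tg, ind)
  # zinc row absent; the Polaprezinc-SOD1 pair is one edge
  expect_false("DB01593" %in% out$protein_drug$drugbank_id)
  expect_equal(sum(out$protein_drug$drugbank_id == "DB09221" &
                     out$protein_drug$uniprot_ac == "P00441"), 1)
  expect_equal(attr(out$protein_drug, "drop_counts")$excluded, 1)
  expect_equal(attr(out$protein_drug, "drop_counts")$duplicate, 1)
  # duplicated indication collapsed, copper excluded
  expect_equal(nrow(out$disease_drug), 1)
  expect_false(any(out$disease_drug$drugbank_id %in% metal_drug_ids()))
})

test_that("non-conforming drug ids warn but rows are kept; empty tables are fine", {
  tg <- write_tsv_fixture(data.frame(drugbank_id = "CHEMBL25",
                                     uniprot_ac = "P00001",
                                     stringsAsFactors = FALSE))
  ind <- write_tsv_fixture(data.frame(drugbank_id = character(),
                                      disease_id = character(),
                                      stringsAsFactors = FALSE))
  expect_warning(out <- read_drug_tables(tg, ind), "DrugBank pattern")
  expect_equal(nrow(out$protein_drug), 1)
  expect_equal(nrow(out$disease_drug), 0)
})

test_that("ingest on generator fixtures reproduces the bookkept drop counts", {
  dir <- synthetic_fixture_dir()
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  ppi <- read_ppi_table(file.path(dir, "ppi.tsv"))
  d <- attr(ppi, "drop_counts")
  expect_equal(d$score, gt$ingest_drops$ppi$score)
  expect_equal(d$organism, gt$ingest_drops$ppi$organism)
  expect_equal(d$duplicate, gt$ingest_drops$ppi$duplicate)
  expect_equal(d$cap, gt$ingest_drops$ppi$cap)
  expect_equal(nrow(ppi), gt$counts$n_pp_edges)
  dp <- read_disease_protein_associations(
    file.path(dir, "disease_protein.tsv"))
  expect_equal(attr(dp$edges, "drop_counts")$duplicate,
               gt$ingest_drops$dp$duplicate)
  expect_equal(nrow(dp$edges), gt$counts$n_dp_edges)
})
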