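# Fixtures built in code: the two-genome hand-computed community used
# throughout the inference tests, plus small synthetic studies.

# Two genomes (genus a: ssu 1, e1:2 e2:1; genus b: ssu 2, e2:2 e3:2), four
# EC units, pathways P1={e1,e2} and P2={e2,e3,e4}, EC->KO cross-map.
fixture_db <- function(with_crossmap = FALSE) {
  genomes <- data.frame(
    genome_id = c("G1", "G2"), domain = "bacteria", phylum = "ph1",
    class = "cl1", order = "or1", family = "fa1", genus = c("a", "b"),
    species = c("a sp1", "b sp1"), ssu_copies = c(1, 2),
    stringsAsFactors = FALSE)
  uc <- rbind(c(2, 1, 0, 0), c(0, 2, 2, 0))
  dimnames(uc) <- list(c("G1", "G2"), c("e1", "e2", "e3", "e4"))
  ko <- NULL
  crossmaps <- NULL
  if (with_crossmap) {
    ko <- data.frame(unit_id = c("K00001", "K00002"), namespace = "KO",
                     description = "ko", stringsAsFactors = FALSE)
    crossmaps <- data.frame(
      source_ns = "EC", target_ns = "KO",
      source_id = c("e1", "e1", "e2"),
      target_id = c("K00001", "K00002", "K00001"),
      stringsAsFactors = FALSE)
  }
  units <- rbind(
    data.frame(unit_id = c("e1", "e2", "e3", "e4"), namespace = "EC",
               description = "enzyme", stringsAsFactors = FALSE), ko)
  pathways <- data.frame(
    pathway_id = c("P1", "P2"), name = c("pathway one", "pathway two"),
    level1 = "Metabolism", level2 = c("Sub1", "Sub2"),
    level3 = c("pathway one", "pathway two"), stringsAsFactors = FALSE)
  pathways$member_units <- list(c("e1", "e2"), c("e2", "e3", "e4"))
  if (is.null(crossmaps)) crossmaps <- funmapper:::empty_crossmaps()
  function_db(genomes, uc, units, pathways, crossmaps)
}

# 50/50 community of the two fixture genera, n_samples identical columns.
fixture_profile <- function(n_samples = 1) {
  tf <- tempfile(fileext = ".tsv")
  s <- paste0("S", seq_len(n_samples))
  header <- paste(c("lineage", s), collapse = "\t")
  rows <- c(
    paste(c("k__Bacteria; p__ph1; g__A", rep("0.5", n_samples)), collapse = "\t"),
    paste(c("k__Bacteria; p__ph1; g__B", rep("0.5", n_samples)), collapse = "\t"))
  writeLines(c(header, rows), tf)
  parse_taxa_table(tf)
}

# A seeded synthetic study parsed end to end: db + TaxaProfile + groups.
synth_study <- function(seed, n_genomes = 8, n_units = 15, n_pathways = 4,
                        n_per_cell = 2) {
  db <- generate_synthetic_db(n_genomes, n_units, n_pathways, seed = seed)
  comm <- generate_synthetic_community(db, n_per_cell = n_per_cell,
                                       seed = seed + 1000)
  tf <- tempfile(fileext = ".tsv")
  funmapper:::write_tsv_plain(comm$taxa_table, tf)
  profile <- suppressMessages(parse_taxa_table(tf))
  groups <- stats::setNames(comm$metadata$Status, comm$metadata$sample_id)
  list(db = db, profile = profile, groups = groups, metadata = comm$metadata)
}

# Presence sets (function ids with positive raw abundance) per sample.
presence_sets <- function(fp) {
  lapply(seq_along(fp$samples), function(s) fp$functions[fp$raw[, s] > 0])
}

# Wrap a ready-made relative-abundance matrix as a FunctionProfile without
# renormalizing, so tests control the exact values under test.
profile_from_matrix <- function(mat, algorithm = "CoM", pec = 50L) {
  structure(list(functions = rownames(mat), samples = colnames(mat),
                 abundance = mat, raw = mat, normalizer = colSums(mat),
                 level = "level3", algorithm = algorithm, pec = pec),
            class = "FunctionProfile")
}

expect_near <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) < tol),
              label = paste("max abs diff",
                            format(max(abs(object - expected)))))
}
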