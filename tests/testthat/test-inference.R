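test_that("copy-number correction matches the hand computation and reports coverage", {
  db <- fixture_db()
  prof <- fixture_profile(1)
  corr <- correct_abundance(prof, db)
  expect_near(unname(corr$abundance[, 1]), c(2 / 3, 1 / 3))

  # all ssu = 1 leaves abundances unchanged
  db1 <- db; db1$genomes$ssu_copies <- c(1, 1)
  corr1 <- correct_abundance(prof, db1)
  expect_near(corr1$abundance, prof$abundance)

  # an unmatched taxon's mass lands in the coverage report
  tf <- tempfile()
  writeLines(c("lineage\tS1",
               "k__Bacteria; p__ph1; g__A\t0.4",
               "k__Bacteria; p__ph1; g__B\t0.4",
               "k__Bacteria; p__ph1; g__Nowhere\t0.2"), tf)
  p3 <- parse_taxa_table(tf)
  corr3 <- suppressMessages(correct_abundance(p3, db))
  expect_near(corr3$coverage$dropped_mass, 0.2)
  expect_near(colSums(corr3$abundance), 1)
})

test_that("pooled unit profile matches the fixture community", {
  db <- fixture_db()
  corr <- correct_abundance(fixture_profile(1), db)
  up <- community_unit_profile(corr, db)
  expect_near(unname(up$abundance[c("e1", "e2", "e3", "e4"), 1]),
              c(4 / 3, 4 / 3, 2 / 3, 0))

  # single taxon at abundance 1: profile equals its mean copy vector
  tf <- tempfile()
  writeLines(c("lineage\tS1", "k__Bacteria; p__ph1; g__A\t1"), tf)
  corrA <- correct_abundance(parse_taxa_table(tf), db)
  upA <- community_unit_profile(corrA, db)
  expect_near(unname(upA$abundance[, 1]), c(2, 1, 0, 0))
  expect_error(community_unit_profile(corr, db, "Pfam"), "Pfam")
})

test_that("cross-mapping splits abundance equally and conserves mapped mass", {
  db <- fixture_db(with_crossmap = TRUE)
  corr <- correct_abundance(fixture_profile(1), db)
  up <- community_unit_profile(corr, db)
  ko <- crossmap_profile(up, db, "KO")
  # e1 (4/3) splits over K00001, K00002; e2 (4/3) maps wholly to K00001
  expect_near(unname(ko$abundance["K00001", 1]), 4 / 3 / 2 + 4 / 3)
  expect_near(unname(ko$abundance["K00002", 1]), 4 / 3 / 2)
  # unmapped source mass (e3, e4) reported; mapped mass conserved
  expect_near(unname(attr(ko, "unmapped_mass")), 2 / 3)
  expect_near(sum(ko$abundance), sum(up$abundance) - 2 / 3)
  expect_error(crossmap_profile(up, db, "Pfam"), "cross-map")
})

test_that("pathway presence follows the PEC quorum on detected-unit fractions", {
  db <- fixture_db()
  corr <- correct_abundance(fixture_profile(1), db)
  up <- community_unit_profile(corr, db)
  p2 <- db$pathways[2, ]  # e2, e3 detected; e4 not: 2/3 of members
  expect_true(pathway_presence(up, p2, 50)[1])
  expect_true(pathway_presence(up, p2, 60)[1])
  expect_false(pathway_presence(up, p2, 70)[1])
  expect_false(pathway_presence(up, p2, 80)[1])
  expect_false(pathway_presence(up, p2, 90)[1])
  expect_true(pathway_presence(up, p2, 0)[1])

  # 4 of 10 members detected fails a 50% quorum
  ab <- matrix(c(rep(1, 4), rep(0, 6)), ncol = 1,
               dimnames = list(paste0("u", 1:10), "S1"))
  up10 <- funmapper:::new_unit_profile(ab, "EC", "CoM")
  pw10 <- data.frame(pathway_id = "px")
  pw10$member_units <- list(paste0("u", 1:10))
  expect_false(pathway_presence(up10, pw10, 50)[1])
})

test_that("CoM pathway abundance reproduces the fixture with multiplicity split", {
  db <- fixture_db()
  corr <- correct_abundance(fixture_profile(1), db)
  up <- community_unit_profile(corr, db)
  com50 <- pathway_abundance_com(up, db, 50)
  expect_near(unname(com50$raw[, 1]), c(2, 4 / 3))
  expect_near(unname(com50$abundance[, 1]), c(0.6, 0.4))
  # PEC 70 excludes P2 entirely
  com70 <- pathway_abundance_com(up, db, 70)
  expect_near(unname(com70$abundance[, 1]), c(1, 0))
  # a pathway sharing no units has multiplicity 1: plain sum (P1 without e2 split)
  db_solo <- db
  db_solo$pathways$member_units <- list(c("e1"), c("e3", "e4"))
  com_solo <- pathway_abundance_com(up, db_solo, 0)
  expect_near(unname(com_solo$raw["P1", 1]), 4 / 3)
})

test_that("ICo evaluates the quorum per taxon and conserves the tensor sum", {
  db <- fixture_db()
  corr <- correct_abundance(fixture_profile(1), db)
  ico <- pathway_abundance_ico(corr, db, 50)
  tens <- ico$tensor$value[, , 1]
  # A detects only e2 of P2 (1/3 < 50%): contributes nothing to P2
  expect_near(unname(tens[1, ]), c(5 / 3, 0))
  # B: e2 alone is 1/2 of P1 (passes), e2+e3 are 2/3 of P2 (passes)
  expect_near(unname(tens[2, ]), c(1 / 3, 1))
  expect_near(unname(ico$profile$raw[, 1]), c(2, 1))
  # conservation: summing the tensor over taxa gives the un-normalized profile
  expect_near(colSums(ico$tensor$value), ico$profile$raw)
})

test_that("single-taxon communities give identical CoM and ICo profiles", {
  for (seed in 1:3) {
    db <- generate_synthetic_db(6, 12, 3, seed = seed)
    g <- db$genomes[1, ]
    tf <- tempfile()
    writeLines(c("lineage\tS1\tS2",
                 sprintf("k__%s; p__%s; g__%s\t1\t1",
                         g$domain, g$phylum, g$genus)), tf)
    prof <- parse_taxa_table(tf)
    corr <- correct_abundance(prof, db)
    up <- community_unit_profile(corr, db)
    for (pec in c(0, 50, 90)) {
      com <- suppressWarnings(pathway_abundance_com(up, db, pec))
      ico <- suppressWarnings(pathway_abundance_ico(corr, db, pec))
      expect_near(com$raw, ico$profile$raw)
      expect_near(com$abundance, ico$profile$abundance)
    }
  }
})

test_that("hierarchy rollup preserves column sums and is idempotent at level1", {
  db <- fixture_db()
  corr <- correct_abundance(fixture_profile(2), db)
  up <- community_unit_profile(corr, db)
  com <- pathway_abundance_com(up, db, 50)
  l2 <- rollup_hierarchy(com, db, "level2")
  l1 <- rollup_hierarchy(com, db, "level1")
  expect_near(colSums(l2$abundance), colSums(com$abundance), 1e-12)
  expect_near(colSums(l1$abundance), colSums(com$abundance), 1e-12)
  # both fixture pathways share level1 "Metabolism"
  expect_equal(l1$functions, "Metabolism")
  expect_near(unname(l1$abundance[1, ]), c(1, 1))
  expect_error(rollup_hierarchy(com, db, "level3"), "level")
})

test_that("PEC presence sets are nested across the sweep on random communities", {
  for (seed in 1:10) {
    st <- synth_study(seed, n_genomes = 6, n_units = 12, n_pathways = 4,
                      n_per_cell = 1)
    corr <- correct_abundance(st$profile, st$db)
    for (alg in c("CoM", "ICo")) {
      sweep <- suppressWarnings(pec_sweep(corr, st$db, alg))
      prof <- lapply(sweep, function(x) if (alg == "CoM") x else x$profile)
      sets <- lapply(prof, presence_sets)
      for (lv in 1:4) for (s in seq_along(sets[[1]]))
        expect_true(all(sets[[lv + 1]][[s]] %in% sets[[lv]][[s]]),
                    label = sprintf("nesting %s seed %d pec %s sample %d",
                                    alg, seed, names(sets)[lv + 1], s))
      # CoM pooling can only add detected units: CoM presence contains ICo's
      if (alg == "ICo") {
        com_sets <- lapply(suppressWarnings(pec_sweep(corr, st$db, "CoM")),
                           presence_sets)
        for (lv in seq_along(sets)) for (s in seq_along(sets[[1]]))
          expect_true(all(sets[[lv]][[s]] %in% com_sets[[lv]][[s]]))
      }
    }
  }
})

test_that("relative outputs are invariant to rescaling one input column", {
  st <- synth_study(11, n_per_cell = 1)
  tf1 <- tempfile(); tf2 <- tempfile()
  tab <- st$profile
  write_taxa_table(tab, tf1)
  raw <- readLines(tf1)
  # multiply sample 1's column by 1000
  parts <- strsplit(raw, "\t")
  for (i in 2:length(parts))
    parts[[i]][2] <- format(as.numeric(parts[[i]][2]) * 1000, digits = 15)
  writeLines(vapply(parts, paste, character(1), collapse = "\t"), tf2)
  p1 <- suppressMessages(parse_taxa_table(tf1))
  p2 <- suppressMessages(parse_taxa_table(tf2))
  c1 <- correct_abundance(p1, st$db); c2 <- correct_abundance(p2, st$db)
  a1 <- pathway_abundance_com(community_unit_profile(c1, st$db), st$db, 50)
  a2 <- pathway_abundance_com(community_unit_profile(c2, st$db), st$db, 50)
  expect_near(a1$abundance, a2$abundance, 1e-6)
})

test_that("implementation matches the brute-force oracle on random small DBs", {
  set.seed(2024)
  for (seed in 1:20) {
    db <- generate_synthetic_db(n_genomes = sample(2:5, 1),
                                n_units = sample(6:10, 1),
                                n_pathways = sample(2:3, 1), seed = seed)
    comm <- generate_synthetic_community(db, n_per_cell = 1, seed = seed + 500)
    tf <- tempfile()
    funmapper:::write_tsv_plain(comm$taxa_table, tf)
    prof <- suppressMessages(parse_taxa_table(tf))
    pec <- sample(c(0, 50, 60, 70, 80, 90), 1)
    oracle <- brute_force_infer(db, prof, pec)

    corr <- correct_abundance(prof, db)
    expect_near(corr$abundance, oracle$corrected)
    up <- community_unit_profile(corr, db)
    expect_near(up$abundance, oracle$unit_ab[rownames(up$abundance), , drop = FALSE])
    com <- suppressWarnings(pathway_abundance_com(up, db, pec))
    expect_near(com$raw, oracle$com_raw[rownames(com$raw), , drop = FALSE])
    expect_near(com$abundance, oracle$com_rel[rownames(com$abundance), , drop = FALSE])
    ico <- suppressWarnings(pathway_abundance_ico(corr, db, pec))
    expect_near(ico$profile$raw, oracle$ico_raw[rownames(ico$profile$raw), , drop = FALSE])
  }
})
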