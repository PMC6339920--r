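# Synthetic genome-function databases and communities.
#
# The generator produces fixtures that are structurally equivalent to a real
# genome-function back-end map, so the whole pipeline is testable without
# any external database: random but internally consistent taxonomies, 16S
# copy numbers spanning the biologically observed 1-15 range, uniform unit
# copy counts, and pathways of 3-12 member units over a full three-level
# functional hierarchy.

# Run code under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome-function database
#'
#' Builds a random but valid \code{FunctionDB}: a nested taxonomy is drawn
#' (two domains, a handful of phyla through genera, one species per genome),
#' 16S copy numbers are uniform on 1..15 (the span observed across
#' sequenced prokaryotes), unit copy numbers uniform on 0..\code{max_copies},
#' and each pathway receives 3-12 member units with a complete
#' level1/level2/level3 hierarchy path.  Roughly a quarter of the units are
#' created in the KO namespace and linked to the EC units by a random
#' many-to-many cross-map; pathways are defined over EC units.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param n_units total number of functional units (>= 4; pathways need at
#'   least 3 candidate EC members).
#' @param n_pathways number of pathway definitions (>= 1).
#' @param max_copies maximum per-genome unit copy count.
#' @param seed integer; the same seed always yields the identical database.
#' @return A validated \code{FunctionDB}.
#' @export
generate_synthetic_db <- function(n_genomes = 20, n_units = 40,
                                  n_pathways = 8, max_copies = 5, seed = 1) {
  if (n_genomes < 1 || n_pathways < 1 || max_copies < 1)
    stop_user("all counts must be >= 1")
  if (n_units < 3)
    stop_user("n_units must be >= 3 (pathways need at least 3 candidate members)")
  with_seed(seed, {
    n_ec <- max(3L, ceiling(0.75 * n_units))
    n_ko <- n_units - n_ec
    ec_ids <- sprintf("EC:%d.%d.%d.%d",
                      sample(1:6, n_ec, TRUE), sample(1:20, n_ec, TRUE),
                      sample(1:30, n_ec, TRUE), seq_len(n_ec))
    ko_ids <- if (n_ko > 0) sprintf("K%05d", seq_len(n_ko)) else character(0)
    units <- data.frame(
      unit_id = c(ec_ids, ko_ids),
      namespace = c(rep("EC", n_ec), rep("KO", n_ko)),
      description = paste("synthetic unit", seq_len(n_ec + n_ko)),
      stringsAsFactors = FALSE
    )

    # Nested taxonomy: parents fixed per child so lineages are consistent.
    n_phy <- max(2L, min(5L, ceiling(n_genomes / 4)))
    n_gen <- max(2L, ceiling(n_genomes / 2))
    phyla <- sprintf("phylum%02d", seq_len(n_phy))
    phy_dom <- sample(c("bacteria", "archaea"), n_phy, TRUE, prob = c(0.85, 0.15))
    classes <- sprintf("class%02d", seq_len(n_phy * 2))
    cls_phy <- rep(seq_len(n_phy), each = 2)
    orders <- sprintf("order%02d", seq_along(classes))
    families <- sprintf("family%02d", seq_along(classes))
    gen_cls <- sample(seq_along(classes), n_gen, TRUE)
    genera <- sprintf("genus%02d", seq_len(n_gen))

    gidx <- sample(seq_len(n_gen), n_genomes, TRUE)
    genomes <- data.frame(
      genome_id = sprintf("G%04d", seq_len(n_genomes)),
      domain = phy_dom[cls_phy[gen_cls[gidx]]],
      phylum = phyla[cls_phy[gen_cls[gidx]]],
      class = classes[gen_cls[gidx]],
      order = orders[gen_cls[gidx]],
      family = families[gen_cls[gidx]],
      genus = genera[gidx],
      species = sprintf("%s sp%03d", genera[gidx], seq_len(n_genomes)),
      ssu_copies = sample(1:15, n_genomes, TRUE),
      stringsAsFactors = FALSE
    )

    uc <- matrix(sample(0:max_copies, n_genomes * n_ec, TRUE),
                 nrow = n_genomes,
                 dimnames = list(genomes$genome_id, ec_ids))
    storage.mode(uc) <- "double"

    lvl1 <- c("Metabolism", "Genetic Information Processing",
              "Environmental Information Processing")
    pw_l1 <- sample(lvl1, n_pathways, TRUE)
    pw_l2 <- paste0(substr(pw_l1, 1, 3), "-sub", sample(1:2, n_pathways, TRUE))
    pathways <- data.frame(
      pathway_id = sprintf("pw%03d", seq_len(n_pathways)),
      name = sprintf("synthetic pathway %d", seq_len(n_pathways)),
      level1 = pw_l1, level2 = pw_l2,
      level3 = sprintf("synthetic pathway %d", seq_len(n_pathways)),
      stringsAsFactors = FALSE
    )
    pathways$member_units <- lapply(seq_len(n_pathways), function(i) {
      k <- sample(3:min(12L, n_ec), 1)
      sort(sample(ec_ids, k))
    })

    crossmaps <- empty_crossmaps()
    if (n_ko > 0) {
      src <- rep(ec_ids, times = sample(1:2, n_ec, TRUE))
      crossmaps <- data.frame(
        source_ns = "EC", target_ns = "KO",
        source_id = src,
        target_id = sample(ko_ids, length(src), TRUE),
        stringsAsFactors = FALSE
      )
      crossmaps <- unique(crossmaps)
    }

    function_db(genomes, uc, units, pathways, crossmaps)
  })
}

#' Generate a synthetic community study (taxa table plus metadata)
#'
#' Draws genus-level relative abundance profiles for a two-factor study
#' design mirroring a treated-versus-control longitudinal layout: a
#' \code{Status} category (Control / Treated) crossed with a
#' \code{Timepoint} category (Day2 / Day42), with \code{n_per_cell} samples
#' per cell.  Baseline abundances are log-normal across the database's
#' genera; in Treated samples a random third of the genera is perturbed by
#' the given fold change, so differential-function signal exists by
#' construction.
#'
#' @param db a \code{FunctionDB} whose genera become the community's taxa.
#' @param n_per_cell samples per Status x Timepoint cell (default 3).
#' @param effect_fold multiplicative perturbation applied to the affected
#'   genera in Treated samples (default 4).
#' @param dialect lineage dialect for the taxa table
#'   (\code{"greengenes"}, \code{"silva"} or \code{"rdp"}).
#' @param seed integer seed; identical seeds give identical bundles.
#' @return list with \code{taxa_table} (data.frame: lineage string column
#'   then one column per sample, raw positive abundances) and
#'   \code{metadata} (data.frame: sample_id, Status, Timepoint).
#' @export
generate_synthetic_community <- function(db, n_per_cell = 3, effect_fold = 4,
                                         dialect = "greengenes", seed = 1) {
  with_seed(seed, {
    lin_cols <- c("domain", "phylum", "class", "order", "family", "genus")
    lin <- unique(db$genomes[lin_cols])
    n_taxa <- nrow(lin)
    cells <- expand.grid(Status = c("Control", "Treated"),
                         Timepoint = c("Day2", "Day42"),
                         rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
    n_samp <- nrow(cells)
    sample_ids <- sprintf("S%02d", seq_len(n_samp))

    base <- exp(stats::rnorm(n_taxa, mean = 0, sd = 1))
    affected <- sample(seq_len(n_taxa), max(1L, round(n_taxa / 3)))
    abund <- matrix(0, n_taxa, n_samp, dimnames = list(NULL, sample_ids))
    for (j in seq_len(n_samp)) {
      x <- base * exp(stats::rnorm(n_taxa, 0, 0.4))
      if (cells$Status[j] == "Treated") x[affected] <- x[affected] * effect_fold
      abund[, j] <- x / sum(x)
    }

    lineage_str <- switch(
      dialect,
      greengenes = apply(lin, 1, function(r)
        paste(paste0(c("k", "p", "c", "o", "f", "g"), "__", r), collapse = "; ")),
      silva = apply(lin, 1, function(r)
        paste(c(tools::toTitleCase(r[["domain"]]), r[-1]), collapse = ";")),
      rdp = apply(lin, 1, function(r)
        paste(c("Root", tools::toTitleCase(r[["domain"]]), r[-1]), collapse = ";")),
      stop_user("unknown dialect: ", dialect)
    )

    taxa_table <- data.frame(lineage = unname(lineage_str),
                             round(abund, 8), check.names = FALSE,
                             stringsAsFactors = FALSE)
    names(taxa_table)[1] <- "#lineage"
    metadata <- data.frame(sample_id = sample_ids,
                           Status = cells$Status, Timepoint = cells$Timepoint,
                           stringsAsFactors = FALSE)
    list(taxa_table = taxa_table, metadata = metadata)
  })
}
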