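# Batch workflow commands binding the modules into the three-module
# pipeline (global mapping -> inter-sample feature analysis -> local
# mapping), with run configuration and reproducible run manifests.

#' Build a run configuration
#'
#' Validated bundle of every user choice a run depends on; serialized into
#' the run manifest so any run can be reproduced exactly.
#'
#' @param algorithm community assumption, \code{"com"} or \code{"ico"}.
#' @param namespace functional-unit namespace for pathway math.
#' @param pec single PEC level used for the tensor/network/local analyses
#'   (the sweep always covers the full 50-90 grid and an unfiltered 0).
#' @param alpha BH-corrected significance level.
#' @param rho_min network Spearman threshold.
#' @param abundance_floor,prevalence_floor core-function floors.
#' @param top_n how many top functions to report.
#' @param split multiplicity split for shared units (see inference docs).
#' @param seed integer seed for any randomized step.
#' @param out_dir output directory.
#' @return A \code{RunConfig} list.
#' @export
make_run_config <- function(algorithm = c("com", "ico"), namespace = "EC",
                            pec = 50, alpha = 0.05, rho_min = 0.6,
                            abundance_floor = 0.01, prevalence_floor = 0.8,
                            top_n = 10, split = TRUE, seed = 1,
                            out_dir = "funmapper_out") {
  algorithm <- match.arg(algorithm)
  if (!(namespace %in% unit_namespaces())) stop_user("unknown namespace: ", namespace)
  if (!(pec %in% pec_allowed())) stop_user("pec must be in ", paste(pec_allowed(), collapse = ","))
  if (alpha <= 0 || alpha >= 1) stop_user("alpha must lie in (0,1)")
  if (rho_min < -1 || rho_min > 1) stop_user("rho_min must lie in [-1,1]")
  if (abundance_floor <= 0 || abundance_floor > 1 ||
      prevalence_floor <= 0 || prevalence_floor > 1)
    stop_user("floors must lie in (0,1]")
  structure(list(algorithm = algorithm, namespace = namespace,
                 pec = as.integer(pec), alpha = alpha, rho_min = rho_min,
                 abundance_floor = abundance_floor,
                 prevalence_floor = prevalence_floor,
                 top_n = as.integer(top_n), split = isTRUE(split),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "RunConfig")
}

write_manifest <- function(out_dir, config, inputs, extra = list()) {
  manifest <- c(list(
    tool = "funmapper",
    version = as.character(utils::packageVersion("funmapper")),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(
      inputs[file.exists(inputs) & !dir.exists(inputs)]))
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_tensor_tsv <- function(ct, path) {
  long <- expand.grid(taxon = ct$taxa, func = ct$functions,
                      sample = ct$samples, stringsAsFactors = FALSE)
  long$value <- as.vector(ct$value)
  long <- long[long$value > 0, , drop = FALSE]
  names(long)[2] <- "function"
  write_tsv_plain(long, path)
  invisible(path)
}

read_tensor_tsv <- function(path, taxa_lineages = NULL) {
  long <- read_tsv_plain(path)
  long$value <- as.numeric(long$value)
  taxa <- sort(unique(long$taxon))
  funs <- sort(unique(long[["function"]]))
  samples <- sort(unique(long$sample))
  arr <- array(0, dim = c(length(taxa), length(funs), length(samples)),
               dimnames = list(taxa, funs, samples))
  arr[cbind(match(long$taxon, taxa), match(long[["function"]], funs),
            match(long$sample, samples))] <- long$value
  structure(list(taxa = taxa, functions = funs, samples = samples,
                 value = arr, normalizer = colSums(colSums(arr)),
                 taxa_lineages = taxa_lineages, pec = NA_integer_),
            class = "ContributionTensor")
}

profile_filename <- function(algorithm, namespace, level, pec) {
  sprintf("%s_%s_%s_pec%02d.tsv", tolower(algorithm), tolower(namespace),
          level, pec)
}

write_function_profile <- function(fp, namespace, out_dir) {
  write_matrix_tsv(fp$abundance,
                   file.path(out_dir, profile_filename(fp$algorithm, namespace,
                                                       fp$level, fp$pec)),
                   id_col = "function")
}

#' Run the full global mapping workflow
#'
#' Parses inputs, corrects for 16S copy number, builds unit profiles (plus
#' cross-mapped namespaces where the database has cross-maps), estimates
#' pathway profiles under the configured algorithm at PEC 0 and over the
#' 50-90 sweep with hierarchy roll-ups, and runs the community analytics
#' (top/core functions, differential tables per metadata category, JSD
#' ordination, co-contribution network from the independent-contributions
#' tensor).  All results are written as TSV plus a JSON run manifest.
#'
#' @param taxa_path taxonomic abundance TSV.
#' @param db either a \code{FunctionDB} or a database directory path.
#' @param config a \code{RunConfig}.
#' @param metadata_path optional metadata TSV (one implicit group "all"
#'   when absent).
#' @return The output directory, invisibly; side effect: files under
#'   \code{config$out_dir}.
#' @export
run_global_map <- function(taxa_path, db, config, metadata_path = NULL) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  db_path <- if (is.character(db)) db else NA_character_
  if (is.character(db)) db <- load_db(db)

  profile <- parse_taxa_table(taxa_path)
  metadata <- if (!is.null(metadata_path)) parse_metadata(metadata_path, profile)
  corrected <- correct_abundance(profile, db)
  write_tsv_plain(corrected$coverage, file.path(out_dir, "coverage_report.tsv"))

  alg <- if (config$algorithm == "com") "CoM" else "ICo"
  up <- community_unit_profile(corrected, db, config$namespace)
  write_matrix_tsv(up$abundance,
                   file.path(out_dir, sprintf("unitprofile_%s_%s.tsv",
                                              tolower(alg), tolower(config$namespace))),
                   id_col = "unit")
  # cross-mapped unit-level matrices for every namespace reachable from here
  reach <- unique(db$crossmaps$target_ns[db$crossmaps$source_ns == config$namespace])
  for (ns in reach) {
    xp <- crossmap_profile(up, db, ns)
    write_matrix_tsv(xp$abundance,
                     file.path(out_dir, sprintf("unitprofile_crossmap_%s.tsv",
                                                tolower(ns))),
                     id_col = "unit")
  }

  # unfiltered + swept pathway profiles, with hierarchy roll-ups
  sweep <- pec_sweep(corrected, db, alg, config$namespace, config$split)
  p0 <- if (alg == "CoM") pathway_abundance_com(up, db, 0, config$split)
        else pathway_abundance_ico(corrected, db, 0, config$namespace, config$split)$profile
  profiles <- c(list(`0` = p0),
                lapply(sweep, function(x) if (alg == "CoM") x else x$profile))
  for (fp in profiles) {
    write_function_profile(fp, config$namespace, out_dir)
    for (lv in c("level2", "level1"))
      write_function_profile(rollup_hierarchy(fp, db, lv), config$namespace, out_dir)
  }

  # contribution tensor at the configured PEC (always ICo by definition)
  ico <- pathway_abundance_ico(corrected, db, config$pec, config$namespace,
                               config$split)
  write_tensor_tsv(ico$tensor, file.path(out_dir, "contribution_tensor.tsv"))

  # analytics on the configured algorithm/PEC profile
  fp_main <- profiles[[as.character(config$pec)]]
  categories <- if (!is.null(metadata)) names(metadata$categories) else NULL
  for (cat_name in c(list(NULL), as.list(categories))) {
    groups <- group_labels(metadata, cat_name, profile$samples)
    tag <- if (is.null(cat_name)) "all" else cat_name
    tops <- top_functions(fp_main, min(config$top_n, length(fp_main$functions)),
                          groups)
    write_tsv_plain(tops$ranking,
                    file.path(out_dir, sprintf("top_functions_%s.tsv", tag)))
    core <- core_functions(fp_main, config$abundance_floor,
                           config$prevalence_floor, groups)
    write_tsv_plain(core, file.path(out_dir, sprintf("core_functions_%s.tsv", tag)))
    if (!is.null(cat_name)) {
      sizes <- table(groups)
      if (length(sizes) >= 2 && all(sizes >= 2)) {
        dt <- differentiating_functions(fp_main, groups)
        write_tsv_plain(dt, file.path(out_dir,
                                      sprintf("differential_%s.tsv", tag)))
      }
    }
  }

  if (length(fp_main$samples) >= 3 &&
      !all(as.matrix(stats::dist(t(fp_main$abundance))) == 0)) {
    ord <- jsd_pcoa(fp_main, k = min(3, length(fp_main$samples) - 1))
    coords <- data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                         stringsAsFactors = FALSE)
    write_tsv_plain(coords, file.path(out_dir, "ordination_coordinates.tsv"))
    write_tsv_plain(data.frame(axis = seq_along(ord$eigenvalues),
                               eigenvalue = ord$eigenvalues,
                               variance_explained = ord$variance_explained),
                    file.path(out_dir, "ordination_eigenvalues.tsv"))
  }

  if (length(ico$tensor$samples) >= 4) {
    net <- contribution_network(ico$tensor, config$rho_min, config$alpha)
    write_tsv_plain(net$edges, file.path(out_dir, "network_edges.tsv"))
    write_tsv_plain(net$node_metrics, file.path(out_dir, "network_node_metrics.tsv"))
    igraph::write_graph(net$graph, file.path(out_dir, "network.graphml"),
                        format = "graphml")
  }

  write_manifest(out_dir, config,
                 c(taxa_path, metadata_path %||% character(0),
                   if (!is.na(db_path)) file.path(db_path, "genomes.tsv")),
                 extra = list(db_path = db_path, command = "global-map",
                              samples = profile$samples))
  invisible(out_dir)
}

read_function_profile_tsv <- function(path, level = "level3",
                                      algorithm = "external", pec = 0L) {
  df <- read_tsv_plain(path)
  mat <- as.matrix(df[-1])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  new_function_profile(mat, level, algorithm, pec)
}

#' Inter-sample feature analysis (rapid or batch mode)
#'
#' Rapid mode tests a single function profile (any functions x samples TSV,
#' from this package or an external inference tool) between the classes of
#' one metadata category.  Batch mode consumes a PEC sweep — the output
#' directory of \code{\link{run_global_map}} or a zip of it — testing every
#' level and adding the consensus significance matrix across the five
#' cut-offs.  When the run contains a contribution tensor, a queryable
#' function x taxon table of per-class mean contributions is also written.
#'
#' @param input rapid: path to one profile TSV; batch: directory or
#'   \code{.zip} containing \code{<alg>_<ns>_level3_pec<NN>.tsv} for all of
#'   50, 60, 70, 80, 90.
#' @param metadata_path metadata TSV.
#' @param category metadata category to compare (default: first column).
#' @param config a \code{RunConfig} (alpha and out_dir are used).
#' @param mode \code{"rapid"} or \code{"batch"}.
#' @return The output directory, invisibly.
#' @export
run_isfa <- function(input, metadata_path, config, category = NULL,
                     mode = c("rapid", "batch")) {
  mode <- match.arg(mode)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (mode == "batch" && grepl("\\.zip$", input)) {
    exdir <- file.path(tempdir(), paste0("isfa_unzip_", basename(input)))
    utils::unzip(input, exdir = exdir)
    input <- exdir
  }

  load_groups <- function(fp) {
    md <- read_tsv_plain(metadata_path)
    cat_name <- category %||% names(md)[2]
    if (!(cat_name %in% names(md))) stop_user("unknown metadata category: ", cat_name)
    lab <- stats::setNames(md[[cat_name]], md[[1]])
    missing_s <- setdiff(fp$samples, names(lab))
    if (length(missing_s))
      stop_user("metadata lacks sample(s): ", paste(missing_s, collapse = ", "))
    lab[fp$samples]
  }

  if (mode == "rapid") {
    fp <- read_function_profile_tsv(input)
    dt <- differentiating_functions(fp, load_groups(fp))
    write_tsv_plain(dt, file.path(out_dir, "differential_rapid.tsv"))
  } else {
    files <- list.files(input, pattern = "_level3_pec[5-9]0\\.tsv$",
                        full.names = TRUE)
    lv <- sub(".*_pec([0-9]+)\\.tsv$", "\\1", files)
    missing_lv <- setdiff(as.character(pec_grid()), lv)
    if (length(missing_lv))
      stop_user("sweep bundle missing PEC level(s): ",
                paste(missing_lv, collapse = ", "))
    tables <- list()
    for (i in order(as.integer(lv))) {
      fp <- read_function_profile_tsv(files[i], pec = as.integer(lv[i]))
      keep <- rowSums(fp$raw) > 0  # functions surviving this PEC filter
      fp$abundance <- fp$abundance[keep, , drop = FALSE]
      fp$raw <- fp$raw[keep, , drop = FALSE]
      fp$functions <- fp$functions[keep]
      dt <- differentiating_functions(fp, load_groups(fp))
      tables[[lv[i]]] <- dt
      write_tsv_plain(dt, file.path(out_dir,
                                    sprintf("differential_pec%s.tsv", lv[i])))
    }
    cons <- pec_consensus(tables, config$alpha)
    cm <- data.frame(function_id = rownames(cons$matrix), cons$matrix,
                     consensus_score = cons$score,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(cm)[2:6] <- paste0("pec", names(tables))
    write_tsv_plain(cm, file.path(out_dir, "pec_consensus.tsv"))

    tensor_path <- file.path(input, "contribution_tensor.tsv")
    if (file.exists(tensor_path)) {
      ct <- read_tensor_tsv(tensor_path)
      md <- read_tsv_plain(metadata_path)
      cat_name <- category %||% names(md)[2]
      lab <- stats::setNames(md[[cat_name]], md[[1]])[ct$samples]
      glabs <- sort(unique(lab))
      rows <- list()
      for (pi in seq_along(ct$functions)) {
        slab <- ct$value[, pi, , drop = TRUE]
        if (is.null(dim(slab)))
          slab <- matrix(slab, nrow = length(ct$taxa),
                         dimnames = list(ct$taxa, ct$samples))
        gm <- vapply(glabs, function(g)
          rowMeans(slab[, names(lab)[lab == g], drop = FALSE]),
          numeric(length(ct$taxa)))
        if (is.null(dim(gm))) gm <- matrix(gm, nrow = length(ct$taxa))
        keep <- rowSums(gm) > 0
        if (!any(keep)) next
        df <- data.frame(`function` = ct$functions[pi], taxon = ct$taxa[keep],
                         gm[keep, , drop = FALSE], check.names = FALSE,
                         stringsAsFactors = FALSE, row.names = NULL)
        names(df)[-(1:2)] <- paste0("mean_", glabs)
        rows[[length(rows) + 1]] <- df
      }
      if (length(rows))
        write_tsv_plain(do.call(rbind, rows),
                        file.path(out_dir, "contribution_table.tsv"))
    }
  }
  write_manifest(out_dir, config, c(input, metadata_path),
                 extra = list(command = "isfa", mode = mode))
  invisible(out_dir)
}

#' Local mapping of one pathway from a global-map run
#'
#' Reads the referenced global-map output (its manifest locates the
#' database), rebuilds the pathway's enzyme profile and contributor table
#' grouped by a metadata category, and, for KEGG-mappable namespaces,
#' writes Search&Color and 3D-height files contrasting the category's
#' first two classes.
#'
#' @param pathway_id pathway of interest (typos get suggestions).
#' @param global_dir output directory of a \code{\link{run_global_map}} run.
#' @param config a \code{RunConfig} (out_dir is used).
#' @param metadata_path optional metadata TSV; \code{category} selects the
#'   grouping column.
#' @param category metadata category (default: first column).
#' @return The output directory, invisibly.
#' @export
run_local_map <- function(pathway_id, global_dir, config,
                          metadata_path = NULL, category = NULL) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- jsonlite::read_json(file.path(global_dir, "manifest.json"))
  db_path <- manifest$db_path
  if (is.null(db_path) || is.na(db_path))
    stop_user("global-map manifest does not record a database path")
  db <- load_db(db_path)
  pw <- find_pathway(db, pathway_id)

  alg <- manifest$config$algorithm
  ns <- manifest$config$namespace
  up_path <- file.path(global_dir, sprintf("unitprofile_%s_%s.tsv",
                                           tolower(alg), tolower(ns)))
  updf <- read_tsv_plain(up_path)
  upmat <- as.matrix(updf[-1]); storage.mode(upmat) <- "double"
  rownames(upmat) <- updf[[1]]
  up <- new_unit_profile(upmat, ns, toupper(alg))

  groups <- NULL
  if (!is.null(metadata_path)) {
    md <- read_tsv_plain(metadata_path)
    cat_name <- category %||% names(md)[2]
    if (!(cat_name %in% names(md))) stop_user("unknown metadata category: ", cat_name)
    groups <- stats::setNames(md[[cat_name]], md[[1]])[up$samples]
  }

  pr <- pathway_enzyme_profile(up, db, pathway_id, groups)
  write_matrix_tsv(pr$enzyme_profile,
                   file.path(out_dir, sprintf("enzyme_profile_%s.tsv", pathway_id)),
                   id_col = "unit")
  write_tsv_plain(data.frame(sample = names(pr$coverage),
                             coverage = unname(pr$coverage)),
                  file.path(out_dir, sprintf("coverage_%s.tsv", pathway_id)))

  ct <- read_tensor_tsv(file.path(global_dir, "contribution_tensor.tsv"))
  if (pathway_id %in% ct$functions) {
    lin_df <- data.frame(matrix("", length(ct$taxa), 7,
                                dimnames = list(NULL, taxonomic_ranks())),
                         stringsAsFactors = FALSE)
    lin_parts <- strsplit(ct$taxa, "|", fixed = TRUE)
    for (i in seq_along(lin_parts))
      lin_df[i, seq_along(lin_parts[[i]])] <- lin_parts[[i]]
    ct$taxa_lineages <- lin_df
    contrib <- pathway_contributors(ct, pathway_id,
                                    if (!is.null(groups)) groups[ct$samples])
    write_tsv_plain(contrib,
                    file.path(out_dir, sprintf("contributors_%s.tsv", pathway_id)))
  } else {
    fm_log("WARN", "pathway ", pathway_id,
           " has no entries in the contribution tensor at the run's PEC")
  }

  if (pr$namespace %in% c("EC", "KO")) {
    classes <- colnames(pr$group_means)
    ca <- classes[1]; cb <- if (length(classes) >= 2) classes[2] else classes[1]
    export_kegg_colormap(pr, ca, cb,
                         file.path(out_dir, sprintf("kegg_colormap_%s.txt", pathway_id)))
    export_kegg_heightmap(pr,
                          file.path(out_dir, sprintf("kegg_heights_%s.txt", pathway_id)))
  } else {
    fm_log("WARN", "namespace ", pr$namespace, " is not KEGG-mappable; export skipped")
  }

  write_manifest(out_dir, config, file.path(global_dir, "manifest.json"),
                 extra = list(command = "local-map", pathway = pathway_id,
                              global_run = global_dir))
  invisible(out_dir)
}

#' Write a complete synthetic study bundle
#'
#' Generates a synthetic genome-function database plus a matching taxa
#' table and two-category metadata (Status x Timepoint), saved under
#' \code{out_dir} as \code{db/}, \code{taxa.tsv} and \code{metadata.tsv} —
#' inputs on which every other workflow command runs.
#'
#' @param out_dir output directory.
#' @param seed integer seed; the same seed always writes the same bundle.
#' @param n_genomes,n_units,n_pathways,n_per_cell generator sizes.
#' @return list with the written paths and the in-memory objects.
#' @export
run_synth <- function(out_dir, seed = 1, n_genomes = 20, n_units = 40,
                      n_pathways = 8, n_per_cell = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  db <- generate_synthetic_db(n_genomes, n_units, n_pathways, seed = seed)
  comm <- generate_synthetic_community(db, n_per_cell = n_per_cell,
                                       seed = seed + 1)
  db_dir <- file.path(out_dir, "db")
  save_db(db, db_dir)
  taxa_path <- file.path(out_dir, "taxa.tsv")
  write_tsv_plain(comm$taxa_table, taxa_path)
  metadata_path <- file.path(out_dir, "metadata.tsv")
  write_tsv_plain(comm$metadata, metadata_path)
  list(db_dir = db_dir, taxa_path = taxa_path, metadata_path = metadata_path,
       db = db, community = comm)
}
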