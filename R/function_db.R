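# Genome-function database: the back-end map that drives all inference.
#
# A FunctionDB holds, for a collection of prokaryotic genomes, the genome's
# taxonomic lineage, its 16S rRNA gene copy number, and its copy number for
# every catalogued functional unit (EC / KO / COG / Pfam / TIGRfam), plus
# pathway definitions over a three-level functional hierarchy and
# many-to-many cross-maps between unit namespaces.

#' Construct a genome-function database
#'
#' Assembles and validates the container used by all inference functions.
#'
#' @param genomes data.frame with columns \code{genome_id}, the seven
#'   canonical ranks (\code{domain} ... \code{species}; "" where unnamed),
#'   and \code{ssu_copies} (positive integer 16S rRNA gene copies).
#' @param unit_copies numeric matrix, genomes x units, of non-negative copy
#'   counts; rownames are genome ids, colnames unit ids.
#' @param units data.frame with columns \code{unit_id}, \code{namespace}
#'   (one of \code{\link{unit_namespaces}}), \code{description}.
#' @param pathways data.frame with columns \code{pathway_id}, \code{name},
#'   \code{level1}, \code{level2}, \code{level3} and a list-column
#'   \code{member_units} of character vectors (all one namespace per pathway).
#' @param crossmaps data.frame with columns \code{source_ns},
#'   \code{target_ns}, \code{source_id}, \code{target_id}; may be empty.
#'
#' @return An object of class \code{FunctionDB}.
#' @export
function_db <- function(genomes, unit_copies, units, pathways,
                        crossmaps = empty_crossmaps()) {
  db <- structure(
    list(genomes = genomes, unit_copies = unit_copies, units = units,
         pathways = pathways, crossmaps = crossmaps),
    class = "FunctionDB"
  )
  validate_function_db(db)
  db
}

empty_crossmaps <- function() {
  data.frame(source_ns = character(), target_ns = character(),
             source_id = character(), target_id = character(),
             stringsAsFactors = FALSE)
}

#' Validate a FunctionDB's invariants
#'
#' Checks referential integrity (every unit referenced by a genome or a
#' pathway or a cross-map exists in the unit catalog), positivity of 16S
#' copies, non-negativity of unit copies, namespace membership, pathway
#' hierarchy completeness and id uniqueness.  Fatal on any violation.
#'
#' @param db a \code{FunctionDB}.
#' @return \code{db}, invisibly.
#' @export
validate_function_db <- function(db) {
  g <- db$genomes
  need <- c("genome_id", taxonomic_ranks(), "ssu_copies")
  if (!all(need %in% names(g)))
    stop_user("genomes table missing columns: ",
              paste(setdiff(need, names(g)), collapse = ", "))
  if (nrow(g) < 1) stop_user("FunctionDB needs at least one genome")
  if (anyDuplicated(g$genome_id))
    stop_user("duplicate genome_id: ",
              paste(unique(g$genome_id[duplicated(g$genome_id)]), collapse = ", "))
  if (any(g$ssu_copies < 1) || any(g$ssu_copies != round(g$ssu_copies)))
    stop_user("ssu_copies must be integers >= 1; offending genomes: ",
              paste(g$genome_id[g$ssu_copies < 1 | g$ssu_copies != round(g$ssu_copies)],
                    collapse = ", "))

  u <- db$units
  if (nrow(u) < 1) stop_user("unit catalog is empty")
  if (!all(u$namespace %in% unit_namespaces()))
    stop_user("unknown namespace(s): ",
              paste(setdiff(u$namespace, unit_namespaces()), collapse = ", "))
  if (anyDuplicated(paste(u$namespace, u$unit_id)))
    stop_user("duplicate unit ids within a namespace")

  m <- db$unit_copies
  if (!is.matrix(m) || !identical(rownames(m), g$genome_id))
    stop_user("unit_copies must be a matrix with one row per genome, in order")
  dangling <- setdiff(colnames(m), u$unit_id)
  if (length(dangling))
    stop_user("unit_copies references unknown units: ",
              paste(dangling, collapse = ", "))
  if (any(m < 0)) stop_user("negative unit copy counts")

  p <- db$pathways
  if (nrow(p) < 1) stop_user("FunctionDB needs at least one pathway")
  if (anyDuplicated(p$pathway_id)) stop_user("duplicate pathway_id")
  if (any(!nzchar(p$level1)) || any(!nzchar(p$level2)) || any(!nzchar(p$level3)))
    stop_user("every pathway needs a full level1/level2/level3 hierarchy path")
  for (i in seq_len(nrow(p))) {
    mu <- p$member_units[[i]]
    if (length(mu) == 0)
      stop_user("pathway ", p$pathway_id[i], " has no member units")
    missing_u <- setdiff(mu, u$unit_id)
    if (length(missing_u))
      stop_user("pathway ", p$pathway_id[i],
                " references unknown units: ", paste(missing_u, collapse = ", "))
    ns <- unique(u$namespace[match(mu, u$unit_id)])
    if (length(ns) != 1)
      stop_user("pathway ", p$pathway_id[i], " mixes unit namespaces")
  }

  cm <- db$crossmaps
  if (nrow(cm)) {
    bad <- !(cm$source_id %in% u$unit_id) | !(cm$target_id %in% u$unit_id)
    if (any(bad))
      stop_user("crossmap references unknown units: ",
                paste(unique(c(cm$source_id[bad], cm$target_id[bad])), collapse = ", "))
  }
  invisible(db)
}

#' @export
print.FunctionDB <- function(x, ...) {
  cat(sprintf(
    "FunctionDB: %d genomes, %d units (%s), %d pathways, %d cross-map pairs\n",
    nrow(x$genomes), nrow(x$units),
    paste(sprintf("%s:%d", names(table(x$units$namespace)),
                  as.integer(table(x$units$namespace))), collapse = " "),
    nrow(x$pathways), nrow(x$crossmaps)))
  invisible(x)
}

#' Load a FunctionDB from a directory of TSV tables
#'
#' Expects \code{genomes.tsv} (genome_id, the seven ranks, ssu_copies, then
#' one column per unit id), \code{units.tsv} (unit_id, namespace,
#' description), \code{pathways.tsv} (pathway_id, name, level1..level3,
#' member_units semicolon-joined) and \code{crossmaps.tsv} (source_ns,
#' target_ns, source_id, target_id).
#'
#' @param path directory containing the four tables.
#' @return A validated \code{FunctionDB}.
#' @seealso \code{\link{save_db}} for the inverse; the round trip is lossless.
#' @export
load_db <- function(path) {
  tabs <- c("genomes", "units", "pathways", "crossmaps")
  files <- file.path(path, paste0(tabs, ".tsv"))
  missing_t <- tabs[!file.exists(files)]
  if (length(missing_t))
    stop_user("database directory ", path, " is missing table(s): ",
              paste(missing_t, collapse = ", "))

  units <- read_tsv_plain(files[2])
  graw <- read_tsv_plain(files[1])
  fixed <- c("genome_id", taxonomic_ranks(), "ssu_copies")
  if (!all(fixed %in% names(graw)))
    stop_user("genomes.tsv missing columns: ",
              paste(setdiff(fixed, names(graw)), collapse = ", "))
  unit_cols <- setdiff(names(graw), fixed)
  genomes <- graw[fixed]
  genomes$ssu_copies <- as.numeric(genomes$ssu_copies)
  uc <- as.matrix(graw[unit_cols])
  storage.mode(uc) <- "double"
  rownames(uc) <- genomes$genome_id

  praw <- read_tsv_plain(files[3])
  pathways <- praw[c("pathway_id", "name", "level1", "level2", "level3")]
  pathways$member_units <- lapply(strsplit(praw$member_units, ";", fixed = TRUE),
                                  trimws)

  crossmaps <- read_tsv_plain(files[4])
  if (!nrow(crossmaps)) crossmaps <- empty_crossmaps()

  function_db(genomes, uc, units, pathways, crossmaps)
}

#' Save a FunctionDB to a directory of TSV tables
#'
#' Inverse of \code{\link{load_db}}; the serialization is lossless so that
#' fixtures can be diffed bit-exactly.
#'
#' @param db a \code{FunctionDB}.
#' @param path output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
save_db <- function(db, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  g <- cbind(db$genomes,
             as.data.frame(db$unit_copies, check.names = FALSE))
  write_tsv_plain(g, file.path(path, "genomes.tsv"))
  write_tsv_plain(db$units, file.path(path, "units.tsv"))
  p <- db$pathways
  pout <- data.frame(pathway_id = p$pathway_id, name = p$name,
                     level1 = p$level1, level2 = p$level2, level3 = p$level3,
                     member_units = vapply(p$member_units, paste,
                                           character(1), collapse = ";"),
                     stringsAsFactors = FALSE)
  write_tsv_plain(pout, file.path(path, "pathways.tsv"))
  write_tsv_plain(db$crossmaps, file.path(path, "crossmaps.tsv"))
  invisible(path)
}

#' Average genome copy numbers for a taxonomic lineage
#'
#' Finds every genome whose lineage matches the query at \code{rank} and at
#' every ancestor rank named in the query (exact string match after
#' \code{\link{normalize_taxon_name}}), and returns the arithmetic mean of
#' their unit copy numbers and 16S copy numbers.  The unweighted mean over
#' matching genomes is the aggregation convention of this tool genre; it is
#' order-independent and treats every sequenced genome equally.
#'
#' @param db a \code{FunctionDB}.
#' @param lineage named character vector or list, rank name -> taxon name
#'   (any subset of the canonical ranks).
#' @param rank the rank at which to match; must name an entry of
#'   \code{lineage} and be one of \code{\link{taxonomic_ranks}}.
#' @return list with \code{unit_copies} (named numeric vector over all db
#'   units; empty when no match), \code{ssu_copies} (mean 16S copies, NA
#'   when no match) and \code{n_matched}.
#' @export
taxon_lookup <- function(db, lineage, rank) {
  ranks <- taxonomic_ranks()
  if (!(rank %in% ranks)) stop_user("unknown rank: ", rank)
  lineage <- unlist(lineage)
  qranks <- ranks[ranks %in% names(lineage)]
  qranks <- qranks[seq_len(match(rank, qranks))]
  if (is.na(match(rank, names(lineage))))
    stop_user("lineage has no name at rank ", rank)

  keep <- rep(TRUE, nrow(db$genomes))
  for (r in qranks) {
    qname <- normalize_taxon_name(lineage[[r]])
    if (!nzchar(qname)) next
    keep <- keep & (normalize_taxon_name(db$genomes[[r]]) == qname)
  }
  idx <- which(keep)
  if (!length(idx)) {
    return(list(unit_copies = numeric(0), ssu_copies = NA_real_, n_matched = 0L))
  }
  list(
    unit_copies = colMeans(db$unit_copies[idx, , drop = FALSE]),
    ssu_copies = mean(db$genomes$ssu_copies[idx]),
    n_matched = length(idx)
  )
}

# Pathway multiplicity: for each unit id, the number of pathway definitions
# (in the unit's namespace) containing it.  Units in no pathway get 1 so
# division is always safe.
unit_multiplicity <- function(db) {
  all_units <- unlist(db$pathways$member_units)
  tab <- table(all_units)
  mult <- stats::setNames(rep(1, nrow(db$units)), db$units$unit_id)
  mult[names(tab)] <- as.numeric(tab)
  mult
}

# Units belonging to a namespace, in catalog order.
namespace_units <- function(db, namespace) {
  db$units$unit_id[db$units$namespace == namespace]
}
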