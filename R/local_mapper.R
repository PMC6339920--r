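# Single-pathway drill-down: enzyme-level profiles, per-taxon contributor
# tables in lineage context ("dendrobar" data), and KEGG Mapper exports.

find_pathway <- function(db, pathway_id) {
  i <- match(pathway_id, db$pathways$pathway_id)
  if (is.na(i)) {
    near <- agrep(pathway_id, db$pathways$pathway_id,
                  max.distance = 0.3, value = TRUE)
    stop_user("unknown pathway '", pathway_id, "'",
              if (length(near)) paste0("; did you mean: ",
                                       paste(near, collapse = ", ")) else "")
  }
  db$pathways[i, , drop = FALSE]
}

#' Enzyme-level profile of one pathway
#'
#' Restricts a unit profile to the pathway's member units and renormalizes
#' each sample within the pathway, so columns show the internal enzyme
#' composition; per-sample coverage is the detected-member fraction (the
#' same count the PEC quorum uses).
#'
#' @param up a \code{UnitProfile} in the pathway's namespace.
#' @param db a \code{FunctionDB}.
#' @param pathway_id pathway to profile (near-matches suggested on typos).
#' @param groups optional named label vector over samples; per-class mean
#'   member abundances (un-normalized) are attached for downstream exports.
#' @return A \code{PathwayReport} with \code{enzyme_profile} (members x
#'   samples, columns summing to 1 where coverage > 0), \code{coverage},
#'   and \code{group_means}.
#' @export
pathway_enzyme_profile <- function(up, db, pathway_id, groups = NULL) {
  pw <- find_pathway(db, pathway_id)
  members <- pw$member_units[[1]]
  ns <- unique(db$units$namespace[match(members, db$units$unit_id)])
  if (ns != up$namespace)
    stop_user("pathway ", pathway_id, " is defined over ", ns,
              " units but the profile is ", up$namespace)
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(up$samples)), up$samples)

  raw <- matrix(0, length(members), length(up$samples),
                dimnames = list(members, up$samples))
  present <- intersect(members, up$units)
  raw[present, ] <- up$abundance[present, , drop = FALSE]
  coverage <- colSums(raw > 0) / length(members)
  prof <- renormalize_columns(raw)
  if (any(coverage == 0))
    fm_log("WARN", "pathway ", pathway_id, " undetected in sample(s): ",
           paste(names(coverage)[coverage == 0], collapse = ", "))
  gm <- vapply(sort(unique(groups)), function(g)
    rowMeans(raw[, names(groups)[groups == g], drop = FALSE]),
    numeric(length(members)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = length(members),
                                     dimnames = list(members, sort(unique(groups))))
  structure(list(pathway_id = pathway_id, members = members, namespace = ns,
                 enzyme_profile = prof, coverage = coverage,
                 group_means = gm, contributors = NULL),
            class = "PathwayReport")
}

#' Per-taxon contributors to one pathway, in lineage context
#'
#' For each metadata group, the mean (over the group's samples) of each
#' taxon's un-normalized contribution to the pathway, attached to the full
#' lineage path so a lineage tree with leaf bars ("dendrobar") can be
#' rendered.  Taxa contributing nothing in every group are omitted.
#'
#' @param ct a \code{ContributionTensor}.
#' @param pathway_id pathway present on the tensor's function axis.
#' @param groups optional named label vector over samples.
#' @return data.frame: taxon, lineage (semicolon-joined path), one
#'   \code{mean_<group>} column per group.
#' @export
pathway_contributors <- function(ct, pathway_id, groups = NULL) {
  pi <- match(pathway_id, ct$functions)
  if (is.na(pi)) stop_user("pathway ", pathway_id, " not in contribution tensor")
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(ct$samples)), ct$samples)
  slab <- ct$value[, pi, , drop = TRUE]
  if (is.null(dim(slab)))
    slab <- matrix(slab, nrow = length(ct$taxa),
                   dimnames = list(ct$taxa, ct$samples))
  glabs <- sort(unique(groups))
  gm <- vapply(glabs, function(g)
    rowMeans(slab[, names(groups)[groups == g], drop = FALSE]),
    numeric(length(ct$taxa)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = length(ct$taxa),
                                     dimnames = list(ct$taxa, glabs))
  keep <- rowSums(gm) > 0
  lin <- ct$taxa_lineages[keep, taxonomic_ranks(), drop = FALSE]
  path <- apply(lin, 1, function(r) paste(r[nzchar(r)], collapse = ";"))
  out <- data.frame(taxon = ct$taxa[keep], lineage = unname(path),
                    gm[keep, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[-(1:2)] <- paste0("mean_", glabs)
  out
}

# Diverging 5-bin palette over log2 ratio clipped to +/-2 (class_b high ->
# first bin, class_a high -> last).  Background hex codes, with foreground
# chosen for contrast.
kegg_palette <- function() {
  list(bg = c("#2166ac", "#92c5de", "#cccccc", "#f4a582", "#b2182b"),
       fg = c("#ffffff", "#000000", "#000000", "#000000", "#ffffff"))
}

kegg_unit_id <- function(unit_id, namespace) {
  if (namespace == "EC") sub("^EC:", "", unit_id) else unit_id
}

#' Export a KEGG Mapper Search&Color file for a pathway
#'
#' One line per member unit, \code{<kegg-id><TAB><bgcolor>,<fgcolor>}, in
#' the dialect accepted by KEGG Mapper's Search&Color Pathway tool.  The
#' background colour encodes the log2 ratio of the two class means (with a
#' 1e-9 pseudocount) on a 5-bin diverging scale clipped to +/-2; units
#' undetected in both classes get the neutral grey mid-bin.
#'
#' @param pr a \code{PathwayReport} with group means for both classes.
#' @param class_a,class_b group labels to contrast (a high = warm colours).
#' @param path output file (plain ASCII, LF endings).
#' @param palette list with \code{bg} and \code{fg} hex vectors of length 5.
#' @return \code{path}, invisibly.
#' @export
export_kegg_colormap <- function(pr, class_a, class_b, path,
                                 palette = kegg_palette()) {
  if (!(pr$namespace %in% c("EC", "KO")))
    stop_user("KEGG export needs EC or KO units; pathway is ", pr$namespace)
  gm <- pr$group_means
  missing_g <- setdiff(c(class_a, class_b), colnames(gm))
  if (length(missing_g))
    stop_user("class(es) not in grouping: ", paste(missing_g, collapse = ", "))
  eps <- 1e-9
  a <- gm[, class_a]; b <- gm[, class_b]
  ratio <- pmin(2, pmax(-2, log2((a + eps) / (b + eps))))
  bin <- pmin(5L, findInterval(ratio, seq(-2, 2, length.out = 6),
                               rightmost.closed = TRUE))
  bin[a == 0 & b == 0] <- 3L  # undetected everywhere: neutral grey
  lines <- sprintf("%s\t%s,%s",
                   vapply(pr$members, kegg_unit_id, character(1), pr$namespace),
                   palette$bg[bin], palette$fg[bin])
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Export KEGG 3D-map heights for a pathway
#'
#' Companion numeric file for KEGG Mapper's 3D view: one line per member
#' unit, \code{<kegg-id><TAB><height>}, height being the unit's mean
#' abundance over all samples.
#'
#' @param pr a \code{PathwayReport}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_kegg_heightmap <- function(pr, path) {
  if (!(pr$namespace %in% c("EC", "KO")))
    stop_user("KEGG export needs EC or KO units; pathway is ", pr$namespace)
  h <- rowMeans(pr$group_means)
  lines <- sprintf("%s\t%.10g",
                   vapply(pr$members, kegg_unit_id, character(1), pr$namespace),
                   h)
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Strictly parse a KEGG Search&Color file
#'
#' Accepts only the exact dialect this package emits: per line a KEGG id,
#' one tab, then \code{#rrggbb,#rrggbb}.  Used to round-trip-test exports.
#'
#' @param path file to parse.
#' @return data.frame: kegg_id, bgcolor, fgcolor.
#' @export
parse_kegg_colormap <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec(
    "^([A-Za-z0-9._-]+)\t(#[0-9a-f]{6}),(#[0-9a-f]{6})$", lines))
  bad <- which(vapply(m, length, integer(1)) != 4)
  if (length(bad))
    stop_user("malformed KEGG colour line(s): ", paste(bad, collapse = ", "))
  data.frame(kegg_id = vapply(m, `[`, character(1), 2),
             bgcolor = vapply(m, `[`, character(1), 3),
             fgcolor = vapply(m, `[`, character(1), 4),
             stringsAsFactors = FALSE)
}
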