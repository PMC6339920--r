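# Core inference: 16S copy-number correction, community functional-unit
# profiles, namespace cross-mapping, and pathway abundance estimation under
# the two community assumptions:
#
#   CoM (co-metabolism)          - members pool the functional units they
#                                  encode; pathway quorum and abundance are
#                                  evaluated on the pooled community profile.
#   ICo (independent contributions) - each taxon is an independent
#                                  functioning entity; quorum and pathway
#                                  abundance are evaluated per taxon on its
#                                  private unit repertoire, then summed.
#
# Pathway presence uses the pathway exclusion cut-off (PEC): a pathway is
# reported present only when the fraction of its member units detected
# (strictly positive abundance) reaches the cut-off, swept over 50-90%.

#' Correct taxon abundances for 16S rRNA gene copy number
#'
#' Divides each taxon's relative abundance by the mean 16S copy number of
#' the genomes matching its lineage (at its deepest named rank), then
#' renormalizes each sample.  Taxa matching no genome are dropped; their
#' per-sample mass is accounted in the coverage report.  Samples whose
#' entire mass is unmatched are flagged uninferable.
#'
#' @param profile a \code{TaxaProfile}.
#' @param db a \code{FunctionDB}.
#' @return A \code{CorrectedProfile}: list with \code{abundance} (matched
#'   taxa x samples, columns summing to 1), \code{taxa} (their lineages),
#'   \code{copy_matrix} (matched taxa x db units, mean copy numbers),
#'   \code{ssu} (mean 16S copies per matched taxon), \code{coverage}
#'   (per-sample dropped mass and uninferable flag) and \code{n_matched}
#'   genomes per taxon.
#' @export
correct_abundance <- function(profile, db) {
  ranks <- taxonomic_ranks()
  n_taxa <- nrow(profile$taxa)
  hits <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    dr <- profile$taxa$deepest_rank[i]
    lin <- stats::setNames(as.character(profile$taxa[i, ranks]), ranks)
    lin <- lin[nzchar(lin)]
    hits[[i]] <- taxon_lookup(db, lin, dr)
  }
  matched <- vapply(hits, function(h) h$n_matched > 0, logical(1))
  if (!any(matched)) stop_user("no taxon in the profile matches any genome")
  if (any(!matched))
    fm_log("WARN", sum(!matched), " taxa match no genome and are dropped")

  ab <- profile$abundance
  dropped_mass <- colSums(ab[!matched, , drop = FALSE])
  ssu <- vapply(hits[matched], `[[`, numeric(1), "ssu_copies")
  nm <- vapply(hits[matched], `[[`, integer(1), "n_matched")
  copy_matrix <- do.call(rbind, lapply(hits[matched], `[[`, "unit_copies"))

  corrected <- sweep(ab[matched, , drop = FALSE], 1, ssu, "/")
  uninferable <- colSums(corrected) == 0
  corrected <- renormalize_columns(corrected)
  rownames(copy_matrix) <- rownames(corrected)
  if (any(uninferable))
    fm_log("WARN", "uninferable sample(s), all mass unmatched: ",
           paste(profile$samples[uninferable], collapse = ", "))

  coverage <- data.frame(sample = profile$samples,
                         dropped_mass = unname(dropped_mass),
                         uninferable = unname(uninferable),
                         stringsAsFactors = FALSE)
  structure(list(abundance = corrected,
                 taxa = profile$taxa[matched, , drop = FALSE],
                 copy_matrix = copy_matrix, ssu = ssu,
                 n_matched = nm, coverage = coverage,
                 samples = profile$samples),
            class = "CorrectedProfile")
}

new_unit_profile <- function(abundance, namespace, provenance) {
  structure(list(units = rownames(abundance), samples = colnames(abundance),
                 abundance = abundance, namespace = namespace,
                 provenance = provenance),
            class = "UnitProfile")
}

#' Pooled community functional-unit profile (co-metabolism)
#'
#' Unit abundance is the abundance-weighted sum of per-taxon mean copy
#' numbers: \code{abundance[u, s] = sum_t corrected[t, s] * copies(t, u)}.
#'
#' @param corrected a \code{CorrectedProfile}.
#' @param db a \code{FunctionDB}.
#' @param namespace functional-unit namespace to profile (default EC).
#' @return A \code{UnitProfile} (units x samples), provenance "CoM".
#' @export
community_unit_profile <- function(corrected, db, namespace = "EC") {
  units <- intersect(namespace_units(db, namespace), colnames(corrected$copy_matrix))
  if (!length(units))
    stop_user("no units with genome copy numbers in namespace ", namespace)
  cm <- corrected$copy_matrix[, units, drop = FALSE]
  ab <- t(cm) %*% corrected$abundance
  new_unit_profile(ab, namespace, "CoM")
}

#' Cross-map a unit profile to another namespace
#'
#' Each source unit's abundance is split equally across the targets it maps
#' to (\code{1/outdegree} each), so total mapped mass is conserved; source
#' units with no mapping are reported as unmapped mass in the
#' \code{"unmapped_mass"} attribute.
#'
#' @param up a \code{UnitProfile}.
#' @param db a \code{FunctionDB} holding a cross-map from \code{up}'s
#'   namespace to \code{target_namespace}.
#' @param target_namespace target namespace.
#' @return A \code{UnitProfile} in the target namespace.
#' @export
crossmap_profile <- function(up, db, target_namespace) {
  cm <- db$crossmaps[db$crossmaps$source_ns == up$namespace &
                     db$crossmaps$target_ns == target_namespace, , drop = FALSE]
  if (!nrow(cm))
    stop_user("no cross-map from ", up$namespace, " to ", target_namespace)
  targets <- sort(unique(cm$target_id))
  outdeg <- table(cm$source_id)
  out <- matrix(0, length(targets), length(up$samples),
                dimnames = list(targets, up$samples))
  present_src <- intersect(unique(cm$source_id), up$units)
  for (u in present_src) {
    tg <- cm$target_id[cm$source_id == u]
    share <- up$abundance[u, ] / as.numeric(outdeg[[u]])
    for (v in tg) out[v, ] <- out[v, ] + share
  }
  unmapped <- setdiff(up$units, unique(cm$source_id))
  res <- new_unit_profile(out, target_namespace,
                          paste0(up$provenance, "+crossmap"))
  attr(res, "unmapped_mass") <- colSums(up$abundance[unmapped, , drop = FALSE])
  res
}

#' Pathway presence under a pathway exclusion cut-off
#'
#' A pathway is present in a sample when the fraction of its member units
#' with strictly positive abundance reaches \code{pec/100} (and at least
#' one member is detected, so an entirely absent pathway is never "present"
#' even at cut-off 0).
#'
#' @param up a \code{UnitProfile}.
#' @param pw one row of a \code{FunctionDB} pathways table (needs
#'   \code{member_units}).
#' @param pec integer percent cut-off in \code{c(0, 50, 60, 70, 80, 90)}.
#' @return Named logical vector over samples.
#' @export
pathway_presence <- function(up, pw, pec) {
  if (!(pec %in% pec_allowed()))
    stop_user("pec must be one of ", paste(pec_allowed(), collapse = ", "))
  members <- pw$member_units[[1]]
  in_profile <- intersect(members, up$units)
  det <- if (length(in_profile))
    colSums(up$abundance[in_profile, , drop = FALSE] > 0) else
    stats::setNames(rep(0, length(up$samples)), up$samples)
  frac <- det / length(members)
  frac >= pec / 100 & det >= 1
}

new_function_profile <- function(raw, level, algorithm, pec, normalizer = NULL) {
  structure(list(functions = rownames(raw), samples = colnames(raw),
                 abundance = renormalize_columns(raw), raw = raw,
                 normalizer = normalizer %||% colSums(raw),
                 level = level, algorithm = algorithm, pec = as.integer(pec)),
            class = "FunctionProfile")
}

#' @export
print.FunctionProfile <- function(x, ...) {
  cat(sprintf("FunctionProfile: %d functions x %d samples (%s, %s, PEC %d%%)\n",
              length(x$functions), length(x$samples), x$algorithm, x$level, x$pec))
  invisible(x)
}

# Per-pathway raw abundance from a unit vector/matrix with multiplicity
# split: each unit's abundance is divided equally among the pathways that
# contain it, so promiscuous enzymes are not double counted and the total
# is conserved.  split = FALSE uses the plain sum instead.
pathway_raw_sum <- function(ab, members, mult, split) {
  m <- intersect(members, rownames(ab))
  if (!length(m)) return(rep(0, ncol(ab)))
  w <- if (split) 1 / mult[m] else rep(1, length(m))
  as.numeric(crossprod(ab[m, , drop = FALSE], w))
}

#' Pathway abundance under co-metabolism
#'
#' For every pathway passing \code{\link{pathway_presence}} at \code{pec}
#' on the pooled community unit profile, raw abundance is the sum of member
#' unit abundances, with each unit's abundance split equally across all
#' pathways containing it (multiplicity split; set \code{split = FALSE}
#' for the plain sum).  Failing pathways get 0 and columns are then
#' renormalized over the surviving pathways.
#'
#' @param up a \code{UnitProfile} built under CoM pooling.
#' @param db a \code{FunctionDB}.
#' @param pec pathway exclusion cut-off (percent).
#' @param split divide shared units across pathways (default TRUE).
#' @return A \code{FunctionProfile} at level3, algorithm "CoM".
#' @export
pathway_abundance_com <- function(up, db, pec, split = TRUE) {
  pws <- db$pathways[vapply(db$pathways$member_units, function(m)
    all(m %in% namespace_units(db, up$namespace)), logical(1)), , drop = FALSE]
  if (!nrow(pws)) stop_user("no pathways defined in namespace ", up$namespace)
  mult <- unit_multiplicity(db)
  raw <- matrix(0, nrow(pws), length(up$samples),
                dimnames = list(pws$pathway_id, up$samples))
  for (i in seq_len(nrow(pws))) {
    pres <- pathway_presence(up, pws[i, ], pec)
    vals <- pathway_raw_sum(up$abundance, pws$member_units[[i]], mult, split)
    raw[i, ] <- vals * pres
  }
  if (all(raw == 0))
    warning("no pathway survives PEC ", pec, "% in any sample", call. = FALSE)
  new_function_profile(raw, "level3", "CoM", pec)
}

#' @export
print.ContributionTensor <- function(x, ...) {
  cat(sprintf("ContributionTensor: %d taxa x %d functions x %d samples\n",
              length(x$taxa), length(x$functions), length(x$samples)))
  invisible(x)
}

#' Pathway abundance under independent contributions, with the
#' taxon-function-sample contribution tensor
#'
#' Each taxon's private unit vector is \code{corrected[t, s] * copies(t, u)};
#' the PEC quorum is evaluated on the taxon's own detected units
#' (functional exclusiveness between members), per-taxon raw pathway
#' abundance uses the same multiplicity split as CoM, and the community
#' profile is the sum over taxa.  The tensor is stored pre-normalization
#' together with the per-sample normalizer, so summing the tensor over taxa
#' reproduces the un-normalized profile exactly.
#'
#' @param corrected a \code{CorrectedProfile}.
#' @param db a \code{FunctionDB}.
#' @param pec pathway exclusion cut-off (percent).
#' @param namespace unit namespace for pathway math (default EC).
#' @param split divide shared units across pathways (default TRUE).
#' @return list with \code{profile} (a \code{FunctionProfile}, algorithm
#'   "ICo") and \code{tensor} (a \code{ContributionTensor}).
#' @export
pathway_abundance_ico <- function(corrected, db, pec, namespace = "EC",
                                  split = TRUE) {
  units <- intersect(namespace_units(db, namespace), colnames(corrected$copy_matrix))
  if (!length(units))
    stop_user("no units with genome copy numbers in namespace ", namespace)
  pws <- db$pathways[vapply(db$pathways$member_units, function(m)
    all(m %in% namespace_units(db, namespace)), logical(1)), , drop = FALSE]
  if (!nrow(pws)) stop_user("no pathways defined in namespace ", namespace)
  mult <- unit_multiplicity(db)
  taxa_ids <- rownames(corrected$abundance)
  samples <- corrected$samples

  tensor <- array(0, dim = c(length(taxa_ids), nrow(pws), length(samples)),
                  dimnames = list(taxa_ids, pws$pathway_id, samples))
  cm <- corrected$copy_matrix[, units, drop = FALSE]
  for (ti in seq_along(taxa_ids)) {
    copies <- cm[ti, ]
    det_units <- names(copies)[copies > 0]
    for (pi in seq_len(nrow(pws))) {
      members <- pws$member_units[[pi]]
      ndet <- length(intersect(members, det_units))
      frac <- ndet / length(members)
      if (ndet < 1 || frac < pec / 100) next
      m <- intersect(members, det_units)
      w <- if (split) 1 / mult[m] else rep(1, length(m))
      per_unit_sum <- sum(copies[m] * w)
      tensor[ti, pi, ] <- corrected$abundance[ti, ] * per_unit_sum
    }
  }
  raw <- colSums(tensor)  # sum over the taxa dimension
  if (all(raw == 0))
    warning("no pathway survives PEC ", pec, "% in any sample", call. = FALSE)
  profile <- new_function_profile(raw, "level3", "ICo", pec)
  ct <- structure(list(taxa = taxa_ids, functions = pws$pathway_id,
                       samples = samples, value = tensor,
                       normalizer = profile$normalizer,
                       taxa_lineages = corrected$taxa, pec = as.integer(pec)),
                  class = "ContributionTensor")
  list(profile = profile, tensor = ct)
}

#' Roll a level3 pathway profile up the functional hierarchy
#'
#' Sums pathway abundances sharing the level1 (or level1/level2) key;
#' column sums are preserved exactly.
#'
#' @param fp a level3 \code{FunctionProfile}.
#' @param db the \code{FunctionDB} supplying the hierarchy.
#' @param level \code{"level1"} or \code{"level2"}.
#' @return A \code{FunctionProfile} at the requested level.
#' @export
rollup_hierarchy <- function(fp, db, level) {
  if (!(level %in% c("level1", "level2")))
    stop_user("level must be level1 or level2")
  if (fp$level != "level3")
    stop_user("rollup starts from a level3 profile")
  idx <- match(fp$functions, db$pathways$pathway_id)
  if (anyNA(idx)) stop_user("profile functions not found in db pathways")
  key <- if (level == "level1") db$pathways$level1[idx] else
    paste(db$pathways$level1[idx], db$pathways$level2[idx], sep = "|")
  raw <- rowsum(fp$raw, group = key, reorder = TRUE)
  new_function_profile(as.matrix(raw), level, fp$algorithm, fp$pec,
                       normalizer = fp$normalizer)
}

#' Sweep the pathway exclusion cut-off grid
#'
#' Computes one \code{FunctionProfile} per PEC level in 50, 60, 70, 80,
#' 90 percent.  Presence sets are nested by construction: any pathway
#' present at a higher cut-off is present at every lower one.
#'
#' @param corrected a \code{CorrectedProfile}.
#' @param db a \code{FunctionDB}.
#' @param algorithm \code{"CoM"} or \code{"ICo"}.
#' @param namespace unit namespace (default EC).
#' @param split multiplicity split flag, as in the single-level functions.
#' @return Named list \code{"50"} ... \code{"90"}; for ICo each element also
#'   carries the contribution tensor in attribute-free form (see Value of
#'   \code{\link{pathway_abundance_ico}}), for CoM the elements are
#'   \code{FunctionProfile}s.
#' @export
pec_sweep <- function(corrected, db, algorithm = c("CoM", "ICo"),
                      namespace = "EC", split = TRUE) {
  algorithm <- match.arg(algorithm)
  up <- if (algorithm == "CoM") community_unit_profile(corrected, db, namespace)
  out <- lapply(pec_grid(), function(p) {
    if (algorithm == "CoM") pathway_abundance_com(up, db, p, split)
    else pathway_abundance_ico(corrected, db, p, namespace, split)
  })
  stats::setNames(out, as.character(pec_grid()))
}
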