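# Parsing of taxonomic abundance tables (Greengenes / SILVA / RDP lineage
# dialects) and multi-column sample metadata.

#' Auto-detect the taxonomy dialect of lineage strings
#'
#' Greengenes when at least half of the strings carry \code{k__}-style rank
#' prefixes; SILVA when they are semicolon-delimited, prefix-free, start
#' with a domain token (Bacteria/Archaea) and have at least five fields;
#' RDP otherwise (plain or name;rank alternating lineages, possibly rooted
#' at "Root").  The decision and its evidence are logged to stderr.
#'
#' @param first_column_values character vector of lineage strings.
#' @return One of \code{"greengenes"}, \code{"silva"}, \code{"rdp"}.
#' @export
detect_dialect <- function(first_column_values) {
  v <- first_column_values[nzchar(trimws(first_column_values))]
  if (!length(v)) stop_user("cannot detect dialect: no non-empty lineage strings")
  frac_prefix <- mean(grepl("[kdpcofgs]__", v))
  if (frac_prefix >= 0.5) {
    fm_log("INFO", sprintf("dialect greengenes (%.0f%% strings have rank prefixes)",
                           100 * frac_prefix))
    return("greengenes")
  }
  parts <- strsplit(v, ";", fixed = TRUE)
  is_silva <- vapply(parts, function(p) {
    p <- trimws(p)
    length(p) >= 5 && tolower(p[1]) %in% c("bacteria", "archaea")
  }, logical(1))
  if (mean(is_silva) >= 0.5) {
    fm_log("INFO", sprintf("dialect silva (%.0f%% strings are >=5-field domain-led lineages)",
                           100 * mean(is_silva)))
    return("silva")
  }
  fm_log("INFO", "dialect rdp (fallback: no rank prefixes, not SILVA-shaped)")
  "rdp"
}

# Parse one lineage string into a named vector over the canonical ranks.
# Unnamed / unresolvable ranks are ""; the lineage is truncated at the first
# unresolvable token so "unclassified" tails never match genomes.
parse_lineage <- function(s, dialect) {
  ranks <- taxonomic_ranks()
  out <- stats::setNames(rep("", 7), ranks)
  toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(out)

  if (dialect == "greengenes") {
    prefmap <- c(k = "domain", d = "domain", p = "phylum", c = "class",
                 o = "order", f = "family", g = "genus", s = "species")
    for (tk in toks) {
      m <- regmatches(tk, regexec("^([kdpcofgs])__(.*)$", tk))[[1]]
      if (length(m) == 3 && m[2] %in% names(prefmap)) {
        out[prefmap[[m[2]]]] <- m[3]
      }
    }
  } else if (dialect == "rdp" &&
             length(toks) >= 2 && length(toks) %% 2 == 0 &&
             all(tolower(toks[seq(2, length(toks), by = 2)]) %in%
                 c(ranks, "superkingdom", "kingdom", "rootrank"))) {
    # name;rank alternation
    for (i in seq(1, length(toks), by = 2)) {
      r <- tolower(toks[i + 1])
      if (r %in% c("superkingdom", "kingdom")) r <- "domain"
      if (r %in% ranks) out[r] <- toks[i]
    }
  } else {
    # positional: silva, or plain rdp (possibly Root-led)
    if (tolower(toks[1]) == "root") toks <- toks[-1]
    n <- min(length(toks), 7)
    out[seq_len(n)] <- toks[seq_len(n)]
  }

  norm <- normalize_taxon_name(out)
  # truncate at the first unresolvable rank among those that were named
  bad <- which(nzchar(out) & !nzchar(norm))
  if (length(bad)) norm[seq(min(bad), 7)] <- ""
  stats::setNames(norm, ranks)
}

deepest_rank_of <- function(lin) {
  named <- which(nzchar(lin))
  if (!length(named)) NA_character_ else taxonomic_ranks()[max(named)]
}

new_taxa_profile <- function(taxa, abundance, dialect, unassigned_mass) {
  structure(list(taxa = taxa, samples = colnames(abundance),
                 abundance = abundance, dialect = dialect,
                 unassigned_mass = unassigned_mass),
            class = "TaxaProfile")
}

#' @export
print.TaxaProfile <- function(x, ...) {
  cat(sprintf("TaxaProfile: %d taxa x %d samples (dialect %s; mean unassigned mass %.3f)\n",
              nrow(x$abundance), ncol(x$abundance), x$dialect,
              mean(x$unassigned_mass)))
  invisible(x)
}

#' Parse a taxonomic abundance table
#'
#' Reads a TSV whose first column holds lineage strings (any of the three
#' supported dialects, auto-detected unless given) and whose remaining
#' columns are per-sample abundances (counts or proportions; each sample is
#' renormalized to sum 1, so the input scale is irrelevant).  Rows with
#' identical parsed lineages are merged by summation; rows whose lineage is
#' entirely unresolvable are dropped and their per-sample mass accounted in
#' \code{unassigned_mass}; all-zero rows are dropped and logged.
#'
#' @param path TSV file with a header row.
#' @param dialect optional dialect override; auto-detected when NULL.
#' @return A \code{TaxaProfile}: parsed lineages with per-taxon deepest
#'   rank, column-normalized abundance matrix, the dialect used, and the
#'   per-sample unassigned mass fraction.
#' @export
parse_taxa_table <- function(path, dialect = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1)
    stop_user("ragged rows in ", path, ": rows have ",
              paste(unique(nf), collapse = "/"), " fields")
  raw <- read_tsv_plain(path)
  if (ncol(raw) < 2) stop_user("taxa table needs a lineage column plus >= 1 sample column")
  lineage_str <- raw[[1]]
  samples <- names(raw)[-1]
  if (anyDuplicated(samples)) stop_user("duplicate sample ids in header")

  vals <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(NULL, samples)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_user("non-numeric abundance at row ", bad[1], ", sample '",
              samples[bad[2]], "': '", vals[bad[1], bad[2]], "'")
  }
  if (any(num < 0)) stop_user("negative abundance values")

  if (is.null(dialect)) dialect <- detect_dialect(lineage_str)

  lin <- t(vapply(lineage_str, parse_lineage, character(7), dialect = dialect))
  rownames(lin) <- NULL
  resolvable <- apply(lin, 1, function(r) any(nzchar(r)))

  col_tot <- colSums(num)
  unassigned <- colSums(num[!resolvable, , drop = FALSE])
  unassigned_mass <- ifelse(col_tot > 0, unassigned / col_tot, 0)
  names(unassigned_mass) <- samples
  if (any(!resolvable))
    fm_log("WARN", sum(!resolvable), " unresolvable lineage row(s) dropped")

  lin <- lin[resolvable, , drop = FALSE]
  num <- num[resolvable, , drop = FALSE]
  if (!nrow(lin)) stop_user("no resolvable taxa in ", path)

  # merge duplicate lineages by summing
  key <- apply(lin, 1, paste, collapse = "|")
  if (anyDuplicated(key)) {
    fm_log("INFO", "merging ", sum(duplicated(key)), " duplicate lineage row(s)")
    agg <- rowsum(num, group = key, reorder = FALSE)
    lin <- lin[!duplicated(key), , drop = FALSE]
    num <- agg[match(unique(key), rownames(agg)), , drop = FALSE]
  }

  zero_rows <- rowSums(num) == 0
  if (any(zero_rows)) {
    fm_log("INFO", "dropping ", sum(zero_rows), " all-zero taxon row(s)")
    lin <- lin[!zero_rows, , drop = FALSE]
    num <- num[!zero_rows, , drop = FALSE]
  }

  taxa <- as.data.frame(lin, stringsAsFactors = FALSE)
  names(taxa) <- taxonomic_ranks()
  taxa$deepest_rank <- apply(lin, 1, deepest_rank_of)
  abund <- renormalize_columns(num)
  rownames(abund) <- apply(lin, 1, paste, collapse = "|")
  if (any(colSums(abund) == 0))
    fm_log("WARN", "all-zero sample column(s): ",
           paste(colnames(abund)[colSums(abund) == 0], collapse = ", "))

  new_taxa_profile(taxa, abund, dialect, unassigned_mass)
}

#' Write a TaxaProfile back to TSV
#'
#' Emits the profile as lineage strings (Greengenes prefixes, the richest
#' of the three dialects) plus the normalized abundance columns, so that
#' parsing the written file reproduces the abundance matrix.
#'
#' @param profile a \code{TaxaProfile}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_taxa_table <- function(profile, path) {
  pref <- c("k", "p", "c", "o", "f", "g", "s")
  lin <- apply(profile$taxa[taxonomic_ranks()], 1, function(r) {
    keep <- nzchar(r)
    paste(paste0(pref[keep], "__", r[keep]), collapse = "; ")
  })
  df <- data.frame(lineage = lin,
                   as.data.frame(profile$abundance, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "#lineage"
  write_tsv_plain(df, path)
}

#' Parse a sample metadata table
#'
#' First column sample id, remaining columns categorical metadata.  Every
#' metadata sample must exist in the companion profile (fatal otherwise);
#' profile samples absent from the metadata receive label "NA" in every
#' category (logged), so a partial metadata file never silently shrinks a
#' study.
#'
#' @param path metadata TSV.
#' @param profile the companion \code{TaxaProfile}.
#' @return A \code{SampleMetadata}: list with \code{samples} and
#'   \code{categories} (category name -> named label vector over samples).
#' @export
parse_metadata <- function(path, profile) {
  raw <- read_tsv_plain(path)
  if (ncol(raw) < 2) stop_user("metadata needs a sample id column plus >= 1 category")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop_user("duplicate sample id rows in metadata: ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  unknown <- setdiff(ids, profile$samples)
  if (length(unknown))
    stop_user("metadata sample id(s) absent from profile: ",
              paste(unknown, collapse = ", "))
  missing_s <- setdiff(profile$samples, ids)
  if (length(missing_s))
    fm_log("WARN", "profile sample(s) without metadata get label NA: ",
           paste(missing_s, collapse = ", "))

  categories <- lapply(names(raw)[-1], function(cn) {
    lab <- stats::setNames(rep("NA", length(profile$samples)), profile$samples)
    lab[ids] <- ifelse(nzchar(raw[[cn]]), raw[[cn]], "NA")
    lab
  })
  names(categories) <- names(raw)[-1]
  structure(list(samples = profile$samples, categories = categories),
            class = "SampleMetadata")
}

# Group labels for a category; category NULL means one implicit group "all".
group_labels <- function(metadata, category, samples) {
  if (is.null(metadata) || is.null(category))
    return(stats::setNames(rep("all", length(samples)), samples))
  if (!(category %in% names(metadata$categories)))
    stop_user("unknown metadata category: ", category)
  metadata$categories[[category]][samples]
}
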