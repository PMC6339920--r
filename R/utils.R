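# Shared constants and small helpers used across modules.

#' Canonical taxonomic ranks, shallowest to deepest
#'
#' The seven-rank lineage scheme used throughout: domain, phylum, class,
#' order, family, genus, species.
#'
#' @return Character vector of the seven rank names in canonical order.
#' @export
taxonomic_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Supported functional-unit namespaces
#'
#' @return Character vector of the closed set of unit namespaces.
#' @export
unit_namespaces <- function() {
  c("EC", "KO", "COG", "Pfam", "TIGRfam")
}

# PEC (pathway exclusion cut-off) grid, in percent.  0 means unfiltered.
pec_grid <- function() c(50L, 60L, 70L, 80L, 90L)

pec_allowed <- function() c(0L, pec_grid())

#' Normalize a taxon name for lineage matching
#'
#' Lowercases, strips Greengenes-style rank prefixes (\code{k__} etc.),
#' bracketed qualifiers (\code{[Clostridium]}), and surrounding whitespace.
#' Tokens such as "unclassified" or "uncultured" normalize to the empty
#' string so they terminate a lineage rather than match spuriously.
#'
#' @param x character vector of taxon names.
#' @return character vector of normalized names ("" where unresolvable).
#' @export
normalize_taxon_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- sub("^[kdpcofgs]__", "", x)
  x <- gsub("\\[|\\]", "", x)
  x <- trimws(x)
  unresolved <- c(
    "unclassified", "uncultured", "unknown", "unassigned", "other",
    "na", "n/a", "root", "incertae sedis", "ambiguous_taxa"
  )
  x[x %in% unresolved] <- ""
  x[is.na(x)] <- ""
  x
}

# Write a data.frame as a plain TSV (LF endings, no quoting surprises).
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = NULL,
                    colClasses = "character", ...)
}

# Write a functions-x-samples matrix with an id column as TSV.
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_plain(df, path)
}

# Renormalize matrix columns to sum 1; all-zero columns are left at zero.
renormalize_columns <- function(mat) {
  cs <- colSums(mat)
  pos <- cs > 0
  mat[, pos] <- sweep(mat[, pos, drop = FALSE], 2, cs[pos], "/")
  mat
}

# Leveled logging to stderr.  level: DEBUG < INFO < WARN.
fm_log <- function(level, ...) {
  msg <- paste0(...)
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"), msg))
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_user <- function(...) {
  stop(paste0(...), call. = FALSE)
}
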