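# Community-level analytics over inferred function profiles: top and core
# functions, nonparametric differential testing with BH correction, PEC
# consensus across the cut-off sweep, Jensen-Shannon ordination, and
# function-driven taxa co-contribution networks.

#' Top functions by mean relative abundance
#'
#' Ranks functions by their mean relative abundance within each sample
#' group, descending; ties are broken lexicographically by function id.
#'
#' @param fp a \code{FunctionProfile}.
#' @param n how many functions per group (capped at the profile size, with
#'   a warning).
#' @param groups optional named label vector over \code{fp$samples} (one
#'   implicit group \code{"all"} when NULL).
#' @return list with \code{ranking} (data.frame: group, rank, function_id,
#'   mean_abundance) and \code{per_sample} (function x sample abundances of
#'   every ranked function, for box plots).
#' @export
top_functions <- function(fp, n, groups = NULL) {
  if (n < 1) stop_user("n must be >= 1")
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(fp$samples)), fp$samples)
  if (n > length(fp$functions)) {
    warning("n exceeds number of functions; returning all", call. = FALSE)
    n <- length(fp$functions)
  }
  ranking <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    cols <- names(groups)[groups == g]
    mu <- rowMeans(fp$abundance[, cols, drop = FALSE])
    ord <- order(-mu, fp$functions)
    data.frame(group = g, rank = seq_len(n),
               function_id = fp$functions[ord][seq_len(n)],
               mean_abundance = mu[ord][seq_len(n)],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  keep <- unique(ranking$function_id)
  list(ranking = ranking,
       per_sample = fp$abundance[keep, , drop = FALSE])
}

#' Core functions of each sample group
#'
#' A function is core to a group when its relative abundance reaches
#' \code{abundance_floor} in at least \code{prevalence_floor} of the
#' group's samples — i.e. "high as well as consistently abundant".
#'
#' @param fp a \code{FunctionProfile}.
#' @param abundance_floor minimum relative abundance, in (0, 1].
#' @param prevalence_floor minimum fraction of the group's samples, in
#'   (0, 1].
#' @param groups optional named label vector over samples.
#' @return data.frame: group, function_id, mean_abundance, prevalence.
#' @export
core_functions <- function(fp, abundance_floor = 0.01,
                           prevalence_floor = 0.8, groups = NULL) {
  if (abundance_floor <= 0 || abundance_floor > 1 ||
      prevalence_floor <= 0 || prevalence_floor > 1)
    stop_user("floors must lie in (0, 1]")
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(fp$samples)), fp$samples)
  out <- lapply(sort(unique(groups)), function(g) {
    cols <- names(groups)[groups == g]
    if (!length(cols)) stop_user("empty group: ", g)
    sub <- fp$abundance[, cols, drop = FALSE]
    hits <- rowSums(sub >= abundance_floor)
    core <- hits >= prevalence_floor * length(cols)
    data.frame(group = rep(g, sum(core)), function_id = fp$functions[core],
               mean_abundance = rowMeans(sub)[core],
               prevalence = hits[core] / length(cols),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Differentiating functions between sample classes
#'
#' Two classes: two-sided Wilcoxon rank-sum test per function (exact when
#' both groups have at most 8 samples, normal approximation with tie
#' correction otherwise).  More than two classes: Kruskal-Wallis.  P values
#' are Benjamini-Hochberg corrected across all tested functions; functions
#' constant across every sample are skipped and listed in the
#' \code{"skipped"} attribute.  Both raw and corrected p values are
#' reported.
#'
#' @param fp a \code{FunctionProfile}.
#' @param groups named label vector over \code{fp$samples}, with at least
#'   two labels of at least two samples each.
#' @return A \code{DifferentialTable} data.frame: function_id, one
#'   \code{median_<label>} column per class, test, statistic, p_raw, p_bh,
#'   direction (class with the highest median).
#' @export
differentiating_functions <- function(fp, groups) {
  groups <- groups[fp$samples]
  labels <- sort(unique(groups))
  if (length(labels) < 2) stop_user("need >= 2 classes, got ", length(labels))
  sizes <- table(groups)
  if (any(sizes < 2))
    stop_user("class(es) with < 2 samples: ",
              paste(names(sizes)[sizes < 2], collapse = ", "))

  const <- apply(fp$abundance, 1, function(x) diff(range(x)) == 0)
  tested <- fp$functions[!const]
  if (!length(tested)) stop_user("all functions constant; nothing to test")

  test_name <- if (length(labels) == 2) "wilcoxon" else "kruskal-wallis"
  res <- lapply(tested, function(f) {
    x <- fp$abundance[f, ]
    med <- vapply(labels, function(g) stats::median(x[groups == g]), numeric(1))
    if (length(labels) == 2) {
      a <- x[groups == labels[1]]; b <- x[groups == labels[2]]
      exact <- length(a) <= 8 && length(b) <= 8
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                                correct = TRUE))
    } else {
      ht <- suppressWarnings(stats::kruskal.test(x, factor(groups)))
    }
    c(med, statistic = unname(ht$statistic), p_raw = ht$p.value)
  })
  res <- do.call(rbind, res)
  med_cols <- paste0("median_", labels)
  colnames(res)[seq_along(labels)] <- med_cols
  tab <- data.frame(function_id = tested, res, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$p_raw[is.na(tab$p_raw)] <- 1  # degenerate within-class ties
  tab$test <- test_name
  tab$p_bh <- stats::p.adjust(tab$p_raw, method = "BH")
  tab$direction <- labels[max.col(as.matrix(tab[med_cols]), ties.method = "first")]
  attr(tab, "skipped") <- fp$functions[const]
  class(tab) <- c("DifferentialTable", "data.frame")
  tab
}

#' Consensus of differential significance across the PEC sweep
#'
#' Marks each function significant (1) or not (0) at every PEC level; a
#' function filtered out at a level is 0 there.  The consensus score is
#' the fraction of the five levels at which the function is significant.
#'
#' @param tables named list, PEC level -> \code{DifferentialTable}.
#' @param alpha significance level applied to BH-corrected p values.
#' @return A \code{PECConsensus}: list with \code{matrix} (functions x
#'   levels, 0/1) and \code{score} (named numeric, row means).
#' @export
pec_consensus <- function(tables, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_user("alpha must lie in (0, 1)")
  levels <- names(tables)
  funs <- sort(unique(unlist(lapply(tables, `[[`, "function_id"))))
  mat <- matrix(0L, length(funs), length(levels),
                dimnames = list(funs, levels))
  for (lv in levels) {
    tb <- tables[[lv]]
    sig <- tb$function_id[tb$p_bh < alpha]
    mat[intersect(sig, funs), lv] <- 1L
  }
  structure(list(matrix = mat, score = rowMeans(mat), alpha = alpha),
            class = "PECConsensus")
}

#' Jensen-Shannon divergence between two distributions
#'
#' Base-2 logarithms, so the divergence is bounded in [0, 1]; a
#' pseudocount is added to both vectors before renormalization so zero
#' entries never produce infinities.
#'
#' @param p,q non-negative vectors of equal length.
#' @param pseudocount added to every entry (default 1e-9).
#' @return JSD in [0, 1].
#' @export
jsd <- function(p, q, pseudocount = 1e-9) {
  p <- p + pseudocount; q <- q + pseudocount
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) sum(a * log2(a / b))
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon ordination (classical PCoA)
#'
#' Computes pairwise \code{sqrt(JSD)} distances between the sample columns
#' of a function profile (square-rooting makes the divergence a metric,
#' so the embedding is well behaved), then classical metric PCoA by
#' eigendecomposition of the double-centred distance matrix.  Negative
#' eigenvalues are reported, never silently dropped; each axis's sign is
#' fixed so its first nonzero loading is positive.
#'
#' @param fp a \code{FunctionProfile} with >= 3 samples.
#' @param k number of ordination axes (<= samples - 1).
#' @return list with \code{coordinates} (samples x k), \code{eigenvalues}
#'   (all of them, including any negative), \code{variance_explained}
#'   (relative to the positive eigenvalue total) and \code{distances}
#'   (the \code{dist} used).
#' @export
jsd_pcoa <- function(fp, k = 2) {
  ns <- length(fp$samples)
  if (ns < 3) stop_user("ordination needs >= 3 samples")
  if (k > ns - 1) stop_user("k must be <= samples - 1")
  ab <- fp$abundance
  D <- matrix(0, ns, ns, dimnames = list(fp$samples, fp$samples))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    D[i, j] <- D[j, i] <- sqrt(jsd(ab[, i], ab[, j]))
  }
  if (all(D == 0))
    stop_user("all samples have identical function profiles; ordination is degenerate")
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {  # axes lost to non-positive eigenvalues
    pts <- cbind(pts, matrix(0, ns, k - ncol(pts)))
  }
  for (a in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, a]) > 1e-12)
    if (length(nz) && pts[nz[1], a] < 0) pts[, a] <- -pts[, a]
  }
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  pos <- sum(fit$eig[fit$eig > 0])
  list(coordinates = pts, eigenvalues = fit$eig,
       variance_explained = fit$eig / pos, distances = stats::as.dist(D))
}

#' Function-driven taxa co-contribution network
#'
#' For every pair of taxa and every pathway both contribute to, the
#' Spearman correlation of their per-sample contribution series is
#' computed.  Pairs with rho >= \code{rho_min} (positive co-contribution
#' only) are candidate edges; their p values are BH-corrected jointly and
#' an edge is kept when at least one of its functions survives
#' \code{alpha}.  Degree, normalized betweenness and the local clustering
#' coefficient are computed on the resulting simple graph.
#'
#' @param ct a \code{ContributionTensor} with at least \code{min_samples}
#'   samples.
#' @param rho_min minimum Spearman correlation (default 0.6).
#' @param alpha BH-corrected significance level (default 0.05).
#' @param min_samples fewest samples for which correlation is meaningful
#'   (default 4).
#' @return A \code{CoContributionNetwork}: list with \code{nodes},
#'   \code{edges} (taxon_i, taxon_j, rho, p_bh, supporting_functions),
#'   \code{node_metrics} (degree, betweenness, clustering) and
#'   \code{graph} (igraph object).
#' @export
contribution_network <- function(ct, rho_min = 0.6, alpha = 0.05,
                                 min_samples = 4) {
  if (length(ct$samples) < min_samples)
    stop_user("need >= ", min_samples, " samples for correlation networks")
  taxa <- ct$taxa
  cand <- list()
  for (pi in seq_along(ct$functions)) {
    slab <- ct$value[, pi, , drop = TRUE]
    if (is.null(dim(slab))) slab <- matrix(slab, nrow = length(taxa))
    contributors <- which(rowSums(slab) > 0)
    if (length(contributors) < 2) next
    for (a in seq_along(contributors)[-length(contributors)]) {
      for (b in (a + 1):length(contributors)) {
        i <- contributors[a]; j <- contributors[b]
        x <- slab[i, ]; y <- slab[j, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        rho <- stats::cor(x, y, method = "spearman")
        if (is.na(rho) || rho < rho_min) next
        pv <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman")$p.value)
        cand[[length(cand) + 1]] <- data.frame(
          taxon_i = taxa[min(i, j)], taxon_j = taxa[max(i, j)],
          function_id = ct$functions[pi], rho = rho, p_raw = pv,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- data.frame(taxon_i = character(), taxon_j = character(),
                      rho = numeric(), p_bh = numeric(),
                      supporting_functions = character(),
                      stringsAsFactors = FALSE)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand$p_bh <- stats::p.adjust(cand$p_raw, method = "BH")
    surv <- cand[cand$p_bh < alpha, , drop = FALSE]
    if (nrow(surv)) {
      key <- paste(surv$taxon_i, surv$taxon_j, sep = "\r")
      edges <- do.call(rbind, lapply(split(surv, key), function(e) {
        best <- which.max(e$rho)
        data.frame(taxon_i = e$taxon_i[1], taxon_j = e$taxon_j[1],
                   rho = e$rho[best], p_bh = e$p_bh[best],
                   supporting_functions = paste(sort(unique(e$function_id)),
                                                collapse = ";"),
                   stringsAsFactors = FALSE)
      }))
      rownames(edges) <- NULL
    }
  }

  g <- igraph::make_empty_graph(n = length(taxa), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = taxa)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$taxon_i, edges$taxon_j))
  clus <- igraph::transitivity(g, type = "local", isolates = "zero")
  node_metrics <- data.frame(
    taxon = taxa,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g, normalized = TRUE)),
    clustering = as.numeric(clus),
    stringsAsFactors = FALSE)
  structure(list(nodes = taxa, edges = edges, node_metrics = node_metrics,
                 graph = g, rho_min = rho_min, alpha = alpha),
            class = "CoContributionNetwork")
}

#' @export
print.CoContributionNetwork <- function(x, ...) {
  cat(sprintf("CoContributionNetwork: %d taxa, %d edges (rho >= %.2f, BH alpha %.2f)\n",
              length(x$nodes), nrow(x$edges), x$rho_min, x$alpha))
  invisible(x)
}
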