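test_that("top functions rank by group mean with lexicographic tie-break", {
  mat <- rbind(fa = c(0.9, 0.9), fb = c(0.05, 0.05), fc = c(0.05, 0.05))
  colnames(mat) <- c("S1", "S2")
  fp <- profile_from_matrix(mat)
  top <- top_functions(fp, 3)
  expect_equal(top$ranking$function_id[1], "fa")
  # fb and fc tie at 0.05: lexicographic order
  expect_equal(top$ranking$function_id[2:3], c("fb", "fc"))
  expect_warning(top_functions(fp, 10), "all")

  # random profiles match a brute-force sort of column means
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(stats::runif(40), 8, 5,
                dimnames = list(sprintf("f%02d", sample(1:99, 8)), paste0("S", 1:5)))
    fp2 <- profile_from_matrix(m)
    got <- top_functions(fp2, 8)$ranking$function_id
    mu <- rowMeans(fp2$abundance)
    expect_equal(got, rownames(m)[order(-mu, rownames(m))])
  }
})

test_that("core functions apply abundance and prevalence floors per group", {
  set.seed(8)
  m <- matrix(stats::runif(100), 10, 10,
              dimnames = list(paste0("f", 1:10), paste0("S", 1:10)))
  fp <- profile_from_matrix(m)
  groups <- stats::setNames(rep(c("g1", "g2"), each = 5), paste0("S", 1:10))
  core <- core_functions(fp, abundance_floor = 0.4, prevalence_floor = 0.8,
                         groups = groups)
  # brute-force double loop
  for (g in c("g1", "g2")) {
    cols <- names(groups)[groups == g]
    for (f in rownames(fp$abundance)) {
      expected <- sum(fp$abundance[f, cols] >= 0.4) >= 0.8 * length(cols)
      expect_equal(f %in% core$function_id[core$group == g], expected)
    }
  }
  # a function above floor in 7 of 10 samples misses a 0.8 prevalence floor
  m2 <- matrix(c(rep(0.5, 7), rep(0, 3)), 1, 10,
               dimnames = list("f", paste0("S", 1:10)))
  core2 <- core_functions(profile_from_matrix(m2), 0.4, 0.8)
  expect_equal(nrow(core2), 0)
  core3 <- core_functions(profile_from_matrix(m2), 0.4, 0.7)
  expect_equal(core3$function_id, "f")
})

test_that("two-class testing is exact Wilcoxon; BH follows the step-up formula", {
  mat <- rbind(f1 = c(1, 2, 3, 10, 20, 30) / 100,
               f2 = c(5, 6, 4, 5.5, 6.5, 4.5) / 100,
               f3 = c(1, 1, 1, 1, 1, 1) / 6)
  colnames(mat) <- paste0("S", 1:6)
  fp <- profile_from_matrix(mat)
  groups <- stats::setNames(rep(c("ctl", "trt"), each = 3), paste0("S", 1:6))
  tab <- differentiating_functions(fp, groups)
  expect_equal(tab$test[1], "wilcoxon")
  # exact two-sided p for complete separation at n = 3/3 is 2/C(6,3)
  expect_near(tab$p_raw[tab$function_id == "f1"], 0.1, 1e-12)
  expect_equal(tab$direction[tab$function_id == "f1"], "trt")
  # constant functions are skipped and listed
  expect_false("f3" %in% tab$function_id)
  expect_equal(attr(tab, "skipped"), "f3")
  # BH matches the closed-form step-up on the raw p values
  m <- nrow(tab)
  ord <- order(tab$p_raw)
  stepup <- rev(cummin(rev(tab$p_raw[ord] * m / seq_len(m))))
  expect_near(tab$p_bh[ord], pmin(1, stepup), 1e-12)
  expect_true(all(tab$p_bh >= tab$p_raw))

  expect_error(differentiating_functions(fp, stats::setNames(
    c("a", "a", "a", "a", "a", "b"), paste0("S", 1:6))), "< 2 samples")
})

test_that("multi-class testing uses Kruskal-Wallis; identical groups give statistic 0", {
  mat <- rbind(f1 = rep(c(0.1, 0.2, 0.3), 3),
               f2 = c(0.1, 0.2, 0.3, 1, 2, 3, 10, 20, 30) / 50)
  colnames(mat) <- paste0("S", 1:9)
  fp <- profile_from_matrix(mat)
  groups <- stats::setNames(rep(c("a", "b", "c"), each = 3), paste0("S", 1:9))
  tab <- differentiating_functions(fp, groups)
  expect_equal(unique(tab$test), "kruskal-wallis")
  # f1: the three groups hold identical values -> statistic 0, p = 1
  expect_near(tab$statistic[tab$function_id == "f1"], 0, 1e-12)
  expect_near(tab$p_raw[tab$function_id == "f1"], 1, 1e-12)
  expect_true(tab$p_raw[tab$function_id == "f2"] < 1)
})

test_that("statistics are invariant to permuting sample order", {
  set.seed(12)
  m <- matrix(stats::runif(60), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("S", 1:10)))
  fp <- profile_from_matrix(m)
  groups <- stats::setNames(rep(c("x", "y"), 5), paste0("S", 1:10))
  perm <- sample(10)
  fp2 <- profile_from_matrix(m[, perm])
  t1 <- differentiating_functions(fp, groups)
  t2 <- differentiating_functions(fp2, groups[perm])
  expect_equal(t1$p_raw, t2$p_raw)
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p_bh, t2$p_bh)
})

test_that("PEC consensus scores count significant levels out of five", {
  mk <- function(ids, p) {
    tab <- data.frame(function_id = ids, p_bh = p, stringsAsFactors = FALSE)
    class(tab) <- c("DifferentialTable", "data.frame")
    tab
  }
  tables <- list(
    "50" = mk(c("fA", "fB", "fC"), c(0.01, 0.02, 0.9)),
    "60" = mk(c("fA", "fB", "fC"), c(0.01, 0.03, 0.8)),
    "70" = mk(c("fA", "fC"), c(0.02, 0.7)),   # fB filtered out from here on
    "80" = mk(c("fA", "fC"), c(0.04, 0.6)),
    "90" = mk(c("fA", "fC"), c(0.02, 0.5)))
  cons <- pec_consensus(tables, alpha = 0.05)
  expect_near(cons$score[["fA"]], 1)
  expect_near(cons$score[["fB"]], 0.4)
  expect_near(cons$score[["fC"]], 0)
  expect_true(all(cons$matrix %in% c(0, 1)))
  # rows scoring 0 are exactly the never-significant functions
  never <- names(cons$score)[cons$score == 0]
  expect_equal(never, "fC")
})

test_that("JSD is bounded, symmetric, zero on identity, one on disjoint support", {
  expect_near(jsd(c(0.2, 0.8), c(0.2, 0.8)), 0, 1e-6)
  expect_near(jsd(c(1, 0), c(0, 1)), 1, 1e-6)
  set.seed(3)
  for (i in 1:20) {
    p <- stats::runif(5); q <- stats::runif(5)
    expect_near(jsd(p, q), jsd(q, p), 1e-12)
    expect_true(jsd(p, q) >= 0 && jsd(p, q) <= 1)
  }
  # sqrt(JSD) satisfies the triangle inequality (spot-checked)
  for (i in 1:20) {
    p <- stats::runif(4); q <- stats::runif(4); r <- stats::runif(4)
    expect_true(sqrt(jsd(p, q)) <= sqrt(jsd(p, r)) + sqrt(jsd(r, q)) + 1e-12)
  }
})

test_that("PCoA embedding reproduces sqrt-JSD distances and reports eigenvalues", {
  set.seed(21)
  m <- matrix(stats::rexp(40), 8, 5, dimnames = list(paste0("f", 1:8), paste0("S", 1:5)))
  m <- sweep(m, 2, colSums(m), "/")
  fp <- profile_from_matrix(m)
  ord <- jsd_pcoa(fp, k = 4)
  expect_equal(length(ord$eigenvalues), 5)
  # Gower property: full-rank embedding reproduces the distances
  D_hat <- as.matrix(stats::dist(ord$coordinates))
  D <- as.matrix(ord$distances)
  expect_near(D_hat, D, 1e-6)
  # sign convention: first nonzero loading of each axis is positive
  for (a in seq_len(ncol(ord$coordinates))) {
    nz <- which(abs(ord$coordinates[, a]) > 1e-12)
    if (length(nz)) expect_true(ord$coordinates[nz[1], a] > 0)
  }
  # identical samples throughout are rejected
  same <- profile_from_matrix(matrix(rep(c(0.5, 0.5), 3), 2, 3,
                                     dimnames = list(c("f1", "f2"), paste0("S", 1:3))))
  expect_error(jsd_pcoa(same, 2), "identical")
})

test_that("perfectly correlated co-contribution yields an edge", {
  samples <- paste0("S", 1:6)
  val <- array(0, dim = c(3, 1, 6),
               dimnames = list(c("t1", "t2", "t3"), "P1", samples))
  series <- c(1, 2, 3, 4, 5, 6)
  val["t1", 1, ] <- series
  val["t2", 1, ] <- series * 2   # identical ranks -> rho = 1
  # t3 contributes nothing: isolated node
  ct <- structure(list(taxa = c("t1", "t2", "t3"), functions = "P1",
                       samples = samples, value = val,
                       normalizer = NULL, taxa_lineages = NULL),
                  class = "ContributionTensor")
  net <- contribution_network(ct, rho_min = 0.6, alpha = 0.05, min_samples = 4)
  expect_equal(nrow(net$edges), 1)
  expect_near(net$edges$rho, 1)
  expect_equal(net$edges$supporting_functions, "P1")
  expect_equal(net$node_metrics$degree[net$node_metrics$taxon == "t3"], 0)
  expect_error(contribution_network(ct, min_samples = 10), "samples")
})

test_that("network centralities match closed forms on a 5-node path graph", {
  # taxa t1..t5 in a path: consecutive pairs share one function each with
  # identical contribution series
  samples <- paste0("S", 1:8)
  funs <- paste0("F", 1:4)
  val <- array(0, dim = c(5, 4, 8),
               dimnames = list(paste0("t", 1:5), funs, samples))
  set.seed(4)
  for (k in 1:4) {
    series <- sort(stats::runif(8))
    val[k, k, ] <- series
    val[k + 1, k, ] <- series
  }
  ct <- structure(list(taxa = paste0("t", 1:5), functions = funs,
                       samples = samples, value = val,
                       normalizer = NULL, taxa_lineages = NULL),
                  class = "ContributionTensor")
  net <- contribution_network(ct, rho_min = 0.6, alpha = 0.05, min_samples = 4)
  expect_equal(nrow(net$edges), 4)
  bt <- stats::setNames(net$node_metrics$betweenness, net$node_metrics$taxon)
  # closed form for a 5-node path, normalized by (n-1)(n-2)/2 = 6:
  # ends 0; t2 and t4 carry 3 pairs each; the middle carries 4
  expect_near(bt[c("t1", "t5")], c(0, 0))
  expect_near(bt[c("t2", "t4")], c(3 / 6, 3 / 6))
  expect_near(bt["t3"], 4 / 6)
  expect_equal(stats::setNames(net$node_metrics$degree, net$node_metrics$taxon),
               c(t1 = 1, t2 = 2, t3 = 2, t4 = 2, t5 = 1))
  # path graph has no triangles: clustering 0 everywhere
  expect_near(net$node_metrics$clustering, rep(0, 5))
  # relabeling taxa leaves the edge set invariant (up to names)
  perm <- c(3, 1, 5, 2, 4)
  val2 <- val[perm, , , drop = FALSE]
  ct2 <- ct; ct2$value <- val2; ct2$taxa <- ct$taxa[perm]
  net2 <- contribution_network(ct2, 0.6, 0.05, 4)
  canon <- function(e) {
    key <- apply(cbind(pmin(e$taxon_i, e$taxon_j), pmax(e$taxon_i, e$taxon_j)),
                 1, paste, collapse = "-")
    sort(key)
  }
  expect_equal(canon(net2$edges), canon(net$edges))
})

test_that("network centralities match closed forms on star and complete graphs", {
  samples <- paste0("S", 1:8)
  set.seed(9)
  # star: hub t1 shares one distinct function with each leaf
  val <- array(0, dim = c(4, 3, 8),
               dimnames = list(paste0("t", 1:4), paste0("F", 1:3), samples))
  for (k in 1:3) {
    series <- sort(stats::runif(8))
    val[1, k, ] <- series
    val[k + 1, k, ] <- series
  }
  ct <- structure(list(taxa = paste0("t", 1:4), functions = paste0("F", 1:3),
                       samples = samples, value = val,
                       normalizer = NULL, taxa_lineages = NULL),
                  class = "ContributionTensor")
  net <- contribution_network(ct, 0.6, 0.05, 4)
  bt <- stats::setNames(net$node_metrics$betweenness, net$node_metrics$taxon)
  expect_near(bt["t1"], 1)          # hub lies on every leaf pair
  expect_near(bt[c("t2", "t3", "t4")], rep(0, 3))

  # complete graph on 4 nodes: one function everyone contributes to equally
  val2 <- array(0, dim = c(4, 1, 8),
                dimnames = list(paste0("t", 1:4), "F1", samples))
  series <- sort(stats::runif(8))
  for (i in 1:4) val2[i, 1, ] <- series * i
  ct2 <- structure(list(taxa = paste0("t", 1:4), functions = "F1",
                        samples = samples, value = val2,
                        normalizer = NULL, taxa_lineages = NULL),
                   class = "ContributionTensor")
  net2 <- contribution_network(ct2, 0.6, 0.05, 4)
  expect_equal(nrow(net2$edges), 6)
  expect_near(net2$node_metrics$betweenness, rep(0, 4))
  expect_near(net2$node_metrics$clustering, rep(1, 4))
})
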