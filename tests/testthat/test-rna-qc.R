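test_that("cell and gene filters apply the printed strict thresholds", {
  fx <- make_qc_fixture()
  out <- filter_cells_and_genes(fx)
  kept <- colnames(out$matrix)
  expect_false("A" %in% kept)  # 1999 counts: below 2000, removed
  expect_true(all(c("B", "E") %in% kept))  # exactly on thresholds: retained
  expect_false("D" %in% kept)  # 21% mito: above 0.20, removed
  # genes expressed in 2 surviving cells drop, in 3 stay
  expect_true(all(sprintf("g%03d", 1:200) %in% rownames(out$matrix)))
  expect_false(any(sprintf("g%03d", 201:250) %in% rownames(out$matrix)))
  rep <- out$report
  expect_identical(rep$n_cells_in - rep$n_cells_out, 2L)
  expect_identical(unname(rep$removed["low_counts"]), 1L)
  expect_identical(unname(rep$removed["high_mito"]), 1L)
  expect_identical(rep$n_genes_in - rep$n_genes_out, 50L)
})

test_that("filtering is monotone in min_counts", {
  sim <- cached_sim()
  kept <- vapply(c(1000, 2000, 4000), function(mc)
    ncol(filter_cells_and_genes(sim$rna, min_counts = mc)$matrix), numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("doublet-cluster rule reproduces the hand-computed threshold", {
  # cluster medians {0.05, 0.06, 0.50}: threshold 0.06 + 1.48*0.01 = 0.0748
  n <- 30
  m <- matrix(1, 2, 3 * n,
              dimnames = list(c("g1", "g2"), sprintf("c%03d", 1:(3 * n))))
  cl <- rep(c("c1", "c2", "c3"), each = n)
  sc <- rep(c(0.05, 0.06, 0.50), each = n)
  sce <- rna_experiment(m, data.frame(pct_mito = 0, cluster_id = cl,
                                      doublet_score = sc, lane_id = "L1"))
  out <- remove_doublet_clusters(sce)
  expect_equal(out$report$lanes$L1$threshold, 0.0748)
  expect_identical(out$report$lanes$L1$removed_clusters, "c3")
  expect_identical(sort(unique(cmeta(out$matrix)$cluster_id)), c("c1", "c2"))
})

test_that("degenerate and single-cluster lanes are left intact", {
  m <- matrix(1, 2, 40, dimnames = list(c("g1", "g2"), sprintf("c%02d", 1:40)))
  # all cluster medians equal: MAD 0, nothing strictly above the threshold
  sce <- rna_experiment(m, data.frame(pct_mito = 0,
                                      cluster_id = rep(c("a", "b"), 20),
                                      doublet_score = 0.1, lane_id = "L1"))
  out <- remove_doublet_clusters(sce)
  expect_identical(ncol(out$matrix), 40L)
  # a lane with one cluster is never removed, and is flagged
  sce1 <- rna_experiment(m, data.frame(pct_mito = 0,
                                       cluster_id = rep("only", 40),
                                       doublet_score = 0.9, lane_id = "L1"))
  out1 <- remove_doublet_clusters(sce1)
  expect_identical(ncol(out1$matrix), 40L)
  expect_true(out1$report$lanes$L1$single_cluster)
})

test_that("doublet-cluster removal is shift-equivariant", {
  sim <- cached_sim()
  base <- remove_doublet_clusters(sim$rna)
  shifted <- remove_doublet_clusters(
    sim$rna, scores = cmeta(sim$rna)$doublet_score + 0.17)
  expect_identical(colnames(base$matrix), colnames(shifted$matrix))
})

test_that("a planted doublet cluster is removed without collateral loss", {
  sim <- cached_sim()
  out <- remove_doublet_clusters(sim$rna)
  removed <- lapply(out$report$lanes, `[[`, "removed_clusters")
  expect_true(all(vapply(removed, function(r) identical(r, "doublet"),
                         logical(1))))
  expect_false(any(cmeta(out$matrix)$cluster_id == "doublet"))
})

test_that("lognorm matches hand computation and preserves proportions", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("g1", "g2", "g3"), "c1"))
  sce <- normalize_lognorm(rna_experiment(m, data.frame(pct_mito = 0)))
  expect_equal(as.vector(assay_of(sce, "lognorm")),
               log1p(c(2500, 2500, 5000)), tolerance = 1e-12)
  expect_equal(as.vector(assay_of(sce, "lognorm"))[1], 7.8244, tolerance = 1e-4)

  sim <- cached_sim()
  qc <- filter_cells_and_genes(sim$rna)$matrix
  norm <- normalize_lognorm(qc)
  ln <- assay_of(norm, "lognorm")
  counts <- assay_of(norm, "counts")
  # scaled layer row sums equal target_sum, and expm1 recovers proportions
  sums <- Matrix::colSums(expm1(as.matrix(ln[, 1:20])))
  expect_equal(unname(sums), rep(1e4, 20), tolerance = 1e-9)
  prop_raw <- counts[, 3] / sum(counts[, 3])
  prop_back <- expm1(as.matrix(ln)[, 3]) / 1e4
  expect_equal(unname(as.vector(prop_back)), unname(as.vector(prop_raw)),
               tolerance = 1e-12)
  # all-zero gene stays zero
  z <- matrix(c(0, 5, 0, 5), 2, 2, dimnames = list(c("gz", "g2"), c("c1", "c2")))
  expect_equal(as.vector(assay_of(normalize_lognorm(
    rna_experiment(z, data.frame(pct_mito = c(0, 0)))), "lognorm")[1, ]),
    c(0, 0))
  # zero-total cell errors
  z2 <- matrix(c(0, 0, 5, 5), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(normalize_lognorm(rna_experiment(z2, data.frame(pct_mito = c(0, 0)))),
               "zero total")
})

test_that("HVG selection excludes constants and out-of-range means, finds markers", {
  set.seed(1)
  n <- 1500
  m <- rbind(
    const = rep(5, n),
    tiny = c(1, rep(0, n - 1)),            # log1p mean ~0.0007: below 0.001
    var1 = rpois(n, c(rep(1, n / 2), rep(40, n / 2))),
    var2 = rpois(n, c(rep(40, n / 2), rep(1, n / 2))),
    flat1 = rpois(n, 10), flat2 = rpois(n, 10), flat3 = rpois(n, 12),
    flat4 = rpois(n, 8), flat5 = rpois(n, 11), flat6 = rpois(n, 9),
    flat7 = rpois(n, 10), flat8 = rpois(n, 12)
  )
  colnames(m) <- sprintf("c%04d", 1:n)
  sce <- normalize_lognorm(rna_experiment(m, data.frame(pct_mito = rep(0, n))),
                           target_sum = 100)
  hv <- select_hvgs(sce, n_top = 2, n_bins = 2)
  expect_setequal(hv, c("var1", "var2"))
  expect_warning(all_el <- select_hvgs(sce, n_top = 50, n_bins = 2),
                 "eligible")
  expect_false("tiny" %in% all_el)   # mean below the lower bound
  expect_false("const" %in% all_el[1:2])

  sim <- cached_sim()
  norm <- normalize_lognorm(filter_cells_and_genes(sim$rna)$matrix)
  hv <- select_hvgs(norm, n_top = 150)
  planted <- intersect(unlist(sim$truth$markers), rownames(norm))
  expect_true(all(planted %in% hv))
})

test_that("marker testing honors the expression-fraction and logFC cut-offs", {
  sim <- cached_sim()
  norm <- normalize_lognorm(
    remove_doublet_clusters(filter_cells_and_genes(sim$rna)$matrix)$matrix)
  groups <- cmeta(norm)$cluster_id
  tab <- rank_marker_genes(norm, groups)
  for (k in seq_len(5)) {
    planted <- sim$truth$markers[[paste0("state", k)]]
    hits <- tab[tab$group == paste0("state", k) & tab$gene %in% planted, ]
    expect_gte(nrow(hits), length(planted) * 0.9)
    expect_true(all(hits$p_adj < 0.05))
    expect_true(all(hits$logFC >= 0.25))
    expect_true(all(hits$frac > 0.25))
  }
})

test_that("marker testing skips low-fraction genes and a null group", {
  set.seed(2)
  n <- 120
  grp <- rep(c("a", "b"), each = n / 2)
  m <- rbind(rare = c(rbinom(n / 2, 1, 0.15) * 50, rep(0, n / 2)),
             matrix(rpois(20 * n, 10), 20, n,
                    dimnames = list(sprintf("g%02d", 1:20), NULL)))
  colnames(m) <- sprintf("c%03d", 1:n)
  sce <- normalize_lognorm(rna_experiment(m, data.frame(pct_mito = rep(0, n))))
  tab <- rank_marker_genes(sce, grp)
  # 'rare' is expressed in <25% of group a cells: never tested
  expect_false("rare" %in% tab$gene)
  # identically distributed groups: no adjusted discoveries expected
  if (!is.null(tab) && nrow(tab)) expect_true(all(tab$p_adj > 0.05))
  expect_error(rank_marker_genes(sce, c("solo", rep("rest", n - 1))),
               "at least 2 cells")
})

test_that("marker p-values are invariant to monotone transforms", {
  set.seed(3)
  n <- 80
  m <- matrix(rpois(10 * n, 8), 10, n,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%03d", 1:n)))
  sce <- normalize_lognorm(rna_experiment(m, data.frame(pct_mito = rep(0, n))))
  grp <- rep(c("a", "b"), each = n / 2)
  t1 <- rank_marker_genes(sce, grp, logfc_cutoff = 0)
  sce2 <- sce
  ln <- assay_of(sce2, "lognorm")
  SummarizedExperiment::assay(sce2, "lognorm") <- ln^3  # monotone, keeps 0s
  t2 <- rank_marker_genes(sce2, grp, logfc_cutoff = 0)
  shared <- intersect(t1$gene[t1$group == "a"], t2$gene[t2$group == "a"])
  expect_gt(length(shared), 0)
  expect_equal(t1$p[t1$group == "a"][match(shared, t1$gene[t1$group == "a"])],
               t2$p[t2$group == "a"][match(shared, t2$gene[t2$group == "a"])],
               tolerance = 1e-12)
})

test_that("partition metrics hit their identities and the frozen oracle", {
  a <- c(1, 1, 2, 2, 3, 3, 1, 2, 3, 3)
  b <- c(1, 2, 2, 2, 3, 1, 1, 2, 3, 3)
  m <- partition_metrics(a, b)
  # frozen from an independent reference implementation of AMI/ARI
  expect_equal(m$ami, 0.4772899900014569, tolerance = 1e-12)
  expect_equal(m$ari, 0.4318181818181818, tolerance = 1e-12)

  ident <- partition_metrics(a, a)
  expect_equal(ident$ami, 1)
  expect_equal(ident$ari, 1)
  perm <- partition_metrics(a, c("x", "z", "y")[a])  # pure relabeling
  expect_equal(perm$ami, 1)
  expect_equal(perm$ari, 1)

  set.seed(9)
  r1 <- sample(1:5, 5000, replace = TRUE)
  r2 <- sample(1:5, 5000, replace = TRUE)
  rnd <- partition_metrics(r1, r2)
  expect_lt(abs(rnd$ari), 0.02)
  expect_lt(abs(rnd$ami), 0.02)
})

test_that("silhouette and WSS come from the embedding; silhouette NA when undefined", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
  lab <- rep(c("a", "b"), each = 20)
  m <- partition_metrics(lab, lab, embedding = emb)
  expect_gt(m$silhouette, 0.5)
  wss_manual <- sum(apply(emb[1:20, ], 2, function(x) sum((x - mean(x))^2))) +
    sum(apply(emb[21:40, ], 2, function(x) sum((x - mean(x))^2)))
  expect_equal(m$wss, wss_manual, tolerance = 1e-12)
  one <- partition_metrics(rep("a", 40), rep("a", 40), embedding = emb)
  expect_true(is.na(one$silhouette))

  sw <- partition_sweep(list(k5 = lab, k10 = rep("a", 40)), lab, emb)
  expect_identical(nrow(sw), 2L)
  expect_equal(sw$ari[1], 1)
})
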