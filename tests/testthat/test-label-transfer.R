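# one medium-size trained model shared across tests in this file
.lt_cache <- new.env(parent = emptyenv())
trained_on_sim <- function() {
  if (is.null(.lt_cache$fit)) {
    sim <- cached_sim()
    norm <- normalize_lognorm(
      remove_doublet_clusters(filter_cells_and_genes(sim$rna)$matrix)$matrix)
    states <- sim$truth$cells$state[match(colnames(norm), sim$truth$cells$cell)]
    # all genes as features: marker coefficients then sit in the upper tail
    # of each class's coefficient distribution, which is what the
    # survival-function significance call assumes
    feats <- rownames(norm)
    ref <- seq_len(ncol(norm)) %% 2L == 1L
    model <- train_transfer_model(norm[, ref], states[ref], feats)
    .lt_cache$fit <- list(model = model, norm = norm, states = states,
                          ref = ref, sim = sim)
  }
  .lt_cache$fit
}

test_that("the CV grid covers 6 x 5 parameter pairs with 15 fold scores each", {
  fit <- trained_on_sim()
  cv <- fit$model$cv
  expect_identical(nrow(unique(cv[, c("l1_ratio", "alpha")])), 30L)
  expect_true(all(table(cv$l1_ratio, cv$alpha) == 15))
  expect_identical(sort(unique(cv$l1_ratio)), c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_identical(sort(unique(cv$alpha)), c(0.2, 0.4, 0.6, 0.8, 1))
  sel <- fit$model$selected
  expect_equal(sel$cv_mse, min(fit$model$cv_grid$mse))
})

test_that("query cells are predicted accurately with few unassigned", {
  fit <- trained_on_sim()
  query <- !fit$ref
  preds <- predict_cells(fit$model, fit$norm[, query])
  truth <- fit$states[query]
  assigned <- preds$label != "unassigned"
  expect_gte(mean(preds$label[assigned] == truth[assigned]), 0.95)
  expect_lte(mean(!assigned), 0.10)
  p <- attr(preds, "probabilities")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
})

test_that("prediction is invariant to cell and feature order, zero-fills gaps", {
  fit <- trained_on_sim()
  x <- t(as.matrix(assay_of(fit$norm, "lognorm")[fit$model$features, !fit$ref]))
  base <- predict_cells(fit$model, x)
  perm_cells <- sample(nrow(x))
  perm_feats <- sample(ncol(x))
  shuf <- predict_cells(fit$model, x[perm_cells, perm_feats])
  expect_identical(shuf$label, base$label[perm_cells])
  expect_equal(shuf$probability, base$probability[perm_cells], tolerance = 1e-12)
  expect_warning(zf <- predict_cells(fit$model, x[, -(1:3)]), "zero-filled")
  expect_identical(nrow(zf), nrow(x))
  expect_error(predict_cells(fit$model,
                             matrix(0, 2, 2, dimnames = list(NULL, c("zz1", "zz2")))),
               "no features")
})

test_that("raising the decision threshold never decreases the unassigned fraction", {
  fit <- trained_on_sim()
  x <- t(as.matrix(assay_of(fit$norm, "lognorm")[fit$model$features, !fit$ref]))
  fr <- vapply(c(0.5, 0.9, 0.99, 0.999), function(th) {
    m <- fit$model
    m$decision_threshold <- th
    mean(predict_cells(m, x)$label == "unassigned")
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("probability fixtures respect the 0.9 decision threshold", {
  mk <- function(p) structure(list(
    classes = c("A", "B", "C"), features = "f1",
    coefficients = matrix(0, 3, 1, dimnames = list(c("A", "B", "C"), "f1")),
    intercepts = log(p), decision_threshold = 0.9
  ), class = "transfer_model")
  x <- matrix(0, 1, 1, dimnames = list("c1", "f1"))
  expect_identical(predict_cells(mk(c(0.95, 0.03, 0.02)), x)$label, "A")
  expect_identical(predict_cells(mk(c(0.60, 0.30, 0.10)), x)$label, "unassigned")
  expect_identical(predict_cells(mk(c(1, 1, 1) / 3), x)$label, "unassigned")
})

test_that("separable two-class data give zero training error and tiny CV-MSE", {
  set.seed(20)
  n <- 60
  x <- cbind(f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             f2 = rnorm(n))
  y <- rep(c("a", "b"), each = n / 2)
  model <- train_transfer_model(x, y, n_folds = 5, n_repeats = 3)
  grid <- model$cv_grid
  expect_true(all(grid$mse[grid$l1_ratio < 1] < 0.05))
  m0 <- model
  m0$decision_threshold <- 0
  expect_identical(predict_cells(m0, x)$label, y)
})

test_that("a label-permuted reference predicts at the majority-class rate", {
  set.seed(21)
  n <- 400
  x <- cbind(f1 = rnorm(n, rep(c(-2, 2), c(0.7 * n, 0.3 * n))), f2 = rnorm(n))
  y <- rep(c("a", "b"), c(0.7 * n, 0.3 * n))  # majority class rate 0.7
  y_perm <- sample(y)
  train <- seq_len(n) %% 2L == 1L            # exchangeable held-out half
  model <- train_transfer_model(x[train, ], y_perm[train],
                                n_folds = 5, n_repeats = 1)
  model$decision_threshold <- 0
  acc <- mean(predict_cells(model, x[!train, ])$label == y[!train])
  expect_lt(abs(acc - 0.7), 0.12)
})

test_that("training rejects impossible class layouts", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_error(train_transfer_model(x, rep("a", 20)), "at least 2 classes")
  expect_error(train_transfer_model(x, c(rep("a", 11), rep("b", 9))),
               "at least 10 cells")
})

test_that("CV folds and grid choice match an independent re-computation", {
  set.seed(22)
  n <- 30
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  x[, 1] <- x[, 1] + rep(c(-1.5, 1.5), each = n / 2)
  y <- factor(rep(c("a", "b"), each = n / 2))
  l1s <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  als <- c(0.2, 0.4, 0.6, 0.8, 1)
  model <- train_transfer_model(x, y, l1_ratios = l1s, alphas = als,
                                n_folds = 5, n_repeats = 3, seed_base = 0)

  # straightforward re-computation: stratified folds, per-fold glmnet fits,
  # frequency-weighted one-hot MSE, unweighted mean over folds
  folds <- matrix(NA_integer_, n, 3)
  for (r in 1:3) {
    set.seed(r - 1)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[sample(idx), r] <- rep_len(1:5, length(idx))
    }
  }
  expect_identical(folds, model$fold_assignments)

  ref_mse <- array(NA_real_, c(length(l1s), length(als), 15))
  for (r in 1:3) for (f in 1:5) {
    test <- folds[, r] == f
    for (i in seq_along(l1s)) for (j in seq_along(als)) {
      lam <- 1 / (als[j] * n)
      fit <- glmnet::glmnet(x[!test, ], y[!test], family = "multinomial",
                            alpha = l1s[i],
                            lambda = sort(1 / (als * n), decreasing = TRUE),
                            standardize = FALSE)
      p <- predict(fit, x[test, , drop = FALSE], s = lam,
                   type = "response")[, , 1][, levels(y)]
      onehot <- outer(as.character(y[test]), levels(y), `==`) * 1
      se <- rowSums((onehot - p)^2)
      cls <- tapply(se, y[test], mean)
      w <- table(y[test]) / sum(test)
      ref_mse[i, j, (r - 1) * 5 + f] <- sum(w * cls)
    }
  }
  mean_ref <- apply(ref_mse, c(1, 2), mean)
  sel_ref <- which(mean_ref == min(mean_ref), arr.ind = TRUE)[1, ]
  expect_equal(model$selected$l1_ratio, l1s[sel_ref[1]])
  expect_equal(model$selected$alpha, als[sel_ref[2]])
  got <- model$cv_grid
  for (i in seq_along(l1s)) for (j in seq_along(als))
    expect_equal(got$mse[got$l1_ratio == l1s[i] & got$alpha == als[j]],
                 mean_ref[i, j], tolerance = 1e-10)
})

test_that("cluster voting reproduces the hand-computed fixtures", {
  # {A:90, B:5, C:5}: threshold 33.33 + 40.07 = 73.4 < 90 -> labeled A
  labs <- c(rep("A", 90), rep("B", 5), rep("C", 5))
  expect_identical(unname(assign_cluster_labels(labs, rep("k1", 100))), "A")
  # {A:34, B:33, C:33}: threshold ~33.8; 34 exceeds it -> labeled A
  labs2 <- c(rep("A", 34), rep("B", 33), rep("C", 33))
  expect_identical(unname(assign_cluster_labels(labs2, rep("k1", 100))), "A")
  # {A:30, B:30}: sd 0, threshold 30, no strict excess -> unresolved
  labs3 <- c(rep("A", 30), rep("B", 30))
  expect_identical(unname(assign_cluster_labels(labs3, rep("k1", 60))),
                   "unresolved")
  # a modal unassigned vote never labels a cluster
  labs4 <- c(rep("unassigned", 90), rep("B", 10))
  expect_identical(unname(assign_cluster_labels(labs4, rep("k1", 100))),
                   "unresolved")
  expect_identical(
    unname(assign_cluster_labels(c(labs, labs3),
                                 rep(c("k1", "k2"), c(100, 60)))["k2"]),
    "unresolved")
})

test_that("impact scores are exp(coefficients) with survival-function p-values", {
  fit <- trained_on_sim()
  imp <- feature_impact(fit$model)
  expect_true(all(imp$impact > 0))
  expect_true(all(imp$p >= 0 & imp$p <= 1))
  expect_equal(imp$impact, exp(imp$coefficient), tolerance = 1e-12)
  zero <- imp[imp$coefficient == 0, ]
  if (nrow(zero)) expect_true(all(zero$impact == 1))
  # hand check of the parametric survival function for one class
  cls <- fit$model$classes[1]
  co <- fit$model$coefficients[cls, ]
  expect_equal(imp$p[imp$class == cls][match(names(co),
                                             imp$gene[imp$class == cls])],
               unname(pnorm(co, mean(co), sd(co), lower.tail = FALSE)),
               tolerance = 1e-12)

  # planted markers drive their class: all significant, and most significant
  # features are planted markers
  sim <- fit$sim
  for (k in seq_len(5)) {
    cl <- paste0("state", k)
    mk <- intersect(sim$truth$markers[[cl]], fit$model$features)
    sub <- imp[imp$class == cl, ]
    expect_true(all(sub$significant[sub$gene %in% mk]))
    expect_gte(mean(sub$gene[sub$significant] %in% mk), 0.9)
  }
})

test_that("fully regularized classes warn and flag nothing", {
  model <- structure(list(
    classes = c("A", "B"), features = c("g1", "g2"),
    coefficients = matrix(0, 2, 2, dimnames = list(c("A", "B"), c("g1", "g2"))),
    intercepts = c(A = 0, B = 0), decision_threshold = 0.9
  ), class = "transfer_model")
  w <- capture_warnings(imp <- feature_impact(model))  # one per class
  expect_true(all(grepl("fully regularized", w)) && length(w) == 2)
  expect_false(any(imp$significant))
  expect_true(all(imp$impact == 1))
})

test_that("empirical survival function is available as an alternative", {
  fit <- trained_on_sim()
  imp <- feature_impact(fit$model, method = "empirical")
  cls <- fit$model$classes[1]
  sub <- imp[imp$class == cls, ]
  # largest impact has the smallest empirical survival fraction (1/n)
  expect_equal(sub$p[which.max(sub$impact)],
               1 / length(fit$model$features), tolerance = 1e-12)
})
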