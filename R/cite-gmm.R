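#' Fit a Gaussian-mixture background model to DSB-normalized cells
#'
#' Fits diagonal-covariance Gaussian mixtures over the cell droplets in
#' protein (dsb) space for k = 2..21 components, computes the conventional
#' information criteria `BIC = -2L + df * log(n)` and `AIC = -2L + 2 * df`
#' for each k, and selects the k minimizing BIC (the AIC choice is recorded,
#' and a disagreement is messaged). The per-protein background mean `mu_bg`
#' is the smallest component mean of that protein in the selected model.
#'
#' Model fitting is delegated to [mclust::Mclust()] (`"VVI"`: diagonal,
#' varying volume and shape) whose model-based hierarchical initialization
#' is deterministic; a deterministic stride subset of at most
#' `init_subset` cells seeds the initialization for large n. The
#' `"univariate"` method instead fits an independent 1-D mixture per protein
#' (same k grid and criteria) and takes each protein's smallest selected
#' component mean.
#'
#' @param assay a `SingleCellExperiment` with a `"dsb"` layer and droplet
#'   `class` metadata (from [dsb_normalize()]).
#' @param k_range candidate component counts.
#' @param method `"multivariate"` (mixture over cells in protein space) or
#'   `"univariate"` (independent mixture per protein).
#' @param init_subset initialization subset size (multivariate only).
#' @return A `"background_model"`: `criteria` (per-k loglik, df, BIC, AIC),
#'   `k` (BIC selection), `k_aic`, component `means`/`weights`, per-protein
#'   `mu_bg`, `loglik`, `n_cells`, `method`.
#' @export
fit_background_gmm <- function(assay, k_range = 2:21,
                               method = c("multivariate", "univariate"),
                               init_subset = 1500L) {
  method <- match.arg(method)
  dsb <- get_layer(assay, "dsb", "fit_background_gmm")
  cls <- cell_meta_col(assay, "class", "fit_background_gmm")
  X <- t(dsb[, cls == "cell", drop = FALSE])
  n <- nrow(X)
  d <- ncol(X)
  if (n < max(k_range) + 1L) stop("fewer cells than mixture components")

  if (method == "multivariate") {
    sub <- unique(round(seq(1L, n, length.out = min(n, init_subset))))
    fit <- mclust::Mclust(X, G = k_range, modelNames = "VVI",
                          initialization = list(subset = sub),
                          verbose = FALSE)
    if (is.null(fit)) stop("mixture fitting failed for every k")
    ## recover per-k loglik from mclust's BIC table (mclust BIC = 2L - df*log n)
    bic_tab <- fit$BIC[, "VVI"]
    df_k <- (k_range - 1) + 2 * k_range * d
    loglik_k <- (as.numeric(bic_tab) + df_k * log(n)) / 2
    ok <- is.finite(loglik_k)
    if (any(!ok))
      warning("mixture fit failed for k = ",
              paste(k_range[!ok], collapse = ", "), "; skipped")
    if (!any(ok)) stop("mixture fitting failed for every k")
    crit <- data.frame(k = k_range, loglik = loglik_k, df = df_k,
                       bic = -2 * loglik_k + df_k * log(n),
                       aic = -2 * loglik_k + 2 * df_k)
    k_bic <- crit$k[which.min(crit$bic)]
    k_aic <- crit$k[which.min(crit$aic)]
    if (k_bic != k_aic)
      message("BIC selects k = ", k_bic, " but AIC selects k = ", k_aic,
              "; using BIC")
    stopifnot(fit$G == k_bic)  # mclust maximizes 2L - df*log(n) = -BIC
    means <- fit$parameters$mean            # d x G
    rownames(means) <- colnames(X)
    mu_bg <- apply(means, 1L, min)
    model <- list(method = method, criteria = crit, k = k_bic, k_aic = k_aic,
                  means = means, weights = fit$parameters$pro,
                  mu_bg = mu_bg, loglik = fit$loglik, n_cells = n)
  } else {
    per_protein <- lapply(seq_len(d), function(p) {
      f <- mclust::Mclust(X[, p], G = k_range, modelNames = "V",
                          verbose = FALSE)
      if (is.null(f)) stop("univariate mixture failed for protein ",
                           colnames(X)[p])
      df_k <- 3 * k_range - 1
      loglik_k <- (as.numeric(f$BIC[, "V"]) + df_k * log(n)) / 2
      crit <- data.frame(k = k_range, loglik = loglik_k, df = df_k,
                         bic = -2 * loglik_k + df_k * log(n),
                         aic = -2 * loglik_k + 2 * df_k)
      list(criteria = crit, k = f$G, means = drop(f$parameters$mean),
           weights = f$parameters$pro, mu_bg = min(f$parameters$mean),
           loglik = f$loglik)
    })
    names(per_protein) <- colnames(X)
    model <- list(method = method, per_protein = per_protein,
                  k = vapply(per_protein, `[[`, numeric(1), "k"),
                  mu_bg = vapply(per_protein, `[[`, numeric(1), "mu_bg"),
                  n_cells = n)
  }
  structure(model, class = "background_model")
}

#' @exportS3Method base::print
print.background_model <- function(x, ...) {
  if (x$method == "multivariate")
    cat("background_model (multivariate):", x$n_cells, "cells, k =", x$k,
        "(AIC:", x$k_aic, ")\n  mu_bg:",
        paste(names(x$mu_bg), round(x$mu_bg, 3), sep = "=", collapse = ", "),
        "\n")
  else
    cat("background_model (univariate):", x$n_cells, "cells, k per protein:",
        paste(x$k, collapse = ","), "\n")
  invisible(x)
}

#' Serialize a background model to JSON
#' @param model a `"background_model"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_background_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
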