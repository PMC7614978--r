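#' Feature impact scores and their significance
#'
#' Per class, the impact of a feature is `exp(coefficient)` (the
#' multiplicative effect of one expression unit on the class odds). A normal
#' distribution is fitted to the class's coefficients (the log impacts) and
#' each feature's p-value is the survival function of its impact under that
#' fit; features with p < 0.05 are flagged significant. The
#' `"empirical"` method instead uses the empirical survival fraction across
#' the class's impact scores.
#'
#' @param model a `"transfer_model"`.
#' @param method `"normal"` (parametric sf) or `"empirical"` (rank-based).
#' @return `data.frame` (class x feature rows) with `class`, `gene`,
#'   `coefficient`, `impact`, `p`, `significant`, ordered within class by
#'   decreasing impact.
#' @examples
#' # coefficient 0 has impact exp(0) = 1; coefficient log(2) has impact 2
#' @export
feature_impact <- function(model, method = c("normal", "empirical")) {
  method <- match.arg(method)
  out <- lapply(model$classes, function(cl) {
    co <- model$coefficients[cl, ]
    if (all(co == 0))
      warning("class '", cl, "' is fully regularized (all coefficients 0); ",
              "no significant features")
    p <- if (sd(co) == 0) rep(1, length(co))
    else if (method == "normal") pnorm(co, mean(co), sd(co), lower.tail = FALSE)
    else vapply(co, function(ci) mean(co >= ci), numeric(1))
    df <- data.frame(class = cl, gene = names(co), coefficient = unname(co),
                     impact = exp(unname(co)), p = unname(p),
                     significant = unname(p) < 0.05)
    df[order(-df$impact), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
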