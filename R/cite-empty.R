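#' Detect ambient/empty droplets from the total-UMI distribution
#'
#' Histograms `log10(total RNA UMIs)` over `round(3.322 * log10(X))` bins
#' (X = number of droplets), detects histogram peaks over a sweep of 21
#' integer minimum-prominence values (0-20) crossed with 11 minimum-width
#' values (0-10 bins), and takes the tallest detected peak as the ambient
#' (empty-droplet) peak provided its position lies below the mean log10 UMI.
#' Droplets at or below the valley between that peak and the tallest peak to
#' its right are classed empty (when no peak lies to the right, the peak
#' position plus half its full width at half prominence is used as the
#' boundary). If no peak qualifies -- a unimodal cells-only distribution, or
#' a degenerate histogram -- the fallback rule applies and droplets with
#' `log10(UMI) < mean - 1.96 * sd` are classed empty, with the `fallback`
#' flag set.
#'
#' @param total_umi nonnegative total RNA UMI count per droplet (>= 100
#'   droplets required; zeros are clamped to 1 before the log).
#' @return A `"droplet_partition"`: `n_bins`, histogram `breaks`/`counts`,
#'   `peaks` (position, height, prominence, width in bins), `empty_peak`
#'   position, `boundary` (log10 units), `fallback_threshold`
#'   (`mu - 1.96 * sd`), the empty droplet index set `empty_idx`, and the
#'   `fallback` flag.
#' @examples
#' # X = 1000 droplets gives round(3.322 * log10(1000)) = 10 bins
#' @export
detect_empty_droplets <- function(total_umi) {
  x <- as.numeric(total_umi)
  if (length(x) < 100) stop("need at least 100 droplets")
  if (any(x < 0) || anyNA(x)) stop("total_umi must be nonnegative")
  lx <- log10(pmax(x, 1))
  n_bins <- as.integer(round(3.322 * log10(length(x))))
  mu <- mean(lx)
  sdv <- sd(lx)
  fallback_thr <- mu - 1.96 * sdv

  degenerate <- diff(range(lx)) == 0 || length(x) < n_bins
  if (!degenerate) {
    h <- graphics::hist(lx, breaks = seq(min(lx), max(lx),
                                         length.out = n_bins + 1L),
                        plot = FALSE)
    ## zero-pad so a mode sitting in the first or last bin is a peak
    hc <- c(0, h$counts, 0)
    ## prominence/width sweep; looser settings detect supersets, the union
    ## over the grid is the retained peak set
    peak_idx <- integer(0)
    for (prom in 0:20) for (wid in 0:10) {
      pk <- find_peaks_1d(hc, min_prominence = prom, min_width = wid)
      peak_idx <- union(peak_idx, pk$index)
    }
    peak_idx <- sort(peak_idx)
    pk <- find_peaks_1d(hc)
    pk <- pk[match(peak_idx, pk$index), , drop = FALSE]
    pk$index <- pk$index - 1L   # un-pad
  }

  if (degenerate || nrow(pk) == 0) {
    empty_idx <- which(lx < fallback_thr)
    return(new_droplet_partition(n_bins, NULL, NULL, NA_real_, fallback_thr,
                                 fallback_thr, empty_idx, TRUE, mu, sdv,
                                 length(x)))
  }

  bin_w <- diff(h$breaks[1:2])
  pos <- h$mids[pk$index]
  tallest <- which.max(pk$height)
  if (pos[tallest] < mu) {
    right <- which(pos > pos[tallest])
    if (length(right)) {
      rp <- right[which.max(pk$height[right])]
      span <- (pk$index[tallest] + 1L):(pk$index[rp] - 1L)
      valley <- if (length(span)) span[which.min(h$counts[span])] else pk$index[tallest]
      boundary <- h$mids[valley]
    } else {
      boundary <- pos[tallest] + pk$width[tallest] / 2 * bin_w
    }
    empty_idx <- which(lx <= boundary)
    return(new_droplet_partition(
      n_bins, h, data.frame(position = pos, height = pk$height,
                            prominence = pk$prominence, width = pk$width),
      pos[tallest], boundary, fallback_thr, empty_idx, FALSE, mu, sdv,
      length(x)))
  }
  empty_idx <- which(lx < fallback_thr)
  new_droplet_partition(
    n_bins, h, data.frame(position = pos, height = pk$height,
                          prominence = pk$prominence, width = pk$width),
    NA_real_, fallback_thr, fallback_thr, empty_idx, TRUE, mu, sdv, length(x))
}

new_droplet_partition <- function(n_bins, h, peaks, empty_peak, boundary,
                                  fallback_thr, empty_idx, fallback, mu, sdv,
                                  n_droplets) {
  structure(list(
    n_bins = n_bins,
    breaks = if (is.null(h)) NULL else h$breaks,
    counts = if (is.null(h)) NULL else h$counts,
    peaks = peaks,
    empty_peak = empty_peak,
    boundary = boundary,
    fallback_threshold = fallback_thr,
    empty_idx = empty_idx,
    fallback = fallback,
    mu_log10 = mu, sd_log10 = sdv,
    n_droplets = n_droplets
  ), class = "droplet_partition")
}

#' @exportS3Method base::print
print.droplet_partition <- function(x, ...) {
  cat("droplet_partition:", x$n_droplets, "droplets,", x$n_bins, "bins,",
      length(x$empty_idx), "empty",
      if (x$fallback) "(fallback rule)" else
        sprintf("(peak at %.3f, boundary %.3f)", x$empty_peak, x$boundary),
      "\n")
  invisible(x)
}

# 1-D peak detection on a nonnegative signal (histogram counts) with
# topographic prominences and widths at half prominence, in the style of
# scipy.signal.find_peaks. Plateaus report their middle sample.
find_peaks_1d <- function(y, min_prominence = 0, min_width = 0) {
  n <- length(y)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(idx))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  prom <- width <- numeric(length(idx))
  for (k in seq_along(idx)) {
    p <- idx[k]
    lmin <- y[p]; i <- p
    while (i > 1L && y[i - 1L] <= y[p]) { i <- i - 1L; lmin <- min(lmin, y[i]) }
    rmin <- y[p]; i <- p
    while (i < n && y[i + 1L] <= y[p]) { i <- i + 1L; rmin <- min(rmin, y[i]) }
    prom[k] <- y[p] - max(lmin, rmin)
    ref <- y[p] - prom[k] / 2
    li <- p
    while (li > 1L && y[li - 1L] > ref) li <- li - 1L
    left <- if (li == 1L || y[li] == ref) li else
      li - (ref - y[li]) / (y[li - 1L] - y[li])
    ri <- p
    while (ri < n && y[ri + 1L] > ref) ri <- ri + 1L
    right <- if (ri == n || y[ri] == ref) ri else
      ri + (ref - y[ri]) / (y[ri + 1L] - y[ri])
    width[k] <- right - left
  }
  keep <- prom >= min_prominence & width >= min_width
  data.frame(index = idx, height = y[idx], prominence = prom,
             width = width)[keep, , drop = FALSE]
}
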