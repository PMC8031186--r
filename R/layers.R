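#' Detect density-profile landmarks
#'
#' Cortical cell-density profiles along the depth axis typically show three
#' convex (local maximum) points -- centers of layer 3, layer 4, and layer 6
#' -- separated by two concave (local minimum) points. After moving-average
#' smoothing, the three most prominent local maxima are selected (prominence
#' ties broken by depth order) and the minimum between each consecutive pair
#' of maxima is taken. Fewer than three maxima is an explicit failure: a
#' classed error (`spikeTE_landmark_error`), never a guess.
#'
#' @param profile data.frame with columns `depth` (strictly increasing) and
#'   `density` (non-negative)
#' @param smoothWindow moving-average window in samples; default 5% of the
#'   profile length (minimum 1 = no smoothing)
#' @return list with `maxima` (3 depths), `minima` (2 depths), and the
#'   smoothed profile
#' @export
detectLandmarks <- function(profile, smoothWindow = NULL) {
  x <- profile$depth
  y <- profile$density
  if (is.unsorted(x, strictly = TRUE)) stop("depth axis must be increasing")
  if (any(y < 0)) stop("densities must be non-negative")
  n <- length(y)
  if (is.null(smoothWindow)) smoothWindow <- max(1L, round(0.05 * n))
  if (n < 2 * smoothWindow + 3) stop("profile too short for smoothing")
  ys <- if (smoothWindow > 1) {
    k <- rep(1 / smoothWindow, smoothWindow)
    as.numeric(stats::filter(y, k, sides = 2))
  } else y
  # edges carry NA after filtering; hold the first/last valid values
  ok <- which(!is.na(ys))
  ys[seq_len(ok[1] - 1)] <- ys[ok[1]]
  ys[seq((ok[length(ok)] + 1), length.out = n - ok[length(ok)])] <-
    ys[ok[length(ok)]]

  peaks <- which(diff(sign(diff(ys))) < 0) + 1L
  fail <- function() stop(structure(
    class = c("spikeTE_landmark_error", "error", "condition"),
    list(message = "fewer than 3 local density maxima found", call = NULL)))
  if (length(peaks) < 3) fail()
  prominence <- vapply(peaks, function(p) {
    h <- ys[p]
    lm <- h; i <- p
    while (i > 1 && ys[i] <= h) { lm <- min(lm, ys[i]); i <- i - 1 }
    left <- if (ys[i] > h) lm else min(ys[1:p])
    rm_ <- h; i <- p
    while (i < n && ys[i] <= h) { rm_ <- min(rm_, ys[i]); i <- i + 1 }
    right <- if (ys[i] > h) rm_ else min(ys[p:n])
    h - max(left, right)
  }, numeric(1))
  top <- peaks[order(-prominence, peaks)[1:3]]
  top <- sort(top)
  mins <- vapply(1:2, function(k) {
    seg <- top[k]:top[k + 1]
    seg[which.min(ys[seg])]
  }, integer(1))
  list(maxima = x[top], minima = x[mins],
       smoothed = data.frame(depth = x, density = ys))
}

#' Layer boundaries from density landmarks
#'
#' Converts the three convex and two concave landmark depths into the four
#' laminar boundaries: L1|L2/3 at one third of the way from the surface to
#' the first maximum; L2/3|L4 at the first minimum; L4|L5 midway between the
#' second maximum and the second minimum; L5|L6 midway between the second
#' minimum and the third maximum.
#'
#' @param landmarks list with `maxima` (3 increasing depths) and `minima`
#'   (2 depths interleaved between them)
#' @return named numeric vector `b1_23`, `b23_4`, `b4_5`, `b5_6`
#' @export
layerBoundaries <- function(landmarks) {
  mx <- landmarks$maxima
  mn <- landmarks$minima
  if (length(mx) != 3 || length(mn) != 2)
    stop("need 3 maxima and 2 minima")
  ord <- c(mx[1], mn[1], mx[2], mn[2], mx[3])
  if (is.unsorted(ord, strictly = TRUE))
    stop("landmarks must strictly alternate max/min/max/min/max by depth")
  b <- c(b1_23 = mx[1] / 3, b23_4 = mn[1], b4_5 = (mx[2] + mn[2]) / 2,
         b5_6 = (mn[2] + mx[3]) / 2)
  if (is.unsorted(b, strictly = TRUE) || b[1] <= 0 || b[4] >= 1)
    stop("derived boundaries are not strictly increasing in (0, 1)")
  b
}

#' Assign laminar labels by depth
#'
#' Half-open intervals: `[0, b1_23)` is L1, `[b1_23, b23_4)` L2/3,
#' `[b23_4, b4_5)` L4, `[b4_5, b5_6)` L5, `[b5_6, 1]` L6.
#'
#' @param depths normalized depths in `[0, 1]` (0 = pial surface)
#' @param b boundaries from [layerBoundaries()]
#' @return character vector of layer labels
#' @export
assignLayers <- function(depths, b) {
  if (any(depths < 0 | depths > 1)) stop("depths must lie in [0, 1]")
  labs <- c("L1", "L2/3", "L4", "L5", "L6")
  idx <- findInterval(depths, c(0, b, 1 + 1e-12),
                      rightmost.closed = FALSE)
  labs[pmin(idx, 5L)]
}
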