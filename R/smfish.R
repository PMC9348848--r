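#' Laplacian-of-Gaussian spot enhancement for 3D stacks
#'
#' Convolves a 3D voxel array with a negated Laplacian-of-Gaussian kernel
#' so that diffraction-limited spots become bright local maxima. The
#' kernel is the 6-neighbour discrete Laplacian of a truncated separable
#' Gaussian and sums exactly to zero, so constant regions map to zero
#' response. Convolution is circular (FFT); spots within `4 * sigma` of
#' the volume edge may feel wrap-around.
#'
#' @param x 3D numeric array (z, y, x), finite values.
#' @param sigma Gaussian sigma in pixels (> 0). Matched to the expected
#'   spot sigma; default 1.5.
#' @return 3D array of the same shape, negated-LoG response.
#' @export
log_filter <- function(x, sigma = 1.5) {
  .check(is.array(x) && length(dim(x)) == 3, "x must be a 3D array")
  .check(all(is.finite(x)), "non-finite voxels in input")
  .check(is.numeric(sigma) && sigma > 0, "sigma must be > 0")
  d <- dim(x)
  w <- ceiling(4 * sigma)
  g1 <- exp(-((-w:w)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  # separable Gaussian with a 1-voxel zero margin, then discrete Laplacian
  k <- 2L * w + 3L
  gz <- gy <- gx <- c(0, g1, 0)
  G <- outer(gz, outer(gy, gx))
  L <- array(0, dim(G))
  idx <- 2:(k - 1)
  L[idx, idx, idx] <-
    G[idx - 1, idx, idx] + G[idx + 1, idx, idx] +
    G[idx, idx - 1, idx] + G[idx, idx + 1, idx] +
    G[idx, idx, idx - 1] + G[idx, idx, idx + 1] -
    6 * G[idx, idx, idx]
  K <- -L  # negate: spot centres become maxima
  K <- K - sum(K) / length(K)  # enforce exact zero response to constants
  # embed kernel centred at the origin (circular convolution); wrapped
  # taps accumulate so volumes smaller than the kernel stay exact
  ctr <- w + 2L
  kid <- as.matrix(expand.grid(z = seq_len(k), y = seq_len(k), x = seq_len(k)))
  zi <- ((kid[, 1] - ctr) %% d[1])
  yi <- ((kid[, 2] - ctr) %% d[2])
  xi <- ((kid[, 3] - ctr) %% d[3])
  lin <- zi + d[1] * (yi + d[2] * xi) + 1
  acc <- rowsum(as.vector(K), lin)
  Kp <- array(0, d)
  Kp[as.integer(rownames(acc))] <- acc[, 1]
  out <- Re(stats::fft(stats::fft(x) * stats::fft(Kp), inverse = TRUE)) /
    prod(d)
  out
}

# 26-connected neighbour offsets in 3D
.neigh26 <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
.neigh26 <- .neigh26[rowSums(abs(.neigh26)) > 0, ]

#' Find 26-connected regional maxima of a thresholded 3D image
#'
#' Returns the voxel coordinates of regional maxima of `x` restricted to
#' voxels with value `>= threshold`. A flat maximal plateau of connected
#' equal-valued voxels counts once; its centroid is reported, rounded to
#' the nearest voxel. Volume faces are treated as boundaries (missing
#' neighbours do not suppress a maximum).
#'
#' @param x 3D numeric array (filtered image).
#' @param threshold Intensity cutoff; must lie within the finite range of
#'   `x` extended by the usual open upper end (a threshold above the
#'   maximum returns no spots).
#' @return data.frame with integer columns `z`, `y`, `x` and the plateau
#'   `value`.
#' @export
count_maxima <- function(x, threshold) {
  .check(is.array(x) && length(dim(x)) == 3, "x must be a 3D array")
  .check(all(is.finite(x)), "non-finite voxels in input")
  .check(is.numeric(threshold) && length(threshold) == 1 && is.finite(threshold),
         "threshold must be a single finite number")
  maxima <- .regional_maxima(x, threshold)
  maxima[, c("z", "y", "x", "value")]
}

# core: regional maxima with value >= threshold
.regional_maxima <- function(x, threshold) {
  d <- dim(x)
  in_set <- x >= threshold
  if (!any(in_set)) {
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      value = numeric(0)))
  }
  # has_greater / has_equal over the 26 neighbourhood via shifted copies
  has_greater <- array(FALSE, d)
  has_equal <- array(FALSE, d)
  for (r in seq_len(nrow(.neigh26))) {
    s <- .neigh26[r, ]
    zi <- .shift_idx(d[1], s[1]); yi <- .shift_idx(d[2], s[2])
    xi <- .shift_idx(d[3], s[3])
    zr <- zi$dst; yr <- yi$dst; xr <- xi$dst
    nb <- x[zi$src, yi$src, xi$src, drop = FALSE]
    cur <- x[zr, yr, xr, drop = FALSE]
    has_greater[zr, yr, xr] <- has_greater[zr, yr, xr] | (nb > cur)
    has_equal[zr, yr, xr] <- has_equal[zr, yr, xr] | (nb == cur)
  }
  cand <- in_set & !has_greater
  if (!any(cand)) {
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      value = numeric(0)))
  }
  iso <- cand & !has_equal       # generic case: singleton maxima
  flat <- which(cand & has_equal)  # plateau members need component checks
  res <- which(iso, arr.ind = TRUE)
  out <- data.frame(z = res[, 1], y = res[, 2], x = res[, 3],
                    value = x[iso])
  if (length(flat) > 0) {
    out <- rbind(out, .plateau_maxima(x, flat, has_greater))
  }
  out[order(out$z, out$y, out$x), , drop = FALSE]
}

# indices for comparing voxels with neighbours shifted by s along one axis
.shift_idx <- function(n, s) {
  if (s == 0) list(src = seq_len(n), dst = seq_len(n))
  else if (s > 0) list(src = (1 + s):n, dst = seq_len(n - s))
  else list(src = seq_len(n + s), dst = (1 - s):n)
}

# flood-fill equal-value plateaus containing candidate voxels; a plateau is
# a regional maximum iff none of its members has a strictly greater neighbour
.plateau_maxima <- function(x, flat_idx, has_greater) {
  d <- dim(x)
  visited <- logical(length(x))
  res <- list()
  to_coord <- function(i) {
    i0 <- i - 1L
    c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2])) + 1L
  }
  to_index <- function(z, y, xx) (xx - 1L) * d[1] * d[2] + (y - 1L) * d[1] + z
  for (start in flat_idx) {
    if (visited[start]) next
    val <- x[start]
    queue <- start
    visited[start] <- TRUE
    members <- start
    is_max <- TRUE
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      if (has_greater[cur]) is_max <- FALSE
      cc <- to_coord(cur)
      for (r in seq_len(nrow(.neigh26))) {
        nz <- cc[1] + .neigh26[r, 1]; ny <- cc[2] + .neigh26[r, 2]
        nx <- cc[3] + .neigh26[r, 3]
        if (nz < 1 || ny < 1 || nx < 1 || nz > d[1] || ny > d[2] || nx > d[3])
          next
        ni <- to_index(nz, ny, nx)
        if (!visited[ni] && x[ni] == val) {
          visited[ni] <- TRUE
          queue <- c(queue, ni)
          members <- c(members, ni)
        }
      }
    }
    if (is_max) {
      coords <- t(vapply(members, to_coord, integer(3)))
      res[[length(res) + 1]] <-
        data.frame(z = as.integer(round(mean(coords[, 1]))),
                   y = as.integer(round(mean(coords[, 2]))),
                   x = as.integer(round(mean(coords[, 3]))),
                   value = val)
    }
  }
  if (length(res) == 0) {
    data.frame(z = integer(0), y = integer(0), x = integer(0),
               value = numeric(0))
  } else do.call(rbind, res)
}

#' Spot counts across a ladder of detection thresholds
#'
#' Applies `n_thresholds` increasingly stringent intensity thresholds
#' (linearly spaced from the filtered image minimum to its maximum) and
#' records the number of 26-connected regional maxima surviving each.
#' A maximum surviving threshold `t` survives every lower threshold, so
#' the count sequence is non-increasing by construction.
#'
#' @param filtered 3D array, typically the output of [log_filter()].
#' @param n_thresholds Number of thresholds (default 100).
#' @return An object of class `threshold_curve`: a list with `thresholds`
#'   (ascending) and `counts`.
#' @export
threshold_curve <- function(filtered, n_thresholds = 100L) {
  .check(.is_count(n_thresholds) && n_thresholds >= 2,
         "n_thresholds must be >= 2")
  rng <- range(filtered)
  .check(diff(rng) > 0, "no dynamic range: image is flat")
  thresholds <- seq(rng[1], rng[2], length.out = n_thresholds)
  maxima <- .regional_maxima(filtered, thresholds[1])
  counts <- vapply(thresholds, function(t) sum(maxima$value >= t), integer(1))
  structure(list(thresholds = thresholds, counts = counts),
            class = "threshold_curve")
}

#' Select a detection threshold from the plateau of a threshold curve
#'
#' Identifies the longest contiguous run of at least `window` thresholds
#' over which the spot count varies by at most `tol`, and returns the
#' run's midpoint threshold. Ties between equally long runs are broken
#' toward the more stringent (higher-threshold) run.
#'
#' @param curve A [threshold_curve()].
#' @param window Minimum run length (>= 3; default 10).
#' @param tol Maximum count spread within the run (default 2).
#' @return The selected threshold (numeric scalar) with attribute
#'   `plateau` giving the run's index range and count.
#' @export
select_threshold <- function(curve, window = 10L, tol = 2L) {
  .check(inherits(curve, "threshold_curve"), "curve must be a threshold_curve")
  .check(.is_count(window) && window >= 3, "window must be >= 3")
  n <- length(curve$counts)
  # longest run ending at each index with spread <= tol (two-pointer scan)
  best_len <- 0L; best_end <- NA_integer_
  lo <- 1L
  for (hi in seq_len(n)) {
    while (max(curve$counts[lo:hi]) - min(curve$counts[lo:hi]) > tol) {
      lo <- lo + 1L
    }
    len <- hi - lo + 1L
    if (len >= best_len) {  # >= : prefer the higher-threshold run on ties
      best_len <- len; best_end <- hi
    }
  }
  if (best_len < window) {
    stop(sprintf("no plateau: no run of >= %d thresholds with spread <= %s",
                 window, format(tol)), call. = FALSE)
  }
  i0 <- best_end - best_len + 1L
  mid <- i0 + (best_len - 1L) %/% 2L
  structure(curve$thresholds[mid],
            plateau = list(from = i0, to = best_end,
                           count = curve$counts[mid]))
}

#' Average plateau threshold across several images
#'
#' Computes [select_threshold()] for the first `min(k, length(curves))`
#' curves of an image set and returns their arithmetic mean, the single
#' threshold then applied to every image in the set.
#'
#' @param curves List of [threshold_curve()] objects.
#' @param k Number of curves to average over (default 5).
#' @param window,tol Passed to [select_threshold()].
#' @return Numeric scalar threshold.
#' @export
batch_threshold <- function(curves, k = 5L, window = 10L, tol = 2L) {
  .check(is.list(curves) && length(curves) >= 1, "need at least one curve")
  use <- curves[seq_len(min(k, length(curves)))]
  mean(vapply(use, function(cv) as.numeric(select_threshold(cv, window, tol)),
              numeric(1)))
}
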