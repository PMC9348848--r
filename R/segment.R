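#' Segment GFP-marked cells from a 3D stack
#'
#' Builds a 2D cell mask the way PGCs are segmented from a GLH-1::GFP
#' channel: maximum-intensity Z-projection, Gaussian blur with a large
#' kernel, gradient-magnitude edge detection with hysteresis, morphological
#' closing and hole filling, then removal of components below a minimum
#' area. The same 2D mask is applied to every Z slice downstream.
#'
#' @param gfp 3D numeric array (z, y, x), the cell-marker channel.
#' @param blur_sigma Blur sigma in pixels (default 8, "a large kernel").
#' @param min_area_px Minimum component area in pixels (default 200).
#' @param max_cells Components above this trigger a `flagged` attribute
#'   (images with more than two cells are flagged, not dropped); default 2.
#' @return An object of class `cell_mask`: list with `mask` (logical y x x
#'   matrix), `labels` (integer matrix, 0 = background), `n_cells`, and a
#'   logical attribute `flagged`.
#' @export
segment_cells <- function(gfp, blur_sigma = 8, min_area_px = 200L,
                          max_cells = 2L) {
  .check(is.array(gfp) && length(dim(gfp)) == 3 && length(gfp) > 0,
         "gfp must be a non-empty 3D array")
  .check(blur_sigma > 0, "blur_sigma must be > 0")
  proj <- apply(gfp, c(2, 3), max)  # maximum-intensity Z-projection
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(proj), sigma = blur_sigma))

  # gradient magnitude via central differences
  gy <- blurred * 0; gx <- blurred * 0
  gy[2:(nrow(blurred) - 1), ] <- (blurred[3:nrow(blurred), ] -
                                    blurred[1:(nrow(blurred) - 2), ]) / 2
  gx[, 2:(ncol(blurred) - 1)] <- (blurred[, 3:ncol(blurred)] -
                                    blurred[, 1:(ncol(blurred) - 2)]) / 2
  grad <- sqrt(gy^2 + gx^2)

  # thin to the gradient ridge (non-maximum suppression along the
  # gradient direction) so the edge sits on the true boundary
  nms <- .edge_nms(grad, gy, gx)

  # hysteresis: strong edges seed weak-edge components; the strong
  # threshold is an Otsu split of the ridge gradients (noise vs edge)
  hi <- .otsu(grad[nms])
  if (!is.finite(hi) || hi <= 0) stop("no cells found", call. = FALSE)
  lo <- hi / 2
  weak <- nms & grad >= lo
  strong <- nms & grad >= hi
  wl <- EBImage::bwlabel(EBImage::Image(weak * 1))
  keep <- setdiff(unique(as.vector(as.matrix(wl))[as.vector(strong)]), 0)
  edges <- matrix(as.matrix(wl) %in% keep, nrow(grad), ncol(grad))

  # close contours, fill interiors
  brush <- EBImage::makeBrush(7, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(edges * 1), brush)
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  labm <- as.matrix(lab)

  # drop small components, relabel compactly
  areas <- table(labm[labm > 0])
  keep_ids <- as.integer(names(areas)[areas >= min_area_px])
  if (length(keep_ids) == 0) stop("no cells found", call. = FALSE)
  relabel <- integer(max(labm) + 1L)
  relabel[keep_ids + 1L] <- seq_along(keep_ids)
  labels <- matrix(relabel[labm + 1L], nrow(labm), ncol(labm))
  structure(list(mask = labels > 0, labels = labels,
                 n_cells = length(keep_ids)),
            flagged = length(keep_ids) > max_cells,
            class = "cell_mask")
}

# Otsu threshold (maximum between-class variance) over a value vector
.otsu <- function(v, n_bins = 256L) {
  if (length(v) == 0 || diff(range(v)) == 0) return(NA_real_)
  br <- seq(min(v), max(v), length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# keep pixels whose gradient magnitude is a local maximum along the
# quantized gradient direction (classic edge thinning)
.edge_nms <- function(grad, gy, gx) {
  ny <- nrow(grad); nx <- ncol(grad)
  ang <- atan2(gy, gx)  # in (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: x, 1: diag, 2: y, 3: anti-diag
  shift2 <- function(m, dy, dx) {
    out <- matrix(-Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
    out
  }
  dirs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  nms <- matrix(FALSE, ny, nx)
  for (s in 0:3) {
    d <- dirs[[as.character(s)]]
    fwd <- shift2(grad, d[1], d[2])
    bwd <- shift2(grad, -d[1], -d[2])
    nms <- nms | (sector == s & grad >= fwd & grad >= bwd)
  }
  nms & grad > 0
}

#' Assign detected spots to segmented cells
#'
#' Each spot is assigned to the mask label at its (y, x) position
#' regardless of its Z coordinate (the mask is 2D). Spots over background
#' pixels are tallied as `outside_count`. The conservation invariant
#' `sum(per_cell_counts) + outside_count == nrow(spots)` always holds.
#'
#' @param spots data.frame with integer columns `z`, `y`, `x` (1-based).
#' @param mask A [segment_cells()] result.
#' @param selected_threshold Optional threshold to record in the result.
#' @return An object of class `spot_call_result`: list with
#'   `selected_threshold`, `spots` (with a `cell` column; 0 = outside),
#'   `per_cell_counts` (named integer vector over labels) and
#'   `outside_count`.
#' @export
count_per_cell <- function(spots, mask, selected_threshold = NA_real_) {
  .check(inherits(mask, "cell_mask"), "mask must be a cell_mask")
  .check(is.data.frame(spots) && all(c("z", "y", "x") %in% names(spots)),
         "spots must have z, y, x columns")
  dmy <- dim(mask$labels)
  .check(nrow(spots) == 0 ||
           (all(spots$y >= 1 & spots$y <= dmy[1]) &&
              all(spots$x >= 1 & spots$x <= dmy[2])),
         "spot (y, x) outside mask shape")
  lab <- if (nrow(spots) > 0) {
    mask$labels[cbind(spots$y, spots$x)]
  } else integer(0)
  spots$cell <- lab
  per_cell <- vapply(seq_len(mask$n_cells),
                     function(i) sum(lab == i), integer(1))
  names(per_cell) <- as.character(seq_len(mask$n_cells))
  structure(list(selected_threshold = selected_threshold,
                 spots = spots,
                 per_cell_counts = per_cell,
                 outside_count = sum(lab == 0L)),
            class = "spot_call_result")
}

#' Compare transcript counts between two groups of cells
#'
#' Mann-Whitney (Wilcoxon rank-sum) test with tie correction: the exact
#' distribution is used when the smaller group has at most 8 observations
#' and there are no ties; otherwise the normal approximation with
#' continuity correction.
#'
#' @param counts_a,counts_b Numeric vectors of per-cell transcript counts
#'   (both non-empty).
#' @return list with `U` (the rank-sum statistic for group a) and `p`
#'   (two-sided).
#' @export
compare_groups <- function(counts_a, counts_b) {
  .check(length(counts_a) >= 1 && length(counts_b) >= 1,
         "both groups must be non-empty")
  no_ties <- !anyDuplicated(c(counts_a, counts_b))
  use_exact <- min(length(counts_a), length(counts_b)) <= 8 && no_ties
  ht <- suppressWarnings(
    wilcox.test(counts_a, counts_b, exact = use_exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Full spot-counting pipeline for one 3D smFISH stack
#'
#' LoG-filters the spot channel, builds the threshold curve, selects (or
#' accepts) a detection threshold, detects regional maxima, segments the
#' GFP channel and assigns spots to cells.
#'
#' @param channels Named list of 3D arrays with elements `spot` and `gfp`
#'   (as produced by [gen_image()] or [read_stack()]).
#' @param sigma LoG sigma (default 1.5 px).
#' @param n_thresholds,window,tol Threshold-curve and plateau parameters.
#' @param threshold Manual threshold override; skips plateau selection.
#' @param blur_sigma,min_area_px Passed to [segment_cells()].
#' @return A [count_per_cell()] result, with the threshold curve attached
#'   as attribute `curve`.
#' @export
smfish_count_stack <- function(channels, sigma = 1.5, n_thresholds = 100L,
                               window = 10L, tol = 2L, threshold = NULL,
                               blur_sigma = 8, min_area_px = 200L) {
  .check(is.list(channels) && all(c("spot", "gfp") %in% names(channels)),
         "channels must contain 'spot' and 'gfp'")
  filt <- log_filter(channels$spot, sigma)
  rng <- range(filt)
  .check(diff(rng) > 0, "no dynamic range: image is flat")
  maxima <- .regional_maxima(filt, rng[1])
  thresholds <- seq(rng[1], rng[2], length.out = n_thresholds)
  curve <- structure(
    list(thresholds = thresholds,
         counts = vapply(thresholds, function(t) sum(maxima$value >= t),
                         integer(1))),
    class = "threshold_curve")
  thr <- if (is.null(threshold)) as.numeric(select_threshold(curve, window, tol))
         else threshold
  spots <- maxima[maxima$value >= thr, c("z", "y", "x", "value")]
  mask <- segment_cells(channels$gfp, blur_sigma, min_area_px)
  res <- count_per_cell(spots, mask, selected_threshold = thr)
  attr(res, "curve") <- curve
  attr(res, "flagged") <- attr(mask, "flagged")
  res
}
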