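test_that("LoG response is zero on constant input and peaks at spot centres", {
  const <- array(7, c(8, 10, 12))
  expect_lt(max(abs(log_filter(const, 1.5))), 1e-9)

  centre <- matrix(c(6, 9, 9), 1)
  stack <- make_spot_stack(c(12, 18, 18), centre, sigma = 1.5)
  resp <- log_filter(stack, 1.5)
  peak <- which(resp == max(resp), arr.ind = TRUE)  # oracle: global argmax
  expect_equal(unname(peak[1, ]), c(6, 9, 9))

  two <- matrix(c(5, 6, 6, 5, 14, 14), 2, byrow = TRUE)
  stack2 <- make_spot_stack(c(10, 20, 20), two, sigma = 1.5)
  resp2 <- log_filter(stack2, 1.5)
  m <- count_maxima(resp2, max(resp2) * 0.5)
  expect_equal(nrow(m), 2)
  expect_equal(m[order(m$x), c("z", "y", "x")],
               data.frame(z = c(5, 5), y = c(6, 14), x = c(6, 14)),
               ignore_attr = TRUE)
  expect_lt(abs(m$value[1] - m$value[2]) / max(m$value), 0.02)

  expect_error(log_filter(array(c(1, NA), c(2, 4, 4)), 1), "non-finite")
  expect_error(log_filter(const, -1), "sigma")
})

test_that("regional maxima respect thresholds, plateaus, and emptiness", {
  zero <- array(0, c(5, 5, 5))
  expect_equal(nrow(count_maxima(zero, 0.5)), 0)

  # a 2-voxel flat plateau counts once, at its centroid
  a <- array(0, c(5, 7, 7))
  a[3, 4, 3] <- 5; a[3, 4, 4] <- 5
  m <- count_maxima(a, 1)
  expect_equal(nrow(m), 1)
  expect_equal(unname(unlist(m[1, c("z", "y", "x")])), c(3, 4, 4))  # round(3.5) = 4

  # interior plateau adjacent to a higher voxel is not a maximum
  b <- array(0, c(3, 5, 5))
  b[2, 3, 2] <- 5; b[2, 3, 3] <- 5; b[2, 3, 4] <- 6
  m2 <- count_maxima(b, 1)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$x, 4)
})

test_that("threshold curves are monotone and plateau at the true count", {
  centres <- matrix(c(5, 8, 8, 5, 8, 20, 5, 20, 12), 3, byrow = TRUE)
  stack <- make_spot_stack(c(10, 28, 28), centres, sigma = 1.5,
                           amplitude = 1000)
  set.seed(1)
  noisy <- stack + array(rnorm(length(stack), 0, 5), dim(stack))
  curve <- threshold_curve(log_filter(noisy, 1.5), 100)
  expect_true(all(diff(curve$counts) <= 0))
  expect_gte(sum(curve$counts == 3), 30)  # wide plateau at the true count

  expect_error(threshold_curve(array(1, c(4, 4, 4))), "dynamic range")

  # monotone for arbitrary noise inputs
  for (s in 1:3) {
    set.seed(s)
    x <- array(rnorm(4 * 12 * 12), c(4, 12, 12))
    cv <- threshold_curve(x, 50)
    expect_true(all(diff(cv$counts) <= 0))
  }
})

test_that("plateau selection picks the stable range and breaks ties stringently", {
  mk <- function(counts, thresholds = seq_along(counts)) {
    structure(list(thresholds = thresholds, counts = counts),
              class = "threshold_curve")
  }
  counts <- c(seq(300, 52, length.out = 29), rep(50, 41), seq(49, 0, length.out = 30))
  sel <- select_threshold(mk(counts), window = 10, tol = 2)
  pl <- attr(sel, "plateau")
  expect_equal(attr(sel, "plateau")$count, 50)
  expect_gte(sel, 29)
  expect_lte(sel, 71)

  expect_error(select_threshold(mk(100:1), window = 10, tol = 0), "no plateau")

  # two equal-length plateaus: the higher-threshold one wins
  two <- c(rep(80, 10), seq(79, 41, length.out = 10), rep(40, 10))
  sel2 <- select_threshold(mk(two), window = 10, tol = 0)
  expect_equal(attr(sel2, "plateau")$count, 40)
})

test_that("batch threshold averages per-image selections", {
  flat <- function(lo, hi) {
    structure(list(thresholds = seq(lo, hi, length.out = 21),
                   counts = rep(5L, 21)), class = "threshold_curve")
  }
  # fully flat curves select their midpoint threshold
  expect_equal(batch_threshold(list(flat(0, 20), flat(0, 40)), k = 2), 15)
  expect_equal(batch_threshold(list(flat(0, 20), flat(0, 20)), k = 5),
               as.numeric(select_threshold(flat(0, 20))))
})

test_that("cell segmentation recovers disk geometry", {
  mk_gfp <- function(centres, r, dyx = 96) {
    g <- array(0, c(4, dyx, dyx))
    yy <- matrix(seq_len(dyx), dyx, dyx)
    xx <- t(yy)
    for (i in seq_len(nrow(centres))) {
      disk <- (yy - centres[i, 1])^2 + (xx - centres[i, 2])^2 <= r^2
      for (z in 1:4) g[z, , ][disk] <- 3000
    }
    set.seed(99)
    g + 100 + array(rnorm(length(g), 0, 20), dim(g))
  }
  one <- mk_gfp(matrix(c(48, 48), 1), r = 20)
  mask <- segment_cells(one)
  expect_equal(mask$n_cells, 1)
  yy <- matrix(seq_len(96), 96, 96); xx <- t(yy)
  truth <- (yy - 48)^2 + (xx - 48)^2 <= 400
  iou <- sum(mask$mask & truth) / sum(mask$mask | truth)
  expect_gte(iou, 0.9)

  two <- mk_gfp(matrix(c(26, 26, 70, 70), 2, byrow = TRUE), r = 16)
  expect_equal(segment_cells(two)$n_cells, 2)

  blank <- array(100, c(4, 64, 64))
  expect_error(segment_cells(blank), "no cells found")
})

test_that("spot-to-cell assignment conserves spots and ignores Z", {
  labels <- matrix(0L, 20, 20)
  labels[2:8, 2:8] <- 1L
  labels[12:18, 12:18] <- 2L
  mask <- structure(list(mask = labels > 0, labels = labels, n_cells = 2L),
                    class = "cell_mask")
  spots <- data.frame(
    z = c(rep(1, 12), rep(3, 7), 1, 2, 5),
    y = c(rep(5, 12), rep(15, 7), 1, 10, 20),
    x = c(rep(5, 12), rep(15, 7), 1, 10, 20))
  res <- count_per_cell(spots, mask)
  expect_equal(unname(res$per_cell_counts), c(12L, 7L))
  expect_equal(res$outside_count, 3L)
  expect_equal(sum(res$per_cell_counts) + res$outside_count, nrow(spots))

  # permuting Z leaves per-cell counts unchanged (mask is 2D)
  set.seed(2)
  spots2 <- spots
  spots2$z <- sample(spots$z)
  res2 <- count_per_cell(spots2, mask)
  expect_equal(res2$per_cell_counts, res$per_cell_counts)
  expect_equal(res2$outside_count, res$outside_count)

  all_in <- data.frame(z = 1:3, y = c(3, 4, 5), x = c(3, 4, 5))
  res3 <- count_per_cell(all_in, mask)
  expect_equal(unname(res3$per_cell_counts), c(3L, 0L))
  expect_equal(res3$outside_count, 0L)
})

test_that("group comparison matches exact enumeration and approximations", {
  r <- compare_groups(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)

  same <- compare_groups(c(3, 1, 2), c(3, 1, 2))
  expect_gte(same$p, 0.99)

  shift <- compare_groups(seq_len(20) + 1000, seq_len(20) + rnorm(20, 0, 1e-3))
  expect_lt(shift$p, 1e-5)

  # agreement with brute-force enumeration for all no-tie splits, n1+n2 <= 8
  set.seed(7)
  for (n1 in 2:4) for (n2 in 2:4) {
    vals <- sample(100, n1 + n2)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    got <- compare_groups(x, y)
    exp <- oracle_mw(x, y)
    expect_equal(got$U, exp$U)
    expect_equal(got$p, exp$p, tolerance = 1e-12)
  }

  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("the full stack pipeline recovers planted per-cell counts", {
  for (s in 101:105) {
    img <- gen_image(image_sim_config(seed = s))
    res <- smfish_count_stack(img$channels)
    expect_true(recovered_exactly(img, res), label = paste("seed", s))
    expect_true(all(diff(attr(res, "curve")$counts) <= 0))
  }
})

test_that("manual threshold override bypasses plateau selection", {
  img <- gen_image(image_sim_config(seed = 31))
  auto <- smfish_count_stack(img$channels)
  manual <- smfish_count_stack(img$channels,
                               threshold = auto$selected_threshold)
  expect_equal(manual$per_cell_counts, auto$per_cell_counts)
  expect_equal(manual$selected_threshold, auto$selected_threshold)
})
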