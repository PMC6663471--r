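test_that("median filter: identity kernel, spike removal, hand-computed
           checkerboard", {
  set.seed(1)
  m <- matrix(runif(36), 6)
  m <- (m + t(m)) / 2
  sm <- structure(list(values = m, n_windows = 6),
                  class = "similarity_matrix")
  expect_equal(median_filter_similarity(sm, 1)$values, m)
  expect_error(median_filter_similarity(sm, 2), "odd")

  spike <- matrix(0, 7, 7)
  spike[4, 4] <- 1
  sp <- median_filter_similarity(
    structure(list(values = spike, n_windows = 7),
              class = "similarity_matrix"), 3)
  expect_equal(sp$values, matrix(0, 7, 7))

  # checkerboard: interior medians flip to the majority of the 3x3
  # neighborhood (5 of 9 cells of the opposite color)
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  fcb <- median_filter_similarity(
    structure(list(values = cb, n_windows = 6),
              class = "similarity_matrix"), 3)
  # hand computation for a few cells
  # cell (3,3): neighborhood has five 1s (corners+center? compute directly)
  nb <- function(i, j) {
    ii <- pmin(pmax((i - 1):(i + 1), 1), 6)
    jj <- pmin(pmax((j - 1):(j + 1), 1), 6)
    median(cb[ii, jj])
  }
  for (ij in list(c(1, 1), c(3, 3), c(4, 2), c(6, 6)))
    expect_equal(fcb$values[ij[1], ij[2]],
                 (nb(ij[1], ij[2]) + nb(ij[2], ij[1])) / 2)
})

test_that("segmentation recovers planted blocks exactly for any a", {
  A <- matrix(0, 13, 13)
  A[1:5, 1:5] <- 1
  A[9:13, 9:13] <- 1
  for (a in c(0.05, 0.3, 0.5, 0.7, 0.95)) {
    seg <- segment_similarity(A, segmentation_config(accuracy_param = a))
    expect_equal(seg$start, c(1, 9))
    expect_equal(seg$end, c(5, 13))
  }
})

test_that("segmentation follows the worked flowchart trace", {
  # 6 windows; window 1 background (low diagonal), windows 2-4 one state,
  # window 5 dissimilar, built so that the running means satisfy
  # S_{1,0} < a; S_{2,0}, S_{2,1}, S_{2,2} > a; S_{2,3} < a.
  a <- 0.5
  A <- matrix(0, 6, 6)
  diag(A) <- c(0.4, 0.9, 0.9, 0.9, 0.9, 0.2)
  A[2, 3] <- A[3, 2] <- 0.8
  A[2, 4] <- A[4, 2] <- 0.7
  A[3, 4] <- A[4, 3] <- 0.8
  A[2, 5] <- A[5, 2] <- 0.1
  A[3, 5] <- A[5, 3] <- 0.1
  A[4, 5] <- A[5, 4] <- 0.1
  # hand-check the paper-form running means:
  expect_lt(A[1, 1], a)                                   # S_{1,0}
  expect_gt(A[2, 2], a)                                   # S_{2,0}
  expect_gt((A[2, 3] + A[3, 2] + A[3, 3]) / 3, a)         # S_{2,1}
  expect_gt((A[2, 4] + A[4, 2] + A[3, 4] + A[4, 3] + A[4, 4]) / 5, a)
  expect_lt((A[2, 5] + A[3, 5] + A[4, 5] + A[5, 2] + A[5, 3] + A[5, 4] +
               A[5, 5]) / 7, a)                           # S_{2,3}
  seg <- segment_similarity(A, segmentation_config(accuracy_param = a))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 2)
  expect_equal(seg$end, 4)
})

test_that("raising a never lengthens segments; raising j_min never
           increases their count", {
  set.seed(21)
  base <- matrix(0, 30, 30)
  for (b in list(2:7, 10:13, 17:25)) base[b, b] <- runif(1, 0.6, 1)
  noise <- matrix(runif(900, 0, 0.25), 30)
  A <- pmax(base, (noise + t(noise)) / 2)
  diag(A) <- pmax(diag(base), 0.5)
  grid <- seq(0.1, 0.9, by = 0.1)
  lens <- sapply(grid, function(a) {
    seg <- segment_similarity(A, segmentation_config(accuracy_param = a))
    sum(seg$end - seg$start + 1)
  })
  expect_true(all(diff(lens) <= 0))
  counts <- sapply(c(1, 2, 3, 5, 8), function(jm) {
    nrow(segment_similarity(A, segmentation_config(accuracy_param = 0.4,
                                                   j_min = jm)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("segments kept only when longer than j_min, disjoint and
           ordered", {
  A <- matrix(0, 10, 10)
  A[1:2, 1:2] <- 1          # 2-window block
  A[5:8, 5:8] <- 1          # 4-window block
  seg1 <- segment_similarity(A, segmentation_config(accuracy_param = 0.5,
                                                    j_min = 1))
  expect_equal(nrow(seg1), 2)
  seg3 <- segment_similarity(A, segmentation_config(accuracy_param = 0.5,
                                                    j_min = 3))
  expect_equal(nrow(seg3), 1)
  expect_equal(c(seg3$start, seg3$end), c(5, 8))
  expect_true(all(seg1$start[-1] > seg1$end[-nrow(seg1)]))
})

test_that("FDR similarity threshold keeps genuine blocks and zeroes
           noise-level entries", {
  set.seed(13)
  n_nodes <- 30
  pa <- rep(1:3, each = 10)
  parts <- c(replicate(6, pa, simplify = FALSE),
             lapply(1:6, function(i)
               canonicalize_partition(sample(1:3, n_nodes, TRUE))))
  sm <- similarity_matrix(parts)
  thr <- fdr_threshold_similarity(sm, parts, q = 0.05, null_draws = 600,
                                  seed = 3)
  expect_equal(thr$values[1:6, 1:6], matrix(1, 6, 6))  # identical block
  # entries among independent random partitions: mostly zeroed
  off <- thr$values[7:12, 7:12][upper.tri(matrix(0, 6, 6))]
  expect_gt(mean(off == 0), 0.5)
  # q -> 1 keeps the matrix unchanged
  thr1 <- fdr_threshold_similarity(sm, parts, q = 0.999, null_draws = 300,
                                   seed = 3)
  expect_equal(thr1$values, sm$values)
  expect_error(fdr_threshold_similarity(sm, parts, q = 2), "q")
})

test_that("consecutive detection on planted partition sequences finds the
           planted states end-to-end", {
  # 24 windows: state A (1-9), background (10-14), state B (15-24);
  # partitions: planted for state windows, random for background
  set.seed(17)
  n_nodes <- 30
  pa <- rep(1:3, each = 10)
  pb <- canonicalize_partition(rep(rep(1:3, 10)))
  parts <- c(replicate(9, pa, simplify = FALSE),
             lapply(1:5, function(i)
               canonicalize_partition(sample(1:6, n_nodes, TRUE))),
             replicate(10, pb, simplify = FALSE))
  det <- detect_consecutive(parts, fast_config(seed = 2),
                            segmentation_config(seed = 3))
  expect_equal(nrow(det$segments), 2)
  expect_equal(det$segments$start, c(1, 15))
  expect_equal(det$segments$end, c(9, 24))
  expect_equal(det$states[[1]]$partition, pa)
  expect_equal(det$states[[2]]$partition, pb)
})
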