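test_that("dyn_tensor validates, symmetrizes and zeroes the diagonal", {
  w <- matrix(c(0, 1, 1, 0), 2)
  tn <- dyn_tensor(w)
  expect_equal(tn$n_nodes, 2)
  expect_equal(tn$n_windows, 1)
  expect_equal(tn$weights[1, 2, 1], 1)

  wd <- matrix(c(5, 1, 1, 5), 2)
  tn2 <- dyn_tensor(wd)
  expect_equal(diag(tn2$weights[, , 1]), c(0, 0))

  wa <- matrix(c(0, 1, 3, 0), 2)  # asymmetric
  expect_warning(tn3 <- dyn_tensor(wa), "asymmetry")
  expect_equal(tn3$weights[1, 2, 1], 2)

  wn <- matrix(c(0, -1, -1, 0), 2)
  expect_error(dyn_tensor(wn), "negative")
  expect_silent(dyn_tensor(wn, allow_negative = TRUE))

  expect_error(dyn_tensor(array(0, c(2, 3, 1))), "square")
})

test_that("CSV round trip reproduces a hand-assembled dense tensor", {
  # 3 nodes, 2 windows, built by hand
  df <- data.frame(window = c(1, 1, 2),
                   node_i = c(1, 2, 1),
                   node_j = c(2, 3, 3),
                   weight = c(0.5, 0.25, 1.5))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tn <- load_tensor(path)
  expected <- array(0, c(3, 3, 2))
  expected[1, 2, 1] <- expected[2, 1, 1] <- 0.5
  expected[2, 3, 1] <- expected[3, 2, 1] <- 0.25
  expected[1, 3, 2] <- expected[3, 1, 2] <- 1.5
  expect_equal(tn$weights, expected)

  # save -> load round trip
  out <- tempfile(fileext = ".csv")
  save_tensor(tn, out)
  tn2 <- load_tensor(out, n_nodes = 3, n_windows = 2)
  expect_equal(tn2$weights, tn$weights)

  # rds round trip is exact
  rds <- tempfile(fileext = ".rds")
  save_tensor(tn, rds)
  expect_equal(load_tensor(rds)$weights, tn$weights)
  unlink(c(path, out, rds))
})

test_that("proportional threshold keeps exactly the strongest edges", {
  # 5 nodes, 10 distinct weights 1..10; keep_fraction 0.2 -> top 2 edges
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- 1:10
  w <- w + t(w)
  tn <- dyn_tensor(w)
  th <- proportional_threshold(tn, 0.2)
  s <- th$weights[, , 1]
  kept <- sort(s[upper.tri(s)][s[upper.tri(s)] > 0])
  expect_equal(kept, c(9, 10))

  # identity at keep_fraction = 1
  expect_equal(proportional_threshold(tn, 1)$weights, tn$weights)

  # idempotence
  expect_equal(proportional_threshold(th, 0.2)$weights, th$weights)

  # parameter validation
  expect_error(proportional_threshold(tn, 0), "keep_fraction")
  expect_error(proportional_threshold(tn, 1.2), "keep_fraction")
})

test_that("ties at the proportional cutoff are all retained", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(1, 5, 5, 5, 2, 3)   # three tied at the cutoff
  w <- w + t(w)
  tn <- dyn_tensor(w)
  th <- proportional_threshold(tn, 1 / 6)  # nominally 1 edge
  s <- th$weights[, , 1]
  expect_equal(sum(s[upper.tri(s)] == 5), 3)
  expect_equal(sum(s[upper.tri(s)] > 0), 3)
})

test_that("thresholding preserves symmetry and zero diagonal", {
  set.seed(5)
  w <- array(abs(rnorm(8 * 8 * 3)), c(8, 8, 3))
  tn <- suppressWarnings(dyn_tensor((w + aperm(w, c(2, 1, 3))) / 2))
  for (th in list(proportional_threshold(tn, 0.3),
                  fdr_threshold_tensor(tn, q = 0.2, null_samples = 200,
                                       seed = 4))) {
    for (t in 1:3) {
      s <- th$weights[, , t]
      expect_equal(s, t(s))
      expect_equal(diag(s), rep(0, 8))
      expect_true(all(s >= 0))
    }
  }
})

test_that("FDR tensor threshold keeps planted strong edges and is
           deterministic given the seed", {
  set.seed(9)
  n <- 8
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- abs(rnorm(choose(n, 2), 0.1, 0.1))
  w[1, 2] <- w[3, 4] <- w[5, 6] <- 10
  w <- w + t(w) - diag(diag(w))
  w <- (w + t(w)) / 2; diag(w) <- 0
  tn <- dyn_tensor(w)
  th <- fdr_threshold_tensor(tn, q = 0.05, null_samples = 800, seed = 3)
  s <- th$weights[, , 1]
  expect_equal(sort(which(s[upper.tri(s)] > 0)),
               which(tn$weights[, , 1][upper.tri(s)] == 10))
  th2 <- fdr_threshold_tensor(tn, q = 0.05, null_samples = 800, seed = 3)
  expect_identical(th$weights, th2$weights)
})

test_that("FDR tensor threshold keeps everything as q approaches 1", {
  set.seed(2)
  w <- matrix(0, 6, 6)
  w[upper.tri(w)] <- runif(15, 0.5, 1)
  w <- w + t(w)
  tn <- dyn_tensor(w)
  th <- fdr_threshold_tensor(tn, q = 0.999, null_samples = 200, seed = 1)
  expect_equal(th$weights, tn$weights)
  expect_warning(fdr_threshold_tensor(tn, q = 0.5, null_samples = 50,
                                      seed = 1), "null_samples")
  expect_error(fdr_threshold_tensor(tn, q = 1.5), "q")
})
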