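test_that("weighted mean matches the per-pixel convex formula", {
  set.seed(4)
  fov <- matrix(TRUE, 16, 16)
  rs <- list(MF = rand_response(16, 16, 1, "MF"),
             FR = rand_response(16, 16, 2, "FR"),
             GW = rand_response(16, 16, 3, "GW"))
  w <- weight_vector(c(MF = 0.5, FR = 0.3, GW = 0.2))
  f <- weighted_mean(rs, w)
  direct <- 1 - (0.5 * rs$MF$response + 0.3 * rs$FR$response +
                   0.2 * rs$GW$response)
  expect_equal(f$response, direct, tolerance = 1e-12)
  expect_identical(f$source, "fused-wm")
  expect_true(all(f$response >= 0 & f$response <= 1))
})

test_that("weighted mean endpoints: single input and all-ones input", {
  g <- rand_response(8, 8, 1, "MF")
  f1 <- weighted_mean(list(MF = g), weight_vector(c(MF = 1)))
  expect_equal(f1$response, 1 - g$response)
  ones <- enhanced_image(matrix(1, 8, 8), matrix(TRUE, 8, 8), "FR")
  f0 <- weighted_mean(list(FR = ones), weight_vector(c(FR = 1)))
  expect_true(all(f0$response == 0))
})

test_that("weighted mean rejects tag mismatches", {
  rs <- list(MF = rand_response(8, 8, 1, "MF"))
  expect_error(weighted_mean(rs, weight_vector(c(FR = 1))),
               "configuration error")
})

test_that("weight vectors enforce the simplex constraint", {
  expect_error(weight_vector(c(MF = 0.5, FR = 0.6)), "sum to 1")
  expect_error(weight_vector(c(MF = 1.2, FR = -0.2)), "non-negative")
  expect_error(weight_vector(c(0.5, 0.5)), "named")
  w <- weight_vector(c(MF = 0.25, FR = 0.75))
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("rank transform orders FOV pixels, ties get mean positions", {
  fov <- matrix(FALSE, 2, 2); fov[1, 1] <- fov[1, 2] <- fov[2, 1] <- TRUE
  resp <- enhanced_image(matrix(c(0.1, 0.5, 0.9, 0), 2, 2), fov, "MF")
  ri <- rank_transform(resp)
  expect_equal(ri$ranks[1, 1], 1)  # intensity 0.1
  expect_equal(ri$ranks[1, 2], 3)  # intensity 0.9
  expect_equal(ri$ranks[2, 1], 2)  # intensity 0.5
  expect_equal(ri$ranks[2, 2], 0)  # outside FOV
  expect_equal(ri$top, 3L)
  # two tied maxima among four pixels share rank 3.5
  resp4 <- enhanced_image(matrix(c(1, 0.2, 1, 0.4), 2, 2),
                          matrix(TRUE, 2, 2), "MF")
  r4 <- rank_transform(resp4)
  expect_equal(sort(r4$ranks[resp4$response == 1]), c(3.5, 3.5))
})

test_that("ranks of a tie-free field are a bijection onto 1..top", {
  r <- rand_response(12, 9, seed = 6)
  ri <- rank_transform(r)
  expect_setequal(ri$ranks[ri$fov], seq_len(ri$top))
})

test_that("rank transform is invariant under monotone remapping", {
  r <- rand_response(10, 10, seed = 7)
  warped <- enhanced_image(r$response^3, r$fov, r$source)
  expect_equal(rank_transform(r)$ranks, rank_transform(warped)$ranks)
  expect_error(rank_transform(enhanced_image(matrix(0.5, 4, 4),
                                             matrix(TRUE, 4, 4), "MF")),
               "degenerate")
})

test_that("median ranking takes per-pixel medians and normalizes", {
  fov <- matrix(TRUE, 1, 3)
  mk <- function(v) rank_image(matrix(v, 1, 3), fov, 3)
  # per-pixel ranks (5,2,9) -> median 5 etc.; verified against sort oracle
  a <- mk(c(5, 1, 2)); b <- mk(c(2, 3, 1)); c_ <- mk(c(9, 2, 3))
  out <- median_ranking(list(a, b, c_))
  stacked <- rbind(c(5, 1, 2), c(2, 3, 1), c(9, 2, 3))
  oracle <- apply(stacked, 2, function(v) sort(v)[2])
  expect_equal(rank(out$response[fov]), rank(oracle))
  expect_equal(out$response[1, 1], 1)  # largest median
  expect_identical(out$source, "fused-mr")
})

test_that("median over an even number of rank images averages the middle", {
  fov <- matrix(TRUE, 1, 2)
  mk <- function(v) rank_image(matrix(v, 1, 2), fov, 2)
  out <- median_ranking(list(mk(c(1, 2)), mk(c(4, 1)), mk(c(6, 2)),
                             mk(c(9, 1))))
  # pixel 1 ranks (1,4,6,9) -> 5; pixel 2 ranks (2,1,2,1) -> 1.5
  expect_equal(out$response[1, 1], 1)
  expect_equal(out$response[1, 2], 0)
  med <- median(c(1, 4, 6, 9))
  expect_equal(med, 5)
})

test_that("median ranking is permutation-invariant and idempotent-like", {
  rs <- lapply(1:3, function(s) rank_transform(rand_response(8, 8, s)))
  o1 <- median_ranking(rs)
  o2 <- median_ranking(rs[c(3, 1, 2)])
  expect_equal(o1$response, o2$response)
  same <- median_ranking(list(rs[[1]], rs[[1]], rs[[1]]))
  expect_equal(rank(same$response[same$fov]),
               rank(rs[[1]]$ranks[rs[[1]]$fov]))
})

test_that("median ranking validates its inputs", {
  r1 <- rank_transform(rand_response(8, 8, 1))
  expect_error(median_ranking(list(r1)), "at least two")
  r2 <- rank_transform(rand_response(9, 8, 2))
  expect_error(median_ranking(list(r1, r2)), "shape")
})

test_that("Otsu agrees with exhaustive search over all 256 cut points", {
  otsu_oracle <- function(v, bins = 256) {
    h <- tabulate(pmin(floor(v * bins), bins - 1) + 1L, nbins = bins)
    mids <- (seq_len(bins) - 0.5) / bins
    bcv <- rep(NA_real_, bins - 1)
    for (k in 1:(bins - 1)) {
      w0 <- sum(h[1:k]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(h[1:k] * mids[1:k]) / w0
      mu1 <- sum(h[(k + 1):bins] * mids[(k + 1):bins]) / w1
      bcv[k] <- w0 * w1 * (mu0 - mu1)^2
    }
    # maximizer set (plateaus over empty bins are exact ties), middle cut
    ties <- which(bcv >= max(bcv, na.rm = TRUE) * (1 - 1e-9))
    ties[ceiling(length(ties) / 2)] / bins
  }
  for (seed in 1:5) {
    set.seed(seed)
    v <- c(rnorm(400, 0.3, 0.08), rnorm(150, 0.75, 0.05), runif(50))
    v <- pmin(pmax(v, 0), 1)
    expect_equal(retinafuse:::otsu_cut(v), otsu_oracle(v),
                 label = sprintf("seed %d", seed))
  }
})

test_that("Otsu splits a separated bimodal mixture between the modes", {
  set.seed(9)
  px <- matrix(pmin(pmax(c(rnorm(300, 0.2, 0.02), rnorm(100, 0.8, 0.02)),
                         0), 1), 20, 20)
  resp <- enhanced_image(px, matrix(TRUE, 20, 20), "MF")
  seg <- otsu_threshold(resp)
  t <- attr(seg, "threshold")
  expect_gt(t, 0.3); expect_lt(t, 0.7)
  expect_identical(seg$labels, px > t)
})

test_that("Otsu polarity flips for weighted-mean (dark-vessel) images", {
  set.seed(9)
  px <- matrix(pmin(pmax(c(rnorm(300, 0.2, 0.02), rnorm(100, 0.8, 0.02)),
                         0), 1), 20, 20)
  fov <- matrix(TRUE, 20, 20)
  bright <- otsu_threshold(enhanced_image(px, fov, "fused-mr"))
  dark <- otsu_threshold(enhanced_image(px, fov, "fused-wm"))
  expect_identical(dark$labels, !bright$labels)
  expect_error(otsu_threshold(enhanced_image(matrix(0.4, 5, 5),
                                             matrix(TRUE, 5, 5), "MF")),
               "degenerate")
})

test_that("Pearson matrix matches direct covariance computation", {
  rs <- list(MF = rand_response(10, 10, 1, "MF"),
             FR = rand_response(10, 10, 2, "FR"))
  cm <- pearson_matrix(rs)
  expect_equal(dim(cm), c(2, 2))
  expect_equal(diag(cm), c(MF = 1, FR = 1))
  a <- rs$MF$response; b <- rs$FR$response
  direct <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(cm[1, 2], direct, tolerance = 1e-12)
  expect_equal(cm, t(cm))
  # perfect anti-correlation of g and 1 - g
  inv <- enhanced_image(1 - a, rs$MF$fov, "IN")
  cm2 <- pearson_matrix(list(MF = rs$MF, IN = inv))
  expect_equal(cm2[1, 2], -1, tolerance = 1e-12)
  flat <- enhanced_image(matrix(0.5, 10, 10), rs$MF$fov, "FR")
  expect_error(pearson_matrix(list(rs$MF, flat)), "constant")
})
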