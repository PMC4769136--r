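# Filter-level behavior is checked on bar/blob phantoms with known
# geometry; separability (vessel response above background) is the property
# the whole fusion pipeline rests on.

centerline_px <- function(ph) which(skeletonize(ph$truth$labels))

test_that("matched filter kills constant images and ignores offsets", {
  flat <- gray_image(matrix(0.5, 48, 48))
  bank <- build_kernel_bank(2, 9, 15)
  raw <- retinafuse:::conv_bank_cpp(1 - flat$pixels, bank$kernels)
  expect_true(all(abs(raw) < 1e-10))
  # adding a constant leaves the (pre-normalization) response unchanged
  set.seed(5)
  px <- matrix(runif(48 * 48, 0.1, 0.6), 48, 48)
  r1 <- retinafuse:::conv_bank_cpp(1 - px, bank$kernels)
  r2 <- retinafuse:::conv_bank_cpp(1 - (px + 0.3), bank$kernels)
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("matched filter arg-max orientation tracks the bar angle", {
  bank <- build_kernel_bank(2, 9, 15)
  for (ang in c(0, 30, 60, 135)) {
    ph <- straight_bar(c(64, 64), angle_deg = ang, width = 3)
    g <- preprocess_fundus(ph)
    resp <- matched_filter(g, bank)
    omap <- attr(resp, "orientation")
    on_cl <- centerline_px(ph)
    picked <- as.integer(names(which.max(table(omap[on_cl]))))
    expect_equal(bank$angles[picked], ang,
                 label = sprintf("bar at %d deg", ang))
  }
})

test_that("all three filters separate phantom vessels from background", {
  ph <- generate_phantom(phantom_spec(size = c(96, 96), n_vessels = 3,
                                      noise_sigma = 0.02, rng_seed = 8))
  g <- preprocess_fundus(ph)
  truth <- ph$truth$labels
  back <- ph$fov & !dilate_oracle(truth, 5)  # >= 5 px away from vessels
  for (tag in c("MF", "FR", "GW")) {
    resp <- enhance(g, tag)[[tag]]$response
    expect_gt(mean(resp[truth]), mean(resp[back]) + 0.1)
  }
})

test_that("filter responses are translation-equivariant in the interior", {
  set.seed(13)
  base <- matrix(runif(60 * 60), 60, 60)
  shifted <- rbind(base[-(1:2), ], base[1:2, ])  # rows shifted by 2
  g1 <- gray_image(base)
  g2 <- gray_image(shifted)
  # FR uses a fixed structure-ness constant (the per-image adaptive one is
  # a global statistic, not translation-equivariant); GW uses a short
  # envelope so its support stays clear of the borders in the core block
  for (fun in list(
    function(g) matched_filter(g)$response,
    function(g) frangi_vesselness(g, scales = c(1, 2), c = 0.1)$response,
    function(g) gabor_wavelet(g, scales = 2, elongation = 2)$response)) {
    r1 <- fun(g1)
    r2 <- fun(g2)
    # compare away from borders (padding differs there); the global
    # min-max normalization constant may differ, so compare the core
    # blocks each rescaled by their own maximum
    core <- 20:40
    aff <- function(m) (m - min(m)) / (max(m) - min(m))
    expect_equal(aff(r2[core - 2, core]), aff(r1[core, core]),
                 tolerance = 1e-6)
  }
})

test_that("vesselness suppresses blobs relative to bars", {
  n <- 64
  s <- 2
  d2 <- outer((1:n - 20)^2, (1:n - 32)^2, "+")
  blob <- exp(-d2 / (2 * s^2))
  u <- outer(rep(1, n), 1:n - 32)
  bar <- exp(-u^2 / (2 * s^2))
  bar[1:28, ] <- 0  # keep bar away from the blob
  img <- gray_image(pmin(pmax(0.8 - 0.6 * pmax(blob, bar), 0), 1))
  v <- frangi_vesselness(img, scales = c(1, 2, 3))$response
  blob_peak <- v[20, 32]
  bar_peak <- max(v[40:60, 32])
  expect_lt(blob_peak, 0.2 * bar_peak)
})

test_that("vesselness selects a scale near half the vessel width", {
  scales <- c(1, 1.5, 2, 2.5, 3, 3.5, 4)
  for (w in c(4, 6)) {
    ph <- straight_bar(c(64, 64), angle_deg = 0, width = w)
    g <- preprocess_fundus(ph)
    resp <- frangi_vesselness(g, scales = scales)
    on_cl <- abs(col(g$pixels) - 32.5) < 1
    winning <- attr(resp, "scale")[on_cl]
    best <- as.numeric(names(which.max(table(winning))))
    expect_lte(abs(best - w / 2), 1.0,
               label = sprintf("width %d chose scale %.1f", w, best))
  }
})

test_that("constant images give zero vesselness and Gabor response", {
  flat <- gray_image(matrix(0.5, 40, 40))
  expect_true(all(frangi_vesselness(flat)$response == 0))
  expect_true(all(gabor_wavelet(flat, scales = 2)$response == 0))
})

test_that("Gabor response is invariant to adding a constant", {
  set.seed(21)
  px <- matrix(runif(50 * 50, 0.1, 0.6), 50, 50)
  k <- retinafuse:::gabor_kernels(2, 4, 45)
  m1 <- Mod(retinafuse:::fft_correlate(px, k)[[1]])
  m2 <- Mod(retinafuse:::fft_correlate(px + 0.3, k)[[1]])
  expect_equal(m1, m2, tolerance = 1e-8)
})

test_that("Gabor centerline response exceeds background", {
  ph <- straight_bar(c(64, 64), angle_deg = 45, width = 3)
  g <- preprocess_fundus(ph)
  resp <- gabor_wavelet(g)$response
  on_cl <- centerline_px(ph)
  far <- !dilate_oracle(ph$truth$labels, 8)
  expect_gt(mean(resp[on_cl]), mean(resp[far]) + 0.2)
})

test_that("normalize_response rescales, preserves order, rejects constants", {
  raw <- matrix(c(-3, 1, 5, 1), 2, 2)
  out <- normalize_response(raw, matrix(TRUE, 2, 2))
  expect_equal(out$response, matrix(c(0, 0.5, 1, 0.5), 2, 2))
  idem <- normalize_response(out$response, out$fov)
  expect_equal(idem$response, out$response)
  set.seed(3)
  raw2 <- matrix(rnorm(100), 10, 10)
  out2 <- normalize_response(raw2, matrix(TRUE, 10, 10))
  expect_equal(rank(raw2), rank(out2$response))
  expect_error(normalize_response(matrix(1, 4, 4), matrix(TRUE, 4, 4)),
               "degenerate")
})

test_that("oversized kernels and bad parameters error out", {
  small <- gray_image(matrix(runif(36), 6, 6))
  expect_error(matched_filter(small, build_kernel_bank(3, 9)), "larger")
  expect_error(frangi_vesselness(rand_gray(), scales = numeric(0)), "scales")
  expect_error(gabor_wavelet(rand_gray(), scales = numeric(0)), "scales")
  expect_error(gabor_wavelet(rand_gray(), elongation = 0.5), "elongation")
})
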