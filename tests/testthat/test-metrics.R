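test_that("confusion counts match a per-pixel loop oracle", {
  set.seed(2)
  fov <- disc_mask(20, 8)
  s <- seg_from(matrix(runif(400) < 0.4, 20, 20) & fov, fov)
  g <- seg_from(matrix(runif(400) < 0.3, 20, 20) & fov, fov)
  cc <- confusion_counts(s, g)
  tp <- tn <- fp <- fn <- 0
  for (i in 1:20) for (j in 1:20) {
    if (!fov[i, j]) next
    if (s$labels[i, j] && g$labels[i, j]) tp <- tp + 1
    else if (!s$labels[i, j] && !g$labels[i, j]) tn <- tn + 1
    else if (s$labels[i, j]) fp <- fp + 1 else fn <- fn + 1
  }
  expect_equal(unclass(cc), list(tp = tp, tn = tn, fp = fp, fn = fn))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, sum(fov))
  # perfect agreement and perfect disagreement
  same <- confusion_counts(g, g)
  expect_equal(same$fp + same$fn, 0)
  comp <- seg_from(!g$labels & fov, fov)
  opp <- confusion_counts(comp, g)
  expect_equal(opp$tp + opp$tn, 0)
})

test_that("accuracy follows its closed form", {
  cc <- structure(list(tp = 8, tn = 80, fp = 6, fn = 6),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 0.88)
  g <- seg_from(matrix(c(TRUE, FALSE), 4, 4))
  expect_equal(accuracy(confusion_counts(g, g)), 1)
  comp <- seg_from(!g$labels)
  expect_equal(accuracy(confusion_counts(comp, g)), 0)
})

test_that("MCC: perfect, discordant, random-marginal and formula cases", {
  g <- seg_from(matrix(rep(c(TRUE, FALSE), c(10, 22)), 4, 8))
  expect_equal(mcc(confusion_counts(g, g)), 1)
  comp <- seg_from(!g$labels)
  expect_equal(mcc(confusion_counts(comp, g)), -1)
  cc <- structure(list(tp = 45, tn = 40, fp = 10, fn = 5),
                  class = "confusion_counts")
  oracle <- (45 * 40 - 10 * 5) /
    sqrt((45 + 10) * (45 + 5) * (40 + 10) * (40 + 5))
  expect_equal(mcc(cc), oracle, tolerance = 1e-15)
  # zero marginal factor -> 0 by convention (all-background prediction)
  cc0 <- structure(list(tp = 0, tn = 90, fp = 0, fn = 10),
                   class = "confusion_counts")
  expect_equal(mcc(cc0), 0)
})

test_that("MCC is symmetric in prediction and reference", {
  set.seed(5)
  a <- seg_from(matrix(runif(144) < 0.4, 12, 12))
  b <- seg_from(matrix(runif(144) < 0.5, 12, 12))
  expect_equal(mcc(confusion_counts(a, b)), mcc(confusion_counts(b, a)))
})

test_that("metrics are invariant under consistent pixel permutation", {
  set.seed(6)
  fov <- matrix(TRUE, 10, 10)
  s <- matrix(runif(100) < 0.4, 10, 10)
  g <- matrix(runif(100) < 0.35, 10, 10)
  perm <- sample(100)
  sp <- matrix(s[perm], 10, 10); gp <- matrix(g[perm], 10, 10)
  cc1 <- confusion_counts(seg_from(s), seg_from(g))
  cc2 <- confusion_counts(seg_from(sp), seg_from(gp))
  expect_equal(accuracy(cc1), accuracy(cc2))
  expect_equal(mcc(cc1), mcc(cc2))
})

test_that("AUC: perfect separation, rank identity, monotone invariance", {
  set.seed(12)
  fov <- matrix(TRUE, 20, 20)
  g <- matrix(runif(400) < 0.3, 20, 20)
  truth <- seg_from(g)
  perfect <- enhanced_image((g * 0.5 + 0.25), fov, "fused-mr")
  expect_equal(roc_auc(perfect, truth)$auc, 1)
  # Mann-Whitney identity on continuous random scores
  sc <- matrix(runif(400), 20, 20)
  resp <- enhanced_image(sc, fov, "fused-mr")
  auc <- roc_auc(resp, truth)$auc
  r <- rank(sc)
  n1 <- sum(g); n0 <- 400 - n1
  u <- sum(r[g]) - n1 * (n1 + 1) / 2
  expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  # strictly increasing transform leaves the AUC unchanged
  warped <- enhanced_image(sc^5, fov, "fused-mr")
  expect_equal(roc_auc(warped, truth)$auc, auc, tolerance = 1e-12)
  # curve endpoints
  curve <- roc_auc(resp, truth)
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_equal(tail(curve$fpr, 1), 1); expect_equal(tail(curve$tpr, 1), 1)
})

test_that("AUC of an uninformative response is near one half", {
  set.seed(77)
  n <- 90
  fov <- matrix(TRUE, n, n)
  g <- matrix(runif(n * n) < 0.3, n, n)
  resp <- enhanced_image(matrix(runif(n * n), n, n), fov, "fused-mr")
  auc <- roc_auc(resp, seg_from(g))$auc
  expect_lt(abs(auc - 0.5), 3 / sqrt(n * n))
})

test_that("AUC demands both classes", {
  fov <- matrix(TRUE, 5, 5)
  resp <- rand_response(5, 5)
  expect_error(roc_auc(resp, seg_from(matrix(FALSE, 5, 5))), "single class")
})

test_that("CAL of a perfect segmentation is 1, of an empty one is 0", {
  truth <- seg_from(bar_mask(20, 9, 11, 3, 18))
  perfect <- cal_score(truth, truth)
  expect_equal(perfect$connectivity, 1)
  expect_equal(perfect$area_overlap, 1)
  expect_equal(perfect$length_overlap, 1)
  expect_equal(perfect$cal, 1)
  # radius-0 dilation is the identity, so a perfect match still scores 1
  expect_equal(cal_score(truth, truth, alpha = 0, beta = 0)$cal, 1)
  empty <- seg_from(matrix(FALSE, 20, 20))
  sc <- cal_score(empty, truth)
  expect_equal(sc$area_overlap, 0)
  expect_equal(sc$cal, 0)
  expect_error(cal_score(truth, empty), "empty ground truth")
})

test_that("CAL of a fragmented bar matches a hand-built morphology oracle", {
  truth_m <- bar_mask(20, 10, 12, 2, 19)
  seg_m <- truth_m
  seg_m[, c(8, 14)] <- FALSE   # three fragments, same bar otherwise
  truth <- seg_from(truth_m)
  seg <- seg_from(seg_m)
  out <- cal_score(seg, truth, alpha = 2, beta = 2)
  # connectivity by its closed form: |#c(SG) - #c(S)| = 2
  expect_equal(out$connectivity, 1 - min(1, 2 / sum(truth_m)))
  # area factor recomputed with an independent dilation
  A <- sum((dilate_oracle(seg_m, 2) & truth_m) |
             (seg_m & dilate_oracle(truth_m, 2))) / sum(seg_m | truth_m)
  expect_equal(out$area_overlap, A)
  # length factor recomputed from the same pinned skeletons
  sks <- skeletonize(seg_m); skg <- skeletonize(truth_m)
  L <- sum((sks & dilate_oracle(truth_m, 2)) |
             (dilate_oracle(seg_m, 2) & skg)) / sum(sks | skg)
  expect_equal(out$length_overlap, L)
  expect_equal(out$cal, out$connectivity * A * L)
})

test_that("the pinned skeletonization matches its golden fixture", {
  m <- bar_mask(9, 3, 5, 2, 8)       # 3 x 7 bar
  sk <- skeletonize(m)
  golden <- matrix(FALSE, 9, 9)
  golden[4, 3:6] <- TRUE             # mid-row line, ends retracted
  expect_identical(sk, golden)
  # a disc collapses to a small central cluster
  d <- disc_mask(15, 5)
  skd <- skeletonize(d)
  expect_lte(sum(skd), 5)
  expect_true(all(which(skd, arr.ind = TRUE) >= 7 &
                    which(skd, arr.ind = TRUE) <= 9))
})

test_that("evaluate_segmentation bundles all scores coherently", {
  set.seed(30)
  fov <- disc_mask(24, 10)
  g <- bar_mask(24, 11, 13, 4, 20) & fov
  truth <- seg_from(g, fov)
  noisy <- g; noisy[12, 5:8] <- FALSE
  seg <- seg_from(noisy, fov)
  resp <- normalize_response(g + matrix(rnorm(576, 0, 0.05), 24, 24),
                             fov, "fused-mr")
  rep <- evaluate_segmentation(seg, truth, resp)
  cc <- confusion_counts(seg, truth)
  expect_equal(rep$acc, accuracy(cc))
  expect_equal(rep$tpr, cc$tp / (cc$tp + cc$fn))
  expect_equal(rep$fpr, cc$fp / (cc$fp + cc$tn))
  expect_equal(rep$mcc, mcc(cc))
  expect_equal(rep$auc, roc_auc(resp, truth)$auc)
  expect_equal(rep$cal,
               rep$connectivity * rep$area_overlap * rep$length_overlap)
})
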