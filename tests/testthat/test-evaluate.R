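test_that("ROC/AUC handles separation, ties and the rank statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # 2 pos x 1 neg: one win (0.9 > 0.8), one loss (0.3 < 0.8) -> 0.5
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "negative")
  expect_error(roc_auc(c(1, 2), c(0, 0)), "positive")
  # ROC points span (0,0) to (1,1)
  ra <- roc_auc(runif(20), rbinom(20, 1, 0.5))
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(101)
  sc <- runif(50)
  y <- rbinom(50, 1, 0.4)
  if (sum(y) %in% c(0, 50)) y[1:2] <- c(0, 1)
  a0 <- roc_auc(sc, y)$auc
  expect_equal(roc_auc(2 * sc + 3, y)$auc, a0)
  expect_equal(roc_auc(log(sc + 0.01), y)$auc, a0)
  expect_equal(roc_auc(sc^3, y)$auc, a0)
})

test_that("distance-decay baseline learns alpha by Bernoulli MLE", {
  expect_lt(fit_distance_decay(c(1e4, 2e4, 3e4), c(0, 0, 0), beta = 1)$alpha,
            1e-6)
  # single distance, half the labels positive: alpha d^-beta = 0.5
  d <- rep(1e4, 40)
  y <- rep(c(1, 0), 20)
  for (beta in c(1, 1.5, 2)) {
    b <- fit_distance_decay(d, y, beta)
    expect_equal(predict(b, 1e4)[1], 0.5, tolerance = 1e-4)
  }
  # alpha rescales scores monotonically, so (below the probability clip)
  # the AUC depends on beta only
  set.seed(102)
  d2 <- sample(1e3:1e6, 100)
  y2 <- rbinom(100, 1, 0.3)
  if (sum(y2) %in% c(0, 100)) y2[1:2] <- c(0, 1)
  ref <- roc_auc(d2^-1.5, y2)$auc
  for (alpha in c(1e-3, 1, 100)) {
    b <- structure(list(alpha = alpha * min(d2)^1.5 / 200, beta = 1.5),
                   class = "decay_baseline")
    expect_equal(roc_auc(predict(b, d2), y2)$auc, ref)
  }
  expect_error(fit_distance_decay(c(-1, 2), c(0, 1), 1), "positive")
})

test_that("compartment calls split a two-block checkerboard by eigenvector sign", {
  blocks <- rep(c(1, 2), each = 3)
  mat <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0.1))
  set.seed(103)
  mat <- mat + matrix(rnorm(36, sd = 0.01), 6, 6)
  mat <- (mat + t(mat)) / 2
  labels <- compartment_calls(mat)
  expect_equal(length(unique(labels[1:3])), 1L)
  expect_equal(length(unique(labels[4:6])), 1L)
  expect_false(labels[1] == labels[4])
  # a global sign flip of the eigenvector is the same partition under NVI
  expect_equal(nvi(labels, 3L - labels), 0)
  expect_error(compartment_calls(matrix(1, 3, 3)), "degenerate")
  expect_lte(length(unique(compartment_calls(diag(2) + 0.01 * matrix(c(0,1,1,0),2)))), 2L)
})

test_that("normalized variation of information matches its closed forms", {
  expect_equal(nvi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(nvi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)  # label-invariant
  # singletons vs one block at n = 4: VI = log 4 -> NVI = 1
  expect_equal(nvi(1:4, rep(1, 4)), 1)
  set.seed(104)
  for (r in 1:10) {
    p <- sample(1:3, 12, replace = TRUE)
    q <- sample(1:4, 12, replace = TRUE)
    v <- nvi(p, q)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, nvi(q, p))
  }
})

test_that("boundary confusion counts greedy one-to-one matches", {
  r <- boundary_confusion(c(10, 20, 30), c(10, 20, 30))
  expect_equal(r$TP, 3L); expect_equal(r$FP, 0L); expect_equal(r$TPR, 1)
  r <- boundary_confusion(c(10, 20), c(100, 200))
  expect_equal(r$TP, 0L); expect_equal(r$FNR, 1)
  # true {10, 20}, pred {11, 40}, tol 1: 11 matches 10; 40 matches nothing
  r <- boundary_confusion(c(10, 20), c(11, 40), tol_bins = 1)
  expect_equal(r$TP, 1L); expect_equal(r$FP, 1L); expect_equal(r$FN, 1L)
  # TPR monotone in the tolerance
  set.seed(105)
  tb <- sort(sample(1:500, 20)); pb <- sort(sample(1:500, 25))
  tprs <- sapply(c(0, 1, 2, 5, 10, 50), function(tol)
    boundary_confusion(tb, pb, tol)$TPR)
  expect_true(all(diff(tprs) >= 0))
})

test_that("stability correlation is Spearman over the upper triangle", {
  cat3 <- mark_catalog(c("a", "b", "c"))
  mk <- function(v) {
    X <- matrix(0, 3, 3)
    X[upper.tri(X, diag = TRUE)] <- v
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
    mark_pair_matrix(X, cat3)
  }
  Xa <- mk(seq(0.05, 0.3, length.out = 6))
  expect_equal(stability_correlation(Xa, Xa), 1)
  Xr <- mk(rev(seq(0.05, 0.3, length.out = 6)))
  expect_equal(stability_correlation(Xa, Xr), -1)
  # ranks (1,2,3) vs (1,3,2): rho = 1 - 12 * 2 / (3 * 8) = 0.5
  ca <- mark_catalog(c("a", "b"))
  A <- mark_pair_matrix(matrix(c(0.1, 0.2, 0.2, 0.3), 2, 2), ca)
  B <- mark_pair_matrix(matrix(c(0.1, 0.3, 0.3, 0.2), 2, 2), ca)
  expect_equal(stability_correlation(A, B), 0.5)
})

test_that("the scored pair universe keeps all negatives when feasible, else samples", {
  truth <- make_truth(3, sparsity = 0.6, seed = 9, n_sites = 30)
  asg <- sample_assignment(truth)
  ctc <- sample_contacts(truth, asg)
  uni <- scored_pair_universe(ctc, asg$index, ratio = 1000, seed = 1)
  expect_equal(sum(uni$label == 1), nrow(ctc))
  expect_equal(nrow(uni), choose(30, 2))  # every within-chromosome pair
  uni2 <- scored_pair_universe(ctc, asg$index, ratio = 2, seed = 1)
  expect_equal(sum(uni2$label == 0), 2 * nrow(ctc))
  expect_identical(scored_pair_universe(ctc, asg$index, ratio = 2, seed = 4),
                   scored_pair_universe(ctc, asg$index, ratio = 2, seed = 4))
})

test_that("nested cross-validation partitions pairs and is seed-deterministic", {
  truth <- make_truth(3, sparsity = 0.6, seed = 10, n_sites = 60)
  asg <- sample_assignment(truth)
  ctc <- sample_contacts(truth, asg)
  grid1 <- list(c(0.1, 0.1))
  cv <- nested_cv(ctc, asg, grid1, outer_k = 3, inner_k = 2, seed = 2,
                  neg_ratio = 3, max_iter = 40, tol = 1e-3)
  expect_equal(unname(cv$lambda), c(0.1, 0.1))  # one-point grid is chosen
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  cv2 <- nested_cv(ctc, asg, grid1, outer_k = 3, inner_k = 2, seed = 2,
                   neg_ratio = 3, max_iter = 40, tol = 1e-3)
  expect_identical(cv$per_fold, cv2$per_fold)
  cv3 <- nested_cv(ctc, asg, grid1, outer_k = 3, inner_k = 2, seed = 3,
                   neg_ratio = 3, max_iter = 40, tol = 1e-3)
  expect_false(identical(cv$per_fold$auc, cv3$per_fold$auc))
})

test_that("masking marks zeroes the region and never raises a probability", {
  truth <- make_truth(4, sparsity = 0.5, seed = 11, n_sites = 50)
  asg <- sample_assignment(truth)
  span <- range(asg$index$pos)
  region <- list("chrS", span[1], span[1] + diff(span) / 3)
  masked <- mask_marks(asg, region, marks = "all")
  expect_true(all(masked$counts <= asg$counts))
  inside <- asg$index$pos >= region[[2]] & asg$index$pos < region[[3]]
  expect_true(all(masked$counts[inside, ] == 0))
  expect_identical(masked$counts[!inside, ], asg$counts[!inside, ])
  # single-mark masking leaves other columns alone
  m1 <- mask_marks(asg, region, marks = "mark01")
  expect_identical(m1$counts[, -1], asg$counts[, -1])
  expect_error(mask_marks(asg, region, marks = "nope"), "unknown mark")
  # pair probabilities through a fully masked endpoint drop to zero
  pairs <- data.frame(chrom1 = "chrS", pos1 = asg$index$pos[which(inside)[1]],
                      chrom2 = "chrS", pos2 = max(asg$index$pos))
  expect_equal(predict_probabilities(truth$X, masked, pairs), 0)
  p_all <- predict_probabilities(truth$X, asg,
                                 scored_pair_universe(sample_contacts(truth, asg),
                                                      asg$index, 2, 1))
  p_msk <- predict_probabilities(truth$X, masked,
                                 scored_pair_universe(sample_contacts(truth, asg),
                                                      asg$index, 2, 1))
  expect_true(all(p_msk <= p_all + 1e-12))
})

test_that("region deletion excises sites, shifts coordinates and drops contacts", {
  truth <- make_truth(3, sparsity = 0.6, seed = 12, n_sites = 40)
  asg <- sample_assignment(truth)
  ctc <- sample_contacts(truth, asg)

  # zero-length region: identity
  d0 <- delete_region(asg, ctc, list("chrS", 16000, 16000))
  expect_equal(d0$assignment$counts, asg$counts)
  expect_equal(as.data.frame(d0$contacts), as.data.frame(ctc))

  # a region holding no site: identity up to the coordinate shift
  gap <- list("chrS", 16100, 16900)   # sites are multiples of 4000
  dg <- delete_region(asg, ctc, gap)
  expect_equal(nrow(dg$assignment$counts), nrow(asg$counts))

  # deleting sites: exact conservation of the remainder
  region <- list("chrS", 16000, 32000)
  inside <- asg$index$pos >= 16000 & asg$index$pos < 32000
  dd <- delete_region(asg, ctc, region)
  expect_equal(nrow(dd$assignment$counts), nrow(asg$counts) - sum(inside))
  touched <- (ctc$pos1 >= 16000 & ctc$pos1 < 32000) |
    (ctc$pos2 >= 16000 & ctc$pos2 < 32000)
  expect_equal(nrow(dd$contacts), sum(!touched))
  # downstream positions shifted left by the region length
  expect_true(all(dd$assignment$index$pos %% 4000 == 0))
  expect_equal(max(dd$assignment$index$pos), max(asg$index$pos) - 16000)
})
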