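# learners, AUC, cross-validation, weighting, max-TSS threshold

test_that("learners hit their closed-form anchor points", {
  ds <- make_separable_dataset(seed = 1)

  env <- fit_learner("envelope", ds)
  inside <- matrix(mean(ds$X_presence), 1, 1,
                   dimnames = list(NULL, "temperature"))
  expect_equal(predict_suitability(env, inside), 1.0)

  mah <- fit_learner("mahalanobis", ds)
  at_mean <- matrix(colMeans(ds$X_presence), 1, 1,
                    dimnames = list(NULL, "temperature"))
  expect_equal(predict_suitability(mah, at_mean), 1.0, tolerance = 1e-9)
})

test_that("every learner outputs suitabilities in [0, 1]", {
  withr::with_seed(8, {
    Xp <- cbind(a = rnorm(30, 1), b = runif(30))
    Xb <- cbind(a = rnorm(50), b = runif(50, 0.5, 2))
    Q <- cbind(a = rnorm(200, 0, 3), b = runif(200, -1, 3))
  })
  ds <- structure(list(species_id = "s", X_presence = Xp, X_background = Xb,
                       covariate_names = c("a", "b")),
                  class = "modeling_dataset")
  for (kind in c("envelope", "mahalanobis", "logistic2", "knn",
                 "boost_stumps")) {
    s <- predict_suitability(fit_learner(kind, ds), Q)
    expect_true(all(s >= 0 & s <= 1), info = kind)
    expect_length(s, 200L)
  }
})

test_that("AUC matches the brute-force pair-count oracle", {
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)          # 3 of 4 pairs
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1.0)           # perfect ranking
  expect_equal(auc(rep(0.5, 4), rep(0.5, 6)), 0.5)           # all ties
  expect_error(auc(numeric(0), 1), class = "fc_undefined_auc")

  withr::with_seed(123, {
    for (i in 1:200) {
      np <- sample(1:12, 1); nb <- sample(1:12, 1)
      sp <- round(runif(np), 2)  # rounding forces frequent ties
      sb <- round(runif(nb), 2)
      expect_equal(auc(sp, sb), auc_pairs_oracle(sp, sb), tolerance = 1e-12)
    }
  })
})

test_that("cross-validated AUC behaves on separable and null data", {
  ds <- make_separable_dataset(n_presence = 40, n_background = 60, seed = 2)
  for (kind in c("logistic2", "knn", "boost_stumps")) {
    expect_gte(cross_validated_auc(kind, ds, n_folds = 5, seed = 1), 0.99)
  }
  # robustness to the fold count
  expect_gte(cross_validated_auc("logistic2", ds, n_folds = 2, seed = 1), 0.99)

  # permutation null: labels carry no signal -> AUC ~ 0.5
  withr::with_seed(77, {
    X <- cbind(temperature = rnorm(1000))
  })
  null_ds <- structure(list(species_id = "null",
                            X_presence = X[1:500, , drop = FALSE],
                            X_background = X[501:1000, , drop = FALSE],
                            covariate_names = "temperature"),
                       class = "modeling_dataset")
  a <- cross_validated_auc("logistic2", null_ds, n_folds = 5, seed = 3)
  expect_lt(abs(a - 0.5), 0.1)

  # fewer presences than folds: folds reduced with a warning
  tiny <- make_separable_dataset(n_presence = 3, n_background = 30, seed = 4)
  expect_warning(cross_validated_auc("envelope", tiny, n_folds = 5, seed = 1),
                 class = "fc_folds_reduced")
})

test_that("ensemble weights follow (AUC - 0.5) with the cutoff", {
  ds <- make_separable_dataset(seed = 3)
  fits <- list(envelope = fit_learner("envelope", ds),
               knn = fit_learner("knn", ds))

  one <- build_ensemble(fits["envelope"], c(envelope = 0.9), 0.7)
  expect_equal(unname(one$weights["envelope"]), 1.0)

  two <- build_ensemble(fits, c(envelope = 0.9, knn = 0.7), 0.7)
  expect_equal(unname(two$weights[c("envelope", "knn")]), c(2, 1) / 3,
               tolerance = 1e-12)

  five_auc <- setNames(rep(0.8, 5), c("a", "b", "c", "d", "e"))
  five <- build_ensemble(setNames(rep(fits["knn"], 5), names(five_auc)),
                         five_auc, 0.7)
  expect_equal(unname(five$weights), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(sum(five$weights), 1, tolerance = 1e-9)

  # excluded learners keep weight zero; weights still sum to 1
  mix <- build_ensemble(fits, c(envelope = 0.95, knn = 0.55), 0.7)
  expect_equal(unname(mix$weights["knn"]), 0)
  expect_equal(sum(mix$weights), 1, tolerance = 1e-9)

  expect_error(build_ensemble(fits, c(envelope = 0.6, knn = 0.5), 0.7),
               class = "fc_unmodelable")
})

test_that("max-TSS threshold equals the exhaustive-scan oracle", {
  # separable: any threshold in (0.3, 0.8] has TSS 1; lowest candidate wins
  sp <- c(0.8, 0.85, 0.9); sb <- c(0.1, 0.2, 0.3)
  t1 <- max_tss_threshold(sp, sb)
  expect_equal(t1, tss_oracle(sp, sb)$threshold)
  expect_gt(t1, 0.3); expect_lte(t1, 0.8)

  sp2 <- c(0.9, 0.6, 0.4); sb2 <- c(0.5, 0.2)
  expect_equal(max_tss_threshold(sp2, sb2), tss_oracle(sp2, sb2)$threshold)

  expect_equal(max_tss_threshold(1, 0), tss_oracle(1, 0)$threshold)
  t3 <- max_tss_threshold(1, 0)
  expect_gt(t3, 0); expect_lte(t3, 1)

  # property: TSS at the returned threshold >= TSS at every candidate
  withr::with_seed(5, {
    for (i in 1:50) {
      sp <- round(runif(sample(2:20, 1)), 2)
      sb <- round(runif(sample(2:20, 1)), 2)
      orc <- tss_oracle(sp, sb)
      t <- max_tss_threshold(sp, sb)
      tss_at <- mean(sp >= t) + mean(sb < t) - 1
      expect_gte(tss_at, max(orc$tss) - 1e-12)
      expect_equal(t, orc$threshold)
    }
  })
})

test_that("full species ensemble is normalized, bounded, and monotone", {
  cur <- generate_climate(extent = c(-20, 20, 50, 62), seed = 6)[[1]]
  vsp <- generate_virtual_species(cur, 1, seed = 7)[[1]]
  occ <- sample_occurrences(vsp, cur, 80, seed = 8)
  ds <- build_modeling_dataset(occ, cur, seed = 9)
  em <- fit_species_ensemble(ds, seed = 10)

  expect_equal(sum(em$weights), 1, tolerance = 1e-9)
  expect_true(all(em$weights >= 0))
  expect_true(em$threshold_tss >= 0 && em$threshold_tss <= 1)

  X <- covariate_matrix(cur)
  s <- predict_ensemble(em, X, clamp = FALSE)
  expect_true(all(s >= 0 & s <= 1))

  # monotone combination: ensemble score is a weighted mean, so it lies
  # inside the hull of the member scores at every cell
  members <- sapply(em$included, function(k)
    predict_suitability(em$learners[[k]], X[, em$covariate_names,
                                            drop = FALSE]))
  expect_true(all(s <= apply(members, 1, max) + 1e-9))
  expect_true(all(s >= apply(members, 1, min) - 1e-9))
})
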