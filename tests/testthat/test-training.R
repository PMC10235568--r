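t0 <- as.POSIXct("2024-03-01", tz = "UTC")

# labelled toy feature matrix with seizures every `gap_min` minutes
toy_patient <- function(n_seizures, gap_min = 60, feat_sd = 1,
                        shift = 0, seed = 1) {
  gap_w <- gap_min * 12
  nw <- gap_w * n_seizures + 60
  onsets <- t0 + (seq_len(n_seizures) * gap_min * 60)
  set.seed(seed)
  vals <- matrix(rnorm(nw * 3, sd = feat_sd), nw, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  fm <- make_fm(vals)
  ann <- seizure_annotation(onsets, onsets + 60)
  fm <- label_windows(fm, ann, preictal_min = 30)
  if (shift != 0) {
    fm$values[fm$labels %in% "preictal", 1] <-
      fm$values[fm$labels %in% "preictal", 1] + shift
  }
  list(fm = fm, ann = ann)
}

test_that("chronological split keeps training strictly before testing", {
  tp <- toy_patient(5)
  sp <- chronological_split(tp$fm, tp$ann)
  expect_length(sp$train_ann, 3)
  expect_length(sp$test_ann, 2)
  expect_true(max(sp$train$window_start_s) < sp$split_s)
  expect_true(min(sp$test$window_start_s) >= sp$split_s)
  expect_equal(nrow(sp$train$values) + nrow(sp$test$values),
               nrow(tp$fm$values))

  tp4 <- toy_patient(4)
  expect_length(chronological_split(tp4$fm, tp4$ann)$test_ann, 1)
  tp3 <- toy_patient(3)
  expect_error(chronological_split(tp3$fm, tp3$ann), ">= 4")
})

test_that("standardizer: train-only statistics, zero-sd drop, idempotence", {
  set.seed(2)
  X <- cbind(a = rnorm(200, 5, 2), b = runif(200), const = rep(3, 200))
  std <- fit_standardizer(X)
  expect_equal(std$dropped, "const")
  Z <- apply_standardizer(std, X)
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # new data transformed with train parameters, not its own
  Xnew <- X; Xnew[, "a"] <- Xnew[, "a"] + 10
  Znew <- apply_standardizer(std, Xnew)
  expect_equal(mean(Znew[, "a"]), mean(Z[, "a"]) + 10 / std$scale[["a"]])
  expect_error(apply_standardizer(std, Z[, 1, drop = FALSE]), "mismatch")
})

test_that("class weights are inverse-frequency balanced", {
  lab <- rep(c("preictal", "interictal"), c(360, 3600))
  w <- lr_class_weights(lab)
  expect_equal(w[1] / w[361], 10)
  expect_equal(sum(w[lab == "preictal"]), sum(w[lab == "interictal"]))
  expect_equal(unique(lr_class_weights(c("a", "b"))), 1)
  expect_error(lr_class_weights(rep("interictal", 5)), "both classes")
})

test_that("segment subsampling spreads draws over the timeline and is seeded", {
  idx <- seq_len(3600)
  s <- segment_subsample(idx, n_segments = 10, per_segment = 36, seed = 5)
  expect_length(s, 360)
  # at least one draw from every decile of time
  expect_true(all(table(cut(s, seq(0, 3600, by = 360))) >= 1))
  expect_identical(s, segment_subsample(idx, 10, 36, seed = 5))
  expect_false(identical(s, segment_subsample(idx, 10, 36, seed = 6)))
  expect_error(segment_subsample(1:5, 10, 1, 1), "shorter")
  expect_warning(segment_subsample(1:25, 2, 13, 1), "taking all")
})

test_that("forest selection finds a planted feature and respects bounds", {
  set.seed(30)
  hits <- 0L
  for (r in 1:20) {
    X <- matrix(rnorm(200 * 50), 200, 50,
                dimnames = list(NULL, paste0("f", 1:50)))
    y <- rep(0:1, each = 100)
    X[y == 1, 17] <- X[y == 1, 17] + 2  # planted 2-sigma shift
    sel <- forest_feature_selection(X, y, n_keep = 5, seed = r)
    hits <- hits + (17L %in% sel)
  }
  expect_gte(hits, 18)

  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  y <- rep(0:1, 5)
  expect_setequal(forest_feature_selection(X, y, 4, seed = 1), 1:4)
  expect_error(forest_feature_selection(X, y, 5, seed = 1), "exceeds")
})

test_that("forest selection is near-uniform on pure noise", {
  set.seed(31)
  counts <- integer(10)
  for (r in 1:150) {
    X <- matrix(rnorm(60 * 10), 60, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(0:1, 30)
    j <- forest_feature_selection(X, y, n_keep = 1, n_trees = 50,
                                  seed = 1000 + r)
    counts[j] <- counts[j] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("logistic training is deterministic, symmetric and matches IRLS", {
  set.seed(4)
  X <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(50, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  w <- runif(50, 0.5, 2)
  fit <- train_logistic(X, y, w)
  beta <- oracle_irls(X, y, w)
  expect_equal(unname(c(fit$intercept, fit$coef)), beta, tolerance = 1e-6)

  # label flip negates coefficients (and the intercept)
  flip <- train_logistic(X, 1 - y, w)
  expect_equal(unname(flip$coef), unname(-fit$coef), tolerance = 1e-6)
  expect_equal(flip$intercept, -fit$intercept, tolerance = 1e-6)

  # linearly separable toy: decision boundary separates training data
  Xs <- cbind(a = c(rnorm(25, -3), rnorm(25, 3)),
              b = rnorm(50))
  ys <- rep(0:1, each = 25)
  sep <- train_logistic(Xs, ys)
  pred <- as.integer(Xs %*% sep$coef + sep$intercept >= 0)
  expect_equal(pred, ys)
})

test_that("window prediction applies decision rules and majority voting", {
  mdl <- linear_window_model(c(a = 1, b = 2), intercept = 0)
  X <- rbind(c(1, 1), c(-1, -1), c(2, -1))
  colnames(X) <- c("a", "b")
  out <- predict_windows(mdl, X)
  expect_equal(as.integer(out), c(1L, 0L, 1L))  # zero margin -> class 1
  expect_equal(attr(out, "prob")[1], plogis(3))
  expect_error(predict_windows(mdl, X[, 1, drop = FALSE]), "mismatch")
})

test_that("SVM ensemble is reproducible, member-wise stochastic, and accurate when separable", {
  tp <- toy_patient(4, gap_min = 90, shift = 4, seed = 8)
  sp <- chronological_split(tp$fm, tp$ann)
  tr <- label_windows(sp$train, sp$train_ann, 30)
  ens <- train_patient_model(tr, "svm_ensemble", seed = 7, n_models = 5,
                             n_keep = 2)
  ens2 <- train_patient_model(tr, "svm_ensemble", seed = 7, n_models = 5,
                              n_keep = 2)
  te <- label_windows(sp$test, sp$test_ann, 30)
  p1 <- predict_windows(ens, te)
  expect_identical(as.integer(p1), as.integer(predict_windows(ens2, te)))
  # majority of member votes defines the ensemble output
  votes <- attr(p1, "votes")
  expect_equal(as.integer(rowSums(votes) * 2 > ncol(votes)),
               as.integer(p1))
  # members agree almost everywhere on strongly separable data
  agree <- rowMeans(votes == as.integer(p1))
  expect_gte(mean(agree >= 1), 0.95)
  # ensemble separates the planted signal
  y <- as.integer(te$labels == "preictal")
  keep <- !is.na(te$labels)
  expect_gte(mean(p1[keep] == y[keep]), 0.9)

  one <- train_patient_model(tr, "svm_ensemble", seed = 7, n_models = 1,
                             n_keep = 2)
  expect_length(one$members, 1)
})

test_that("logistic patient model recovers a planted discriminative feature", {
  tp <- toy_patient(4, gap_min = 90, shift = 3, seed = 9)
  sp <- chronological_split(tp$fm, tp$ann)
  tr <- label_windows(sp$train, sp$train_ann, 30)
  mdl <- train_patient_model(tr, "lr", seed = 2, select_features = FALSE)
  expect_gt(mdl$coef[["a"]], abs(mdl$coef[["b"]]))
  te <- label_windows(sp$test, sp$test_ann, 30)
  keep <- !is.na(te$labels)
  acc <- mean(predict_windows(mdl, te)[keep] ==
                as.integer(te$labels[keep] == "preictal"))
  expect_gt(acc, 0.85)
})

test_that("grid search degenerates gracefully", {
  tp <- toy_patient(3, seed = 10)
  gs <- grid_search_preictal(tp$fm, tp$ann, grid = 40)
  expect_equal(gs$best_minutes, 40)
  # pure-noise features: no alarm-level evidence -> seeded uniform draw
  gs2 <- grid_search_preictal(tp$fm, tp$ann, seed = 3)
  if (gs2$no_evidence) {
    expect_identical(gs2$best_minutes,
                     grid_search_preictal(tp$fm, tp$ann,
                                          seed = 3)$best_minutes)
  }
  expect_error(grid_search_preictal(tp$fm, tp$ann, grid = numeric(0)),
               "empty")
})
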