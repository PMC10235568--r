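#!/usr/bin/env Rscript
# Patient-specific chronological training on the demonstration patient:
# the first three seizures drive the preictal grid search (30-60 min in
# steps of 10, leave-one-seizure-out alarm score), standardization,
# class balancing and model fitting; the remaining seizures are held
# out for testing. Trains both the weighted logistic regression and the
# 15-member linear-SVM voting ensemble and records the selected
# preictal duration and the logistic coefficients.

library(seizecast)

record <- read_record("results/patient_demo")
ann <- read_annotations("results/patient_demo_seizures.csv")
fm <- extract_features(record, features = c("relpower", "sef", "moments",
                                            "hjorth", "decorr"))

sp <- chronological_split(fm, ann, n_train = 3)
gs <- grid_search_preictal(sp$train, sp$train_ann)
cat("preictal grid search (LOSO alarm score / window AUC):\n")
print(gs$scores)
cat("selected preictal duration:", gs$best_minutes, "min\n")

train <- label_windows(sp$train, sp$train_ann, gs$best_minutes)
lr <- train_patient_model(train, "lr", seed = 42, n_keep = 20)
svm <- train_patient_model(train, "svm_ensemble", seed = 42,
                           n_models = 15, n_keep = 20)
print(lr); print(svm)

coefs <- sort(lr$coef, decreasing = TRUE)
cat("\ntop logistic-regression coefficients (standardized units):\n")
print(round(head(coefs, 8), 3))

saveRDS(list(lr = lr, svm = svm, grid = gs, split_s = sp$split_s),
        "results/patient_demo_models.rds")
write.csv(data.frame(feature = names(lr$coef), coefficient = lr$coef),
          "results/patient_demo_lr_coefficients.csv", row.names = FALSE)
write.csv(gs$scores, "results/patient_demo_grid_search.csv",
          row.names = FALSE)
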