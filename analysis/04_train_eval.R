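#!/usr/bin/env Rscript
# Classification experiment on the study-shaped synthetic crop set: 84
# training crops (16 nodular / 68 non-nodular) are augmented with the
# class-specific plans (flip + 3 stretches; flip + 1 stretch) to 256 + 272 =
# 528 training images; the 25 held-out crops are scored by the baseline
# classifier and evaluated.

suppressMessages(library(thyrotherm))
dir.create("results", showWarnings = FALSE)

ds <- study_shaped_crops(seed = 7)
cat(sprintf("train: %d nodular / %d non-nodular; test: %d (%d nodular)\n",
            sum(ds$train$labels), sum(!ds$train$labels),
            length(ds$test$labels), sum(ds$test$labels)))

aug_n <- augment(ds$train$crops[ds$train$labels],
                 augmentation_plan("nodular"))
aug_b <- augment(ds$train$crops[!ds$train$labels],
                 augmentation_plan("non_nodular"))
cat(sprintf("augmented: %d nodular + %d non-nodular = %d training images\n",
            length(aug_n), length(aug_b), length(aug_n) + length(aug_b)))

model <- train_baseline(c(aug_n, aug_b),
                        rep(c(TRUE, FALSE),
                            c(length(aug_n), length(aug_b))),
                        experiment_config(seed = 7))
m <- evaluate(predict_baseline(model, ds$test$crops), ds$test$labels)
print(m)
write_metrics(m, "results/metrics.json")
data.table::fwrite(augmentation_manifest(c(aug_n, aug_b)),
                   "results/augmentation_manifest.csv")
cat("wrote results/metrics.json and results/augmentation_manifest.csv\n")
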