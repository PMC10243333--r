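#!/usr/bin/env Rscript
# Stage 4 — train the three denoising architectures.
#
# DnCNN, Win5RB and ResUnet are trained with MSE loss and Adam on the
# standardized pairs; widths are 1/16 of the clinical-scale defaults so the
# study runs on one CPU. The checkpoint with minimum validation loss is kept.

library(fastdmsa)
out <- "results/analysis"
ds <- readRDS(file.path(out, "dataset.rds"))

cfg <- train_config(learning_rate = 2e-3, max_epochs = 6L, batch_size = 2L,
                    seed = 1L)
builders <- list(
  dncnn = function() build_dncnn(n_filters = 4L, units = 15L, seed = 1L),
  win5rb = function() build_win5rb(n_filters = 4L, seed = 1L),
  resunet = function() build_resunet(level_filters = c(4L, 8L, 16L),
                                     bridge_filters = 32L, seed = 1L))

for (arch in names(builders)) {
  t0 <- Sys.time()
  res <- train(builders[[arch]](), ds$train, ds$validation, cfg)
  save_model(res$model, file.path(out, sprintf("model_%s.rds", arch)))
  write.csv(res$history, file.path(out, sprintf("history_%s.csv", arch)),
            row.names = FALSE)
  message(sprintf("%s: best val loss %.4f at epoch %d (%.1f s)", arch,
                  attr(res$history, "best_val_loss"),
                  attr(res$history, "best_epoch"),
                  as.numeric(Sys.time() - t0, units = "secs")))
}
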