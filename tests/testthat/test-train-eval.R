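# Loss and metric closed forms, optimizer degenerate cases, training
# determinism, and the fitted-object methods.

test_that("smooth-L1 loss matches its closed form", {
  expect_equal(smooth_l1(0, 0), 0)
  expect_equal(smooth_l1(0.5, 0), 0.125)       # 0.5 * 0.25 / 1
  expect_equal(smooth_l1(2, 0), 1.5)           # 2 - 0.5
  expect_equal(smooth_l1(-2, 0), 1.5)
  expect_equal(smooth_l1(0.3, 0.1, beta = 0.1), abs(0.2) - 0.05)
  expect_error(smooth_l1(1, 0, beta = 0), "beta")
})

test_that("smooth-L1 is continuous and once-differentiable at the transition", {
  beta <- 1
  eps <- 1e-7
  below <- smooth_l1(beta - eps, 0, beta)
  above <- smooth_l1(beta + eps, 0, beta)
  expect_equal(below, above, tolerance = 1e-6)
  # numerical derivative approaches 1 from both sides
  d_below <- (smooth_l1(beta - eps, 0, beta) - smooth_l1(beta - 2 * eps, 0, beta)) / eps
  d_above <- (smooth_l1(beta + 2 * eps, 0, beta) - smooth_l1(beta + eps, 0, beta)) / eps
  expect_equal(d_below, d_above, tolerance = 1e-5)
  expect_equal(d_below, 1, tolerance = 1e-5)
})

test_that("metrics satisfy their closed-form identities", {
  truths <- c(1, 2, 3)
  perfect <- evaluate_predictions(truths, truths)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)

  mean_pred <- evaluate_predictions(rep(mean(truths), 3), truths)
  expect_equal(mean_pred$r2, 0)

  worked <- evaluate_predictions(c(1, 2, 4), truths)
  expect_equal(worked$mae, 1 / 3)
  expect_equal(worked$rmse, sqrt(1 / 3))
  expect_equal(worked$r2, 0.5)  # SS_res 1, SS_tot 2
})

test_that("rmse >= mae and r2 <= 1 on random evaluations", {
  set.seed(4)
  for (i in 1:20) {
    truth <- rnorm(50)
    pred <- truth + rnorm(50, 0, runif(1, 0.01, 2))
    m <- evaluate_predictions(pred, truth)
    expect_gte(m$rmse, m$mae)
    expect_lte(m$r2, 1)
  }
})

test_that("per-group metrics partition the overall evaluation", {
  set.seed(9)
  truth <- rnorm(40, 3)
  pred <- truth + rnorm(40, 0, 0.5)
  groups <- rep(c("A", "B", "C"), length.out = 40)
  m <- evaluate_predictions(pred, truth, groups)
  expect_setequal(m$group, c("overall", "A", "B", "C"))
  expect_equal(sum(m$n[m$group != "overall"]), m$n[m$group == "overall"])
  # overall equals direct evaluation of the concatenation
  expect_equal(m[m$group == "overall", c("r2", "rmse", "mae")],
               evaluate_predictions(pred, truth)[, c("r2", "rmse", "mae")])
  # singleton groups are skipped
  g2 <- c(rep("A", 39), "B")
  expect_setequal(evaluate_predictions(pred, truth, g2)$group, c("overall", "A"))
})

test_that("zero truth variance flags R2 as undefined instead of a number", {
  m <- evaluate_predictions(c(1, 2), c(5, 5))
  expect_false(m$r2_defined)
  expect_true(is.na(m$r2))
  expect_gt(m$rmse, 0)
})

test_that("zero learning rate leaves parameters unchanged and history flat", {
  feats <- tiny_features()
  cfg <- model_config(gat_hidden = 8L, gat_heads = 2L, atom_embed_dim = 4L,
                      desc_dims = c(544L, 8L, 6L), head_hidden = 4L,
                      gat_dropout = 0, desc_dropout = 0, head_dropout = 0)
  model <- init_ic50net(cfg, seed = 2)
  tr <- train_ic50net(model, feats,
                      control = train_control(learning_rate = 0, epochs = 5,
                                              batch_size = 16,
                                              init_output_bias = FALSE,
                                              bn_refresh = FALSE,
                                              eval_every = 5, seed = 1))
  expect_equal(tr$model$params, model$params, tolerance = 1e-14)
  expect_equal(var(tr$history$train_loss), 0, tolerance = 1e-20)
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  feats <- tiny_features()
  cfg <- model_config(gat_hidden = 16L, gat_heads = 2L, atom_embed_dim = 8L,
                      desc_dims = c(544L, 16L, 8L), head_hidden = 8L)
  run <- function() {
    train_ic50net(init_ic50net(cfg, seed = 2), feats,
                  control = train_control(epochs = 20, batch_size = 6,
                                          eval_every = 20, seed = 11))
  }
  a <- run()
  b <- run()
  expect_equal(a$history, b$history, tolerance = 1e-12)
  expect_equal(a$model$params, b$model$params, tolerance = 1e-12)
  expect_lt(a$history$train_loss[20], a$history$train_loss[1])
})

test_that("training rejects degenerate inputs", {
  feats <- tiny_features()
  bad <- feats
  bad$y <- rep(NA_real_, 6)
  model <- init_ic50net(seed = 1)
  expect_error(train_ic50net(model, bad, control = train_control(epochs = 1)),
               "finite")
})

test_that("the fitted object exposes the standard modelling methods", {
  fit <- tiny_fit()
  expect_s3_class(fit, "ic50net")
  expect_output(print(fit), "Hybrid graph-attention")
  s <- summary(fit)
  expect_s3_class(s, "summary.ic50net")
  expect_true("overall" %in% s$train$group)
  expect_length(fitted(fit), nrow(fit$train_data))
  expect_equal(residuals(fit), fit$train_data$log_ic50 - fitted(fit))
  cf <- coef(fit)
  expect_true(all(c("embed", "head.W1", "desc.W1") %in% names(cf)))
  # history carries loss curves for both sets
  expect_true(all(c("train_loss", "test_loss", "test_r2") %in% names(fit$history)))
  # predict: canonicalization happens internally, so any valid writing works
  p <- predict(fit, c("OCC", "CCO"))
  expect_equal(p[1], p[2], tolerance = 1e-10)
  # raw attention weights are exposed on request
  att <- predict(fit, "CCO", attention = TRUE)
  expect_named(att, c("pred", "attention"))
  expect_length(att$attention[[1]], fit$config$gat_layers)
  # checkpoint round trip predicts identically from bare SMILES
  f <- tempfile(fileext = ".rds")
  save_ic50net(fit, f)
  fit2 <- load_ic50net(f)
  expect_equal(predict(fit2, "c1ccccc1"), predict(fit, "c1ccccc1"))
  # plots render without error
  png_file <- tempfile(fileext = ".png")
  grDevices::png(png_file)
  expect_no_error(plot(fit))
  expect_no_error(plot(fit, which = "fit"))
  grDevices::dev.off()
})
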