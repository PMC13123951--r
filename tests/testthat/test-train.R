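test_that("loss primitives match hand arithmetic", {
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_identical(cycle_loss(a, a), 0)
  expect_equal(cycle_loss(a, b), 0.5)
  expect_equal(cycle_loss(a, b), cycle_loss(b, a))
  expect_error(cycle_loss(a, matrix(0, 3, 3)), "shape")

  expect_identical(identity_loss(a, a), 0)
  expect_equal(identity_loss(matrix(0, 2, 2), matrix(1, 2, 2)), 1)
  expect_gte(identity_loss(a, b), 0)

  expect_equal(adversarial_losses(real_scores = matrix(1, 2, 2),
                                  fake_scores = matrix(0, 2, 2),
                                  role = "discriminator"), 0)
  expect_equal(adversarial_losses(fake_scores = matrix(1, 2, 2),
                                  role = "generator"), 0)
  expect_equal(adversarial_losses(real_scores = matrix(0.5, 2, 2),
                                  fake_scores = matrix(0.5, 2, 2),
                                  role = "discriminator"), 0.5)
  # cross-entropy form: positive and finite for mixed scores
  ce <- adversarial_losses(matrix(2, 2, 2), matrix(-1, 2, 2),
                           role = "discriminator", form = "cross-entropy")
  expect_true(is.finite(ce) && ce > 0)
})

test_that("a training step returns finite losses and the stated total", {
  b <- tiny_bundle(seed = 2)
  bx <- list(rand_img(32, 32, 1), rand_img(32, 32, 2))
  by <- list(rand_img(32, 32, 3), rand_img(32, 32, 4))
  cfg <- train_config(epochs = 1, crop_size = 32, resize_to = 32)
  res <- train_step(bx, by, b, cfg)
  r <- res$losses
  expect_true(all(vapply(r, function(v) all(is.finite(v)), logical(1))))
  expect_equal(r$total_G,
               r$loss_adv_G + cfg$lambda_cycle * r$loss_cycle +
                 cfg$lambda_identity * r$loss_identity)
  # parameters actually moved
  expect_false(identical(res$bundle$gen$enc0.W, b$gen$enc0.W))

  # weight-zero ablation: total_G collapses to the adversarial term
  cfg0 <- train_config(lambda_cycle = 0, lambda_identity = 0, epochs = 1,
                       crop_size = 32, resize_to = 32)
  r0 <- train_step(bx, by, b, cfg0)$losses
  expect_identical(r0$total_G, r0$loss_adv_G)
})

test_that("training steps are pure functions of their inputs", {
  b <- tiny_bundle(seed = 4)
  bx <- list(rand_img(32, 32, 5))
  by <- list(rand_img(32, 32, 6))
  cfg <- train_config(epochs = 1, crop_size = 32, resize_to = 32)
  r1 <- train_step(bx, by, b, cfg)
  r2 <- train_step(bx, by, b, cfg)
  expect_identical(r1$losses, r2$losses)
  expect_identical(r1$bundle$gen, r2$bundle$gen)
})

test_that("fit runs epochs over folders, checkpoints, and is resumable", {
  d <- withr::local_tempdir()
  generate_dataset(3, d, seed = 9, size = c(64, 64))
  out <- withr::local_tempdir()
  cfg <- train_config(epochs = 2, crop_size = 32, resize_to = 48, seed = 12)
  f <- fit_usgan(file.path(d, "X"), file.path(d, "Y"), cfg, out_dir = out,
                 base_channels = 4, n_res_blocks = 1)
  expect_s3_class(f, "usgan_fit")
  expect_identical(nrow(f$history), 6L)  # 3 steps/epoch x 2 epochs
  expect_true(all(is.finite(as.matrix(f$history[-1]))))
  expect_true(file.exists(file.path(out, "epoch_002.rds")))
  expect_true(file.exists(file.path(out, "loss_history.csv")))
  # loss history is append-only across a resumed run
  cfg1 <- train_config(epochs = 1, crop_size = 32, resize_to = 48, seed = 12)
  f2 <- fit_usgan(file.path(d, "X"), file.path(d, "Y"), cfg1,
                  bundle = f$model, history = f$history)
  expect_identical(f2$history$step, 1:9)
  expect_equal(f2$history[1:6, ], f$history[1:6, ],
               ignore_attr = "epochs_done")
  expect_error(fit_usgan(list(), file.path(d, "Y"), cfg), "domain")

  # S3 surface
  expect_output(print(f), "Switchable CycleGAN fit")
  s <- summary(f)
  expect_s3_class(s, "summary.usgan_fit")
  expect_output(print(s), "median cycle loss")
  pr <- predict(f, rand_img(32, 32, 1))
  expect_identical(dim(pr), c(32L, 32L))
  pdf(NULL); on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(f))
})

test_that("enhance_images preserves names and sizes", {
  d <- withr::local_tempdir()
  generate_dataset(2, d, seed = 3, size = c(64, 64))
  out <- withr::local_tempdir()
  b <- tiny_bundle()
  written <- enhance_images(b, file.path(d, "X"), out)
  expect_identical(basename(written), c("x_001.png", "x_002.png"))
  img <- load_image(written[1])
  expect_identical(dim(img), c(64L, 64L))
})
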