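# Two-cycle adversarial training: forward cycle X -> Y -> X and backward
# cycle Y -> X -> Y through the single shared generator (direction selected
# by the ACG code), identity passes for stability, least-squares (or
# cross-entropy) adversarial terms against the two discriminators, and
# simultaneous Adam updates of generator + ACG and of each discriminator.

#' Training configuration
#'
#' @param lambda_cycle Weight of the cycle-consistency loss (>= 0).
#' @param lambda_identity Weight of the identity loss (>= 0).
#' @param learning_rate Adam learning rate for all four networks.
#' @param betas Adam momentum pair.
#' @param epochs Number of passes over the smaller domain folder.
#' @param batch_size Images per domain per step.
#' @param crop_size Square crop fed to the networks (must divide by 4).
#' @param resize_to Short-side length before cropping; >= `crop_size`.
#' @param seed Master seed for shuffling, cropping and initialization.
#' @param adversarial_form `"least-squares"` (default) or `"cross-entropy"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lambda_cycle = 10, lambda_identity = 5,
                         learning_rate = 2e-4, betas = c(0.5, 0.999),
                         epochs = 25, batch_size = 1, crop_size = 64,
                         resize_to = 64, seed = 1,
                         adversarial_form = c("least-squares",
                                              "cross-entropy")) {
  adversarial_form <- match.arg(adversarial_form)
  stopifnot(lambda_cycle >= 0, lambda_identity >= 0, learning_rate > 0,
            length(betas) == 2, epochs >= 1, batch_size >= 1,
            crop_size <= resize_to, crop_size %% GEN_DOWN_FACTOR == 0)
  structure(list(lambda_cycle = lambda_cycle,
                 lambda_identity = lambda_identity,
                 learning_rate = learning_rate, betas = betas,
                 epochs = epochs, batch_size = batch_size,
                 crop_size = crop_size, resize_to = resize_to, seed = seed,
                 adversarial_form = adversarial_form),
            class = "train_config")
}

#' Cycle-consistency loss
#'
#' Mean absolute pixel difference between an image and its reconstruction
#' after translating to the other domain and back.
#'
#' @param original,reconstructed Grey image matrices of identical shape.
#' @return Non-negative scalar.
#' @export
cycle_loss <- function(original, reconstructed) {
  if (!identical(dim(original), dim(reconstructed)))
    stop("cycle_loss: shape mismatch", call. = FALSE)
  mean(abs(original - reconstructed))
}

#' Identity loss
#'
#' Mean absolute difference between an image already in the target domain and
#' its translation into that same domain (forward code applied to a Y image,
#' backward code to an X image); penalizes unnecessary modification.
#'
#' @param img Grey image matrix.
#' @param translated Output of the generator applied to `img` with the code
#'   of `img`'s own domain.
#' @return Non-negative scalar.
#' @export
identity_loss <- function(img, translated) {
  if (!identical(dim(img), dim(translated)))
    stop("identity_loss: shape mismatch", call. = FALSE)
  mean(abs(img - translated))
}

#' Adversarial loss
#'
#' Least-squares form (default): the discriminator minimizes
#' `mean((real - 1)^2) + mean(fake^2)`, the generator `mean((fake - 1)^2)`.
#' Cross-entropy form treats scores as logits of a sigmoid real/fake
#' classifier.
#'
#' @param real_scores,fake_scores Score grids from [discriminate()]
#'   (`real_scores` may be `NULL` for the generator role).
#' @param role `"generator"` or `"discriminator"`.
#' @param form `"least-squares"` or `"cross-entropy"`.
#' @return Non-negative scalar.
#' @export
adversarial_losses <- function(real_scores = NULL, fake_scores,
                               role = c("generator", "discriminator"),
                               form = c("least-squares", "cross-entropy")) {
  role <- match.arg(role)
  form <- match.arg(form)
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  if (role == "generator") {
    if (form == "least-squares") mean((fake_scores - 1)^2)
    else mean(softplus(-fake_scores))
  } else {
    if (form == "least-squares")
      mean((real_scores - 1)^2) + mean(fake_scores^2)
    else mean(softplus(-real_scores)) + mean(softplus(fake_scores))
  }
}

# gradient of the adversarial loss w.r.t. a score grid
adv_grad <- function(scores, target, form) {
  n <- length(scores)
  if (form == "least-squares") {
    if (target == "real") 2 * (scores - 1) / n else 2 * scores / n
  } else {
    s <- 1 / (1 + exp(-scores))
    if (target == "real") (s - 1) / n else s / n
  }
}

l1_grad <- function(a, b, weight) weight * sign(a - b) / length(a)

check_finite <- function(losses) {
  bad <- names(losses)[!vapply(losses, is.finite, logical(1))]
  if (length(bad))
    stop("non-finite training loss term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
}

#' One training step of the switchable CycleGAN
#'
#' Executes the forward cycle (X to Y with the forward code, back with the
#' backward code), the backward cycle, the two identity passes, then updates
#' the generator + ACG jointly on
#' `total_G = l_adv + lambda_cycle * l_cycle + lambda_identity * l_iden`,
#' and each discriminator on its least-squares (or cross-entropy) objective.
#' All four networks are updated in the same step.
#'
#' @param batch_X,batch_Y Lists of grey image matrices (equal length).
#' @param bundle A `usgan_model`.
#' @param cfg A [train_config()].
#' @param opt Optimizer state from a previous call, or `NULL` to start.
#' @param step Step counter recorded in the loss record.
#' @return List with the updated `bundle`, optimizer state `opt`, and a
#'   one-row data frame `losses` (all terms finite, else an error naming the
#'   offending term).
#' @export
train_step <- function(batch_X, batch_Y, bundle, cfg, opt = NULL, step = 1L) {
  stopifnot(inherits(bundle, "usgan_model"), inherits(cfg, "train_config"),
            length(batch_X) == length(batch_Y), length(batch_X) >= 1)
  hp <- bundle$hp
  form <- cfg$adversarial_form
  if (is.null(opt))
    opt <- list(gen = adam_init(bundle$gen), acg = adam_init(bundle$acg),
                dA = adam_init(bundle$dA), dB = adam_init(bundle$dB))

  gg <- ga <- gdA <- gdB <- NULL
  acc <- c(adv_G = 0, adv_D_A = 0, adv_D_B = 0, cycle = 0, identity = 0)
  nb <- length(batch_X)

  for (b in seq_len(nb)) {
    x <- batch_X[[b]]; y <- batch_Y[[b]]
    acgF <- acg_fwd(bundle$acg, hp, "forward")
    acgB <- acg_fwd(bundle$acg, hp, "backward")

    fakeY <- gen_fwd(bundle$gen, hp, x, acgF$code)
    recX  <- gen_fwd(bundle$gen, hp, fakeY$y, acgB$code)
    fakeX <- gen_fwd(bundle$gen, hp, y, acgB$code)
    recY  <- gen_fwd(bundle$gen, hp, fakeX$y, acgF$code)
    idY   <- gen_fwd(bundle$gen, hp, y, acgF$code)
    idX   <- gen_fwd(bundle$gen, hp, x, acgB$code)

    dB_fake <- disc_fwd(bundle$dB, hp, fakeY$y)
    dA_fake <- disc_fwd(bundle$dA, hp, fakeX$y)

    l_adv <- adversarial_losses(fake_scores = dB_fake$scores,
                                role = "generator", form = form) +
             adversarial_losses(fake_scores = dA_fake$scores,
                                role = "generator", form = form)
    l_cyc <- cycle_loss(x, recX$y) + cycle_loss(y, recY$y)
    l_idn <- identity_loss(y, idY$y) + identity_loss(x, idX$y)

    # --- generator + ACG gradients -----------------------------------------
    gF <- gB <- NULL  # code grads per direction
    add_code <- function(tot, gc) {
      if (is.null(tot)) return(gc)
      for (l in seq_along(gc)) {
        tot[[l]]$gshift <- tot[[l]]$gshift + gc[[l]]$gshift
        tot[[l]]$gscale <- tot[[l]]$gscale + gc[[l]]$gscale
      }
      tot
    }
    # cycle reconstructions
    brecX <- gen_bwd(bundle$gen, hp, recX$cache,
                     l1_grad(recX$y, x, cfg$lambda_cycle))
    gB <- add_code(gB, brecX$gcode)
    brecY <- gen_bwd(bundle$gen, hp, recY$cache,
                     l1_grad(recY$y, y, cfg$lambda_cycle))
    gF <- add_code(gF, brecY$gcode)
    # translated images: adversarial + the gradient flowing back from the
    # reconstruction pass
    g_fakeY <- disc_bwd(bundle$dB, hp, dB_fake$cache,
                        adv_grad(dB_fake$scores, "real", form))$gx + brecX$gx
    bfakeY <- gen_bwd(bundle$gen, hp, fakeY$cache, g_fakeY)
    gF <- add_code(gF, bfakeY$gcode)
    g_fakeX <- disc_bwd(bundle$dA, hp, dA_fake$cache,
                        adv_grad(dA_fake$scores, "real", form))$gx + brecY$gx
    bfakeX <- gen_bwd(bundle$gen, hp, fakeX$cache, g_fakeX)
    gB <- add_code(gB, bfakeX$gcode)
    # identity passes
    bidY <- gen_bwd(bundle$gen, hp, idY$cache,
                    l1_grad(idY$y, y, cfg$lambda_identity))
    gF <- add_code(gF, bidY$gcode)
    bidX <- gen_bwd(bundle$gen, hp, idX$cache,
                    l1_grad(idX$y, x, cfg$lambda_identity))
    gB <- add_code(gB, bidX$gcode)

    ggen <- Reduce(acc_grads, list(brecX$grads, brecY$grads, bfakeY$grads,
                                   bfakeX$grads, bidY$grads, bidX$grads))
    gacg <- acc_grads(acg_bwd(bundle$acg, hp, acgF$cache, gF)$grads,
                      acg_bwd(bundle$acg, hp, acgB$cache, gB)$grads)

    # --- discriminator gradients (fakes held fixed) -------------------------
    dA_real <- disc_fwd(bundle$dA, hp, x)
    dB_real <- disc_fwd(bundle$dB, hp, y)
    l_dA <- adversarial_losses(dA_real$scores, dA_fake$scores,
                               role = "discriminator", form = form)
    l_dB <- adversarial_losses(dB_real$scores, dB_fake$scores,
                               role = "discriminator", form = form)
    gdA_b <- acc_grads(
      disc_bwd(bundle$dA, hp, dA_real$cache,
               adv_grad(dA_real$scores, "real", form))$grads,
      disc_bwd(bundle$dA, hp, dA_fake$cache,
               adv_grad(dA_fake$scores, "fake", form))$grads)
    gdB_b <- acc_grads(
      disc_bwd(bundle$dB, hp, dB_real$cache,
               adv_grad(dB_real$scores, "real", form))$grads,
      disc_bwd(bundle$dB, hp, dB_fake$cache,
               adv_grad(dB_fake$scores, "fake", form))$grads)

    gg <- acc_grads(gg, ggen); ga <- acc_grads(ga, gacg)
    gdA <- acc_grads(gdA, gdA_b); gdB <- acc_grads(gdB, gdB_b)
    acc <- acc + c(l_adv, l_dA, l_dB, l_cyc, l_idn)
  }

  losses <- as.list(acc / nb)
  names(losses) <- c("loss_adv_G", "loss_adv_D_A", "loss_adv_D_B",
                     "loss_cycle", "loss_identity")
  losses$total_G <- losses$loss_adv_G + cfg$lambda_cycle * losses$loss_cycle +
    cfg$lambda_identity * losses$loss_identity
  check_finite(losses)

  up <- adam_step(bundle$gen, scale_grads(gg, 1 / nb), opt$gen,
                  cfg$learning_rate, cfg$betas[1], cfg$betas[2])
  bundle$gen <- up$params; opt$gen <- up$state
  up <- adam_step(bundle$acg, scale_grads(ga, 1 / nb), opt$acg,
                  cfg$learning_rate, cfg$betas[1], cfg$betas[2])
  bundle$acg <- up$params; opt$acg <- up$state
  up <- adam_step(bundle$dA, scale_grads(gdA, 1 / nb), opt$dA,
                  cfg$learning_rate, cfg$betas[1], cfg$betas[2])
  bundle$dA <- up$params; opt$dA <- up$state
  up <- adam_step(bundle$dB, scale_grads(gdB, 1 / nb), opt$dB,
                  cfg$learning_rate, cfg$betas[1], cfg$betas[2])
  bundle$dB <- up$params; opt$dB <- up$state

  list(bundle = bundle, opt = opt,
       losses = data.frame(step = step, as.data.frame(losses)))
}

load_domain <- function(x) {
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.(png|dcm)$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no readable images in ", x, call. = FALSE)
    imgs <- list()
    for (f in files) {
      img <- tryCatch(load_image(f), error = function(e) {
        warning("skipping unreadable image ", f, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (!is.null(img)) imgs[[length(imgs) + 1L]] <- img
    }
    if (!length(imgs)) stop("no readable images in ", x, call. = FALSE)
    imgs
  } else if (is.list(x) && length(x) >= 1) {
    lapply(x, assert_grey)
  } else stop("domain input must be a directory or a list of images",
              call. = FALSE)
}

#' Fit the switchable CycleGAN on two unpaired image folders
#'
#' The central fitting function. Runs `cfg$epochs` epochs of [train_step()]
#' over seeded-shuffled unpaired batches with resize + random-crop
#' augmentation, optionally checkpointing every epoch, and returns the fitted
#' model with its full loss history.
#'
#' @param x,y Low- and high-quality domains: directories of PNG/DICOM images
#'   or lists of grey image matrices.
#' @param cfg A [train_config()].
#' @param bundle Optional initial `usgan_model` (e.g. to resume); by default
#'   a fresh bundle seeded from `cfg$seed`.
#' @param out_dir Optional directory receiving one checkpoint per epoch and
#'   the loss history CSV.
#' @param base_channels,n_res_blocks Architecture of the fresh bundle when
#'   `bundle` is not supplied.
#' @param history Loss history to append to when resuming.
#' @param verbose Print a line per epoch.
#' @return An object of class `usgan_fit`: list with elements `model`,
#'   `history` (one row per step), and `config`.
#' @export
fit_usgan <- function(x, y, cfg = train_config(), bundle = NULL,
                      out_dir = NULL, base_channels = 16, n_res_blocks = 4,
                      history = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  imgs_x <- load_domain(x)
  imgs_y <- load_domain(y)
  if (is.null(bundle))
    bundle <- model_bundle(base_channels = base_channels,
                           n_res_blocks = n_res_blocks, seed = cfg$seed)
  opt <- NULL
  step <- if (is.null(history)) 0L else max(history$step)
  start_epoch <- if (is.null(history)) 0L else
    attr(history, "epochs_done") %||% 0L
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  steps_per_epoch <- floor(min(length(imgs_x), length(imgs_y)) /
                           cfg$batch_size)
  if (steps_per_epoch < 1)
    stop("batch_size exceeds the smaller domain", call. = FALSE)

  for (e in (start_epoch + 1L):(start_epoch + cfg$epochs)) {
    old <- get_rng_state()
    set.seed(cfg$seed + e)
    ox <- sample(length(imgs_x))
    oy <- sample(length(imgs_y))
    for (s in seq_len(steps_per_epoch)) {
      ix <- ox[((s - 1) * cfg$batch_size + 1):(s * cfg$batch_size)]
      iy <- oy[((s - 1) * cfg$batch_size + 1):(s * cfg$batch_size)]
      cs <- sample.int(.Machine$integer.max - 1L, 2 * cfg$batch_size)
      bx <- lapply(seq_along(ix), function(i)
        preprocess(imgs_x[[ix[i]]], cfg$resize_to, cfg$crop_size, cs[i]))
      by <- lapply(seq_along(iy), function(i)
        preprocess(imgs_y[[iy[i]]], cfg$resize_to, cfg$crop_size,
                   cs[cfg$batch_size + i]))
      step <- step + 1L
      res <- train_step(bx, by, bundle, cfg, opt, step = step)
      bundle <- res$bundle; opt <- res$opt
      history <- rbind(history, res$losses)
    }
    set_rng_state(old)
    attr(history, "epochs_done") <- e
    if (!is.null(out_dir)) {
      save_checkpoint(bundle, file.path(out_dir,
                                        sprintf("epoch_%03d.rds", e)),
                      history = history)
      utils::write.csv(history, file.path(out_dir, "loss_history.csv"),
                       row.names = FALSE)
    }
    if (verbose)
      message(sprintf(
        "epoch %d | step %d | total_G %.4f cycle %.4f identity %.4f", e,
        step, history$total_G[nrow(history)],
        history$loss_cycle[nrow(history)],
        history$loss_identity[nrow(history)]))
  }
  structure(list(model = bundle, history = history, config = cfg),
            class = "usgan_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- S3 methods for the fitted object ---------------------------------------

#' @export
print.usgan_fit <- function(x, ...) {
  cat("Switchable CycleGAN fit\n")
  cat(sprintf("  %d training steps, final total_G %.4f (cycle %.4f, identity %.4f)\n",
              nrow(x$history), x$history$total_G[nrow(x$history)],
              x$history$loss_cycle[nrow(x$history)],
              x$history$loss_identity[nrow(x$history)]))
  print(x$model)
  invisible(x)
}

#' @export
summary.usgan_fit <- function(object, ...) {
  h <- object$history
  n <- nrow(h)
  head_n <- max(1L, floor(n * 0.1))
  s <- list(
    steps = n,
    cycle_first = stats::median(h$loss_cycle[seq_len(head_n)]),
    cycle_last = stats::median(h$loss_cycle[(n - head_n + 1):n]),
    final = h[n, ])
  class(s) <- "summary.usgan_fit"
  s
}

#' @export
print.summary.usgan_fit <- function(x, ...) {
  cat(sprintf("usgan fit over %d steps\n", x$steps))
  cat(sprintf("  median cycle loss: first 10%% %.4f -> last 10%% %.4f\n",
              x$cycle_first, x$cycle_last))
  cat("  final losses:\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
plot.usgan_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$step, cbind(h$total_G, h$loss_cycle, h$loss_identity,
                                  h$loss_adv_G),
                    type = "l", lty = 1, xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", c("total_G", "cycle", "identity", "adv_G"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

#' Translate new images with a fitted model
#'
#' @param object A `usgan_fit`.
#' @param newdata A grey image matrix or a list of them.
#' @param direction `"forward"` (enhance) or `"backward"`.
#' @param ... Unused.
#' @return A matrix (single input) or list of matrices.
#' @export
predict.usgan_fit <- function(object, newdata,
                              direction = c("forward", "backward"), ...) {
  direction <- match.arg(direction)
  one <- function(img) generate(img, object$model, direction)
  if (is.matrix(newdata)) one(newdata) else lapply(newdata, one)
}

#' Enhance a folder of images with a trained model
#'
#' Loads every PNG/DICOM image in `in_dir`, centre-crops to the largest size
#' divisible by the generator's downsampling factor, translates it, and
#' writes the result to `out_dir` preserving file names (as PNG).
#'
#' @param bundle A `usgan_model` (or `usgan_fit`).
#' @param in_dir,out_dir Input and output directories.
#' @param direction Translation direction.
#' @return Character vector of written files, invisibly.
#' @export
enhance_images <- function(bundle, in_dir, out_dir,
                           direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (inherits(bundle, "usgan_fit")) bundle <- bundle$model
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(in_dir, pattern = "\\.(png|dcm)$",
                           ignore.case = TRUE))
  written <- character()
  for (f in files) {
    img <- load_image(file.path(in_dir, f))
    d <- GEN_DOWN_FACTOR
    h <- (nrow(img) %/% d) * d; w <- (ncol(img) %/% d) * d
    r0 <- (nrow(img) - h) %/% 2; c0 <- (ncol(img) - w) %/% 2
    img <- img[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), drop = FALSE]
    out <- generate(img, bundle, direction)
    dest <- file.path(out_dir, sub("\\.dcm$", ".png", f,
                                   ignore.case = TRUE))
    save_image(out, dest)
    written <- c(written, dest)
  }
  invisible(written)
}
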