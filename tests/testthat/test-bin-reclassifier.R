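test_that("the AA-gapped dilation set collapses mass collisions", {
  d <- gapped_dilations()
  expect_lte(length(d), 21)
  expect_equal(max(d), 186)           # tryptophan
  expect_equal(sum(aa_bins() == 128), 2)  # K and Q collide
})

test_that("a gapped convolution layer has the stated receptive field", {
  d <- gapped_dilations()
  x <- matrix(0, 1, 500)
  expect_equal(gapped_conv_layer(x), matrix(0, 1, 500))  # linear, no bias
  x[1, 401] <- 1   # impulse at bin 400 (0-based)
  y <- gapped_conv_layer(x)
  expect_equal(ncol(y), 500)
  reach <- sort(unique(c(400, 400 + d, 400 - d)))
  reach <- reach[reach >= 0 & reach < 500]
  expect_identical(which(y[1, ] != 0) - 1L, as.integer(reach))
  expect_error(gapped_conv_layer(matrix(0, 1, 100)), "bins")
})

test_that("stacked layers cannot see past L dilation steps", {
  set.seed(3)
  model <- init_reclassifier(reclass_config(n_layers = 2L, n_filters = 4L,
                                            max_mz = 900L))
  base <- array(0, c(4, 900, 1))
  probe <- base
  probe[1, 1, 1] <- 5   # perturb bin 0
  p0 <- predict_bins(model, base[, , 1])
  p1 <- predict_bins(model, probe[, , 1])
  moved <- which(abs(p1$p_y - p0$p_y) > 1e-12) - 1L
  expect_lte(max(moved), 2 * max(gapped_dilations()))
})

test_that("focal loss reduces to cross-entropy at gamma 0 and vanishes
           for perfect predictions", {
  set.seed(9)
  p <- runif(500, 0.01, 0.99)
  t <- rbinom(500, 1, 0.3)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(focal_loss(p, t, gamma = 0, alpha = NULL), bce,
               tolerance = 1e-9)
  perfect <- ifelse(t == 1, 1 - 1e-9, 1e-9)
  expect_lt(focal_loss(perfect, t, gamma = 2), 1e-12)
  expect_gt(focal_loss(1 - perfect, t, gamma = 2), 1)
})

test_that("analytic gradients match finite differences", {
  set.seed(13)
  cfg <- reclass_config(n_layers = 2L, n_filters = 3L, max_mz = 400L)
  m <- init_reclassifier(cfg)
  N <- 2L
  x2 <- seqmend:::.to_sample_fastest(array(runif(4 * 400 * N), c(4, 400, N)))
  targ <- matrix(rbinom(2 * 400 * N, 1, 0.1), 2)
  fwd <- seqmend:::.reclass_forward(m, x2, N, training = TRUE,
                                    keep_cache = TRUE)
  g <- seqmend:::.reclass_backward(
    m, fwd, seqmend:::.focal_grad_logits(fwd$p, targ, cfg$gamma, cfg$alpha))
  loss_at <- function(params) {
    m2 <- m
    m2$params <- params
    focal_loss(seqmend:::.reclass_forward(m2, x2, N, training = TRUE)$p,
               targ, cfg$gamma, cfg$alpha)
  }
  probes <- list(
    list(get = function(p) p$layers[[1]]$W0[2, 3],
         set = function(p, v) { p$layers[[1]]$W0[2, 3] <- v; p },
         grad = g$layers[[1]]$W0[2, 3]),
    list(get = function(p) p$layers[[2]]$Wd[[5]][1, 4],
         set = function(p, v) { p$layers[[2]]$Wd[[5]][1, 4] <- v; p },
         grad = g$layers[[2]]$Wd[[5]][1, 4]),
    list(get = function(p) p$layers[[1]]$bn_gamma[2],
         set = function(p, v) { p$layers[[1]]$bn_gamma[2] <- v; p },
         grad = g$layers[[1]]$bn_gamma[2]),
    list(get = function(p) p$head$W[2, 1],
         set = function(p, v) { p$head$W[2, 1] <- v; p },
         grad = g$head$W[2, 1]))
  eps <- 1e-6
  for (pr in probes) {
    v <- pr$get(m$params)
    num <- (loss_at(pr$set(m$params, v + eps)) -
            loss_at(pr$set(m$params, v - eps))) / (2 * eps)
    expect_equal(pr$grad, num, tolerance = 1e-4)
  }
})

test_that("an initialized model with a zeroed head predicts 0.5 and is
           batch-order invariant", {
  set.seed(17)
  model <- init_reclassifier(reclass_config(max_mz = 800L))
  model$params$head$W[] <- 0
  model$params$head$b[] <- 0
  x <- array(runif(4 * 800 * 3), c(4, 800, 3))
  p <- predict_bins(model, x)
  expect_equal(unname(as.numeric(p$p_y)), rep(0.5, 800 * 3))
  # restore a random head: permuting the batch permutes the outputs
  set.seed(18)
  model$params$head$W[] <- rnorm(length(model$params$head$W))
  p1 <- predict_bins(model, x)
  p2 <- predict_bins(model, x[, , c(3, 1, 2)])
  expect_equal(p2$p_y, p1$p_y[, c(3, 1, 2)])
  expect_error(predict_bins(model, matrix(0, 4, 700)), "4 x 800")
})

test_that("change probabilities flip with the initial label", {
  p <- c(0.9, 0.8, 0.1, 0.2, 0.1, 0.1)
  init <- c(1, 0, 0, 1, 0, 0)
  expect_equal(change_probs(p, init), c(0.1, 0.8, 0.1, 0.8, 0.1, 0.1))
  expect_equal(change_probs(p, 1 - init), 1 - change_probs(p, init))
})

test_that("change precision-recall follows the hand-computed toy case", {
  init <- c(1, 0, 0, 1, 0, 0)
  truth <- c(1, 1, 0, 0, 0, 0)
  p_y <- c(0.9, 0.8, 0.1, 0.2, 0.1, 0.1)
  pr <- pr_at_threshold(change_probs(p_y, init), as.numeric(init != truth),
                        0.5)
  expect_equal(unname(pr), c(1, 1))
  curve <- change_pr_curve(p_y, init, truth)
  expect_equal(curve$auprc, 1)   # both change events score highest
  expect_error(change_pr_curve(p_y, truth, truth),
               class = "seqmend_no_changes")
})

test_that("training reduces the focal loss on simulator data", {
  ds <- tiny_reclass_dataset(n = 40, max_mz = 800)
  set.seed(31)
  cfg <- reclass_config(max_mz = 800L, batch_size = 8L, max_epochs = 6L,
                        patience = 6L, lr_patience = 6L)
  m <- train_reclassifier(ds, cfg)
  expect_true(m$trained)
  expect_gte(nrow(m$history), 5)
  expect_lt(min(m$history$train_loss), m$history$train_loss[1])
  # the loss trend over the first epochs is decreasing
  expect_lt(mean(diff(m$history$train_loss[1:5])), 0)
  expect_error(train_reclassifier(list(x = ds$x[, , 1, drop = FALSE],
                                       yb = ds$yb[, 1, drop = FALSE],
                                       yy = ds$yy[, 1, drop = FALSE]), cfg),
               "at least 2")
})
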