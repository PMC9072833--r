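# CNN contract, LDAM loss, backpropagation correctness and the training loop.

test_that("forward pass maps batches to probability rows", {
  cfg <- model_config(n_species = 40, input_channels = 48, input_px = 8,
                      backbone = "small-inception", seed = 2)
  m <- build_model(cfg)
  x <- array(rnorm(8 * 8 * 48 * 2), c(8, 8, 48, 2))
  p <- predict_sdm(m, x)
  expect_equal(dim(p), c(2, 40))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  # evaluation mode is deterministic (dropout disabled)
  expect_identical(predict_sdm(m, x), p)
  # duplicated occurrence gives identical rows
  x2 <- x
  x2[, , , 2] <- x[, , , 1]
  p2 <- predict_sdm(m, x2)
  expect_equal(p2[1, ], p2[2, ])
  # shape mismatch and non-finite input are rejected
  expect_error(predict_sdm(m, array(0, c(8, 8, 12, 2))), "shape")
  x[1] <- NaN
  expect_error(predict_sdm(m, x), "non-finite")
})

test_that("config defaults and guards match the training recipe", {
  cfg <- model_config(10, 48, 16)
  expect_equal(cfg$dropout_p, 0.5)
  expect_equal(cfg$s_scale, 30)
  expect_error(model_config(10, 48, 16, dropout_p = 1), "dropout_p")
  expect_error(model_config(10, 48, 16, backbone = "inception-v3-adapted"),
               "not provided")
  sched <- train_schedule()
  expect_equal(sched$lr_init, 0.1)
  expect_equal(sched$batch_size, 64)
  expect_equal(sched$eval_k, 30)
  expect_error(train_schedule(epochs = 10, drw_epoch = 12), "drw_epoch")
})

test_that("a zeroed classifier yields uniform predictions", {
  cfg <- model_config(n_species = 12, input_channels = 8, input_px = 8,
                      backbone = "plain-cnn", seed = 4)
  m <- build_model(cfg)
  m$layers[[length(m$layers)]]$W[] <- 0
  p <- predict_sdm(m, array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3)))
  expect_equal(p, matrix(1 / 12, 3, 12), ignore_attr = TRUE)
})

test_that("LDAM margins scale as n^(-1/4) with the prescribed maximum", {
  # counts (16, 256): margin ratio (256/16)^(1/4) = 2
  d <- ldam_margins(c(16, 256), max_margin = 0.5)
  expect_equal(d[1] / d[2], 2)
  expect_equal(max(d), 0.5) # rarest class carries the max margin
  expect_error(ldam_margins(c(0, 5)), "class_counts")
})

test_that("LDAM loss equals hand-computed margin-shifted cross-entropy", {
  scores <- rbind(c(0.6, -0.2, 0.1), c(-0.3, 0.4, 0.0))
  y <- c(1, 3)
  n <- c(16, 256, 81)
  mu <- 0.5
  s <- 30
  # oracle: scalar arithmetic
  delta <- mu * min(n)^(1 / 4) / n^(1 / 4)
  hand <- mean(vapply(1:2, function(i) {
    z <- s * scores[i, ]
    z[y[i]] <- z[y[i]] - s * delta[y[i]]
    -(z[y[i]] - log(sum(exp(z))))
  }, 0))
  expect_equal(as.numeric(ldam_loss(scores, y, n, mu, s)), hand)
  expect_gte(as.numeric(ldam_loss(scores, y, n, mu, s)), 0)

  # zero margin reduces to plain cross-entropy on the same scaled scores
  ce <- mean(vapply(1:2, function(i) {
    z <- s * scores[i, ]
    -(z[y[i]] - log(sum(exp(z))))
  }, 0))
  expect_equal(as.numeric(ldam_loss(scores, y, n, max_margin = 0, s_scale = s)),
               ce)
  expect_error(ldam_loss(scores, y, c(16, 256, 0)), "zero training count")
})

test_that("backpropagation matches finite differences in both backbones", {
  ns <- asNamespace("phenosdm")
  set.seed(88)
  B <- 2; px <- 8; Cin <- 5; S <- 4
  x <- array(rnorm(px * px * Cin * B), c(px, px, Cin, B))
  y <- c(2, 4)
  counts <- c(7, 30, 3, 50)
  for (backbone in c("plain-cnn", "small-inception")) {
    m <- build_model(model_config(S, Cin, px, backbone = backbone,
                                  dropout_p = 0, width = 0.25, seed = 6))
    lossfun <- function(layers) {
      fw <- ns$net_forward(layers, x, training = TRUE)
      as.numeric(ldam_loss(fw$out, y, counts))
    }
    fw <- ns$net_forward(m$layers, x, training = TRUE)
    l0 <- ldam_loss(fw$out, y, counts)
    bw <- ns$net_backward(fw$layers, fw$caches, attr(l0, "grad"))
    eps <- 1e-5

    probe <- function(mutate, analytic) {
      plus <- mutate(+eps); minus <- mutate(-eps)
      num <- (lossfun(plus) - lossfun(minus)) / (2 * eps)
      expect_equal(analytic, num, tolerance = 1e-4)
    }
    for (i in seq_along(m$layers)) {
      l <- fw$layers[[i]]
      if (l$type == "inception") {
        for (j in seq_along(l$branches)) {
          for (bi in seq_along(l$branches[[j]])) {
            lb <- l$branches[[j]][[bi]]
            for (p in intersect(c("W", "gamma", "beta"), names(lb))) {
              k <- sample(length(lb[[p]]), 1)
              probe(function(e) {
                ll <- fw$layers
                ll[[i]]$branches[[j]][[bi]][[p]][k] <-
                  ll[[i]]$branches[[j]][[bi]][[p]][k] + e
                ll
              }, bw$grads[[i]]$branches[[j]][[bi]][[p]][k])
            }
          }
        }
      } else {
        for (p in intersect(c("W", "b", "gamma", "beta"), names(l))) {
          k <- sample(length(l[[p]]), 1)
          probe(function(e) {
            ll <- fw$layers
            ll[[i]][[p]][k] <- ll[[i]][[p]][k] + e
            ll
          }, bw$grads[[i]][[p]][k])
        }
      }
    }
    # input gradient
    k <- sample(length(x), 1)
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    fwd <- function(xx) {
      as.numeric(ldam_loss(ns$net_forward(fw$layers, xx, TRUE)$out, y, counts))
    }
    expect_equal(bw$dx[k], (fwd(xp) - fwd(xm)) / (2 * eps), tolerance = 1e-4)
  }
})

# a tiny linearly separable 3-species problem: species differ by strong mean
# shifts in distinct channels
toy_separable <- function(n_per = 30, px = 8, Cin = 4, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per
  x <- array(rnorm(px * px * Cin * n, sd = 0.5), c(px, px, Cin, n))
  y <- rep(1:3, each = n_per)
  for (i in seq_len(n)) x[, , y[i], i] <- x[, , y[i], i] + 2
  perm <- sample(n)
  list(x = x[, , , perm, drop = FALSE], y = y[perm])
}

test_that("training learns a separable toy problem and follows the schedule", {
  toy <- toy_separable()
  te <- toy_separable(n_per = 10, seed = 2)
  m <- build_model(model_config(3, 4, 8, backbone = "plain-cnn",
                                width = 0.5, seed = 3))
  sched <- train_schedule(epochs = 8, batch_size = 30, lr_init = 0.05,
                          lr_decay_epochs = c(6, 8), drw_epoch = 8,
                          eval_every = 2, eval_k = 1, seed = 5)
  fit <- train_sdm(m, toy$x, toy$y, te$x, te$y, sched)
  # loss decreased and accuracy is high
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  pred <- predict_sdm(fit$model, te$x)
  top1 <- micro_accuracy(top_k_hits(pred, te$y, 1))
  expect_gte(top1, 0.95)
  # history: one evaluation per eval_every epochs, stepped learning rate
  expect_equal(fit$history$epoch, c(2, 4, 6, 8))
  expect_equal(fit$history$lr, c(0.05, 0.05, 0.005, 0.0005))
  expect_error(train_sdm(m, toy$x[, , , 0, drop = FALSE], integer(0),
                         te$x, te$y, sched), "empty training stream")
})

test_that("deferred re-weighting weights are off until drw_epoch and mean 1", {
  ns <- asNamespace("phenosdm")
  w <- ns$drw_weights(c(100, 10, 0))
  expect_equal(mean(w[1:2]), 1)
  expect_gt(w[2], w[1]) # rarer class weighs more
  expect_equal(w[3], 0)
})
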