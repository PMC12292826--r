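test_that("MLM loss matches analytic and brute-force cross-entropy", {
  # uniform logits over a 10-word vocabulary -> ln 10
  expect_equal(mlm_loss(matrix(0, 4, 10), c(1L, 5L, 9L, 2L)), log(10))
  # confidently correct -> ~0
  big <- matrix(-50, 3, 10); big[cbind(1:3, c(2L, 3L, 4L))] <- 50
  expect_lt(mlm_loss(big, c(2L, 3L, 4L)), 1e-10)
  # hand-set 3-position batch against an explicit softmax oracle
  withr::with_seed(71, L <- matrix(rnorm(3 * 7), 3, 7))
  tg <- c(3L, 1L, 6L)
  oracle <- mean(vapply(1:3, function(i) {
    p <- exp(L[i, ]) / sum(exp(L[i, ]))
    -log(p[tg[i]])
  }, numeric(1)))
  expect_equal(mlm_loss(L, tg), oracle, tolerance = 1e-12)
  # zero masked positions -> 0 with a warning
  expect_warning(z <- mlm_loss(NULL, integer(0)), "no masked positions")
  expect_equal(as.numeric(z), 0)
})

test_that("MIM loss is the mean squared error over masked patches only", {
  pm <- structure(list(mask = c(1L, 0L, 1L, 1L), budget = 3L),
                  class = "patch_mask")
  true <- matrix(c(1, 0.2, 0.3, 0.4), 4, 1)
  pred_perfect <- true
  expect_equal(mim_loss(pred_perfect, true, pm), 0)
  # one masked single-pixel patch: 0.5 vs 1.0 -> 0.25
  pm1 <- structure(list(mask = c(1L, 0L), budget = 1L), class = "patch_mask")
  expect_equal(mim_loss(matrix(c(0.5, 9), 2, 1), matrix(c(1, 0), 2, 1), pm1),
               0.25)
  # brute-force oracle on 3 masked patches of 4 pixels
  withr::with_seed(72, {
    P <- matrix(runif(16), 4, 4); Q <- matrix(runif(16), 4, 4)
  })
  oracle <- mean((P[c(1, 3, 4), ] - Q[c(1, 3, 4), ])^2)
  expect_equal(mim_loss(P, Q, pm), oracle)
  # invariance: predictions at unmasked patches never matter
  P2 <- P; P2[2, ] <- 99
  expect_equal(mim_loss(P2, Q, pm), mim_loss(P, Q, pm))
  # empty mask is an error
  pm0 <- structure(list(mask = c(0L, 0L), budget = 0L), class = "patch_mask")
  expect_error(mim_loss(matrix(0, 2, 1), matrix(0, 2, 1), pm0), "undefined")
})

test_that("matching batches flip pairs at the requested rate with valid partners", {
  corpus <- toy_corpus()
  pairs <- tibble::tibble(caption = paste("caption", 1:8),
                          pixels = corpus$pixels)
  none <- make_itm_batch(pairs, 0)
  expect_true(all(none$label == 1L))

  withr::with_seed(73, {
    counts <- vapply(1:400, function(i)
      sum(make_itm_batch(pairs, 0.5)$label == 0L), numeric(1))
  })
  expect_equal(mean(counts), 4, tolerance = 0.05)

  withr::with_seed(74, b <- make_itm_batch(pairs, 1))
  neg <- which(b$label == 0L)
  expect_true(all(b$partner[neg] != neg))
  swapped_caption <- b$caption[neg] != pairs$caption[neg]
  swapped_image <- !mapply(identical, b$pixels[neg], pairs$pixels[neg])
  expect_true(all(swapped_caption | swapped_image))

  expect_error(make_itm_batch(pairs[1, ], 0.5), "at least 2")
})

test_that("ITM loss matches analytic binary cross-entropy and is monotone in the correct logit", {
  expect_equal(itm_loss(matrix(0, 5, 2), c(1, 0, 1, 1, 0)), log(2))
  conf <- matrix(c(-40, 40), 1, 2)  # p(match) ~ 1
  expect_lt(itm_loss(conf, 1), 1e-10)
  withr::with_seed(75, L <- matrix(rnorm(8), 4, 2))
  labs <- c(1, 0, 0, 1)
  oracle <- mean(vapply(1:4, function(i) {
    p <- exp(L[i, ]) / sum(exp(L[i, ]))
    -log(p[labs[i] + 1])
  }, numeric(1)))
  expect_equal(itm_loss(L, labs), oracle, tolerance = 1e-12)
  # raising the correct-class logit strictly decreases the loss
  prev <- Inf
  for (delta in c(0, 1, 2, 4)) {
    L2 <- L; L2[cbind(1:4, labs + 1)] <- L2[cbind(1:4, labs + 1)] + delta
    cur <- itm_loss(L2, labs)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("loss composition is exactly the unweighted printed arithmetic", {
  rep135 <- compose_losses(1, 2, 3, 4, 5)
  expect_identical(rep135$pretrain, 6)
  expect_identical(rep135$distill, 9)
  expect_identical(rep135$total, 15)
  z <- compose_losses(0, 0, 0, 0, 0)
  expect_identical(z$total, 0)
  withr::with_seed(76, {
    for (i in 1:200) {
      v <- runif(5)
      r <- compose_losses(v[1], v[2], v[3], v[4], v[5])
      expect_identical(r$total - (r$pretrain + r$distill), 0)
      expect_identical(r$pretrain, v[1] + v[2] + v[3])
      expect_identical(r$distill, v[4] + v[5])
    }
  })
  expect_error(compose_losses(1, NaN, 3, 4, 5), "mim")
  expect_error(compose_losses(1, 2, 3, Inf, 5), "hid")
  tr <- tidy(rep135)
  expect_equal(tr$total, 15)
})

test_that("all objectives yield finite gradients on a toy training batch", {
  student <- with_param_nodes(toy_student())
  tok <- toy_tok()
  corpus <- toy_corpus()
  ids <- toy_ids(2)
  withr::with_seed(77, {
    plans <- mvldistill:::make_token_plans(ids, tok, 0.15)
    pms <- lapply(1:2, function(i) random_patch_mask(16, 0.75))
  })
  rec_mlm <- forward_with_records(student, corpus$pixels[1:2], ids,
                                  token_plan = plans, with_grad = TRUE,
                                  heads = "mlm")
  rec_mim <- forward_with_records(student, corpus$pixels[1:2], ids,
                                  patch_mask = pms, with_grad = TRUE,
                                  heads = "mim")
  rec_itm <- forward_with_records(student, corpus$pixels[1:2], ids,
                                  with_grad = TRUE, heads = "itm")
  l1 <- mlm_loss(rec_mlm$mlm_logits, rec_mlm$mlm_targets)
  Sd <- rec_mim$mim_seq
  rows <- unlist(lapply(1:2, function(b)
    (b - 1L) * Sd + 1L + which(pms[[b]]$mask == 1L)))
  tgt <- do.call(rbind, lapply(1:2, function(b)
    patchify(corpus$pixels[[b]], 8)[which(pms[[b]]$mask == 1L), ]))
  l2 <- ag_mse(ag_rows(rec_mim$mim_pred, rows), tgt)
  l3 <- itm_loss(rec_itm$itm_logits, c(1, 1))
  total <- ag_sum_scalars(list(l1, l2, l3))
  mvldistill::ag_backward(total)
  grads <- Filter(Negate(is.null),
                  lapply(student$.param_nodes, function(nd) nd$grad))
  expect_gt(length(grads), 50)
  expect_true(all(vapply(grads, function(g) all(is.finite(g)), logical(1))))
})
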