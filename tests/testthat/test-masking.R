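# Brute-force reference for the grouped mask generator: materialise the
# high- and low-attention groups explicitly, mask the whole high group, then
# draw the remaining budget from the low group.
reference_guided_mask <- function(salience, r, total_ratio) {
  N <- length(salience)
  rhu <- function(x) floor(x + 0.5)
  budget <- rhu(total_ratio * N)
  k_high <- rhu((1 - r) * N)
  ranked <- order(-salience, seq_len(N))
  high_group <- ranked[seq_len(min(k_high, budget))]
  low_group <- ranked[setdiff(seq_len(N), seq_len(min(k_high, budget)))]
  picks <- if (budget > length(high_group))
    low_group[sample(length(low_group), budget - length(high_group))]
  else integer(0)
  mask <- integer(N)
  mask[c(high_group, picks)] <- 1L
  mask
}

test_that("token masking selects floor(rate x maskable) positions and skips special-only sequences", {
  tok <- toy_tok()
  specials <- c(tok$pad_id, tok$cls_id, tok$sep_id)
  only_special <- rep(c(tok$cls_id, tok$sep_id, tok$pad_id), 4)
  plan <- plan_token_masking(only_special, specials, vocab_size = 48)
  expect_length(plan$positions, 0)

  withr::with_seed(31, {
    seq20 <- c(tok$cls_id, rep(tok$ids[["opacity"]], 20), tok$sep_id)
    plan <- plan_token_masking(seq20, specials, rate = 0.15, vocab_size = 48)
    expect_length(plan$positions, 3)              # floor(0.15 * 20)
    expect_true(all(!seq20[plan$positions] %in% specials))
    expect_identical(plan$target_ids, seq20[plan$positions])
  })
})

test_that("replacement actions split 80/10/10 and apply correctly", {
  tok <- toy_tok()
  specials <- c(tok$pad_id, tok$cls_id, tok$sep_id)
  seqs <- c(tok$cls_id, rep(tok$ids[["lesion"]], 40), tok$sep_id)
  withr::with_seed(32, {
    acts <- character(0)
    for (i in 1:2000) {
      plan <- plan_token_masking(seqs, specials, vocab_size = 48)
      acts <- c(acts, plan$actions)
    }
  })
  frac <- table(factor(acts, c("mask", "random", "keep"))) / length(acts)
  expect_equal(unname(frac[["mask"]]), 0.8, tolerance = 0.03)
  expect_equal(unname(frac[["random"]]), 0.1, tolerance = 0.15)
  expect_equal(unname(frac[["keep"]]), 0.1, tolerance = 0.15)

  withr::with_seed(33, plan <- plan_token_masking(seqs, specials, vocab_size = 48))
  applied <- apply_token_plan(seqs, plan, tok$mask_id)
  expect_true(all(applied[plan$positions[plan$actions == "mask"]] == tok$mask_id))
  expect_true(all(applied[plan$positions[plan$actions == "keep"]] ==
                    seqs[plan$positions[plan$actions == "keep"]]))
  expect_true(all(applied[-plan$positions] == seqs[-plan$positions]))
})

test_that("random patch masks hit the exact rounded budget and are seed-deterministic", {
  withr::with_seed(41, m1 <- random_patch_mask(324, 0.75))
  expect_equal(m1$budget, 243L)                  # 288/16 grid
  expect_equal(sum(m1$mask), 243L)
  expect_equal(random_patch_mask(4, 0.75)$budget, 3L)
  withr::with_seed(42, a <- random_patch_mask(16, 0.75))
  withr::with_seed(42, b <- random_patch_mask(16, 0.75))
  expect_identical(a, b)
  expect_error(random_patch_mask(0, 0.75), ">= 1")
})

test_that("attention aggregation min-max normalises, guards degeneracy, and ignores scale", {
  I2 <- diag(2)
  f <- aggregate_attention(I2, I2, I2, I2)
  expect_equal(f$aggregate, matrix(c(1, 0, 0, 1), 2, 2))

  C <- matrix(0.25, 2, 2)
  expect_equal(aggregate_attention(C, C, C, C)$aggregate, matrix(0.5, 2, 2))

  # hand-written 3x3 maps against an element-wise oracle computed right here
  m1 <- matrix(c(0.1, 0.3, 0.6, 0.2, 0.2, 0.6, 0.5, 0.25, 0.25), 3, 3, byrow = TRUE)
  m2 <- matrix(c(0.4, 0.4, 0.2, 0.1, 0.8, 0.1, 0.3, 0.3, 0.4), 3, 3, byrow = TRUE)
  m3 <- diag(3)
  m4 <- matrix(1 / 3, 3, 3)
  s <- m1 + m2 + m3 + m4
  oracle <- (s - min(s)) / (max(s) - min(s))
  expect_equal(aggregate_attention(m1, m2, m3, m4)$aggregate, oracle)

  # positive rescaling of all four inputs changes nothing
  g1 <- aggregate_attention(m1, m2, m3, m4)$aggregate
  g2 <- aggregate_attention(7 * m1, 7 * m2, 7 * m3, 7 * m4)$aggregate
  expect_equal(g1, g2)

  expect_error(aggregate_attention(I2, I2, I2, diag(3)), "identical shape")
  expect_error(aggregate_attention(I2, I2, I2, -I2), "negative")
})

test_that("salience is the column mean of the aggregate", {
  f <- aggregate_attention(diag(2), diag(2), diag(2), diag(2))
  f$aggregate <- matrix(c(0.2, 0.4, 0.8, 0.6), 2, 2)  # cols (0.2,0.4), (0.8,0.6)
  expect_equal(salience_from_attention(f), c(0.3, 0.7))
  expect_equal(salience_from_attention(
    aggregate_attention(diag(2), diag(2), diag(2), diag(2))), c(0.5, 0.5))
  u <- matrix(0.5, 4, 4)
  expect_equal(salience_from_attention(aggregate_attention(u, u, u, u)),
               rep(0.5, 4))
})

test_that("the progressive schedule interpolates linearly between its printed endpoints", {
  sch <- mask_schedule(max_steps = 100)
  expect_equal(schedule_r(0, sch), 0.95)
  expect_equal(schedule_r(100, sch), 0.3)
  expect_equal(schedule_r(50, sch), 0.625)
  expect_equal(schedule_r(250, sch), 0.3)   # clamps beyond the horizon
  expect_error(schedule_r(-1, sch), "nonnegative")
  # exact linearity: differences proportional to step gaps
  d1 <- schedule_r(10, sch) - schedule_r(30, sch)
  d2 <- schedule_r(40, sch) - schedule_r(60, sch)
  expect_equal(d1, d2)
})

test_that("guided masks obey group sizes at the schedule endpoints", {
  withr::with_seed(51, sal <- runif(20))
  top1 <- which.max(sal)
  withr::with_seed(52, m_hi <- attention_guided_mask(sal, r = 0.95))
  expect_equal(sum(m_hi$mask), 15L)              # round(0.75 * 20)
  expect_equal(m_hi$high_group, top1)            # round(0.05 * 20) = 1
  expect_equal(m_hi$mask[top1], 1L)

  withr::with_seed(53, m_lo <- attention_guided_mask(sal, r = 0.3))
  expect_equal(sum(m_lo$mask), 15L)
  top14 <- order(-sal, seq_along(sal))[1:14]     # round(0.7 * 20) = 14
  expect_setequal(m_lo$high_group, top14)
  expect_true(all(m_lo$mask[top14] == 1L))

  withr::with_seed(54, m_u <- attention_guided_mask(rep(0.5, 20), r = 0.5))
  expect_equal(sum(m_u$mask), 15L)               # budget conserved under ties
})

test_that("budget is conserved and high-group coverage grows monotonically across the schedule", {
  sch <- mask_schedule(max_steps = 40)
  withr::with_seed(55, sal <- runif(36))
  k_prev <- -1L
  for (step in seq(0, 40, by = 5)) {
    r <- schedule_r(step, sch)
    m <- attention_guided_mask(sal, r)
    expect_equal(sum(m$mask), 27L)               # round(0.75 * 36) everywhere
    k <- length(m$high_group)
    expect_gte(k, k_prev)
    k_prev <- k
    # the top-k salience patches are always masked
    topk <- order(-sal, seq_along(sal))[seq_len(k)]
    expect_true(all(m$mask[topk] == 1L))
  }
})

test_that("guided masking agrees with the explicit-group reference across random salience fields", {
  for (trial in 1:300) {
    withr::with_seed(6000 + trial, {
      N <- sample(4:12, 1)
      sal <- runif(N)
      r <- runif(1, 0.05, 0.95)
      seed <- sample.int(1e6, 1)
    })
    withr::with_seed(seed, got <- attention_guided_mask(sal, r)$mask)
    withr::with_seed(seed, want <- reference_guided_mask(sal, r, 0.75))
    expect_identical(got, want)
  }
})

test_that("live-model guided masks are identical when teacher and student share weights", {
  student <- toy_student()
  corpus <- toy_corpus()
  sch <- mask_schedule(max_steps = 10)
  ids <- toy_ids(2)
  withr::with_seed(61,
    m1 <- compute_guided_mask_for_batch(student, student, corpus$pixels[1:2],
                                        ids, 2, sch))
  # doubling both contributions is absorbed by min-max normalisation, so
  # masks from (student, student) match masks from either model's own maps
  rec <- forward_with_records(student, corpus$pixels[1:2], ids)
  for (b in 1:2) {
    field <- aggregate_attention(guidance_map(rec, "uni", b),
                                 guidance_map(rec, "uni", b),
                                 guidance_map(rec, "mul", b),
                                 guidance_map(rec, "mul", b))
    expect_equal(attr(m1[[b]], "salience"), field$salience)
  }
  expect_error(
    compute_guided_mask_for_batch(toy_student(),
                                  build_model(preset_config("toy-teacher",
                                                            vocab_size = 48),
                                              seed = 8),
                                  corpus$pixels[1:2], ids, 0, sch),
    NA)
})
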