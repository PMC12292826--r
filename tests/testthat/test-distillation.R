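test_that("layer maps use even interval sampling with aligned deepest layers", {
  expect_equal(build_layer_map(12, 12)$hidden_map, 1:12)
  expect_equal(build_layer_map(12, 6)$hidden_map, c(2, 4, 6, 8, 10, 12))
  expect_equal(build_layer_map(12, 5)$hidden_map, c(3, 5, 8, 10, 12))
  expect_equal(build_layer_map(12, 4)$hidden_map, c(3, 6, 9, 12))
  expect_equal(build_layer_map(6, 2)$hidden_map, c(3, 6))
  expect_equal(build_layer_map(6, 1)$hidden_map, 6)
  # ceiling spacing for the non-integral published depths
  expect_equal(build_layer_map(12, 7)$hidden_map, c(2, 4, 6, 7, 9, 11, 12))
  for (l in 1:12) {
    m <- build_layer_map(12, l)$hidden_map
    expect_true(all(diff(m) > 0))
    expect_equal(m[l], 12L)
  }
  expect_error(build_layer_map(4, 6), "1 <= l")
})

test_that("hidden distillation equals brute-force per-layer MSE sums", {
  withr::with_seed(81, {
    teacher <- lapply(1:6, function(i) matrix(rnorm(12), 4, 3))
    student <- lapply(1:3, function(i) matrix(rnorm(12), 4, 3))
  })
  map <- build_layer_map(6, 3)
  expect_equal(map$hidden_map, c(2, 4, 6))
  oracle <- 0
  for (i in 1:3) {
    d <- student[[i]] - teacher[[map$hidden_map[i]]]
    oracle <- oracle + mean(d * d)
  }
  expect_equal(hidden_distillation_loss(student, teacher, map), oracle,
               tolerance = 1e-12)
  # identical stacks with the identity map -> exactly 0
  expect_identical(hidden_distillation_loss(teacher, teacher,
                                            build_layer_map(6, 6)), 0)
  # single layer: [[0,0]] vs [[2,2]] -> mean(4, 4) = 4
  expect_equal(hidden_distillation_loss(list(matrix(0, 1, 2)),
                                        list(matrix(2, 1, 2)),
                                        build_layer_map(1, 1)), 4)
  # width mismatch is an error
  expect_error(hidden_distillation_loss(list(matrix(0, 1, 3)),
                                        list(matrix(0, 1, 2)),
                                        build_layer_map(1, 1)),
               "projection")
})

test_that("attention distillation equals the brute-force head-and-layer loop", {
  # single head, single layer: identity student vs uniform teacher -> 0.25
  s <- array(diag(2), c(2, 2, 1, 1))
  t0 <- array(0.5, c(2, 2, 1, 1))
  expect_equal(attention_distillation_loss(list(s), list(t0),
                                           build_layer_map(1, 1)), 0.25)
  expect_identical(attention_distillation_loss(list(s), list(s),
                                               build_layer_map(1, 1)), 0)

  withr::with_seed(82, {
    teacher <- lapply(1:6, function(i) array(runif(3 * 3 * 2), c(3, 3, 2, 1)))
    student <- lapply(1:2, function(i) array(runif(3 * 3 * 2), c(3, 3, 2, 1)))
  })
  map <- build_layer_map(6, 2)
  expect_equal(map$attn_map, c(3, 6))
  h <- 2
  oracle <- 0
  for (j in 1:2) {
    for (i in 1:h) {
      d <- student[[j]][, , i, 1] - teacher[[map$attn_map[j]]][, , i, 1]
      oracle <- oracle + mean(d * d)
    }
  }
  oracle <- oracle / h
  expect_equal(attention_distillation_loss(student, teacher, map), oracle,
               tolerance = 1e-12)

  bad <- lapply(1:6, function(i) array(runif(9), c(3, 3, 1, 1)))
  expect_error(attention_distillation_loss(student, bad, map), "head counts")
})

test_that("published preset depths give the printed distillation ratios where integral", {
  t_cfg <- preset_config("teacher-m3ae")
  b_cfg <- preset_config("student-base")
  s_cfg <- preset_config("student-small")
  # Base: 2:1 on the text encoder, 3:1 on the fusion module
  expect_equal(build_layer_map(t_cfg$text_layers, b_cfg$text_layers)$hidden_map,
               seq(2, 12, by = 2))
  expect_equal(build_layer_map(t_cfg$fusion_layers, b_cfg$fusion_layers)$hidden_map,
               c(3, 6))
  # Small: 3:1 on the text encoder, 6:1 on the fusion module
  expect_equal(build_layer_map(t_cfg$text_layers, s_cfg$text_layers)$hidden_map,
               c(3, 6, 9, 12))
  expect_equal(build_layer_map(t_cfg$fusion_layers, s_cfg$fusion_layers)$hidden_map,
               6L)
})

test_that("scaling student states away from the teacher increases the hidden loss", {
  withr::with_seed(83, {
    teacher <- list(matrix(rnorm(20), 4, 5))
    student <- list(matrix(rnorm(20), 4, 5))
  })
  map <- build_layer_map(1, 1)
  base <- hidden_distillation_loss(student, teacher, map)
  grown <- hidden_distillation_loss(lapply(student, function(m) m * 1.05),
                                    teacher, map)
  # local sensitivity away from the matched point
  expect_false(isTRUE(all.equal(base, grown)))
})

test_that("distillation gradients flow to the student only; the teacher is untouched", {
  student <- with_param_nodes(toy_student())
  teacher <- toy_teacher()
  digest_before <- params_digest(teacher$params)
  ids <- toy_ids(2)
  corpus <- toy_corpus()
  rec_s <- forward_with_records(student, corpus$pixels[1:2], ids,
                                with_grad = TRUE)
  rec_t <- forward_with_records(teacher, corpus$pixels[1:2], ids)
  dl <- distillation_losses(rec_s, rec_t)
  expect_gt(ag_value(dl$hid), 0)
  expect_gt(ag_value(dl$attn), 0)
  mvldistill::ag_backward(ag_sum_scalars(list(dl$hid, dl$attn)))
  grads <- Filter(Negate(is.null),
                  lapply(student$.param_nodes, function(nd) nd$grad))
  expect_gt(length(grads), 20)
  # the teacher record holds plain arrays: no gradient state exists at all
  expect_false(mvldistill:::is_agnode(rec_t$image_hidden[[1]]))
  expect_identical(params_digest(teacher$params), digest_before)
  # both-zero fixed point: a student identical to the teacher
  rec_t2 <- forward_with_records(teacher, corpus$pixels[1:2], ids)
  dl0 <- distillation_losses(rec_t2, rec_t)
  expect_identical(dl0$hid, 0)
  expect_identical(dl0$attn, 0)
})
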