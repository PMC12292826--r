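# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# 8-pair toy corpus (32 px images, 8 px patches) on disk.
toy_corpus_dir <- function() {
  if (is.null(.fixtures$corpus_dir)) {
    dir <- file.path(tempdir(), "mvld-toy-corpus")
    generate_corpus(8, dir, image_size = 32, patch_size = 8, seed = 42)
    .fixtures$corpus_dir <- dir
  }
  .fixtures$corpus_dir
}

toy_corpus <- function() {
  if (is.null(.fixtures$corpus)) .fixtures$corpus <- load_corpus(toy_corpus_dir())
  .fixtures$corpus
}

toy_tok <- function() {
  if (is.null(.fixtures$tok))
    .fixtures$tok <- load_tokenizer(file.path(toy_corpus_dir(), "vocab.txt"))
  .fixtures$tok
}

toy_student <- function() {
  if (is.null(.fixtures$student))
    .fixtures$student <- build_model(preset_config("toy-student"), seed = 3)
  .fixtures$student
}

toy_teacher <- function() {
  if (is.null(.fixtures$teacher))
    .fixtures$teacher <- build_model(preset_config("toy-teacher"), seed = 4)
  .fixtures$teacher
}

toy_ids <- function(n = 8) {
  cfg <- preset_config("toy-student")
  encode_text(toy_tok(), toy_corpus()$caption, cfg$max_text_len)[seq_len(n), , drop = FALSE]
}

# internal autodiff ops exercised directly by the engine tests
ag_value <- mvldistill:::ag_value
ag_linear <- mvldistill:::ag_linear
ag_tlinear <- mvldistill:::ag_tlinear
ag_layernorm <- mvldistill:::ag_layernorm
ag_gelu <- mvldistill:::ag_gelu
ag_rows <- mvldistill:::ag_rows
ag_scatter_rows <- mvldistill:::ag_scatter_rows
ag_attn_core <- mvldistill:::ag_attn_core
ag_mse <- mvldistill:::ag_mse
ag_cross_entropy <- mvldistill:::ag_cross_entropy
ag_sum_scalars <- mvldistill:::ag_sum_scalars
ag_add <- mvldistill:::ag_add
ag_scale <- mvldistill:::ag_scale
patchify <- mvldistill:::patchify

# central-difference numerical gradient of f at x
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
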