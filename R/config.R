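# Encoder configurations, architecture presets, and parameter-shape
# enumeration (the latter lets parameter counts be computed without
# allocating weights, which matters for the full-scale presets).

#' Encoder/architecture configuration
#'
#' Describes one model stack: the image and text uni-modal encoders, the
#' two-stream co-attention fusion module, the masked-image-modelling decoder
#' and the task heads. The same structure describes teachers and students;
#' they differ only in depth (and possibly decoder size).
#'
#' @param image_layers,text_layers,fusion_layers Transformer depth of the
#'   image encoder, text encoder, and fusion module (all >= 1).
#' @param hidden_dim Width `d` of every encoder stream; must be divisible by
#'   `num_heads`.
#' @param num_heads Attention heads `h`.
#' @param mlp_ratio Feed-forward expansion factor (hidden size of the MLP is
#'   `mlp_ratio * hidden_dim`).
#' @param patch_size,image_size Patch edge and (square) image edge in pixels;
#'   `image_size` must be divisible by `patch_size`. The number of patches is
#'   `N = (image_size / patch_size)^2`.
#' @param image_channels Input channels (grayscale corpora replicate to this).
#' @param vocab_size Tokenizer vocabulary size.
#' @param max_text_len Token sequence length `T` (>= 2, for `[CLS]`/`[SEP]`).
#' @param decoder_layers,decoder_dim Depth and width of the pixel
#'   reconstruction decoder.
#' @param role `"teacher"` or `"student"`.
#' @param name Optional preset name carried for reporting.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(image_layers, text_layers, fusion_layers,
                           hidden_dim, num_heads, mlp_ratio = 4,
                           patch_size, image_size, image_channels = 1,
                           vocab_size, max_text_len,
                           decoder_layers = 2, decoder_dim = 16,
                           role = c("student", "teacher"),
                           name = NULL) {
  role <- match.arg(role)
  cfg <- structure(list(
    image_layers = as.integer(image_layers),
    text_layers = as.integer(text_layers),
    fusion_layers = as.integer(fusion_layers),
    hidden_dim = as.integer(hidden_dim),
    num_heads = as.integer(num_heads),
    mlp_ratio = mlp_ratio,
    patch_size = as.integer(patch_size),
    image_size = as.integer(image_size),
    image_channels = as.integer(image_channels),
    vocab_size = as.integer(vocab_size),
    max_text_len = as.integer(max_text_len),
    decoder_layers = as.integer(decoder_layers),
    decoder_dim = as.integer(decoder_dim),
    role = role,
    name = name %||% "custom"
  ), class = "encoder_config")
  validate_config(cfg)
  cfg
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf(
    "<encoder_config '%s' (%s)> layers %d/%d/%d, d=%d, h=%d, patch %d/%d px, vocab %d, T=%d, decoder %d@%d\n",
    x$name, x$role, x$image_layers, x$text_layers, x$fusion_layers,
    x$hidden_dim, x$num_heads, x$patch_size, x$image_size,
    x$vocab_size, x$max_text_len, x$decoder_layers, x$decoder_dim))
  invisible(x)
}

validate_config <- function(cfg) {
  bad <- function(msg) stop("invalid encoder_config: ", msg, call. = FALSE)
  if (cfg$hidden_dim %% cfg$num_heads != 0)
    bad(sprintf("hidden_dim (%d) not divisible by num_heads (%d)",
                cfg$hidden_dim, cfg$num_heads))
  if (cfg$image_size %% cfg$patch_size != 0)
    bad(sprintf("image_size (%d) not divisible by patch_size (%d)",
                cfg$image_size, cfg$patch_size))
  if (any(c(cfg$image_layers, cfg$text_layers, cfg$fusion_layers,
            cfg$decoder_layers) < 1))
    bad("all layer counts must be >= 1")
  if (cfg$max_text_len < 2)
    bad("max_text_len must be >= 2 (room for [CLS]/[SEP])")
  if (cfg$vocab_size < 6) bad("vocab_size must cover the special tokens")
  if (cfg$mlp_ratio <= 0) bad("mlp_ratio must be positive")
  invisible(cfg)
}

#' Number of image patches for a configuration
#' @param cfg An `encoder_config`.
#' @return Integer `N = (image_size/patch_size)^2`.
#' @export
num_patches <- function(cfg) (cfg$image_size %/% cfg$patch_size)^2

# pixels per patch row-vector
patch_dim <- function(cfg) cfg$patch_size^2 * cfg$image_channels

#' Architecture presets
#'
#' `"teacher-m3ae"`, `"student-base"` and `"student-small"` are the published
#' full-scale stacks (12/12/6, 7/6/2 and 5/4/1 layers at width 768 with
#' 16-px patches on 288-px images); `"toy-teacher"` and `"toy-student"` are
#' CPU-sized counterparts (width 32, 8-px patches on 32-px images) used
#' throughout the test suite and the default pipeline profile.
#'
#' @param name Preset name.
#' @param vocab_size Override the vocabulary size (the toy presets default to
#'   the bundled toy vocabulary; full-scale presets default to a RoBERTa-sized
#'   vocabulary of 50265).
#' @return An `encoder_config`.
#' @export
preset_config <- function(name = c("teacher-m3ae", "student-base",
                                   "student-small", "toy-teacher",
                                   "toy-student"),
                          vocab_size = NULL) {
  name <- match.arg(name)
  full <- function(il, tl, fl, role) encoder_config(
    image_layers = il, text_layers = tl, fusion_layers = fl,
    hidden_dim = 768, num_heads = 12, mlp_ratio = 4,
    patch_size = 16, image_size = 288, image_channels = 3,
    vocab_size = vocab_size %||% 50265L, max_text_len = 64,
    decoder_layers = 6, decoder_dim = 512, role = role, name = name)
  toy <- function(il, tl, fl, role) encoder_config(
    image_layers = il, text_layers = tl, fusion_layers = fl,
    hidden_dim = 32, num_heads = 2, mlp_ratio = 4,
    patch_size = 8, image_size = 32, image_channels = 1,
    vocab_size = vocab_size %||% length(default_vocab()), max_text_len = 24,
    decoder_layers = 2, decoder_dim = 16, role = role, name = name)
  switch(name,
    "teacher-m3ae"  = full(12, 12, 6, "teacher"),
    "student-base"  = full(7, 6, 2, "student"),
    "student-small" = full(5, 4, 1, "student"),
    "toy-teacher"   = toy(4, 4, 2, "teacher"),
    "toy-student"   = toy(2, 2, 1, "student"))
}

# ---- parameter shape enumeration --------------------------------------------

.block_shapes <- function(prefix, d, mlp_hidden, cross = FALSE) {
  att <- function(tag) {
    s <- list()
    s[[paste0(prefix, tag, ".Wq")]] <- c(d, d)
    s[[paste0(prefix, tag, ".bq")]] <- d
    s[[paste0(prefix, tag, ".Wk")]] <- c(d, d)
    s[[paste0(prefix, tag, ".bk")]] <- d
    s[[paste0(prefix, tag, ".Wv")]] <- c(d, d)
    s[[paste0(prefix, tag, ".bv")]] <- d
    s[[paste0(prefix, tag, ".Wo")]] <- c(d, d)
    s[[paste0(prefix, tag, ".bo")]] <- d
    s
  }
  ln <- function(tag) {
    s <- list()
    s[[paste0(prefix, tag, ".g")]] <- d
    s[[paste0(prefix, tag, ".b")]] <- d
    s
  }
  s <- c(ln("ln1"), att("attn"))
  if (cross) s <- c(s, ln("lnx"), att("xattn"))
  s <- c(s, ln("ln2"))
  s[[paste0(prefix, "mlp.W1")]] <- c(d, mlp_hidden)
  s[[paste0(prefix, "mlp.b1")]] <- mlp_hidden
  s[[paste0(prefix, "mlp.W2")]] <- c(mlp_hidden, d)
  s[[paste0(prefix, "mlp.b2")]] <- d
  s
}

#' Enumerate every weight array's name and shape for a configuration
#'
#' The authoritative description of the architecture's parameters; model
#' building allocates exactly these arrays and parameter counting sums their
#' element counts. Component prefixes are `image.`, `text.`, `fusion.`, and
#' `heads.` (decoder + output heads).
#'
#' @param cfg An `encoder_config`.
#' @return Named list mapping parameter name to its dim vector.
#' @export
param_shapes <- function(cfg) {
  d <- cfg$hidden_dim
  mh <- as.integer(round(cfg$mlp_ratio * d))
  N <- num_patches(cfg)
  pd <- patch_dim(cfg)
  dd <- cfg$decoder_dim
  mhd <- as.integer(round(cfg$mlp_ratio * dd))
  s <- list()
  # image encoder
  s[["image.patch_proj.W"]] <- c(pd, d)
  s[["image.patch_proj.b"]] <- d
  s[["image.cls"]] <- c(1, d)
  s[["image.pos"]] <- c(N + 1, d)
  for (i in seq_len(cfg$image_layers))
    s <- c(s, .block_shapes(sprintf("image.blocks.%d.", i), d, mh))
  s[["image.final_ln.g"]] <- d
  s[["image.final_ln.b"]] <- d
  # text encoder
  s[["text.tok_emb"]] <- c(cfg$vocab_size, d)
  s[["text.pos"]] <- c(cfg$max_text_len, d)
  for (i in seq_len(cfg$text_layers))
    s <- c(s, .block_shapes(sprintf("text.blocks.%d.", i), d, mh))
  s[["text.final_ln.g"]] <- d
  s[["text.final_ln.b"]] <- d
  # fusion module: two streams, each with self-attn + cross-attn + MLP
  for (stream in c("img", "txt")) {
    for (i in seq_len(cfg$fusion_layers))
      s <- c(s, .block_shapes(sprintf("fusion.%s.%d.", stream, i), d, mh,
                              cross = TRUE))
    s[[sprintf("fusion.%s_final_ln.g", stream)]] <- d
    s[[sprintf("fusion.%s_final_ln.b", stream)]] <- d
  }
  # heads: reconstruction decoder, tied-MLM bias, matching head
  s[["heads.dec.proj.W"]] <- c(d, dd)
  s[["heads.dec.proj.b"]] <- dd
  s[["heads.dec.mask_token"]] <- c(1, dd)
  s[["heads.dec.pos"]] <- c(N + 1, dd)
  for (i in seq_len(cfg$decoder_layers))
    s <- c(s, .block_shapes(sprintf("heads.dec.blocks.%d.", i), dd, mhd))
  s[["heads.dec.final_ln.g"]] <- dd
  s[["heads.dec.final_ln.b"]] <- dd
  s[["heads.dec.out.W"]] <- c(dd, pd)
  s[["heads.dec.out.b"]] <- pd
  s[["heads.mlm_bias"]] <- cfg$vocab_size
  s[["heads.itm.W"]] <- c(d, 2)
  s[["heads.itm.b"]] <- 2
  s
}

#' Parameter counts from a configuration (no allocation)
#'
#' @param cfg An `encoder_config`.
#' @return Named numeric vector with `total` and the per-component
#'   breakdown (`image`, `text`, `fusion`, `heads`).
#' @export
count_parameters_config <- function(cfg) {
  shapes <- param_shapes(cfg)
  sizes <- vapply(shapes, prod, numeric(1))
  comp <- sub("\\..*$", "", names(shapes))
  out <- tapply(sizes, comp, sum)
  c(total = sum(sizes),
    image = out[["image"]], text = out[["text"]],
    fusion = out[["fusion"]], heads = out[["heads"]])
}
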