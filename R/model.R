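# Model core: dual-stream transformer encoders with a two-stream
# co-attention fusion module, a pixel-reconstruction decoder and task heads.
# Forward passes run on batch-stacked matrices ((batch * seq) x d) through
# the autodiff ops in autograd.R; with plain-matrix parameters the same code
# is the gradient-free path used for frozen teachers.

#' Build a model from a configuration
#'
#' Allocates every weight array named by [param_shapes()] and initialises it
#' from the global RNG: truncated normal (sd 0.02, clipped at 2 sd) for
#' projections and embeddings, ones/zeros for layer-norm gains/biases, zeros
#' for linear biases.
#'
#' @param config An `encoder_config`.
#' @param seed Optional integer; when given, `set.seed(seed)` is called first
#'   so builds are reproducible.
#' @return A `vl_model`: list with `config` and `params` (named list of
#'   matrices/vectors).
#' @export
build_model <- function(config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  shapes <- param_shapes(config)
  params <- vector("list", length(shapes))
  names(params) <- names(shapes)
  for (nm in names(shapes)) {
    dm <- shapes[[nm]]
    n <- prod(dm)
    is_ln_gain <- grepl("(final_ln|ln1|ln2|lnx)\\.g$", nm)
    is_bias <- grepl("\\.(b|bq|bk|bv|bo|b1|b2)$", nm) || grepl("_bias$", nm)
    v <- if (is_ln_gain) rep(1, n)
      else if (is_bias) rep(0, n)
      else trunc_normal(n)
    params[[nm]] <- if (length(dm) == 2L) matrix(v, dm[1], dm[2]) else v
  }
  structure(list(config = config, params = params), class = "vl_model")
}

#' @export
print.vl_model <- function(x, ...) {
  cnt <- count_parameters(x)
  cat(sprintf("<vl_model '%s' (%s)> %s parameters\n",
              x$config$name, x$config$role,
              format(cnt["total"], big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a built model
#'
#' @param model A `vl_model`.
#' @return Named numeric vector: `total` plus the per-component breakdown
#'   (`image`, `text`, `fusion`, `heads`). The total equals the sum of the
#'   components exactly.
#' @export
count_parameters <- function(model) {
  sizes <- vapply(model$params, length, numeric(1))
  comp <- sub("\\..*$", "", names(sizes))
  out <- tapply(sizes, comp, sum)
  c(total = sum(sizes),
    image = out[["image"]], text = out[["text"]],
    fusion = out[["fusion"]], heads = out[["heads"]])
}

# Split an image into row-major patch row-vectors (N x patch_dim).
patchify <- function(pixels, patch_size) {
  size <- nrow(pixels)
  grid <- size %/% patch_size
  N <- grid * grid
  out <- matrix(0, N, patch_size * patch_size)
  k <- 0L
  for (pr in seq_len(grid)) {
    rows <- ((pr - 1L) * patch_size + 1L):(pr * patch_size)
    for (pc in seq_len(grid)) {
      cols <- ((pc - 1L) * patch_size + 1L):(pc * patch_size)
      k <- k + 1L
      out[k, ] <- as.numeric(pixels[rows, cols])
    }
  }
  out
}

# Reassemble patch row-vectors into an image matrix (inverse of patchify).
unpatchify <- function(patches, patch_size, image_size) {
  grid <- image_size %/% patch_size
  img <- matrix(0, image_size, image_size)
  k <- 0L
  for (pr in seq_len(grid)) {
    rows <- ((pr - 1L) * patch_size + 1L):(pr * patch_size)
    for (pc in seq_len(grid)) {
      cols <- ((pc - 1L) * patch_size + 1L):(pc * patch_size)
      k <- k + 1L
      img[rows, cols] <- matrix(patches[k, ], patch_size, patch_size)
    }
  }
  img
}

# One pre-norm transformer block on a stacked batch. Returns list(out, attns).
.block_forward <- function(x, P, prefix, nheads, batch, kv = NULL) {
  g <- function(tag) P[[paste0(prefix, tag)]]
  h <- ag_layernorm(x, g("ln1.g"), g("ln1.b"))
  core <- ag_attn_core(ag_linear(h, g("attn.Wq"), g("attn.bq")),
                       ag_linear(h, g("attn.Wk"), g("attn.bk")),
                       ag_linear(h, g("attn.Wv"), g("attn.bv")),
                       nheads, batch)
  x <- ag_add(x, ag_linear(core$ctx, g("attn.Wo"), g("attn.bo")))
  xattn <- NULL
  if (!is.null(kv)) {
    hq <- ag_layernorm(x, g("lnx.g"), g("lnx.b"))
    xcore <- ag_attn_core(ag_linear(hq, g("xattn.Wq"), g("xattn.bq")),
                          ag_linear(kv, g("xattn.Wk"), g("xattn.bk")),
                          ag_linear(kv, g("xattn.Wv"), g("xattn.bv")),
                          nheads, batch)
    x <- ag_add(x, ag_linear(xcore$ctx, g("xattn.Wo"), g("xattn.bo")))
    xattn <- xcore$attn
  }
  h2 <- ag_layernorm(x, g("ln2.g"), g("ln2.b"))
  m <- ag_linear(ag_gelu(ag_linear(h2, g("mlp.W1"), g("mlp.b1"))),
                 g("mlp.W2"), g("mlp.b2"))
  list(out = ag_add(x, m), attn = core$attn, xattn = xattn)
}

#' Forward pass with full records
#'
#' Runs image encoder, text encoder, the co-attention fusion module and any
#' requested task heads, recording every layer's hidden states and
#' (row-stochastic) attention maps. When `patch_mask` is given, only
#' unmasked patches (plus the image summary token) enter the image encoder;
#' when `token_plan` is given, it is applied to the token ids before
#' encoding. With `with_grad = TRUE` the returned record holds autodiff
#' nodes (use [ag_value()] to read values); otherwise plain arrays.
#'
#' @param model A `vl_model`.
#' @param images List of pixel matrices in `[0, 1]` (one per sample), each
#'   `image_size x image_size`.
#' @param token_ids Integer matrix (batch x `max_text_len`).
#' @param patch_mask Optional list of `patch_mask` objects, one per sample
#'   (all with the same budget).
#' @param token_plan Optional list of `token_mask_plan` objects.
#' @param with_grad Track gradients (students) or not (teachers).
#' @param heads Character subset of `c("mlm", "mim", "itm")` to evaluate.
#' @return A `forward_record`; see Details.
#' @details The record fields: `image_hidden`, `text_hidden`,
#'   `fusion_image_hidden`, `fusion_text_hidden` (lists over layers of
#'   stacked `(batch*seq) x d` matrices); `image_attn`, `text_attn`,
#'   `fusion_image_attn`, `fusion_text_attn`, `fusion_image_xattn`,
#'   `fusion_text_xattn` (lists over layers of `seq x seq x heads x batch`
#'   arrays); `pooled_joint` (`batch x d`); per-head outputs `mlm_logits`
#'   (masked positions x vocab), `mim_pred` (list per sample, `N x
#'   patch_dim`), `itm_logits` (`batch x 2`); plus geometry metadata.
#' @export
forward_with_records <- function(model, images, token_ids,
                                 patch_mask = NULL, token_plan = NULL,
                                 with_grad = FALSE,
                                 heads = character(0),
                                 .visible_order = NULL) {
  cfg <- model$config
  N <- num_patches(cfg)
  Tn <- cfg$max_text_len
  B <- length(images)
  if (is.null(dim(token_ids))) token_ids <- matrix(token_ids, nrow = 1)
  stopifnot(nrow(token_ids) == B, ncol(token_ids) == Tn)
  for (img in images)
    if (nrow(img) != cfg$image_size || ncol(img) != cfg$image_size)
      stop("image size does not match config", call. = FALSE)
  if (!is.null(patch_mask)) {
    lens <- vapply(patch_mask, function(m) length(m$mask), integer(1))
    if (any(lens != N))
      stop("patch mask length does not match the patch grid", call. = FALSE)
    vis_counts <- vapply(patch_mask, function(m) sum(m$mask == 0L), integer(1))
    if (length(unique(vis_counts)) != 1L)
      stop("all samples in a batch must share one mask budget", call. = FALSE)
  }

  P <- if (with_grad) {
    if (is.null(model$.param_nodes))
      stop("call with_grad forwards through pretrain()/with_param_nodes()",
           call. = FALSE)
    model$.param_nodes
  } else model$params
  h <- cfg$num_heads; d <- cfg$hidden_dim

  # ---- token ids after masking plan
  ids_in <- token_ids
  if (!is.null(token_plan)) {
    tok <- attr(token_plan, "mask_id")
    if (is.null(tok)) stop("token_plan list needs a 'mask_id' attribute")
    for (b in seq_len(B))
      ids_in[b, ] <- apply_token_plan(token_ids[b, ], token_plan[[b]], tok)
  }

  # ---- image embedding (visible patches + summary token)
  vis <- lapply(seq_len(B), function(b) {
    if (is.null(patch_mask)) seq_len(N) else which(patch_mask[[b]]$mask == 0L)
  })
  if (!is.null(.visible_order)) vis <- .visible_order
  V <- length(vis[[1]])
  Si <- V + 1L
  patch_rows <- do.call(rbind, lapply(seq_len(B), function(b) {
    p <- patchify(images[[b]], cfg$patch_size)[vis[[b]], , drop = FALSE]
    if (cfg$image_channels > 1L) p <- do.call(cbind, rep(list(p), cfg$image_channels))
    p
  }))
  emb <- ag_linear(patch_rows, P[["image.patch_proj.W"]],
                   P[["image.patch_proj.b"]])
  cls_rep <- ag_rows(P[["image.cls"]], rep(1L, B))
  map_patch <- integer(B * Si); map_cls <- integer(B * Si)
  pos_idx <- integer(B * Si)
  for (b in seq_len(B)) {
    base <- (b - 1L) * Si
    map_cls[base + 1L] <- b
    map_patch[base + 1L + seq_len(V)] <- (b - 1L) * V + seq_len(V)
    pos_idx[base + 1L] <- 1L
    pos_idx[base + 1L + seq_len(V)] <- vis[[b]] + 1L
  }
  zero_d <- numeric(d)
  xi <- ag_add(ag_scatter_rows(emb, zero_d, map_patch, B * Si),
               ag_scatter_rows(cls_rep, zero_d, map_cls, B * Si))
  xi <- ag_add(xi, ag_rows(P[["image.pos"]], pos_idx))

  image_hidden <- vector("list", cfg$image_layers)
  image_attn <- vector("list", cfg$image_layers)
  for (l in seq_len(cfg$image_layers)) {
    blk <- .block_forward(xi, P, sprintf("image.blocks.%d.", l), h, B)
    xi <- blk$out
    image_hidden[[l]] <- xi
    image_attn[[l]] <- blk$attn
  }
  img_feat <- ag_layernorm(xi, P[["image.final_ln.g"]], P[["image.final_ln.b"]])

  # ---- text embedding
  tok_idx <- as.vector(t(ids_in))
  xt <- ag_add(ag_rows(P[["text.tok_emb"]], tok_idx),
               ag_rows(P[["text.pos"]], rep(seq_len(Tn), B)))
  text_hidden <- vector("list", cfg$text_layers)
  text_attn <- vector("list", cfg$text_layers)
  for (l in seq_len(cfg$text_layers)) {
    blk <- .block_forward(xt, P, sprintf("text.blocks.%d.", l), h, B)
    xt <- blk$out
    text_hidden[[l]] <- xt
    text_attn[[l]] <- blk$attn
  }
  txt_feat <- ag_layernorm(xt, P[["text.final_ln.g"]], P[["text.final_ln.b"]])

  # ---- co-attention fusion (two streams, parallel update per layer)
  fi <- img_feat; ft <- txt_feat
  fusion_image_hidden <- vector("list", cfg$fusion_layers)
  fusion_text_hidden <- vector("list", cfg$fusion_layers)
  fusion_image_attn <- vector("list", cfg$fusion_layers)
  fusion_text_attn <- vector("list", cfg$fusion_layers)
  fusion_image_xattn <- vector("list", cfg$fusion_layers)
  fusion_text_xattn <- vector("list", cfg$fusion_layers)
  for (l in seq_len(cfg$fusion_layers)) {
    bi <- .block_forward(fi, P, sprintf("fusion.img.%d.", l), h, B, kv = ft)
    bt <- .block_forward(ft, P, sprintf("fusion.txt.%d.", l), h, B, kv = fi)
    fi <- bi$out; ft <- bt$out
    fusion_image_hidden[[l]] <- fi
    fusion_text_hidden[[l]] <- ft
    fusion_image_attn[[l]] <- bi$attn
    fusion_text_attn[[l]] <- bt$attn
    fusion_image_xattn[[l]] <- bi$xattn
    fusion_text_xattn[[l]] <- bt$xattn
  }
  fi <- ag_layernorm(fi, P[["fusion.img_final_ln.g"]], P[["fusion.img_final_ln.b"]])
  ft <- ag_layernorm(ft, P[["fusion.txt_final_ln.g"]], P[["fusion.txt_final_ln.b"]])

  cls_i <- ag_rows(fi, (seq_len(B) - 1L) * Si + 1L)
  cls_t <- ag_rows(ft, (seq_len(B) - 1L) * Tn + 1L)
  pooled <- ag_scale(ag_add(cls_i, cls_t), 0.5)

  rec <- list(config = cfg, batch = B, seq_image = Si, seq_text = Tn,
              visible = vis, ids_in = ids_in, token_ids = token_ids,
              image_hidden = image_hidden, image_attn = image_attn,
              text_hidden = text_hidden, text_attn = text_attn,
              fusion_image_hidden = fusion_image_hidden,
              fusion_text_hidden = fusion_text_hidden,
              fusion_image_attn = fusion_image_attn,
              fusion_text_attn = fusion_text_attn,
              fusion_image_xattn = fusion_image_xattn,
              fusion_text_xattn = fusion_text_xattn,
              pooled_joint = pooled)

  # ---- heads
  if ("mlm" %in% heads) {
    stopifnot(!is.null(token_plan))
    rows <- unlist(lapply(seq_len(B), function(b) {
      (b - 1L) * Tn + token_plan[[b]]$positions
    }))
    targets <- unlist(lapply(token_plan, `[[`, "target_ids"))
    if (length(rows) > 0) {
      rec$mlm_logits <- ag_tlinear(ag_rows(ft, rows),
                                   P[["text.tok_emb"]], P[["heads.mlm_bias"]])
    } else rec$mlm_logits <- NULL
    rec$mlm_targets <- targets
  }
  if ("mim" %in% heads) {
    stopifnot(!is.null(patch_mask))
    proj <- ag_linear(fi, P[["heads.dec.proj.W"]], P[["heads.dec.proj.b"]])
    Sd <- N + 1L
    map <- integer(B * Sd)
    for (b in seq_len(B)) {
      base <- (b - 1L) * Sd
      map[base + 1L] <- (b - 1L) * Si + 1L
      map[base + 1L + vis[[b]]] <- (b - 1L) * Si + 1L + seq_len(V)
    }
    xd <- ag_scatter_rows(proj, P[["heads.dec.mask_token"]], map, B * Sd)
    xd <- ag_add(xd, ag_rows(P[["heads.dec.pos"]], rep(seq_len(Sd), B)))
    for (l in seq_len(cfg$decoder_layers)) {
      blk <- .block_forward(xd, P, sprintf("heads.dec.blocks.%d.", l), 1L, B)
      xd <- blk$out
    }
    xd <- ag_layernorm(xd, P[["heads.dec.final_ln.g"]], P[["heads.dec.final_ln.b"]])
    pred <- ag_linear(xd, P[["heads.dec.out.W"]], P[["heads.dec.out.b"]])
    rec$mim_pred <- pred          # (B*(N+1)) x patch_dim; row 1 of each block is the summary slot
    rec$mim_seq <- Sd
  }
  if ("itm" %in% heads) {
    rec$itm_logits <- ag_linear(pooled, P[["heads.itm.W"]], P[["heads.itm.b"]])
  }
  structure(rec, class = "forward_record")
}

#' Extract one sample's per-patch prediction matrix from a record
#' @param rec A `forward_record` produced with the `"mim"` head.
#' @param b Sample index.
#' @return `N x patch_dim` matrix of predicted pixels.
#' @export
mim_prediction <- function(rec, b) {
  Sd <- rec$mim_seq
  rows <- (b - 1L) * Sd + 1L + seq_len(Sd - 1L)
  ag_value(rec$mim_pred)[rows, , drop = FALSE]
}

#' Extract an `N x N` guidance attention map from a forward record
#'
#' Head-averaged self-attention of the last image-encoder layer (`"uni"`) or
#' of the last fusion layer's image stream (`"mul"`), with the summary-token
#' row/column dropped and rows renormalised to sum to one. Requires an
#' unmasked forward (all patches visible).
#'
#' @param rec A `forward_record`.
#' @param which `"uni"` or `"mul"`.
#' @param b Sample index.
#' @return `N x N` matrix with row sums 1.
#' @export
guidance_map <- function(rec, which = c("uni", "mul"), b = 1L) {
  which <- match.arg(which)
  A <- ag_value(switch(which,
    uni = rec$image_attn[[length(rec$image_attn)]],
    mul = rec$fusion_image_attn[[length(rec$fusion_image_attn)]]))
  S <- dim(A)[1]
  h <- dim(A)[3]
  M <- matrix(A[, , 1, b], S, S)
  if (h > 1) for (i in 2:h) M <- M + matrix(A[, , i, b], S, S)
  M <- M[-1, -1, drop = FALSE] / h
  M / rowSums(M)
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file checkpoint holding the weights, the configuration (also as a
#' JSON string) and a config digest used to refuse mismatched loads.
#'
#' @param model A `vl_model`.
#' @param path Output file.
#' @param extra Optional named list stored alongside (optimizer state, RNG
#'   state, step counters ...).
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  obj <- list(config = model$config,
              config_json = jsonlite::toJSON(unclass(model$config),
                                             auto_unbox = TRUE),
              config_digest = object_digest(unclass(model$config)),
              params = model$params,
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file from [save_checkpoint()].
#' @param expect_config Optional `encoder_config`; if supplied the load is
#'   refused unless the stored config digest matches.
#' @return A `vl_model` with attribute `"extra"`.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  obj <- readRDS(path)
  if (!is.null(expect_config)) {
    if (!identical(object_digest(unclass(expect_config)), obj$config_digest))
      stop("checkpoint config digest does not match the expected configuration",
           call. = FALSE)
  }
  model <- structure(list(config = obj$config, params = obj$params),
                     class = "vl_model")
  attr(model, "extra") <- obj$extra
  model
}

#' Wrap a model's parameters as autodiff leaves
#'
#' Returns a copy of the model whose forward passes with `with_grad = TRUE`
#' track gradients; leaves are in `$.param_nodes` (same names as `$params`).
#'
#' @param model A `vl_model`.
#' @return The model with parameter nodes attached.
#' @export
with_param_nodes <- function(model) {
  model$.param_nodes <- lapply(model$params, ag_param)
  model
}

# Forward with an explicit visible-patch ordering (used to verify that
# permuting patches together with their position indices is a no-op).
forward_visible_order <- function(model, img, ids, order) {
  rec <- forward_with_records(model, list(img), ids,
                              .visible_order = list(as.integer(order)))
  ag_value(rec$pooled_joint)
}
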