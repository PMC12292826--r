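# Mask/salience overlay rendering: side-by-side PNG panels comparing random
# and attention-guided masking for each corpus sample.

.mask_overlay <- function(pixels, mask, patch_size) {
  img <- pixels
  grid <- nrow(img) %/% patch_size
  for (j in which(mask == 1L)) {
    pr <- (j - 1L) %/% grid
    pc <- (j - 1L) %% grid
    rows <- pr * patch_size + seq_len(patch_size)
    cols <- pc * patch_size + seq_len(patch_size)
    img[rows, cols] <- 0.08
  }
  img
}

.salience_panel <- function(salience, image_size, patch_size) {
  grid <- image_size %/% patch_size
  s <- salience
  if (diff(range(s)) > 0) s <- (s - min(s)) / diff(range(s))
  img <- matrix(0, image_size, image_size)
  for (j in seq_along(s)) {
    pr <- (j - 1L) %/% grid
    pc <- (j - 1L) %% grid
    img[pr * patch_size + seq_len(patch_size),
        pc * patch_size + seq_len(patch_size)] <- s[j]
  }
  img
}

#' Render mask-comparison panels
#'
#' For each corpus sample writes one PNG panel: original image, random mask,
#' attention-guided mask (from the checkpointed model's own attention maps,
#' used for both the teacher and student contributions), and the salience
#' heat map.
#'
#' @param checkpoint Path to a checkpoint or a `vl_model`.
#' @param corpus_dir Corpus directory.
#' @param step Schedule step at which to evaluate `r` (within
#'   `[0, max_steps]`).
#' @param out_dir Output directory.
#' @param max_steps Schedule horizon (defaults to the checkpoint's recorded
#'   step when available, else 100).
#' @param r_start,r_end,mask_ratio Masking parameters.
#' @return Invisibly, the written file paths.
#' @export
visualize_masks <- function(checkpoint, corpus_dir, step, out_dir,
                            max_steps = NULL, r_start = 0.95, r_end = 0.3,
                            mask_ratio = 0.75) {
  model <- if (inherits(checkpoint, "vl_model")) checkpoint
    else load_checkpoint(checkpoint)
  if (is.null(max_steps)) {
    max_steps <- attr(model, "extra")$step %||% 100L
  }
  if (step < 0 || step > max_steps)
    stop("step must lie in [0, max_steps]", call. = FALSE)
  corpus <- load_corpus(corpus_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- mask_schedule(r_start, r_end, max_steps)
  tokenizer <- load_tokenizer(attr(corpus, "vocab_path"))
  cfg <- model$config
  N <- num_patches(cfg)
  ids <- encode_text(tokenizer, corpus$caption, cfg$max_text_len)
  masks <- compute_guided_mask_for_batch(model, model, corpus$pixels, ids,
                                         step, sched, mask_ratio)
  paths <- character(nrow(corpus))
  for (b in seq_len(nrow(corpus))) {
    px <- corpus$pixels[[b]]
    rnd <- random_patch_mask(N, mask_ratio)
    sal <- attr(masks[[b]], "salience")
    sep <- matrix(1, nrow(px), 2L)
    panel <- cbind(px, sep,
                   .mask_overlay(px, rnd$mask, cfg$patch_size), sep,
                   .mask_overlay(px, masks[[b]]$mask, cfg$patch_size), sep,
                   .salience_panel(sal, nrow(px), cfg$patch_size))
    paths[b] <- file.path(out_dir, sprintf("panel_%04d.png", b))
    png::writePNG(panel, paths[b])
  }
  invisible(paths)
}
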