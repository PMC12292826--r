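# Stage-1 pre-training loop: attention-guided masking, the three task
# branches, distillation on the masked-text branch, one AdamW step on the
# total loss, JSONL metrics and periodic checkpoints.

#' Pre-training run configuration
#'
#' @param student Preset name or `encoder_config` for the model being
#'   trained.
#' @param teacher Preset name, `encoder_config`, `vl_model`, path to a
#'   checkpoint, or `NULL`. With `NULL` the model trains standalone (random
#'   patch masking, no distillation) -- the mode used to prepare a teacher.
#' @param corpus_dir Directory from [generate_corpus()].
#' @param out_dir Output directory for metrics and checkpoints.
#' @param max_steps Total optimizer steps (also the masking schedule's
#'   horizon).
#' @param batch_size Pairs per step.
#' @param learning_rate,warmup_frac,weight_decay AdamW settings: linear
#'   warm-up for `warmup_frac * max_steps` steps then linear decay to zero.
#'   The default rate (1e-3) is the toy profile; full-scale runs mirror the
#'   published 1e-5.
#' @param r_start,r_end Progressive masking schedule endpoints.
#' @param mask_ratio Total patch masking budget fraction.
#' @param mlm_rate Token selection rate.
#' @param negative_fraction ITM flip probability.
#' @param distill,guided_mask Toggles for the distillation losses and
#'   attention-guided (vs random) patch masking; both require a teacher.
#' @param checkpoint_every Save a checkpoint every this many steps (the
#'   final step is always saved).
#' @param dump_masks Also write a `masks.jsonl` stream (one row per sample
#'   per step with the binary patch mask and, for guided masking, the
#'   salience vector).
#' @param seed Run seed.
#' @return A `run_config`.
#' @export
run_config <- function(student = "toy-student", teacher = NULL,
                       corpus_dir, out_dir = tempfile("run"),
                       max_steps = 100, batch_size = 8,
                       learning_rate = 1e-3, warmup_frac = 0.1,
                       weight_decay = 0.01,
                       r_start = 0.95, r_end = 0.3, mask_ratio = 0.75,
                       mlm_rate = 0.15, negative_fraction = 0.5,
                       distill = !is.null(teacher),
                       guided_mask = !is.null(teacher),
                       dump_masks = FALSE,
                       checkpoint_every = max_steps, seed = 1) {
  stopifnot(learning_rate > 0, max_steps >= 1,
            warmup_frac >= 0, warmup_frac < 1)
  if (is.null(teacher) && (isTRUE(distill) || isTRUE(guided_mask)))
    stop("distillation and guided masking require a teacher", call. = FALSE)
  structure(list(student = student, teacher = teacher,
                 corpus_dir = corpus_dir, out_dir = out_dir,
                 max_steps = as.integer(max_steps),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, warmup_frac = warmup_frac,
                 weight_decay = weight_decay,
                 r_start = r_start, r_end = r_end, mask_ratio = mask_ratio,
                 mlm_rate = mlm_rate, negative_fraction = negative_fraction,
                 distill = distill, guided_mask = guided_mask,
                 dump_masks = dump_masks,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.resolve_model <- function(x, fallback_seed) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "vl_model")) return(x)
  if (inherits(x, "encoder_config")) return(build_model(x, seed = fallback_seed))
  if (is.character(x) && file.exists(x)) return(load_checkpoint(x))
  if (is.character(x)) return(build_model(preset_config(x), seed = fallback_seed))
  stop("cannot resolve a model from: ", deparse(x), call. = FALSE)
}

# Token masking plans for a batch, tagged with the tokenizer's [MASK] id.
make_token_plans <- function(ids, tokenizer, rate) {
  excl <- c(tokenizer$pad_id, tokenizer$cls_id, tokenizer$sep_id)
  plans <- lapply(seq_len(nrow(ids)), function(b) {
    plan_token_masking(ids[b, ], special_ids = excl, rate = rate,
                       vocab_size = length(tokenizer$vocab))
  })
  attr(plans, "mask_id") <- tokenizer$mask_id
  plans
}

#' Run Stage-1 pre-training
#'
#' Per step: (1) a gradient-free teacher + student forward on the unmasked
#' pairs computes the attention-guided patch masks; (2) the three task
#' branches run their own forwards (masked text + full image for MLM, full
#' text + masked image for MIM, full pairs with in-batch negatives for ITM);
#' (3) hidden and attention distillation are computed on the masked-text
#' branch; (4) one AdamW step on the unweighted total. A JSONL metrics row
#' per step records every loss component, the schedule value `r` and the
#' learning rate. Fully reproducible given the seed.
#'
#' @param config A [run_config()].
#' @param resume_from Optional checkpoint path written by a previous run of
#'   the same configuration; training continues from its recorded step with
#'   restored optimizer and RNG state.
#' @return A `pretrain_result`: list with `student` (trained `vl_model`),
#'   `teacher` (or NULL), `metrics` (tibble), `checkpoint` (final path),
#'   `metrics_path`, and `config`.
#' @export
pretrain <- function(config, resume_from = NULL) {
  stopifnot(inherits(config, "run_config"))
  corpus <- load_corpus(config$corpus_dir)
  tokenizer <- load_tokenizer(attr(corpus, "vocab_path"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(config$seed)
  teacher <- .resolve_model(config$teacher, fallback_seed = config$seed + 1L)
  student <- .resolve_model(config$student, fallback_seed = config$seed)
  cfg <- student$config
  if (!is.null(teacher)) {
    if (num_patches(teacher$config) != num_patches(cfg))
      stop("teacher and student patch grids differ", call. = FALSE)
    if (teacher$config$num_heads != cfg$num_heads)
      stop("teacher and student head counts differ", call. = FALSE)
  }
  N <- num_patches(cfg)
  sched <- mask_schedule(config$r_start, config$r_end, config$max_steps)
  opt <- adamw_init(student$params)
  start_step <- 0L
  set.seed(config$seed + 17L)

  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from, expect_config = cfg)
    student$params <- ck$params
    extra <- attr(ck, "extra")
    opt <- extra$opt
    start_step <- extra$step
    assign(".Random.seed", extra$rng, globalenv())
  }

  # echo the resolved configuration, including the layer maps the
  # distillation losses will use, for reproducibility
  layer_maps <- if (!is.null(teacher)) list(
    image = build_layer_map(teacher$config$image_layers, cfg$image_layers,
                            "image")$hidden_map,
    text = build_layer_map(teacher$config$text_layers, cfg$text_layers,
                           "text")$hidden_map,
    fusion = build_layer_map(teacher$config$fusion_layers, cfg$fusion_layers,
                             "fusion")$hidden_map) else NULL
  echo <- c(lapply(unclass(config), function(x)
    if (inherits(x, "vl_model") || inherits(x, "encoder_config"))
      x$name %||% "inline" else x),
    list(layer_maps = layer_maps))
  writeLines(jsonlite::toJSON(echo, auto_unbox = TRUE, null = "null"),
             file.path(config$out_dir, "config_echo.json"))

  ids_all <- encode_text(tokenizer, corpus$caption, cfg$max_text_len)
  n <- nrow(corpus)
  metrics_path <- file.path(config$out_dir, "metrics.jsonl")
  mcon <- file(metrics_path, if (is.null(resume_from)) "wb" else "ab")
  on.exit(close(mcon))
  dcon <- NULL
  if (isTRUE(config$dump_masks)) {
    dcon <- file(file.path(config$out_dir, "masks.jsonl"),
                 if (is.null(resume_from)) "wb" else "ab")
    on.exit(close(dcon), add = TRUE)
  }
  metrics <- vector("list", config$max_steps - start_step)
  ckpt_path <- file.path(config$out_dir, "student_final.rds")

  for (step in seq.int(start_step + 1L, config$max_steps)) {
    idx <- if (n >= config$batch_size) sample(n, config$batch_size)
      else sample(n, config$batch_size, replace = TRUE)
    images <- corpus$pixels[idx]
    ids <- ids_all[idx, , drop = FALSE]

    # (1) patch masks
    r_now <- schedule_r(step - 1L, sched)
    pmasks <- if (isTRUE(config$guided_mask)) {
      compute_guided_mask_for_batch(teacher, student, images, ids,
                                    step - 1L, sched, config$mask_ratio)
    } else {
      lapply(seq_along(idx), function(i)
        random_patch_mask(N, config$mask_ratio))
    }
    plans <- make_token_plans(ids, tokenizer, config$mlm_rate)
    if (!is.null(dcon)) {
      for (b in seq_along(idx)) {
        writeLines(jsonlite::toJSON(list(
          step = step, sample = idx[b], mask = pmasks[[b]]$mask,
          salience = attr(pmasks[[b]], "salience")),
          auto_unbox = TRUE, null = "null", digits = NA), dcon)
      }
    }

    student <- with_param_nodes(student)

    # (2a) MLM branch: masked text + full image
    rec_mlm <- forward_with_records(student, images, ids,
                                    token_plan = plans, with_grad = TRUE,
                                    heads = "mlm")
    l_mlm <- suppressWarnings(mlm_loss(rec_mlm$mlm_logits, rec_mlm$mlm_targets))

    # (3) distillation on the masked-text branch
    if (isTRUE(config$distill)) {
      rec_t <- forward_with_records(teacher, images, ids, token_plan = plans)
      dl <- distillation_losses(rec_mlm, rec_t)
      l_hid <- dl$hid; l_attn <- dl$attn
    } else {
      l_hid <- 0; l_attn <- 0
    }

    # (2b) MIM branch: masked image + full text
    rec_mim <- forward_with_records(student, images, ids,
                                    patch_mask = pmasks, with_grad = TRUE,
                                    heads = "mim")
    Sd <- rec_mim$mim_seq
    rows <- integer(0); tgt <- NULL
    tgt_list <- vector("list", length(idx))
    for (b in seq_along(idx)) {
      masked <- which(pmasks[[b]]$mask == 1L)
      rows <- c(rows, (b - 1L) * Sd + 1L + masked)
      tp <- patchify(images[[b]], cfg$patch_size)[masked, , drop = FALSE]
      if (cfg$image_channels > 1L)
        tp <- do.call(cbind, rep(list(tp), cfg$image_channels))
      tgt_list[[b]] <- tp
    }
    tgt <- do.call(rbind, tgt_list)
    l_mim <- ag_mse(ag_rows(rec_mim$mim_pred, rows), tgt)

    # (2c) ITM branch: full pairs with in-batch negatives
    itm_pairs <- make_itm_batch(
      tibble::tibble(caption = corpus$caption[idx], pixels = images),
      config$negative_fraction)
    itm_ids <- encode_text(tokenizer, itm_pairs$caption, cfg$max_text_len)
    rec_itm <- forward_with_records(student, itm_pairs$pixels, itm_ids,
                                    with_grad = TRUE, heads = "itm")
    l_itm <- itm_loss(rec_itm$itm_logits, itm_pairs$label)

    # (4) total loss, backward, AdamW
    total <- ag_sum_scalars(list(l_mlm, l_mim, l_itm, l_hid, l_attn))
    report <- compose_losses(ag_value(l_mlm), ag_value(l_mim),
                             ag_value(l_itm), ag_value(l_hid),
                             ag_value(l_attn))
    ag_backward(total)
    grads <- lapply(student$.param_nodes, function(nd) nd$grad)
    lr <- lr_at(step, config$learning_rate, config$max_steps,
                config$warmup_frac)
    upd <- adamw_step(student$params, grads, opt, lr,
                      weight_decay = config$weight_decay)
    student$params <- upd$params
    opt <- upd$state
    student$.param_nodes <- NULL

    row <- c(list(step = step, r = r_now, lr = lr), unclass(report))
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), mcon)
    metrics[[step - start_step]] <- tibble::as_tibble(row)

    if (step %% config$checkpoint_every == 0L || step == config$max_steps) {
      save_checkpoint(student,
                      if (step == config$max_steps) ckpt_path
                      else file.path(config$out_dir,
                                     sprintf("student_step%05d.rds", step)),
                      extra = list(step = step, opt = opt,
                                   rng = get(".Random.seed", globalenv())))
    }
  }

  structure(list(student = student, teacher = teacher,
                 metrics = dplyr::bind_rows(metrics),
                 checkpoint = ckpt_path, metrics_path = metrics_path,
                 layer_maps = layer_maps, config = config),
            class = "pretrain_result")
}

#' @export
print.pretrain_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<pretrain_result> %d steps; total loss %.4f -> %.4f (checkpoint: %s)\n",
    nrow(m), m$total[1], m$total[nrow(m)], x$checkpoint))
  invisible(x)
}

#' Tidy per-step training metrics
#' @param x A `pretrain_result`.
#' @param ... Unused.
#' @return The metrics tibble (one row per step).
#' @export
tidy.pretrain_result <- function(x, ...) x$metrics

#' One-row summary of a training run
#' @param x A `pretrain_result`.
#' @param ... Unused.
#' @return Tibble with initial/final total loss and run metadata.
#' @export
glance.pretrain_result <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(steps = nrow(m),
                 total_initial = m$total[1], total_final = m$total[nrow(m)],
                 pretrain_final = m$pretrain[nrow(m)],
                 distill_final = m$distill[nrow(m)],
                 r_final = m$r[nrow(m)])
}

#' Read a metrics JSONL file as a tibble
#' @param path Path to `metrics.jsonl`.
#' @return Tibble, one row per step.
#' @export
read_metrics <- function(path) {
  dplyr::bind_rows(lapply(readLines(path), function(l)
    tibble::as_tibble(jsonlite::fromJSON(l))))
}
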