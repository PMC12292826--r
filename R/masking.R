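# Masking logic: MLM token-masking plans, random patch masking, attention
# aggregation and salience scoring, the progressive high-attention schedule,
# and grouped attention-guided mask generation.

#' Plan masked-language-model token masking
#'
#' Uniformly selects `floor(rate * #maskable)` non-special positions and
#' independently assigns each the standard replacement action: probability
#' 0.8 replace with `[MASK]`, 0.1 replace with a random vocabulary word, 0.1
#' keep unchanged. Original ids at the selected positions are recorded as
#' prediction targets. Uses the global RNG; seed with `set.seed()` for
#' reproducibility.
#'
#' @param token_ids Integer vector of token ids (one sequence).
#' @param special_ids Integer ids never selected (pad/cls/sep at minimum).
#' @param rate Selection rate in (0, 1); default 0.15.
#' @param vocab_size Vocabulary size, used to draw random replacement words
#'   (uniform over non-special ids). Required when any position is selected.
#' @return A `token_mask_plan`: list with `positions`, `actions` (factor of
#'   `"mask"`, `"random"`, `"keep"`), `target_ids`, `replacement_ids`.
#' @export
plan_token_masking <- function(token_ids, special_ids, rate = 0.15,
                               vocab_size = NULL) {
  stopifnot(rate > 0, rate < 1)
  maskable <- which(!(token_ids %in% special_ids))
  n_sel <- floor(rate * length(maskable))
  if (n_sel == 0L) {
    return(structure(list(positions = integer(0),
                          actions = character(0),
                          target_ids = integer(0),
                          replacement_ids = integer(0),
                          n_maskable = length(maskable)),
                     class = "token_mask_plan"))
  }
  positions <- sort(sample(maskable, n_sel))
  u <- stats::runif(n_sel)
  actions <- ifelse(u < 0.8, "mask", ifelse(u < 0.9, "random", "keep"))
  if (is.null(vocab_size))
    stop("vocab_size is required to draw random replacements", call. = FALSE)
  word_ids <- setdiff(seq_len(vocab_size), special_ids)
  replacement_ids <- sample(word_ids, n_sel, replace = TRUE)
  structure(list(positions = positions, actions = actions,
                 target_ids = token_ids[positions],
                 replacement_ids = replacement_ids,
                 n_maskable = length(maskable)),
            class = "token_mask_plan")
}

#' Apply a token masking plan to a sequence
#'
#' @param token_ids Integer vector the plan was made for.
#' @param plan A `token_mask_plan`.
#' @param mask_id Id of the `[MASK]` token.
#' @return Integer vector with replacements applied.
#' @export
apply_token_plan <- function(token_ids, plan, mask_id) {
  out <- token_ids
  if (length(plan$positions) == 0L) return(out)
  is_mask <- plan$actions == "mask"
  is_rand <- plan$actions == "random"
  out[plan$positions[is_mask]] <- mask_id
  out[plan$positions[is_rand]] <- plan$replacement_ids[is_rand]
  out
}

#' Random patch mask
#'
#' Chooses `round(ratio * N)` patches uniformly without replacement
#' (round-half-up). Uses the global RNG.
#'
#' @param num_patches Number of patches `N` (>= 1).
#' @param ratio Masking ratio in (0, 1); default 0.75.
#' @return A `patch_mask`: list with binary vector `mask` (1 = masked) and
#'   `budget`.
#' @export
random_patch_mask <- function(num_patches, ratio = 0.75) {
  if (num_patches < 1) stop("num_patches must be >= 1", call. = FALSE)
  stopifnot(ratio > 0, ratio < 1)
  budget <- round_half_up(ratio * num_patches)
  mask <- integer(num_patches)
  mask[sample(num_patches, budget)] <- 1L
  structure(list(mask = mask, budget = as.integer(budget)),
            class = "patch_mask")
}

#' Aggregate the four guidance attention maps
#'
#' Element-wise sum of the student/teacher uni-modal and multi-modal `N x N`
#' maps followed by min--max normalisation to `[0, 1]`. When the summed map
#' is (numerically) constant, a uniform 0.5 matrix is returned so downstream
#' salience is uniform rather than undefined.
#'
#' @param a_s_uni,a_t_uni,a_s_mul,a_t_mul `N x N` nonnegative matrices.
#' @return A `salience_field`: list with `aggregate` (`N x N` in `[0,1]`),
#'   `salience` (length-`N` column means) and `provenance`.
#' @export
aggregate_attention <- function(a_s_uni, a_t_uni, a_s_mul, a_t_mul) {
  maps <- list(student_uni = a_s_uni, teacher_uni = a_t_uni,
               student_mul = a_s_mul, teacher_mul = a_t_mul)
  dims <- lapply(maps, dim)
  if (length(unique(lapply(dims, identity))) != 1L ||
      dims[[1]][1] != dims[[1]][2])
    stop("all four attention maps must be square with identical shape",
         call. = FALSE)
  for (nm in names(maps)) {
    if (any(!is.finite(maps[[nm]])) || any(maps[[nm]] < 0))
      stop("attention map ", nm, " has non-finite or negative entries",
           call. = FALSE)
  }
  s <- a_s_uni + a_t_uni + a_s_mul + a_t_mul
  rng <- range(s)
  agg <- if (diff(rng) < 1e-12) {
    matrix(0.5, nrow(s), ncol(s))
  } else {
    (s - rng[1]) / diff(rng)
  }
  structure(list(aggregate = agg, salience = colMeans(agg),
                 provenance = names(maps)),
            class = "salience_field")
}

#' Per-patch salience from an aggregated attention field
#'
#' The reduction from the `N x N` guidance matrix to sortable per-patch
#' scores is the column mean: the average attention each patch *receives*
#' across all query patches.
#'
#' @param field A `salience_field`.
#' @return Numeric length-`N` vector.
#' @export
salience_from_attention <- function(field) {
  stopifnot(inherits(field, "salience_field"))
  colMeans(field$aggregate)
}

#' Progressive masking schedule
#'
#' @param r_start,r_end High-attention threshold fractions at step 0 and at
#'   `max_steps` (defaults 0.95 and 0.3: the high-attention group grows from
#'   the top 5% to the top 70% of patches over training).
#' @param max_steps Total scheduled steps (>= 1).
#' @return A `mask_schedule`.
#' @export
mask_schedule <- function(r_start = 0.95, r_end = 0.3, max_steps) {
  stopifnot(max_steps >= 1, r_end > 0, r_end <= r_start, r_start < 1)
  structure(list(r_start = r_start, r_end = r_end,
                 max_steps = as.integer(max_steps)),
            class = "mask_schedule")
}

#' Evaluate the progressive schedule at a step
#'
#' Linear interpolation `r = r_start - (r_start - r_end) * step / max_steps`;
#' steps beyond `max_steps` clamp to `r_end`.
#'
#' @param step Nonnegative step count.
#' @param schedule A `mask_schedule`.
#' @return The threshold fraction `r`.
#' @export
schedule_r <- function(step, schedule) {
  if (step < 0) stop("step must be nonnegative", call. = FALSE)
  frac <- min(step / schedule$max_steps, 1)
  schedule$r_start - (schedule$r_start - schedule$r_end) * frac
}

#' Attention-guided patch mask
#'
#' Patches are ranked by salience; the `round((1 - r) * N)` highest-salience
#' patches form the high-attention group and are all masked (ties broken by
#' lower patch index). The remaining budget -- the total is fixed at
#' `round(total_ratio * N)` -- is drawn uniformly from the low-attention
#' group. At `r = 0.95` this masks the top 5% plus 70% random low-attention
#' patches; by `r = 0.3` the high-attention group itself covers 70%.
#'
#' @param salience Length-`N` nonnegative score vector.
#' @param r High-attention threshold fraction in (0, 1).
#' @param total_ratio Total masking ratio in (0, 1); default 0.75.
#' @return A `patch_mask` in original patch order.
#' @export
attention_guided_mask <- function(salience, r, total_ratio = 0.75) {
  N <- length(salience)
  stopifnot(N >= 1, r > 0, r < 1, total_ratio > 0, total_ratio < 1)
  budget <- round_half_up(total_ratio * N)
  if (budget > N) stop("mask budget exceeds number of patches", call. = FALSE)
  k_high <- round_half_up((1 - r) * N)
  ord <- order(-salience, seq_len(N))  # descending salience, stable by index
  high <- ord[seq_len(min(k_high, budget))]
  low <- setdiff(ord, high)
  n_rand <- budget - length(high)
  extra <- if (n_rand > 0) low[sample(length(low), n_rand)] else integer(0)
  mask <- integer(N)
  mask[c(high, extra)] <- 1L
  structure(list(mask = mask, budget = as.integer(budget),
                 high_group = sort(high)),
            class = "patch_mask")
}

#' Compute attention-guided masks for a batch from live models
#'
#' Runs one gradient-free forward of the teacher and the student on the
#' unmasked image--text pairs, extracts the four `N x N` guidance maps (last
#' image-encoder layer and last fusion-layer image-stream self-attention,
#' head-averaged, summary row/column dropped, rows renormalised), aggregates
#' them, scores patches, and generates one mask per sample with
#' `r = schedule_r(step, schedule)`.
#'
#' @param teacher,student Built models (see [build_model()]).
#' @param images List of pixel matrices.
#' @param token_ids Integer matrix of token ids (one row per sample).
#' @param step,schedule Current step and a [mask_schedule()].
#' @param total_ratio Total masking ratio; default 0.75.
#' @return List of `patch_mask`, one per sample, with the per-sample
#'   `salience` attached as an attribute.
#' @export
compute_guided_mask_for_batch <- function(teacher, student, images, token_ids,
                                          step, schedule, total_ratio = 0.75) {
  if (num_patches(teacher$config) != num_patches(student$config))
    stop("teacher and student patch grids differ", call. = FALSE)
  r <- schedule_r(step, schedule)
  rec_t <- forward_with_records(teacher, images, token_ids)
  rec_s <- forward_with_records(student, images, token_ids)
  B <- length(images)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    field <- aggregate_attention(
      guidance_map(rec_s, "uni", b), guidance_map(rec_t, "uni", b),
      guidance_map(rec_s, "mul", b), guidance_map(rec_t, "mul", b))
    pm <- attention_guided_mask(field$salience, r, total_ratio)
    attr(pm, "salience") <- field$salience
    out[[b]] <- pm
  }
  out
}
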