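# Pre-training objectives: masked-language-model cross-entropy, masked-image
# reconstruction MSE, image--text matching cross-entropy, matching-batch
# construction, and the unweighted loss composition.

# Loss functions accept plain numeric inputs (returning a numeric scalar) or
# autodiff nodes (returning a scalar node), so the same formulas serve tests
# and the training loop.
.as_scalar <- function(x, node_in) if (node_in) x else as.numeric(ag_value(x))

#' Masked-language-modelling loss
#'
#' Mean cross-entropy over the masked positions only (logits at unmasked
#' positions never enter). A batch with zero masked positions yields 0 with
#' attribute `"empty" = TRUE` and a warning, since a batch can legitimately
#' contain no maskable tokens.
#'
#' @param logits Matrix (or node) of shape `n_masked x vocab_size`.
#' @param targets Integer vector of true token ids (1-based), length
#'   `n_masked`.
#' @return Nonnegative scalar (or scalar node).
#' @export
mlm_loss <- function(logits, targets) {
  if (is.null(logits) || length(targets) == 0L) {
    warning("no masked positions in batch; MLM loss defined as 0")
    return(structure(0, empty = TRUE))
  }
  .as_scalar(ag_cross_entropy(logits, targets), is_agnode(logits))
}

#' Masked-image-modelling loss
#'
#' Mean squared error over the masked patches' pixel vectors only; unmasked
#' patches are excluded.
#'
#' @param predicted,true Matrices (`N x patch_dim`) of predicted and original
#'   pixels for one sample, or stacked batches with `mask` a list.
#' @param mask A `patch_mask` (or list of them for a stacked batch given as a
#'   list of per-sample matrices).
#' @return Nonnegative scalar (or scalar node).
#' @export
mim_loss <- function(predicted, true, mask) {
  if (inherits(mask, "patch_mask")) {
    masked <- which(mask$mask == 1L)
    if (length(masked) == 0L)
      stop("MIM loss undefined without masked patches", call. = FALSE)
    node_in <- is_agnode(predicted)
    p <- if (node_in) ag_rows(predicted, masked) else
      ag_value(predicted)[masked, , drop = FALSE]
    t0 <- ag_value(true)[masked, , drop = FALSE]
    return(.as_scalar(ag_mse(p, t0), node_in))
  }
  stop("mask must be a patch_mask", call. = FALSE)
}

#' Construct an image--text matching batch
#'
#' Each matched pair is independently flipped to a negative with probability
#' `negative_fraction`; a negative substitutes the caption or the image
#' (chosen with probability 0.5) with that of a different, uniformly chosen
#' batch member. Labels: 1 = matched, 0 = mismatched. Uses the global RNG.
#'
#' @param pairs Tibble/data frame with at least `caption` and an image
#'   column (any list-column, e.g. `pixels`).
#' @param negative_fraction Probability of flipping each pair.
#' @return The input with columns replaced where substituted, plus `label`
#'   (integer) and `partner` (substitute's row index, `NA` for positives).
#' @export
make_itm_batch <- function(pairs, negative_fraction = 0.5) {
  n <- nrow(pairs)
  if (n < 2 && negative_fraction > 0)
    stop("need at least 2 pairs to build negatives", call. = FALSE)
  out <- pairs
  out$label <- 1L
  out$partner <- NA_integer_
  flip <- stats::runif(n) < negative_fraction
  for (i in which(flip)) {
    partner <- sample(setdiff(seq_len(n), i), 1L)
    if (stats::runif(1) < 0.5) {
      out$caption[i] <- pairs$caption[partner]
    } else {
      out$pixels[i] <- pairs$pixels[partner]
    }
    out$label[i] <- 0L
    out$partner[i] <- partner
  }
  out
}

#' Image--text matching loss
#'
#' Mean binary cross-entropy from 2-way logits (column 1 = mismatched,
#' column 2 = matched).
#'
#' @param logits Matrix (or node) `n x 2`.
#' @param labels Integer vector of 0/1 match labels.
#' @return Nonnegative scalar (or scalar node).
#' @export
itm_loss <- function(logits, labels) {
  stopifnot(length(labels) >= 1)
  targets <- as.integer(labels) + 1L  # class index: 1 = mismatch, 2 = match
  .as_scalar(ag_cross_entropy(logits, targets), is_agnode(logits))
}

#' Compose the loss report
#'
#' Unweighted sums exactly as defined: `pretrain = mlm + mim + itm`,
#' `distill = hid + attn`, `total = pretrain + distill`.
#'
#' @param mlm,mim,itm,hid,attn Finite nonnegative components.
#' @return A `loss_report` (named list; see [tidy.loss_report()]).
#' @export
compose_losses <- function(mlm, mim, itm, hid, attn) {
  comps <- list(mlm = mlm, mim = mim, itm = itm, hid = hid, attn = attn)
  for (nm in names(comps)) {
    if (!is.finite(as.numeric(ag_value(comps[[nm]]))))
      stop("non-finite loss component: ", nm, call. = FALSE)
  }
  vals <- lapply(comps, function(x) as.numeric(ag_value(x)))
  structure(c(vals, list(
    pretrain = vals$mlm + vals$mim + vals$itm,
    distill = vals$hid + vals$attn,
    total = vals$mlm + vals$mim + vals$itm + vals$hid + vals$attn)),
    class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    "<loss_report> total %.4f (pretrain %.4f = mlm %.4f + mim %.4f + itm %.4f; distill %.4f = hid %.4f + attn %.4f)\n",
    x$total, x$pretrain, x$mlm, x$mim, x$itm, x$distill, x$hid, x$attn))
  invisible(x)
}

#' Tidy a loss report into a one-row tibble
#' @param x A `loss_report`.
#' @param ... Unused.
#' @return Tibble with one column per component and sum.
#' @export
tidy.loss_report <- function(x, ...) {
  tibble::as_tibble(x[c("mlm", "mim", "itm", "hid", "attn",
                        "pretrain", "distill", "total")])
}

#' Generic tidier
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic one-row model summary
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
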