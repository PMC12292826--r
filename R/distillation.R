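# Teacher -> student knowledge transfer: uniform layer mapping, hidden-state
# MSE distillation, and post-softmax attention-map MSE distillation.

#' Build a uniform teacher-layer mapping
#'
#' Maps student layer `i` (of `l`) to teacher layer `ceil(i * L / l)`: the
#' teacher's depth is split into `l` even intervals and each student layer
#' aligns with the last layer of its interval. Whenever `L / l` is integral
#' this reproduces the fixed per-layer ratios (2:1, 3:1, 6:1) of the
#' published presets; non-integral depths fall back to the same ceiling
#' spacing. The deepest layers always align (`m(l) = L`).
#'
#' @param teacher_layers Teacher depth `L`.
#' @param student_layers Student depth `l` (`1 <= l <= L`).
#' @param component Which stack the map is for (carried as metadata).
#' @return A `layer_map`: list with `hidden_map`, `attn_map` (integer
#'   vectors of length `l`) and `component`.
#' @export
build_layer_map <- function(teacher_layers, student_layers,
                            component = c("image", "text", "fusion")) {
  component <- match.arg(component)
  L <- as.integer(teacher_layers); l <- as.integer(student_layers)
  if (l < 1 || l > L)
    stop("student depth must satisfy 1 <= l <= teacher depth", call. = FALSE)
  m <- as.integer(ceiling(seq_len(l) * L / l))
  structure(list(hidden_map = m, attn_map = m, component = component),
            class = "layer_map")
}

#' Hidden-state distillation loss
#'
#' Sum over student layers of the element-wise MSE between the student's
#' hidden states and the mapped teacher layer's hidden states. The teacher
#' side is treated as a constant (no gradient).
#'
#' @param student_hidden List over student layers of `(seq x d)` matrices
#'   (or autodiff nodes).
#' @param teacher_hidden List over teacher layers of matrices of matching
#'   shape.
#' @param map A `layer_map`.
#' @param projection Optional `d_student x d_teacher` matrix (or node)
#'   applied to the student states before comparison; by default widths must
#'   match (all presets share one width).
#' @return Nonnegative scalar (or scalar node when the student side is
#'   tracked).
#' @export
hidden_distillation_loss <- function(student_hidden, teacher_hidden, map,
                                     projection = NULL) {
  l <- length(student_hidden)
  stopifnot(length(map$hidden_map) == l,
            max(map$hidden_map) <= length(teacher_hidden))
  terms <- vector("list", l)
  node_in <- FALSE
  for (i in seq_len(l)) {
    s <- student_hidden[[i]]
    if (!is.null(projection)) s <- ag_linear(s, projection)
    t0 <- ag_value(teacher_hidden[[map$hidden_map[i]]])
    if (!identical(dim(ag_value(s)), dim(t0)))
      stop("hidden-state shape mismatch at student layer ", i,
           " (supply a projection for unequal widths)", call. = FALSE)
    node_in <- node_in || is_agnode(s)
    terms[[i]] <- ag_mse(s, t0)
  }
  out <- ag_sum_scalars(terms)
  if (node_in) out else as.numeric(ag_value(out))
}

#' Attention-map distillation loss
#'
#' `(1/h) * sum_j sum_i MSE(A_S(i, j), A_T(i, m'(j)))` over student layers
#' `j` and heads `i`, comparing post-softmax row-stochastic maps. Head `i`
#' pairs with head `i`; teacher and student must share the head count.
#'
#' @param student_attn List over student layers of `S x S x h x batch`
#'   arrays (or nodes).
#' @param teacher_attn List over teacher layers of arrays of matching shape.
#' @param map A `layer_map`.
#' @return Nonnegative scalar (or scalar node).
#' @export
attention_distillation_loss <- function(student_attn, teacher_attn, map) {
  l <- length(student_attn)
  stopifnot(length(map$attn_map) == l,
            max(map$attn_map) <= length(teacher_attn))
  d_s <- dim(ag_value(student_attn[[1]]))
  d_t <- dim(ag_value(teacher_attn[[map$attn_map[1]]]))
  if (d_s[3] != d_t[3])
    stop("teacher and student head counts differ", call. = FALSE)
  if (!identical(d_s, d_t))
    stop("attention map shapes differ between teacher and student",
         call. = FALSE)
  h <- d_s[3]
  terms <- vector("list", l)
  node_in <- FALSE
  for (j in seq_len(l)) {
    s <- student_attn[[j]]
    t0 <- ag_value(teacher_attn[[map$attn_map[j]]])
    node_in <- node_in || is_agnode(s)
    # the per-(layer, head) MSE sum equals h * MSE over the whole array,
    # so sum_i MSE_i / h == mean over all elements of the layer's stack
    terms[[j]] <- ag_mse(s, t0)
  }
  out <- ag_sum_scalars(terms)
  if (node_in) out else as.numeric(ag_value(out))
}

#' Distillation losses from two forward records
#'
#' Convenience wrapper computing the hidden and attention distillation
#' losses across the image, text and fusion stacks of a student and a
#' teacher record (teacher values constant). Per-stack layer maps are built
#' from the recorded depths; fusion uses the image- and text-stream
#' self-attentions and hidden states.
#'
#' @param student_rec,teacher_rec `forward_record`s from the same inputs.
#' @return List with scalar (or node) `hid` and `attn`.
#' @export
distillation_losses <- function(student_rec, teacher_rec) {
  maps <- list(
    image = build_layer_map(length(teacher_rec$image_hidden),
                            length(student_rec$image_hidden), "image"),
    text = build_layer_map(length(teacher_rec$text_hidden),
                           length(student_rec$text_hidden), "text"),
    fusion = build_layer_map(length(teacher_rec$fusion_image_hidden),
                             length(student_rec$fusion_image_hidden), "fusion"))
  hid_terms <- list(
    hidden_distillation_loss(student_rec$image_hidden,
                             teacher_rec$image_hidden, maps$image),
    hidden_distillation_loss(student_rec$text_hidden,
                             teacher_rec$text_hidden, maps$text),
    hidden_distillation_loss(student_rec$fusion_image_hidden,
                             teacher_rec$fusion_image_hidden, maps$fusion),
    hidden_distillation_loss(student_rec$fusion_text_hidden,
                             teacher_rec$fusion_text_hidden, maps$fusion))
  attn_terms <- list(
    attention_distillation_loss(student_rec$image_attn,
                                teacher_rec$image_attn, maps$image),
    attention_distillation_loss(student_rec$text_attn,
                                teacher_rec$text_attn, maps$text),
    attention_distillation_loss(student_rec$fusion_image_attn,
                                teacher_rec$fusion_image_attn, maps$fusion),
    attention_distillation_loss(student_rec$fusion_text_attn,
                                teacher_rec$fusion_text_attn, maps$fusion))
  node_in <- any(vapply(c(hid_terms, attn_terms), is_agnode, logical(1)))
  hid <- ag_sum_scalars(hid_terms)
  attn <- ag_sum_scalars(attn_terms)
  if (!node_in) {
    hid <- as.numeric(ag_value(hid)); attn <- as.numeric(ag_value(attn))
  }
  list(hid = hid, attn = attn, maps = maps)
}
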