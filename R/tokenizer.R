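# Whitespace tokenizer over a fixed, file-backed vocabulary. This is the toy
# tokenizer used with the synthetic corpus; a full-scale subword tokenizer
# can be plugged in by supplying a function with the same signature to the
# pipeline (untested hook).

SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[MASK]", "[UNK]")

#' Default toy vocabulary
#'
#' Special tokens first, then the closed word list used by the synthetic
#' caption grammar.
#'
#' @return Character vector of tokens.
#' @export
default_vocab <- function() {
  c(SPECIAL_TOKENS,
    "a", "the", "small", "large", "tiny", "round", "oval", "elongated",
    "faint", "bright", "dense", "opacity", "lesion", "nodule", "in",
    "region", "upper", "lower", "left", "right", "central", "of", "lung",
    "field", "is", "seen", "with", "margin", "smooth", "irregular", "no",
    "other", "finding", "noted", "chest", "image", "shows", "area", "zone",
    "diffuse", "focal", "patchy", "well")
}

#' Write a vocabulary file (one token per line, specials first)
#' @param path Output path.
#' @param vocab Character vector; defaults to [default_vocab()].
#' @return Invisibly, `path`.
#' @export
write_vocab <- function(path, vocab = default_vocab()) {
  writeLines(vocab, path)
  invisible(path)
}

#' Load a tokenizer from a vocabulary file
#'
#' @param path Path to a plain-text vocabulary (one token per line; the five
#'   special tokens `[PAD] [CLS] [SEP] [MASK] [UNK]` must come first).
#' @return A `toy_tokenizer` object with `$vocab`, `$ids` (named lookup), and
#'   the special-token ids (`pad_id`, `cls_id`, `sep_id`, `mask_id`,
#'   `unk_id`, all 1-based).
#' @export
load_tokenizer <- function(path) {
  vocab <- readLines(path)
  if (!identical(vocab[seq_along(SPECIAL_TOKENS)], SPECIAL_TOKENS))
    stop("vocabulary must start with the special tokens ",
         paste(SPECIAL_TOKENS, collapse = " "), call. = FALSE)
  if (anyDuplicated(vocab)) stop("vocabulary contains duplicate tokens")
  ids <- stats::setNames(seq_along(vocab), vocab)
  structure(list(vocab = vocab, ids = ids,
                 pad_id = ids[["[PAD]"]], cls_id = ids[["[CLS]"]],
                 sep_id = ids[["[SEP]"]], mask_id = ids[["[MASK]"]],
                 unk_id = ids[["[UNK]"]]),
            class = "toy_tokenizer")
}

#' Tokenizer backed by the bundled default vocabulary
#' @return A `toy_tokenizer`.
#' @export
default_tokenizer <- function() {
  path <- tempfile(fileext = ".txt")
  write_vocab(path)
  on.exit(unlink(path))
  load_tokenizer(path)
}

#' Encode captions to fixed-length id sequences
#'
#' Lowercases, splits on whitespace, maps unknown words to `[UNK]`, wraps in
#' `[CLS]`/`[SEP]`, then pads with `[PAD]` (or truncates, keeping the final
#' `[SEP]`) to `max_len`.
#'
#' @param tokenizer A `toy_tokenizer`.
#' @param text Character vector of captions.
#' @param max_len Output sequence length.
#' @return Integer matrix, one row per caption (`length(text)` x `max_len`).
#' @export
encode_text <- function(tokenizer, text, max_len) {
  stopifnot(max_len >= 2)
  out <- matrix(tokenizer$pad_id, length(text), max_len)
  for (i in seq_along(text)) {
    words <- strsplit(tolower(trimws(text[i])), "\\s+")[[1]]
    words <- words[nzchar(words)]
    ids <- unname(tokenizer$ids[words])
    ids[is.na(ids)] <- tokenizer$unk_id
    ids <- c(tokenizer$cls_id, ids)
    if (length(ids) > max_len - 1L) ids <- ids[seq_len(max_len - 1L)]
    ids <- c(ids, tokenizer$sep_id)
    out[i, seq_along(ids)] <- ids
  }
  out
}

#' Decode id sequences back to token strings
#' @param tokenizer A `toy_tokenizer`.
#' @param ids Integer vector or matrix of token ids.
#' @param drop_special Drop pad/cls/sep tokens from the output.
#' @return Character vector of space-joined tokens (one per row).
#' @export
decode_text <- function(tokenizer, ids, drop_special = TRUE) {
  if (is.null(dim(ids))) ids <- matrix(ids, nrow = 1)
  apply(ids, 1L, function(row) {
    toks <- tokenizer$vocab[row]
    if (drop_special)
      toks <- toks[!toks %in% c("[PAD]", "[CLS]", "[SEP]")]
    paste(toks, collapse = " ")
  })
}

#' Special-token ids of a tokenizer
#' @param tokenizer A `toy_tokenizer`.
#' @return Integer vector of the five special-token ids.
#' @export
special_token_ids <- function(tokenizer) {
  c(tokenizer$pad_id, tokenizer$cls_id, tokenizer$sep_id,
    tokenizer$mask_id, tokenizer$unk_id)
}
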