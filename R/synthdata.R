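# Deterministic synthetic radiograph-like image--caption corpus.
#
# Each image is a smooth, low-contrast grayscale background (a seeded sum of
# low-frequency sinusoids) with one bright elliptical "lesion". The patches
# the lesion covers are recorded, and the caption is drawn from a closed
# template grammar that names the lesion's size, shape, intensity and image
# quadrant -- so attention-guided masking and the cross-modal objectives have
# verifiable structure without any external dataset.

.size_words <- c("tiny", "small", "large")
.shape_words <- c("round", "oval", "elongated")
.intensity_words <- c("faint", "bright", "dense")

# quadrant -> (vertical word, horizontal word)
.quadrant_words <- function(cy, cx, size) {
  v <- if (cy <= size / 2) "upper" else "lower"
  h <- if (cx <= size / 2) "left" else "right"
  c(v, h)
}

.render_background <- function(size) {
  xs <- seq(0, 1, length.out = size)
  img <- matrix(0.35, size, size)
  for (k in 1:4) {
    fx <- stats::runif(1, 0.5, 2.5); fy <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi); amp <- stats::runif(1, 0.015, 0.04)
    img <- img + amp * outer(sin(2 * pi * fy * xs + ph[1]),
                             sin(2 * pi * fx * xs + ph[2]))
  }
  pmin(pmax(img, 0), 1)
}

# Patch index (row-major over the patch grid) covered by each pixel block.
.lesion_patches <- function(mask_px, size, patch_size) {
  grid <- size %/% patch_size
  hits <- which(mask_px, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(integer(0))
  pr <- (hits[, 1] - 1L) %/% patch_size
  pc <- (hits[, 2] - 1L) %/% patch_size
  sort(unique(pr * grid + pc + 1L))
}

.render_sample <- function(image_size, patch_size) {
  img <- .render_background(image_size)
  # lesion geometry: centre away from the border, radii scaled to the image
  # centres keep a buffer from the quadrant midlines so the caption's
  # position words are unambiguous even for clipped, elongated lesions
  margin <- image_size / 5
  half <- image_size / 2
  pick_coord <- function() {
    lo <- stats::runif(1, margin, half - image_size / 10)
    hi <- stats::runif(1, half + image_size / 10, image_size - margin)
    if (stats::runif(1) < 0.5) lo else hi
  }
  cy <- pick_coord()
  cx <- pick_coord()
  shape <- sample(.shape_words, 1)
  base_r <- stats::runif(1, image_size / 11, image_size / 7)
  ry_rx <- switch(shape,
    round = c(1, 1), oval = c(1, 1.6), elongated = c(1, 2.6))
  ry <- base_r * ry_rx[1]; rx <- base_r * ry_rx[2]
  theta <- stats::runif(1, 0, pi)
  intensity <- sample(.intensity_words, 1)
  # even "faint" clears the brightest background ridge, so the lesion is
  # always the image's top-intensity structure (the premise of the salience
  # oracle)
  gain <- switch(intensity, faint = 0.38, bright = 0.5, dense = 0.62)
  ys <- matrix(seq_len(image_size), image_size, image_size)
  xs <- t(ys)
  dy <- ys - cy; dx <- xs - cx
  u <- dy * cos(theta) + dx * sin(theta)
  w <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / ry)^2 + (w / rx)^2 <= 1
  soft <- exp(-pmax((u / ry)^2 + (w / rx)^2 - 0.6, 0) * 3)
  img <- pmin(img + gain * soft * ((u / ry)^2 + (w / rx)^2 <= 1.4), 1)
  patches <- .lesion_patches(inside, image_size, patch_size)
  area_frac <- mean(inside)
  size_word <- .size_words[findInterval(area_frac, c(0, 0.015, 0.045, 1))]
  pos <- .quadrant_words(cy, cx, image_size)
  margin_word <- sample(c("smooth", "irregular"), 1)
  field_word <- sample(c("lung", "chest"), 1)
  # fixed 20-word template so every caption has the same maskable length
  caption <- paste("a", size_word, shape, intensity, "opacity is seen in the",
                   pos[1], pos[2], "region of the", field_word,
                   "field with", margin_word, "margin noted")
  list(image = img, caption = caption, lesion_patches = patches,
       centroid = c(cy, cx), area_frac = area_frac,
       descriptor = list(position = pos, shape = shape,
                         intensity = intensity, size = size_word))
}

#' Generate a synthetic image--caption corpus
#'
#' Writes `n` grayscale PNG images and a JSONL manifest (keys `image`,
#' `caption`, `salient_patches`) plus the vocabulary file. Fully
#' deterministic given `seed`.
#'
#' @param n Number of image--caption pairs (>= 1).
#' @param dir Output directory (created if needed).
#' @param image_size,patch_size Image edge and patch edge in pixels.
#' @param vocab Character vector written as the corpus vocabulary.
#' @param seed Integer seed.
#' @return Invisibly, the manifest as a tibble (`image`, `caption`,
#'   `salient_patches` list-column, `centroid_y`, `centroid_x`, `area_frac`).
#' @export
generate_corpus <- function(n, dir, image_size = 32, patch_size = 8,
                            vocab = default_vocab(), seed = 42) {
  stopifnot(n >= 1, image_size %% patch_size == 0)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create corpus directory: ", dir, call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  write_vocab(file.path(dir, "vocab.txt"), vocab)
  rows <- vector("list", n)
  con <- file(file.path(dir, "manifest.jsonl"), "wb")
  on.exit(close(con), add = TRUE, after = FALSE)
  for (i in seq_len(n)) {
    s <- .render_sample(image_size, patch_size)
    fname <- sprintf("img_%04d.png", i)
    png::writePNG(s$image, file.path(dir, fname))
    rec <- list(image = fname, caption = s$caption,
                salient_patches = as.integer(s$lesion_patches))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    rows[[i]] <- tibble::tibble(
      image = fname, caption = s$caption,
      salient_patches = list(as.integer(s$lesion_patches)),
      centroid_y = s$centroid[1], centroid_x = s$centroid[2],
      area_frac = s$area_frac)
  }
  invisible(dplyr::bind_rows(rows))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Load a synthetic corpus from disk
#'
#' @param dir Corpus directory written by [generate_corpus()].
#' @return A tibble with columns `image` (file name), `caption`,
#'   `salient_patches` (list-column of patch indices) and `pixels`
#'   (list-column of numeric matrices in `[0, 1]`), plus the vocabulary path
#'   in attribute `"vocab_path"`.
#' @export
load_corpus <- function(dir) {
  mf <- file.path(dir, "manifest.jsonl")
  if (!file.exists(mf)) stop("no manifest.jsonl under ", dir, call. = FALSE)
  recs <- lapply(readLines(mf), jsonlite::fromJSON)
  out <- tibble::tibble(
    image = vapply(recs, `[[`, character(1), "image"),
    caption = vapply(recs, `[[`, character(1), "caption"),
    salient_patches = lapply(recs, function(r) as.integer(r$salient_patches)),
    pixels = lapply(recs, function(r) {
      px <- png::readPNG(file.path(dir, r$image))
      if (length(dim(px)) == 3L) px <- px[, , 1]
      px
    }))
  attr(out, "vocab_path") <- file.path(dir, "vocab.txt")
  out
}

#' Ground-truth salience for a synthetic sample
#'
#' A per-patch vector with 1 on the planted lesion's patches and 0 elsewhere
#' (already in `[0, 1]`); used as a stand-in attention field when testing the
#' attention-guided masking path.
#'
#' @param lesion_patches Integer patch indices of the lesion.
#' @param num_patches Total number of patches `N`.
#' @return Numeric length-`N` vector.
#' @export
oracle_salience <- function(lesion_patches, num_patches) {
  v <- numeric(num_patches)
  v[lesion_patches] <- 1
  v
}
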