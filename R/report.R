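# Preset comparison: parameter counts (from configuration shapes, no
# allocation) and, optionally, measured per-step forward cost ratios.

#' Report preset sizes and relative step cost
#'
#' Parameter totals and per-component breakdowns for a set of presets, with
#' each preset's total expressed relative to the first (the teacher by
#' convention). With `measure = TRUE` the models are built and a forward
#' pass is timed on a small dummy batch; timings are hardware-dependent and
#' purely informational.
#'
#' @param presets Character vector of preset names (see [preset_config()]).
#' @param measure Time a dummy forward per preset (builds the models; only
#'   sensible at toy scale).
#' @param batch Dummy batch size used when measuring.
#' @return A tibble with columns `preset`, `layers` (image/text/fusion),
#'   `params_total`, `params_image`, `params_text`, `params_fusion`,
#'   `params_heads`, `param_ratio_vs_first`, and (if measured)
#'   `step_ms` and `step_ratio_vs_first` (informational,
#'   hardware-dependent).
#' @export
report_efficiency <- function(presets = c("teacher-m3ae", "student-base",
                                          "student-small"),
                              measure = FALSE, batch = 2L) {
  rows <- lapply(presets, function(nm) {
    cfg <- preset_config(nm)
    cnt <- count_parameters_config(cfg)
    tibble::tibble(
      preset = nm,
      layers = sprintf("%d/%d/%d", cfg$image_layers, cfg$text_layers,
                       cfg$fusion_layers),
      params_total = cnt[["total"]], params_image = cnt[["image"]],
      params_text = cnt[["text"]], params_fusion = cnt[["fusion"]],
      params_heads = cnt[["heads"]])
  })
  out <- dplyr::bind_rows(rows)
  out$param_ratio_vs_first <- out$params_total[1] / out$params_total
  if (isTRUE(measure)) {
    ms <- vapply(presets, function(nm) {
      cfg <- preset_config(nm)
      model <- build_model(cfg, seed = 1)
      tok <- default_tokenizer()
      ids <- matrix(tok$pad_id, batch, cfg$max_text_len)
      ids[, 1] <- tok$cls_id; ids[, 2] <- tok$sep_id
      imgs <- replicate(batch, matrix(0.5, cfg$image_size, cfg$image_size),
                        simplify = FALSE)
      unname(system.time(
        forward_with_records(model, imgs, ids, heads = "itm"))["elapsed"]) * 1e3
    }, numeric(1))
    out$step_ms <- ms
    out$step_ratio_vs_first <- ms / ms[1]
  }
  out
}
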