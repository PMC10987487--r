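#' Save a trained pairwise order model to a directory
#'
#' Writes the six comparator parameter sets, the best-feature index, the
#' ensemble weights and the training metadata as JSON files, so a model
#' trained once can be reloaded and applied (or transferred) later.
#'
#' @param model a `pairwise_order_model`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_order_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_along(model$comparators)) {
    cmp <- model$comparators[[l]]
    jsonlite::write_json(
      list(W = cmp$W, b = cmp$b, v = cmp$v, center = cmp$center,
           scale = cmp$scale, hidden = cmp$hidden, seed = cmp$seed),
      file.path(dir, sprintf("comparator_%d.json", l)),
      digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  }
  jsonlite::write_json(
    list(best_feature = model$best_feature, weights = model$weights,
         feature_names = model$feature_names, dim = model$dim,
         seed = model$seed, training_meta = model$training_meta),
    file.path(dir, "ensemble.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Load a pairwise order model saved by [save_order_model]
#'
#' @param dir directory containing the model bundle.
#' @return a `pairwise_order_model`.
#' @export
load_order_model <- function(dir) {
  ens <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^comparator_\\d+\\.json$"))
  comparators <- lapply(files, function(f) {
    d <- jsonlite::read_json(file.path(dir, f), simplifyVector = TRUE)
    structure(list(W = as.matrix(d$W), b = as.numeric(d$b),
                   v = as.numeric(d$v), center = as.numeric(d$center),
                   scale = as.numeric(d$scale),
                   hidden = as.integer(d$hidden),
                   seed = as.integer(d$seed)),
              class = "cpnn_comparator")
  })
  structure(list(comparators = comparators,
                 best_feature = as.integer(ens$best_feature),
                 weights = as.numeric(ens$weights),
                 feature_names = ens$feature_names,
                 dim = as.integer(ens$dim), seed = as.integer(ens$seed),
                 training_meta = ens$training_meta),
            class = "pairwise_order_model")
}
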