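#' Bundled olive field-campaign tables
#'
#' Reference records from a two-campaign table-olive phenotyping trial in
#' southern Spain (flights 15 and 27 months after planting, one intensive
#' and one hedgerow training system), shipped as package data so the
#' validation statistics can be exercised without any field work:
#'
#' * `olive_detection_counts()` — visually counted trees versus
#'   automatically detected trees per campaign and system, the input to
#'   [counting_accuracy()].
#' * `olive_height_summary()` — per-campaign summaries (min, max, range,
#'   mean, sd) of field-measured and automatically estimated tree heights,
#'   the input to [bias_percent()].
#'
#' @return A data frame.
#' @export
#' @examples
#' counts <- olive_detection_counts()
#' counting_accuracy(counts$detected_trees[1], counts$field_trees[1])
olive_detection_counts <- function() {
  utils::read.csv(system.file("extdata", "detection_counts.csv",
                              package = "olivecloud"))
}

#' @rdname olive_detection_counts
#' @export
olive_height_summary <- function() {
  utils::read.csv(system.file("extdata", "height_summary.csv",
                              package = "olivecloud"))
}
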