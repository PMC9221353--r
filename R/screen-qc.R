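# Plate-level Z'-factor quality control.
#
# Z' = 1 - (3*SD_pos + 3*SD_neg) / |mean_pos - mean_neg|
#
# computed per assay plate from the eight positive-control and eight
# negative-control wells. Standard deviations are sample SDs (n - 1), the
# usual HTS convention; with only 8 wells per control column the estimator
# choice is material and is therefore fixed and documented here.

#' Summary statistics of a plate's control wells
#'
#' @param pos Numeric vector of positive-control RLUs (length >= 2).
#' @param neg Numeric vector of negative-control RLUs (length >= 2).
#' @return A list of class `control_stats`: `m_pos`, `m_neg`, `sd_pos`,
#'   `sd_neg`, `n_pos`, `n_neg`.
#' @export
control_stats <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop("need at least 2 wells per control group (sample SD undefined)",
         call. = FALSE)
  }
  if (any(!is.finite(c(pos, neg)))) {
    stop("control values must be finite", call. = FALSE)
  }
  structure(
    list(m_pos = mean(pos), m_neg = mean(neg),
         sd_pos = stats::sd(pos), sd_neg = stats::sd(neg),
         n_pos = length(pos), n_neg = length(neg)),
    class = "control_stats"
  )
}

#' Z'-factor of one plate
#'
#' @param stats A `control_stats` object, or a numeric vector of
#'   positive-control RLUs (then `neg` must be given).
#' @param neg Optional numeric vector of negative-control RLUs.
#' @return A list of class `z_prime_result`: `z_prime` (NaN when the control
#'   means coincide), `classification` (see [classify_z()]), and the input
#'   statistics.
#' @export
#' @examples
#' z_prime(control_stats(c(900, 1000, 1100), c(90, 100, 110)))
z_prime <- function(stats, neg = NULL) {
  if (!inherits(stats, "control_stats")) {
    stats <- control_stats(stats, neg)
  }
  gap <- abs(stats$m_pos - stats$m_neg)
  if (gap == 0) {
    z <- NaN
  } else {
    z <- 1 - (3 * stats$sd_pos + 3 * stats$sd_neg) / gap
  }
  structure(
    list(z_prime = z, classification = classify_z(z), stats = stats),
    class = "z_prime_result"
  )
}

#' Classify a Z'-factor
#'
#' Bands: `good` for 0.5 <= Z' <= 1, `fair` for 0 <= Z' < 0.5, `poor` for
#' Z' < 0, `undefined` when the control means coincide (Z' is NaN). The
#' good/fair boundary at 0.5 follows the standard screening-window
#' interpretation; the fair band's lower edge at 0 is this package's
#' documented convention.
#'
#' @param z Numeric Z'-factor (may be NaN).
#' @return Character: `"good"`, `"fair"`, `"poor"`, or `"undefined"`.
#' @export
classify_z <- function(z) {
  dplyr::case_when(
    is.nan(z) | is.na(z) ~ "undefined",
    z >= 0.5 ~ "good",
    z >= 0 ~ "fair",
    .default = "poor"
  )
}

#' Screen-wide Z'-factor QC report
#'
#' Computes one Z'-factor per (plate, condition, replicate day) from the
#' in-plate control columns, and the arithmetic mean Z' per condition pooled
#' across plates and replicate days. Plates whose control means coincide
#' (Z' undefined) are excluded from the mean and listed.
#'
#' @param reads Long tibble of plate reads (`plate_id`, `replicate_id`,
#'   `condition`, `well`, `rlu`).
#' @param layout A `screen_layout`.
#' @return A list of class `screen_qc`: `per_plate` (tibble with `z_prime`
#'   and `classification` per plate/condition/replicate), `condition_summary`
#'   (`mean_z`, `n_plates`, `n_undefined` per condition), and `excluded`
#'   (plates with undefined Z').
#' @export
screen_qc_report <- function(reads, layout) {
  keys <- dplyr::distinct(reads, .data$plate_id, .data$condition,
                          .data$replicate_id)
  per_plate <- dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    read <- dplyr::filter(reads,
                          .data$plate_id == k$plate_id,
                          .data$condition == k$condition,
                          .data$replicate_id == k$replicate_id)
    pos <- control_values(read, layout, "positive_control")
    neg <- control_values(read, layout, "negative_control")
    zr <- z_prime(control_stats(pos, neg))
    tibble::tibble(plate_id = k$plate_id, condition = k$condition,
                   replicate_id = k$replicate_id,
                   m_pos = zr$stats$m_pos, m_neg = zr$stats$m_neg,
                   sd_pos = zr$stats$sd_pos, sd_neg = zr$stats$sd_neg,
                   z_prime = zr$z_prime,
                   classification = zr$classification)
  }))
  per_plate <- dplyr::arrange(per_plate, .data$condition, .data$replicate_id,
                              .data$plate_id)
  condition_summary <- dplyr::summarise(
    dplyr::group_by(per_plate, .data$condition),
    mean_z = mean(.data$z_prime[!is.nan(.data$z_prime)]),
    n_plates = dplyr::n(),
    n_undefined = sum(is.nan(.data$z_prime)),
    .groups = "drop"
  )
  excluded <- dplyr::filter(per_plate, is.nan(.data$z_prime))
  structure(
    list(per_plate = per_plate, condition_summary = condition_summary,
         excluded = excluded[, c("plate_id", "condition", "replicate_id")]),
    class = "screen_qc"
  )
}
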