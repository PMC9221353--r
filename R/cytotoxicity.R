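# Percent specific lysis for luciferase-release killing assays.
#
# Target cells carry a cytoplasmic nano-luciferase; killing releases the
# enzyme into the supernatant, so luminescence reports lysis. The readout is
# normalised between the spontaneous release of targets alone and the
# maximal release of detergent (digitonin) lysed targets.

#' Percent specific lysis
#'
#' \deqn{\%\,lysis = \frac{experimental - spontaneous}
#'                        {maximal - spontaneous} \times 100}
#'
#' Values below 0% or above 100% are legitimate assay outcomes (noise around
#' the controls, or a compound releasing more signal than the detergent
#' control) and are returned unclipped; use [lysis_flags()] to mark them.
#'
#' @param experimental Raw luminescence (RLU) of effector + target wells.
#' @param spontaneous Raw luminescence of target-alone wells (or their mean).
#' @param maximal Raw luminescence of digitonin-lysed target wells (or their
#'   mean).
#' @return Numeric vector of percent specific lysis, unclipped.
#' @export
#' @examples
#' specific_lysis(500, 100, 900) # 50
specific_lysis <- function(experimental, spontaneous, maximal) {
  vals <- c(experimental, spontaneous, maximal)
  if (any(!is.finite(vals))) {
    stop("all releases must be finite", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("negative luminescence is not a valid release value", call. = FALSE)
  }
  if (any(maximal <= spontaneous)) {
    stop("degenerate assay: maximal release must exceed spontaneous release",
         call. = FALSE)
  }
  (experimental - spontaneous) / (maximal - spontaneous) * 100
}

#' Flag out-of-range lysis values
#'
#' @param percent_lysis Numeric vector from [specific_lysis()].
#' @return Character vector: `"below_zero"`, `"above_max"`, or `""`.
#' @export
lysis_flags <- function(percent_lysis) {
  dplyr::case_when(
    percent_lysis < 0 ~ "below_zero",
    percent_lysis > 100 ~ "above_max",
    .default = ""
  )
}

#' Lysis curve across effector:target ratios
#'
#' Computes percent specific lysis per replicate well at each E:T ratio,
#' anchored on the mean of the supplied spontaneous-release and
#' maximal-release wells, and summarises each ratio by its mean and sample
#' standard deviation across replicates.
#'
#' @param experimental Tibble or data frame with columns `e_t_ratio`
#'   (positive), `replicate`, `rlu`.
#' @param spontaneous_wells Numeric vector of target-alone RLUs (>= 1 well).
#' @param maximal_wells Numeric vector of digitonin-well RLUs (>= 1 well).
#' @return A list with `per_replicate` (one row per well, with
#'   `percent_lysis` and `flag`) and `summary` (per-ratio `mean_lysis`,
#'   `sd_lysis`, `n`).
#' @export
lysis_curve <- function(experimental, spontaneous_wells, maximal_wells) {
  stopifnot(all(c("e_t_ratio", "replicate", "rlu") %in% names(experimental)))
  if (nrow(experimental) == 0) {
    stop("no experimental wells supplied", call. = FALSE)
  }
  if (length(spontaneous_wells) < 1 || length(maximal_wells) < 1) {
    stop("need at least one spontaneous and one maximal well", call. = FALSE)
  }
  if (any(experimental$e_t_ratio <= 0)) {
    stop("E:T ratios must be strictly positive", call. = FALSE)
  }
  spont <- mean(spontaneous_wells)
  maximal <- mean(maximal_wells)

  per_rep <- tibble::as_tibble(experimental)
  per_rep$percent_lysis <- specific_lysis(per_rep$rlu, spont, maximal)
  per_rep$flag <- lysis_flags(per_rep$percent_lysis)

  summary <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$e_t_ratio),
    mean_lysis = mean(.data$percent_lysis),
    sd_lysis = stats::sd(.data$percent_lysis),
    n = dplyr::n(),
    .groups = "drop"
  )
  summary <- dplyr::arrange(summary, .data$e_t_ratio)
  list(per_replicate = per_rep, summary = summary,
       spontaneous_mean = spont, maximal_mean = maximal)
}
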