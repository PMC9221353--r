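# Fold-change normalisation and hit calling.
#
# Each compound well is normalised to the mean of the eight in-plate DMSO
# wells (column 1) of its own plate, separately per condition and replicate
# day. A compound is a hit when its co-culture fold-change is >= the
# threshold (default 1.3) on every screening day, with at least two days,
# and it is not excluded by the counter-screen: any target-alone
# fold-change >= threshold marks the compound as directly toxic to the
# target cells (luciferase release without NK activity) and dominates every
# other status.

HIT_STATUSES <- c("hit", "single_replicate_hit", "non_hit", "excluded_toxic")

#' Per-plate fold-change over DMSO controls
#'
#' @param read Plate read tibble for a single plate/condition/replicate
#'   (`plate_id`, `replicate_id`, `condition`, `well`, `rlu`).
#' @param layout A `screen_layout`.
#' @param dmso_stat Aggregator for the column-1 DMSO wells: `"mean"`
#'   (default) or `"median"`.
#' @return Tibble of fold-change records: `compound_id`, `condition`,
#'   `replicate_id`, `plate_id`, `well`, `fc`. Empty wells are skipped.
#' @export
fold_change_plate <- function(read, layout, dmso_stat = c("mean", "median")) {
  dmso_stat <- match.arg(dmso_stat)
  pid <- unique(read$plate_id)
  cond <- unique(read$condition)
  rep_id <- unique(read$replicate_id)
  stopifnot(length(pid) == 1, length(cond) == 1, length(rep_id) == 1)
  lay <- plate_layout(layout, pid, cond)

  dmso <- control_values(read, layout, "negative_control")
  dmso_ref <- if (dmso_stat == "mean") mean(dmso) else stats::median(dmso)
  if (!is.finite(dmso_ref) || dmso_ref <= 0) {
    stop("DMSO control ", dmso_stat, " must be positive on plate ", pid,
         call. = FALSE)
  }

  cmp <- dplyr::filter(lay, .data$role == "compound")
  vals <- read$rlu[match(cmp$well, read$well)]
  if (any(is.na(vals))) {
    stop("compound wells missing from read on plate ", pid, ": ",
         paste(cmp$well[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    compound_id = cmp$compound_id,
    condition = cond,
    replicate_id = rep_id,
    plate_id = pid,
    well = cmp$well,
    fc = vals / dmso_ref
  )
}

#' Fold-changes for every plate of a screen
#'
#' Convenience wrapper applying [fold_change_plate()] to each
#' (plate, condition, replicate) present in a long read table.
#'
#' @param reads Long read tibble covering one or more plates.
#' @inheritParams fold_change_plate
#' @return Tibble of fold-change records across the screen.
#' @export
fold_change_screen <- function(reads, layout, dmso_stat = c("mean", "median")) {
  dmso_stat <- match.arg(dmso_stat)
  keys <- dplyr::distinct(reads, .data$plate_id, .data$condition,
                          .data$replicate_id)
  dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    read <- dplyr::filter(reads,
                          .data$plate_id == k$plate_id,
                          .data$condition == k$condition,
                          .data$replicate_id == k$replicate_id)
    fold_change_plate(read, layout, dmso_stat)
  }))
}

#' Aggregate fold-changes across replicate days
#'
#' @param records Fold-change records for one condition (`compound_id`,
#'   `replicate_id`, `fc`).
#' @return Tibble per compound: `mean_fc` (arithmetic mean over available
#'   replicates), `n_replicates`, and the per-replicate values in `fcs`
#'   (list-column).
#' @export
aggregate_replicates <- function(records) {
  if (nrow(records) == 0) {
    stop("no fold-change records to aggregate", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(records, .data$compound_id),
    mean_fc = mean(.data$fc),
    n_replicates = dplyr::n(),
    fcs = list(.data$fc),
    .groups = "drop"
  )
}

#' Call hits with the toxicity counter-screen
#'
#' Statuses per compound:
#' * `excluded_toxic` — any target-alone replicate fold-change >= threshold
#'   (counter-screen; dominates everything else);
#' * `hit` — fold-change >= threshold in every co-culture replicate, with at
#'   least two replicate days;
#' * `single_replicate_hit` — only one co-culture replicate available and it
#'   meets the threshold;
#' * `non_hit` — otherwise.
#'
#' The threshold comparison is inclusive (a fold-change of exactly 1.3
#' passes the default). The result is ranked by descending mean co-culture
#' fold-change, ties broken by `compound_id`.
#'
#' @param coculture Fold-change records from the effector/target co-culture
#'   condition.
#' @param target_alone Fold-change records from the target-alone
#'   counter-screen condition.
#' @param threshold Hit threshold on the fold-change (default 1.3).
#' @return A `hit_table`: tibble with `compound_id`, `mean_fc`,
#'   `n_replicates`, `status`, `fc_target_alone_max`, and list-columns
#'   `coculture_fcs`, `target_alone_fcs`; `threshold` stored as attribute.
#' @export
call_hits <- function(coculture, target_alone, threshold = 1.3) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  co <- aggregate_replicates(coculture)
  ta_split <- split(target_alone$fc, target_alone$compound_id)

  only_co <- setdiff(co$compound_id, names(ta_split))
  only_ta <- setdiff(names(ta_split), co$compound_id)
  if (length(only_co) > 0 || length(only_ta) > 0) {
    warning("compounds present in one condition only: ",
            paste(c(only_co, only_ta), collapse = ", "),
            "; statuses computed from available data", call. = FALSE)
  }

  ta_fcs <- ta_split[co$compound_id]
  ta_fcs[vapply(ta_fcs, is.null, logical(1))] <- list(numeric(0))
  names(ta_fcs) <- co$compound_id

  toxic <- vapply(ta_fcs, function(v) any(v >= threshold), logical(1))
  all_pass <- vapply(co$fcs, function(v) all(v >= threshold), logical(1))
  status <- dplyr::case_when(
    toxic ~ "excluded_toxic",
    all_pass & co$n_replicates >= 2 ~ "hit",
    all_pass & co$n_replicates == 1 ~ "single_replicate_hit",
    .default = "non_hit"
  )

  out <- tibble::tibble(
    compound_id = co$compound_id,
    mean_fc = co$mean_fc,
    n_replicates = co$n_replicates,
    status = status,
    fc_target_alone_max = vapply(
      ta_fcs, function(v) if (length(v)) max(v) else NA_real_, numeric(1)),
    coculture_fcs = co$fcs,
    target_alone_fcs = unname(ta_fcs),
    condition_coverage = ifelse(co$compound_id %in% only_co,
                                "coculture_only", "both")
  )
  out <- rank_hits(out)
  attr(out, "threshold") <- threshold
  class(out) <- c("hit_table", class(out))
  out
}

#' Rank a hit table
#'
#' Orders by descending mean co-culture fold-change; ties are broken by
#' `compound_id` (lexicographic), making the order stable and reproducible.
#'
#' @param table A `hit_table` (or compatible tibble with `mean_fc`).
#' @return The table, reordered.
#' @export
rank_hits <- function(table) {
  dplyr::arrange(table, dplyr::desc(.data$mean_fc), .data$compound_id)
}

#' Compounds passing the screen
#'
#' @param table A `hit_table`.
#' @param include_single_replicate Count single-replicate passes as part of
#'   the hit set (default TRUE, matching screens where some compounds ran on
#'   one day only).
#' @return The subset of rows with a passing status, in rank order.
#' @export
screen_hits <- function(table, include_single_replicate = TRUE) {
  keep <- if (include_single_replicate) {
    c("hit", "single_replicate_hit")
  } else {
    "hit"
  }
  dplyr::filter(table, .data$status %in% keep)
}

#' Apply curation annotations to select candidate compounds
#'
#' Screens prioritise hits for follow-up by curation: compounds no longer in
#' clinical use, unavailable, or already known actives are deprioritised.
#' This step is curation, not computation — the flags are supplied
#' externally.
#'
#' @param table A `hit_table`.
#' @param annotations Tibble with columns `compound_id` and `deprioritize`
#'   (logical), or a named logical vector. Hits missing from the annotation
#'   are treated as not flagged, with a warning.
#' @return Tibble of candidate hits (passing status, not deprioritised),
#'   order preserved.
#' @export
select_candidates <- function(table, annotations = NULL) {
  hits <- screen_hits(table)
  if (is.null(annotations) ||
      (is.data.frame(annotations) && nrow(annotations) == 0) ||
      (!is.data.frame(annotations) && length(annotations) == 0)) {
    return(hits)
  }
  if (!is.data.frame(annotations)) {
    annotations <- tibble::tibble(compound_id = names(annotations),
                                  deprioritize = as.logical(annotations))
  }
  stopifnot(all(c("compound_id", "deprioritize") %in% names(annotations)))
  flag <- annotations$deprioritize[match(hits$compound_id,
                                         annotations$compound_id)]
  if (any(is.na(flag))) {
    warning("no annotation for: ",
            paste(hits$compound_id[is.na(flag)], collapse = ", "),
            "; treated as not flagged", call. = FALSE)
    flag[is.na(flag)] <- FALSE
  }
  hits[!flag, ]
}
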