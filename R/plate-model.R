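# 96-well plate geometry and the screen layout model.
#
# Wells are addressed by the plate-reader convention "A1".."H12" (rows A-H,
# columns 1-12, 1-based). The screen layout places library compounds in
# columns 2-11, vehicle (DMSO) negative controls in column 1 and positive
# controls in column 12: digitonin full-lysis wells on target-alone plates,
# 9:1 effector:target wells on co-culture plates.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12
COMPOUND_COLS <- 2:11
NEG_CTRL_COL <- 1L
POS_CTRL_COL <- 12L
WELLS_PER_PLATE <- 96L
COMPOUND_WELLS_PER_PLATE <- 80L

SCREEN_CONDITIONS <- c("target_alone", "coculture")
WELL_ROLES <- c("compound", "negative_control", "positive_control", "empty")

#' Well coordinates of a 96-well plate
#'
#' @param order `"row_major"` gives A1, A2, ..., A12, B1, ...; `"column_major"`
#'   gives A1, B1, ..., H1, A2, ....
#' @return Character vector of 96 well names such as `"A1"`, `"H12"`.
#' @export
#' @examples
#' head(plate_wells())
plate_wells <- function(order = c("row_major", "column_major")) {
  order <- match.arg(order)
  if (order == "row_major") {
    as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
  } else {
    as.vector(outer(PLATE_ROWS, PLATE_COLS, paste0))
  }
}

#' Split well names into row letter and column number
#'
#' @param well Character vector of well names (`"A1"`-`"H12"`).
#' @return A tibble with columns `well`, `row`, `column`.
#' @export
parse_well <- function(well) {
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", well)
  if (!all(ok)) {
    stop("invalid well name(s): ", paste(unique(well[!ok]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    well = well,
    row = substr(well, 1, 1),
    column = as.integer(substring(well, 2))
  )
}

#' Build the plate layout for the full screen
#'
#' Compounds are assigned to columns 2-11 in row-major order (A2...A11,
#' B2...B11, ...) within each plate, plates in manifest order, giving 80
#' compound wells per plate. The same compound occupies the same plate and
#' well in both assay conditions (target cells alone and the
#' effector/target co-culture), mirroring paired assay plates dispensed from
#' one stock plate. Column 1 carries DMSO negative controls and column 12
#' positive controls on every plate; a partially filled final plate leaves
#' its unused compound wells `empty`.
#'
#' @param compound_ids Character vector of unique compound identifiers, in
#'   stock-plate dispensing order.
#' @return A `screen_layout`: a tibble with one row per (plate, condition,
#'   well) and columns `plate_id`, `condition`, `well`, `row`, `column`,
#'   `role`, `compound_id`, plus a `compound_index` attribute mapping each
#'   compound to its plate and well.
#' @export
#' @examples
#' layout <- build_screen_layout(sprintf("C%04d", 1:160))
#' dplyr::count(layout, plate_id, condition, role)
build_screen_layout <- function(compound_ids) {
  compound_ids <- as.character(compound_ids)
  if (length(compound_ids) == 0) {
    stop("at least one compound is required", call. = FALSE)
  }
  if (anyDuplicated(compound_ids)) {
    stop("duplicate compound_ids: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(compound_ids)) || any(compound_ids == "")) {
    stop("compound_ids must be non-missing and non-empty", call. = FALSE)
  }

  n <- length(compound_ids)
  n_plates <- ceiling(n / COMPOUND_WELLS_PER_PLATE)
  plate_ids <- sprintf("P%02d", seq_len(n_plates))

  # row-major compound well order within one plate: A2..A11, B2..B11, ...
  compound_well_order <- as.vector(t(outer(PLATE_ROWS, COMPOUND_COLS, paste0)))

  one_plate <- function(i) {
    idx_start <- (i - 1L) * COMPOUND_WELLS_PER_PLATE
    ids <- compound_ids[seq.int(idx_start + 1L,
                                min(idx_start + COMPOUND_WELLS_PER_PLATE, n))]
    slot <- rep(NA_character_, COMPOUND_WELLS_PER_PLATE)
    slot[seq_along(ids)] <- ids
    grid <- parse_well(plate_wells("row_major"))
    grid$role <- dplyr::case_when(
      grid$column == NEG_CTRL_COL ~ "negative_control",
      grid$column == POS_CTRL_COL ~ "positive_control",
      .default = "compound"
    )
    grid$compound_id <- NA_character_
    m <- match(grid$well, compound_well_order)
    in_block <- !is.na(m)
    grid$compound_id[in_block] <- slot[m[in_block]]
    grid$role[in_block & is.na(grid$compound_id)] <- "empty"
    grid$plate_id <- plate_ids[i]
    grid
  }

  plates <- dplyr::bind_rows(lapply(seq_len(n_plates), one_plate))
  layout <- dplyr::bind_rows(lapply(SCREEN_CONDITIONS, function(cond) {
    dplyr::mutate(plates, condition = cond)
  }))
  layout <- dplyr::select(layout, "plate_id", "condition", "well", "row",
                          "column", "role", "compound_id")
  idx <- dplyr::filter(plates, .data$role == "compound")
  attr(layout, "compound_index") <-
    tibble::tibble(compound_id = idx$compound_id,
                   plate_id = idx$plate_id,
                   well = idx$well)
  class(layout) <- c("screen_layout", class(layout))
  layout
}

#' Compound-to-position index of a screen layout
#'
#' @param layout A `screen_layout` from [build_screen_layout()] or
#'   [read_layout_json()].
#' @return Tibble with columns `compound_id`, `plate_id`, `well`.
#' @export
compound_index <- function(layout) {
  idx <- attr(layout, "compound_index")
  if (is.null(idx)) {
    cmp <- dplyr::filter(layout,
                         .data$role == "compound",
                         .data$condition == layout$condition[1])
    idx <- tibble::tibble(compound_id = cmp$compound_id,
                          plate_id = cmp$plate_id, well = cmp$well)
  }
  idx
}

#' Extract the layout of one plate in one condition
#'
#' @param layout A `screen_layout`.
#' @param plate_id,condition Plate identifier and assay condition.
#' @return Tibble of 96 rows (one per well).
#' @export
plate_layout <- function(layout, plate_id, condition) {
  out <- dplyr::filter(layout,
                       .data$plate_id == !!plate_id,
                       .data$condition == !!condition)
  if (nrow(out) == 0) {
    stop("no plate '", plate_id, "' in condition '", condition,
         "' in this layout", call. = FALSE)
  }
  out
}

#' Validate a plate read against its layout
#'
#' Checks that a set of raw luminescence values covers every well the layout
#' expects, contains no negative readings, and reports values for wells the
#' layout marks `empty`.
#'
#' @param read A tibble of plate-reader values with columns `plate_id`,
#'   `replicate_id`, `condition`, `well`, `rlu` for a single plate.
#' @param layout A `screen_layout`.
#' @return A tibble of findings with columns `well`, `finding`; zero rows
#'   means the read passes. The `pass` attribute carries the overall verdict.
#' @export
validate_read <- function(read, layout) {
  stopifnot(all(c("plate_id", "condition", "well", "rlu") %in% names(read)))
  pid <- unique(read$plate_id)
  cond <- unique(read$condition)
  if (length(pid) != 1 || length(cond) != 1) {
    stop("validate_read() expects a single plate/condition read", call. = FALSE)
  }
  lay <- plate_layout(layout, pid, cond)

  findings <- tibble::tibble(well = character(), finding = character())
  expected <- lay$well[lay$role != "empty"]
  missing <- setdiff(expected, read$well)
  if (length(missing) > 0) {
    miss_roles <- lay$role[match(missing, lay$well)]
    findings <- dplyr::bind_rows(findings, tibble::tibble(
      well = missing, finding = paste("missing", miss_roles, "well")))
  }
  dup <- unique(read$well[duplicated(read$well)])
  if (length(dup) > 0) {
    findings <- dplyr::bind_rows(findings, tibble::tibble(
      well = dup, finding = "duplicate well"))
  }
  neg <- read$well[!is.na(read$rlu) & read$rlu < 0]
  if (length(neg) > 0) {
    findings <- dplyr::bind_rows(findings, tibble::tibble(
      well = neg, finding = "negative luminescence"))
  }
  nonnum <- read$well[is.na(read$rlu)]
  if (length(nonnum) > 0) {
    findings <- dplyr::bind_rows(findings, tibble::tibble(
      well = nonnum, finding = "missing luminescence value"))
  }
  empties <- lay$well[lay$role == "empty"]
  stray <- intersect(read$well, empties)
  if (length(stray) > 0) {
    findings <- dplyr::bind_rows(findings, tibble::tibble(
      well = stray, finding = "value reported for empty well"))
  }
  unknown <- setdiff(read$well, lay$well)
  if (length(unknown) > 0) {
    findings <- dplyr::bind_rows(findings, tibble::tibble(
      well = unknown, finding = "well not on plate"))
  }
  attr(findings, "pass") <- nrow(findings) == 0
  findings
}

#' Control-well luminescence values of one plate read
#'
#' Returns the eight raw values of the requested control column in row order
#' (A to H): column 1 for `negative_control` (DMSO), column 12 for
#' `positive_control` (digitonin on target-alone plates, 9:1
#' effector:target on co-culture plates).
#'
#' @inheritParams validate_read
#' @param role `"negative_control"` or `"positive_control"`.
#' @return Numeric vector of 8 RLU values in row order.
#' @export
control_values <- function(read, layout, role) {
  if (!role %in% c("negative_control", "positive_control")) {
    stop("role must be 'negative_control' or 'positive_control'; ",
         "use compound accessors for compound wells", call. = FALSE)
  }
  pid <- unique(read$plate_id)
  cond <- unique(read$condition)
  stopifnot(length(pid) == 1, length(cond) == 1)
  lay <- plate_layout(layout, pid, cond)
  wells <- lay$well[lay$role == role]
  wells <- wells[order(substr(wells, 1, 1))]
  vals <- read$rlu[match(wells, read$well)]
  if (any(is.na(vals))) {
    stop("control wells missing from read: ",
         paste(wells[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  vals
}
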