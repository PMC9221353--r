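# File dialects: long-format and grid-format plate-reader CSV, layout
# JSON/TSV, and the stage output writers. The long CSV
# (plate_id,replicate_id,condition,well,rlu) is the canonical interchange
# format; the 8x12 grid CSV with a key=value metadata header matches common
# plate-reader exports and is import-oriented. Stage outputs embed their
# analysis parameters as '#'-prefixed header comments.

#' Read plate reads from CSV
#'
#' @param path File path.
#' @param dialect `"long_csv"` (header
#'   `plate_id,replicate_id,condition,well,rlu`) or `"grid_csv"` (a
#'   `key=value` metadata block naming `plate_id`, `condition` and
#'   `replicate_id`, followed by an 8-row by 12-column block of values with
#'   row letters and column numbers).
#' @param layout Optional `screen_layout`; when given, each plate read is
#'   validated with [validate_read()] and findings raise an error.
#' @return Long tibble of plate reads.
#' @export
read_plate_reads <- function(path, dialect = c("long_csv", "grid_csv"),
                             layout = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  reads <- if (dialect == "long_csv") {
    read_long_csv(path)
  } else {
    read_grid_csv(path)
  }
  if (!is.null(layout)) {
    keys <- dplyr::distinct(reads, .data$plate_id, .data$condition,
                            .data$replicate_id)
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      read <- dplyr::filter(reads,
                            .data$plate_id == k$plate_id,
                            .data$condition == k$condition,
                            .data$replicate_id == k$replicate_id)
      findings <- validate_read(read, layout)
      if (nrow(findings) > 0) {
        stop("plate ", k$plate_id, " (", k$condition, ", replicate ",
             k$replicate_id, ") failed validation: ",
             paste(findings$well, findings$finding, collapse = "; "),
             call. = FALSE)
      }
    }
  }
  reads
}

read_long_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plate_id", "replicate_id", "condition", "well", "rlu")
  if (!all(need %in% names(df))) {
    stop("long CSV must have header ", paste(need, collapse = ","),
         call. = FALSE)
  }
  raw <- as.character(df$rlu)
  rlu <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(rlu) & !is.na(raw) & raw != "")
  if (length(bad) > 0) {
    stop("non-numeric RLU at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  df$rlu <- rlu
  key <- paste(df$plate_id, df$condition, df$replicate_id, df$well)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (plate, condition, replicate, well) rows, e.g. well ",
         df$well[dup[1]], " of plate ", df$plate_id[dup[1]],
         " (data row ", dup[1], ")", call. = FALSE)
  }
  parse_well(df$well) # validates well names
  tibble::as_tibble(df[, need])
}

read_grid_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  meta_lines <- grep("^[A-Za-z_]+=", lines, value = TRUE)
  meta <- stats::setNames(
    sub("^[A-Za-z_]+=", "", meta_lines),
    sub("=.*$", "", meta_lines)
  )
  need <- c("plate_id", "condition", "replicate_id")
  if (!all(need %in% names(meta))) {
    stop("grid CSV metadata block must define ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  body <- lines[!seq_along(lines) %in% grep("^[A-Za-z_]+=", lines)]
  header <- strsplit(body[1], ",")[[1]]
  if (!identical(trimws(header[-1]), as.character(1:12))) {
    stop("grid CSV body must start with a header row listing columns 1-12",
         call. = FALSE)
  }
  rows <- body[-1]
  if (length(rows) != 8) {
    stop("grid CSV must contain 8 data rows (A-H), found ", length(rows),
         call. = FALSE)
  }
  parsed <- lapply(rows, function(l) strsplit(l, ",")[[1]])
  row_letters <- vapply(parsed, `[`, character(1), 1)
  if (!identical(sort(row_letters), PLATE_ROWS)) {
    stop("grid CSV rows must be labelled A-H", call. = FALSE)
  }
  dplyr::bind_rows(lapply(parsed, function(p) {
    vals <- suppressWarnings(as.numeric(p[-1]))
    if (length(vals) != 12) {
      stop("grid row ", p[1], " must have 12 values", call. = FALSE)
    }
    tibble::tibble(
      plate_id = meta[["plate_id"]],
      replicate_id = as.integer(meta[["replicate_id"]]),
      condition = meta[["condition"]],
      well = paste0(p[1], 1:12),
      rlu = vals
    )
  }))
}

#' Write plate reads as long CSV
#'
#' @param reads Long read tibble.
#' @param path Output path.
#' @export
write_plate_reads <- function(reads, path) {
  utils::write.csv(
    reads[, c("plate_id", "replicate_id", "condition", "well", "rlu")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one plate read as a grid CSV
#'
#' @param read Read tibble for a single plate/condition/replicate.
#' @param path Output path.
#' @export
write_grid_csv <- function(read, path) {
  pid <- unique(read$plate_id)
  cond <- unique(read$condition)
  rep_id <- unique(read$replicate_id)
  stopifnot(length(pid) == 1, length(cond) == 1, length(rep_id) == 1)
  vals <- read$rlu[match(plate_wells("row_major"), read$well)]
  m <- matrix(vals, nrow = 8, ncol = 12, byrow = TRUE)
  lines <- c(
    paste0("plate_id=", pid),
    paste0("condition=", cond),
    paste0("replicate_id=", rep_id),
    paste0(",", paste(1:12, collapse = ",")),
    vapply(1:8, function(i) {
      paste0(PLATE_ROWS[i], ",", paste(m[i, ], collapse = ","))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a screen layout as JSON
#'
#' @param layout A `screen_layout`.
#' @param path Output path.
#' @export
write_layout_json <- function(layout, path) {
  keys <- dplyr::distinct(layout, .data$plate_id, .data$condition)
  plates <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    lay <- plate_layout(layout, k$plate_id, k$condition)
    list(plate_id = k$plate_id, condition = k$condition,
         wells = lapply(seq_len(nrow(lay)), function(j) {
           w <- list(well = lay$well[j], role = lay$role[j])
           if (!is.na(lay$compound_id[j])) w$compound_id <- lay$compound_id[j]
           w
         }))
  })
  jsonlite::write_json(list(plates = plates), path, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a screen layout from JSON
#'
#' @param path Path to a layout JSON written by [write_layout_json()].
#' @return A `screen_layout`.
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- dplyr::bind_rows(lapply(obj$plates, function(p) {
    dplyr::bind_rows(lapply(p$wells, function(w) {
      tibble::tibble(plate_id = p$plate_id, condition = p$condition,
                     well = w$well, role = w$role,
                     compound_id = w$compound_id %||% NA_character_)
    }))
  }))
  as_screen_layout(rows)
}

#' Read a screen layout from TSV
#'
#' Expects columns `plate_id`, `condition`, `well`, `role`, `compound_id`
#' (empty `compound_id` for non-compound wells).
#'
#' @param path Path to a layout TSV.
#' @return A `screen_layout`.
#' @export
read_layout_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("plate_id", "condition", "well", "role", "compound_id")
  if (!all(need %in% names(df))) {
    stop("layout TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  as_screen_layout(tibble::as_tibble(df[, need]))
}

# assemble + validate a screen_layout from its (plate, condition, well) rows
as_screen_layout <- function(rows) {
  wc <- parse_well(rows$well)
  rows$row <- wc$row
  rows$column <- wc$column
  if (!all(rows$role %in% WELL_ROLES)) {
    stop("unknown well roles: ",
         paste(setdiff(unique(rows$role), WELL_ROLES), collapse = ", "),
         call. = FALSE)
  }
  per_plate <- dplyr::count(rows, .data$plate_id, .data$condition)
  if (any(per_plate$n != WELLS_PER_PLATE)) {
    stop("each plate/condition must have exactly 96 wells", call. = FALSE)
  }
  if (any(rows$column == NEG_CTRL_COL & rows$role != "negative_control") ||
      any(rows$column == POS_CTRL_COL & rows$role != "positive_control") ||
      any(rows$column %in% COMPOUND_COLS &
          !rows$role %in% c("compound", "empty"))) {
    stop("layout violates the screen column scheme ",
         "(controls in columns 1 and 12, compounds in 2-11)", call. = FALSE)
  }
  bad_id <- xor(rows$role == "compound", !is.na(rows$compound_id))
  if (any(bad_id)) {
    stop("compound_id must be present exactly for compound wells",
         call. = FALSE)
  }
  cmp <- dplyr::filter(rows, .data$role == "compound")
  dup <- dplyr::count(cmp, .data$plate_id, .data$condition, .data$compound_id)
  if (any(dup$n > 1)) {
    stop("a compound_id appears twice on one plate", call. = FALSE)
  }
  by_cond <- split(cmp[, c("plate_id", "well", "compound_id")],
                   cmp$condition)
  if (length(by_cond) == 2) {
    a <- dplyr::arrange(by_cond[[1]], .data$compound_id)
    b <- dplyr::arrange(by_cond[[2]], .data$compound_id)
    if (!identical(as.data.frame(a), as.data.frame(b))) {
      stop("conditions must share one compound-to-position map",
           call. = FALSE)
    }
  }
  rows <- dplyr::arrange(rows, match(.data$condition, SCREEN_CONDITIONS),
                         .data$plate_id,
                         match(.data$well, plate_wells("row_major")))
  rows <- dplyr::select(rows, "plate_id", "condition", "well", "row",
                        "column", "role", "compound_id")
  idx <- dplyr::filter(rows, .data$role == "compound",
                       .data$condition == rows$condition[1])
  attr(rows, "compound_index") <-
    tibble::tibble(compound_id = idx$compound_id, plate_id = idx$plate_id,
                   well = idx$well)
  class(rows) <- c("screen_layout", class(rows))
  rows
}

provenance_header <- function(params) {
  c(paste0("# nkscreen ",
           as.character(utils::packageVersion("nkscreen"))),
    paste0("# ", names(params), "=", unname(unlist(params))))
}

#' Write a hit table as TSV
#'
#' Fold-changes are printed with two decimals; the unrounded values remain
#' in the in-memory table.
#'
#' @param table A `hit_table`.
#' @param path Output path.
#' @param names Optional tibble (`compound_id`, `name`) of display names.
#' @export
write_hits_tsv <- function(table, path, names = NULL) {
  df <- tibble::tibble(
    compound_id = table$compound_id,
    name = if (is.null(names)) table$compound_id else
      names$name[match(table$compound_id, names$compound_id)],
    mean_fc = sprintf("%.2f", table$mean_fc),
    fc_rep1 = sprintf("%.4f", vapply(table$coculture_fcs, `[`, numeric(1), 1)),
    fc_rep2 = vapply(table$coculture_fcs, function(v) {
      if (length(v) >= 2) sprintf("%.4f", v[2]) else "NA"
    }, character(1)),
    fc_target_alone_max = sprintf("%.4f", table$fc_target_alone_max),
    n_replicates = table$n_replicates,
    status = table$status
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(
    list(threshold = attr(table, "threshold") %||% NA)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a hit table as JSON with provenance
#'
#' @param table A `hit_table`.
#' @param path Output path.
#' @param provenance Named list of extra provenance fields (seed, input
#'   paths, control aggregation mode, ...).
#' @export
write_hits_json <- function(table, path, provenance = list()) {
  calls <- lapply(seq_len(nrow(table)), function(i) {
    list(compound_id = table$compound_id[i],
         mean_fc = table$mean_fc[i],
         n_replicates = table$n_replicates[i],
         status = table$status[i],
         coculture_fcs = table$coculture_fcs[[i]],
         target_alone_fcs = table$target_alone_fcs[[i]])
  })
  jsonlite::write_json(
    list(version = as.character(utils::packageVersion("nkscreen")),
         threshold = attr(table, "threshold"),
         provenance = provenance,
         calls = calls),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a screen QC report as JSON
#'
#' @param qc A `screen_qc` from [screen_qc_report()].
#' @param path Output path.
#' @export
write_qc_json <- function(qc, path) {
  by_cond <- split(qc$per_plate, qc$per_plate$condition)
  out <- lapply(by_cond, function(pp) {
    cond <- pp$condition[1]
    ms <- qc$condition_summary$mean_z[qc$condition_summary$condition == cond]
    list(mean_z = ms,
         plates = lapply(seq_len(nrow(pp)), function(i) {
           list(plate_id = pp$plate_id[i], replicate_id = pp$replicate_id[i],
                z = pp$z_prime[i], class = pp$classification[i])
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "string")
  invisible(path)
}

#' Write a screen QC report as TSV
#'
#' @inheritParams write_qc_json
#' @export
write_qc_tsv <- function(qc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list(sd = "sample (n-1)")), con)
  utils::write.table(qc$per_plate, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a lysis curve as TSV
#'
#' @param curve Result of [lysis_curve()].
#' @param path Output path.
#' @export
write_lysis_tsv <- function(curve, path) {
  per <- curve$per_replicate
  per$mean <- curve$summary$mean_lysis[match(per$e_t_ratio,
                                             curve$summary$e_t_ratio)]
  per$sd <- curve$summary$sd_lysis[match(per$e_t_ratio,
                                         curve$summary$e_t_ratio)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(
    list(spontaneous_mean = curve$spontaneous_mean,
         maximal_mean = curve$maximal_mean)), con)
  utils::write.table(
    per[, c("e_t_ratio", "replicate", "percent_lysis", "mean", "sd", "flag")],
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulated screen outputs to a directory
#'
#' Writes `reads.csv` (long dialect), `layout.json`,
#' `truth_compounds.tsv` and `truth_plates.tsv`.
#'
#' @param sim A `sim_screen` from [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @export
write_sim_screen <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plate_reads(sim$reads, file.path(dir, "reads.csv"))
  write_layout_json(sim$layout, file.path(dir, "layout.json"))
  utils::write.table(sim$truth$compounds,
                     file.path(dir, "truth_compounds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth$plates, file.path(dir, "truth_plates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Packaged dual-day hit fixture
#'
#' A transcription of a published screen's dual-day hit list: 14 compounds
#' with co-culture fold-change >= 1.3 on both screening days, their printed
#' aggregate fold-changes and drug classes, the 8 compounds selected as
#' follow-up candidates, and the flag marking the one compound whose
#' printed fold-change derives from a single screening day.
#'
#' @return Tibble with columns `rank`, `compound_id`, `name`,
#'   `fold_change`, `drug_class`, `candidate`, `single_replicate`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_fixture.tsv", package = "nkscreen")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$candidate <- as.logical(df$candidate)
  df$single_replicate <- as.logical(df$single_replicate)
  tibble::as_tibble(df)
}

#' Reconstruct fold-change records from the packaged fixture
#'
#' The fixture stores printed per-compound aggregates, not raw per-day
#' values, so this reconstruction assigns each compound its printed
#' fold-change on both screening days (one day for the single-replicate
#' compound) and a neutral target-alone fold-change: the listed compounds
#' all passed the toxicity counter-screen.
#'
#' @param fixture Tibble from [table1_fixture()].
#' @param target_alone_fc Target-alone fold-change assigned to every
#'   compound (default 1).
#' @return List with `coculture` and `target_alone` fold-change record
#'   tibbles suitable for [call_hits()].
#' @export
fixture_fold_change_records <- function(fixture = table1_fixture(),
                                        target_alone_fc = 1) {
  one <- function(cond) {
    dplyr::bind_rows(lapply(seq_len(nrow(fixture)), function(i) {
      reps <- if (fixture$single_replicate[i]) 1L else 1:2
      fc_val <- if (cond == "coculture") fixture$fold_change[i] else
        target_alone_fc
      tibble::tibble(
        compound_id = fixture$compound_id[i],
        condition = cond,
        replicate_id = reps,
        fc = fc_val)
    }))
  }
  list(coculture = one("coculture"), target_alone = one("target_alone"))
}
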