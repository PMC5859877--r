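# Canonical on-disk schema for screen tables. One CSV row per
# (plate, well, strain); RF columns use the literal token "OUT" for the
# sentinel and an empty cell for values never measured.
screen_schema_cols <- c(
  "Plate", "Well", "WellType", "Reagent_ID", "Strain",
  "Ad_R1", "Prg_R1", "Ad_R2", "Prg_R2",
  "RF_R1", "RF_R2", "RF_Avg", "RF_ratio", "GeneSymbol"
)
screen_mandatory_cols <- c("Plate", "Well", "WellType", "Strain",
                           "Ad_R1", "Prg_R1", "Ad_R2", "Prg_R2")
well_type_codes <- c("S", "CN1", "CN2", "CP", "C", "E")
strain_codes <- c("control", "mutant")

#' Parse 96-well coordinates
#'
#' Converts well labels such as `"A1"` or `"H12"` into 0-based row and column
#' indices of a 96-well plate (rows A-H, columns 1-12). Zero-padded labels
#' (`"A01"`) and lower-case row letters are accepted; [well_label()] is the
#' inverse and always writes the unpadded upper-case form.
#'
#' @param label character vector of well labels.
#' @return A tibble with columns `label` (normalized), `row` (0-7) and
#'   `col` (0-11).
#' @examples
#' parse_well(c("A1", "H12"))
#' @export
parse_well <- function(label) {
  if (length(label) == 0 || any(!nzchar(label) | is.na(label))) {
    abort("well labels must be non-empty.")
  }
  lab <- toupper(trimws(label))
  ok <- grepl("^[A-H](0?[1-9]|1[0-2])$", lab)
  if (any(!ok)) {
    abort(paste0("invalid 96-well label(s): ",
                 paste(unique(label[!ok]), collapse = ", ")))
  }
  row <- match(substr(lab, 1, 1), LETTERS[1:8]) - 1L
  col <- as.integer(sub("^[A-H]0?", "", lab)) - 1L
  tibble::tibble(label = well_label(row, col), row = row, col = col)
}

#' @rdname parse_well
#' @param row,col 0-based row (0-7) and column (0-11) indices.
#' @export
well_label <- function(row, col) {
  stopifnot(all(row >= 0 & row <= 7), all(col >= 0 & col <= 11))
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Default 96-well plate layout of an RNAi screening plate
#'
#' Library plates reserve column 1 for controls (the pin replicator's first
#' column is removed) and carry library dsRNA clones in columns 2-12 (88
#' wells). The column-1 template assigns the well-type codes: `CN1` empty
#' dsRNA vector (negative), `CN2` \emph{hil-5(RNAi)} (negative), `CP`
#' \emph{lis-1(RNAi)} (positive, defines the hit threshold), `C`
#' \emph{plk-1(RNAi)} (RNAi-efficiency control, fully lethal), `E` empty.
#'
#' @param control_template character vector of length 8 of well-type codes for
#'   column-1 rows A-H, or `NULL` for an all-library plate (96 `S` wells).
#' @return A 96-row tibble with columns `Well`, `row`, `col`, `WellType`.
#' @examples
#' table(default_layout()$WellType)
#' @export
default_layout <- function(control_template = c("CN1", "CN2", "CP", "C",
                                                "CN1", "CN2", "CP", "E")) {
  grid <- tidyr::expand_grid(row = 0:7, col = 0:11)
  grid$Well <- well_label(grid$row, grid$col)
  if (is.null(control_template)) {
    grid$WellType <- "S"
  } else {
    if (length(control_template) != 8 ||
        !all(control_template %in% well_type_codes)) {
      abort("`control_template` must give 8 valid well-type codes (rows A-H).")
    }
    grid$WellType <- ifelse(grid$col == 0L, control_template[grid$row + 1L], "S")
  }
  dplyr::select(grid, "Well", "row", "col", "WellType")
}

# ---- reading -----------------------------------------------------------------

parse_rf_cell <- function(x) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  is_sentinel <- !is.na(x) & toupper(x) == "OUT"
  out[is_sentinel] <- rf_out()
  num_idx <- !is_sentinel & !is.na(x) & nzchar(x)
  suppressWarnings(out[num_idx] <- as.numeric(x[num_idx]))
  bad <- num_idx & is.na(out)
  list(value = out, bad = bad)
}

#' Read a screen-record CSV
#'
#' Reads a table in the deposited screen-record schema: one row per
#' (plate, well, strain) with adult/progeny counts for two technical
#' replicates, RF fields carrying either non-negative numbers or the literal
#' `"OUT"` sentinel, and the well-type vocabulary `S`/`CN1`/`CN2`/`CP`/`C`/`E`.
#' Headers are matched case-insensitively. Rows with unparseable cells
#' (unknown well type, malformed well label or strain, negative or non-numeric
#' counts) are not silently dropped: they are collected into a rejects report
#' attached as `attr(x, "rejects")`, with one reason per row.
#'
#' @param path CSV file path.
#' @return A tibble with the canonical columns `Plate`, `Well`, `WellType`,
#'   `Reagent_ID`, `Strain`, `Ad_R1`, `Prg_R1`, `Ad_R2`, `Prg_R2`, `RF_R1`,
#'   `RF_R2`, `RF_Avg`, `RF_ratio`, `GeneSymbol`; RF columns numeric with
#'   `NaN` for `"OUT"` (see [rf_out()]). Rejected rows are in
#'   `attr(x, "rejects")`.
#' @seealso [write_screen_table()]
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  hit <- match(tolower(names(raw)), tolower(screen_schema_cols))
  names(raw)[!is.na(hit)] <- screen_schema_cols[hit[!is.na(hit)]]
  missing_cols <- setdiff(screen_mandatory_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("screen table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(screen_schema_cols, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[screen_schema_cols]

  reject_reason <- rep(NA_character_, nrow(raw))
  note <- function(idx, reason) {
    new <- idx & is.na(reject_reason)
    reject_reason[new] <<- reason
  }

  well_ok <- grepl("^[A-Ha-h](0?[1-9]|1[0-2])$", trimws(raw$Well))
  note(!well_ok, "malformed well label")
  note(!(trimws(raw$WellType) %in% well_type_codes), "unknown WellType")
  note(!(tolower(trimws(raw$Strain)) %in% strain_codes), "unknown Strain")

  counts <- lapply(raw[c("Ad_R1", "Prg_R1", "Ad_R2", "Prg_R2")], function(x) {
    suppressWarnings(as.numeric(x))
  })
  for (nm in names(counts)) {
    x <- counts[[nm]]
    present <- !is.na(raw[[nm]]) & nzchar(trimws(raw[[nm]]))
    note(present & is.na(x), paste0("non-numeric ", nm))
    note(!is.na(x) & (x < 0 | x != floor(x)), paste0("invalid count in ", nm))
  }
  rfs <- lapply(raw[c("RF_R1", "RF_R2", "RF_Avg", "RF_ratio")], parse_rf_cell)
  for (nm in names(rfs)) {
    note(rfs[[nm]]$bad, paste0("unparseable ", nm))
    neg <- !is.na(rfs[[nm]]$value) & !is_out(rfs[[nm]]$value) & rfs[[nm]]$value < 0
    note(neg, paste0("negative ", nm))
  }

  keep <- is.na(reject_reason)
  out <- tibble::tibble(
    Plate = raw$Plate[keep],
    Well = if (any(keep)) parse_well(trimws(raw$Well)[keep])$label else character(0),
    WellType = trimws(raw$WellType)[keep],
    Reagent_ID = raw$Reagent_ID[keep],
    Strain = tolower(trimws(raw$Strain))[keep],
    Ad_R1 = as.integer(counts$Ad_R1[keep]),
    Prg_R1 = as.integer(counts$Prg_R1[keep]),
    Ad_R2 = as.integer(counts$Ad_R2[keep]),
    Prg_R2 = as.integer(counts$Prg_R2[keep]),
    RF_R1 = rfs$RF_R1$value[keep],
    RF_R2 = rfs$RF_R2$value[keep],
    RF_Avg = rfs$RF_Avg$value[keep],
    RF_ratio = rfs$RF_ratio$value[keep],
    GeneSymbol = raw$GeneSymbol[keep]
  )
  dup <- duplicated(out[c("Plate", "Well", "Strain")])
  if (any(dup)) {
    abort(paste0("duplicate (plate, well, strain) key(s): ",
                 paste(unique(paste(out$Plate[dup], out$Well[dup],
                                    out$Strain[dup])), collapse = "; ")))
  }
  rejects <- tibble::tibble(
    line = which(!keep),
    reason = reject_reason[!keep],
    Well = raw$Well[!keep],
    WellType = raw$WellType[!keep]
  )
  attr(out, "rejects") <- rejects
  if (nrow(rejects) > 0) {
    warn(paste0(nrow(rejects), " row(s) rejected while reading ", path,
                "; see attr(x, \"rejects\")."))
  }
  out
}

format_rf_col <- function(x) {
  out <- rep("", length(x))
  out[is_out(x)] <- "OUT"
  num <- !is.na(x) & !is_out(x)
  out[num] <- sprintf("%.17g", x[num])
  out
}

#' Write a screen table in the screen-record CSV schema
#'
#' Inverse of [read_screen_table()]: RF sentinels are written as `"OUT"`,
#' missing values as empty cells, and numeric RF values with full double
#' precision so that a write/read round trip is field-identical.
#'
#' @param x a screen table tibble (canonical columns; extra columns dropped
#'   with a warning).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(x, path) {
  missing_cols <- setdiff(screen_mandatory_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("cannot write screen table; missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(screen_schema_cols, names(x))) x[[col]] <- NA
  extra <- setdiff(names(x), screen_schema_cols)
  if (length(extra) > 0) {
    warn(paste0("dropping non-schema column(s): ", paste(extra, collapse = ", ")))
  }
  out <- x[screen_schema_cols]
  out$Well <- parse_well(out$Well)$label
  for (col in c("RF_R1", "RF_R2", "RF_Avg", "RF_ratio")) {
    out[[col]] <- format_rf_col(out[[col]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
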