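#' Reproductive fitness of a well
#'
#' Reproductive fitness (RF) is the number of larval progeny per parent worm.
#' A well is only scoreable when its parent count lies inside the validity
#' window (default 3-13 parents, where progeny counts scale linearly with
#' parents); outside the window the replicate is `OUT` (see [rf_out()]).
#'
#' @param n_adults,n_progeny non-negative integer vectors (recycled).
#' @param config a [screen_config()].
#' @return Numeric vector of RF values; `OUT` (`NaN`) where the parent count
#'   falls outside the window, `NA` where a count is missing.
#' @examples
#' compute_rf(c(7, 2, 13), c(70, 50, 0))  # 10, OUT, 0
#' @export
compute_rf <- function(n_adults, n_progeny, config = screen_config()) {
  if (any(n_adults < 0, na.rm = TRUE) || any(n_progeny < 0, na.rm = TRUE)) {
    abort("counts must be non-negative.")
  }
  n <- max(length(n_adults), length(n_progeny))
  n_adults <- rep_len(n_adults, n)
  n_progeny <- rep_len(n_progeny, n)
  valid <- n_adults >= config$parent_window[1] & n_adults <= config$parent_window[2]
  out <- ifelse(valid, n_progeny / n_adults, rf_out())
  out[is.na(n_adults) | is.na(n_progeny)] <- NA_real_
  out
}

#' Average RF over technical replicates
#'
#' The replicate mean skips `OUT` replicates: if a single replicate worked,
#' the average is that replicate's RF; if no replicate worked, the average is
#' itself `OUT`.
#'
#' @param replicates numeric vector of per-replicate RF values (may contain
#'   `OUT`/`NA`).
#' @return A single RF value.
#' @examples
#' average_rf(c(10, 20))       # 15
#' average_rf(c(10, rf_out())) # 10
#' @export
average_rf <- function(replicates) {
  if (length(replicates) == 0) abort("need at least one replicate.")
  mean_rf(replicates)
}

#' RF ratio of mutant over control strain
#'
#' The per-clone RF ratio divides the mutant strain's replicate-averaged RF by
#' the control strain's. The ratio is undetermined (`NA`) when either average
#' is `OUT`/missing or the control average is not positive.
#'
#' @param rf_avg_mutant,rf_avg_control numeric vectors of replicate-averaged
#'   RF values (recycled).
#' @return Numeric vector of ratios, `NA` where undetermined.
#' @examples
#' rf_ratio(5, 10)        # 0.5
#' rf_ratio(4, rf_out())  # NA
#' @export
rf_ratio <- function(rf_avg_mutant, rf_avg_control) {
  n <- max(length(rf_avg_mutant), length(rf_avg_control))
  m <- rep_len(rf_avg_mutant, n)
  ctl <- rep_len(rf_avg_control, n)
  ok <- !is.na(m) & !is_out(m) & !is.na(ctl) & !is_out(ctl) & ctl > 0
  ifelse(ok, m / ctl, NA_real_)
}

#' Lethality exclusion
#'
#' Clones that reduce viable progeny in the control strain by strictly more
#' than the lethality fraction (default 85 %), relative to a negative-control
#' baseline RF, are excluded: their RF ratio cannot be reliably calculated.
#'
#' @param rf_avg_control replicate-averaged control-strain RF values.
#' @param baseline_control_rf positive baseline RF (mean of the plate's
#'   negative-control wells in the control strain).
#' @param config a [screen_config()].
#' @return Character vector, `"retain"` or `"lethal_excluded"`; `NA` where the
#'   control RF is itself `OUT`/missing.
#' @examples
#' lethality_filter(c(1, 1.5, 10), baseline_control_rf = 10)
#' @export
lethality_filter <- function(rf_avg_control, baseline_control_rf,
                             config = screen_config()) {
  if (!is.numeric(baseline_control_rf) || length(baseline_control_rf) != 1 ||
      is.na(baseline_control_rf) || baseline_control_rf <= 0) {
    abort("`baseline_control_rf` must be a single positive number.")
  }
  reduction <- 1 - rf_avg_control / baseline_control_rf
  status <- ifelse(reduction > config$lethality_fraction,
                   "lethal_excluded", "retain")
  status[is.na(rf_avg_control) | is_out(rf_avg_control)] <- NA_character_
  status
}

#' Control-derived RF-ratio threshold
#'
#' The diagnostic hit threshold is derived from the positive-control
#' (\emph{lis-1(RNAi)}) RF ratios collected across plates: mean + k * SD
#' (default k = 2, sample SD). The pipeline reports this threshold alongside
#' the configured hit cutoff used for selection.
#'
#' @param positive_control_ratios numeric vector of at least two determinate
#'   positive-control RF ratios.
#' @param config a [screen_config()].
#' @return The threshold (a single number).
#' @examples
#' compute_threshold(c(0.2, 0.3, 0.4))  # 0.3 + 2 * 0.1 = 0.5
#' @export
compute_threshold <- function(positive_control_ratios, config = screen_config()) {
  x <- positive_control_ratios
  x <- x[!is.na(x) & !is_out(x)]
  if (length(x) < 2) {
    abort("need at least two determinate positive-control ratios.")
  }
  s <- sd(x)
  if (config$sd_flavor == "population") {
    s <- s * sqrt((length(x) - 1) / length(x))
  }
  mean(x) + config$threshold_sigma_multiplier * s
}

#' Primary hit selection
#'
#' A scored clone is a primary hit when its RF ratio is at or below the hit
#' cutoff (inclusive, default 0.5). Undetermined and lethal-excluded clones
#' are never hits.
#'
#' @param results a per-clone results tibble with columns `rf_ratio` and
#'   `status` (as produced by [score_primary()]).
#' @param config a [screen_config()].
#' @return The subset of `results` that are hits.
#' @export
select_primary_hits <- function(results, config = screen_config()) {
  stopifnot(all(c("rf_ratio", "status") %in% names(results)))
  dplyr::filter(results, .data$status == "scored",
                !is.na(.data$rf_ratio), .data$rf_ratio <= config$hit_cutoff)
}

#' Final (secondary-screen) interactor selection
#'
#' A clone enters the final interactor list when the mean of its
#' biological-replicate RF ratios (each built from its own technical-replicate
#' RF averages) is at or below the hit cutoff. Undetermined replicate ratios
#' are skipped; a clone with no determinate biological replicate is reported
#' undetermined, never final.
#'
#' @param secondary_ratios tibble with one row per (clone, biological
#'   replicate): columns `Reagent_ID`, `bio_rep`, `rf_ratio` (NA when
#'   undetermined); extra identifier columns (e.g. `GeneSymbol`) are carried
#'   through.
#' @param config a [screen_config()].
#' @return A tibble with one row per clone: `mean_rf_ratio`, `n_bio_reps`
#'   (determinate replicate count), `status` and `is_final`.
#' @export
select_final_hits <- function(secondary_ratios, config = screen_config()) {
  stopifnot(all(c("Reagent_ID", "rf_ratio") %in% names(secondary_ratios)))
  carry <- intersect(c("GeneSymbol", "Plate", "Well"), names(secondary_ratios))
  out <- secondary_ratios |>
    dplyr::group_by(.data$Reagent_ID) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      mean_rf_ratio = mean_rf(.data$rf_ratio),
      n_bio_reps = sum(!is.na(.data$rf_ratio) & !is_out(.data$rf_ratio)),
      .groups = "drop"
    )
  out$mean_rf_ratio[is_out(out$mean_rf_ratio)] <- NA_real_
  out$status <- ifelse(out$n_bio_reps == 0, "undetermined", "scored")
  out$is_final <- out$status == "scored" & out$mean_rf_ratio <= config$hit_cutoff
  out
}

#' Flag putative suppressors
#'
#' Clones whose RF ratio lies strictly above the suppressor bound (default 1)
#' show decreased lethality in the mutant and are flagged as putative
#' suppressors. Undetermined clones are never flagged.
#'
#' @param results per-clone results tibble with `rf_ratio` and `status`.
#' @param config a [screen_config()].
#' @return `results` with a logical `is_suppressor` column.
#' @export
flag_suppressors <- function(results, config = screen_config()) {
  stopifnot(all(c("rf_ratio", "status") %in% names(results)))
  dplyr::mutate(results, is_suppressor = .data$status == "scored" &
                  !is.na(.data$rf_ratio) &
                  .data$rf_ratio > config$suppressor_bound)
}

# ---- table-level scoring -----------------------------------------------------

# per-row RF fields from counts (both technical replicates)
add_rf_columns <- function(tbl, config) {
  tbl |>
    dplyr::mutate(
      RF_R1 = compute_rf(.data$Ad_R1, .data$Prg_R1, config),
      RF_R2 = compute_rf(.data$Ad_R2, .data$Prg_R2, config),
      RF_Avg = purrr::map2_dbl(.data$RF_R1, .data$RF_R2, ~ mean_rf(c(.x, .y)))
    )
}

# plate-local negative-control baseline (CN1 wells, control strain), with a
# global fallback when a plate's own CN1 wells are all invalid
control_baselines <- function(scored, config) {
  cn1 <- scored |>
    dplyr::filter(.data$Strain == "control", .data$WellType == "CN1",
                  !is.na(.data$RF_Avg), !is_out(.data$RF_Avg))
  if (nrow(cn1) == 0) {
    abort("no usable empty-vector (CN1) control wells in the control strain; cannot set the lethality baseline.")
  }
  global <- mean(cn1$RF_Avg)
  per_plate <- cn1 |>
    dplyr::group_by(.data$Plate) |>
    dplyr::summarise(baseline = mean(.data$RF_Avg), .groups = "drop")
  list(per_plate = per_plate, global = global)
}

#' Score a primary-screen table
#'
#' Computes per-replicate RF values, replicate averages (skipping `OUT`),
#' mutant-over-control RF ratios, the lethality exclusion against the
#' plate-local empty-vector baseline, and the scored/undetermined/
#' lethal_excluded partition for every library clone of a two-strain screen
#' table.
#'
#' @param screen_tbl canonical screen table (see [read_screen_table()]) with
#'   both strains present.
#' @param config a [screen_config()].
#' @return A tibble with one row per library clone: identifiers, per-strain
#'   RF replicate values and averages, `rf_ratio`, `status`, `is_hit`,
#'   `is_suppressor`.
#' @export
score_primary <- function(screen_tbl, config = screen_config()) {
  stopifnot(all(screen_mandatory_cols %in% names(screen_tbl)))
  missing_strain <- setdiff(strain_codes, unique(screen_tbl$Strain))
  if (length(missing_strain) > 0) {
    abort(paste0("screen table lacks strain(s): ",
                 paste(missing_strain, collapse = ", ")))
  }
  scored <- add_rf_columns(screen_tbl, config)
  baselines <- control_baselines(scored, config)

  wide <- scored |>
    dplyr::filter(.data$WellType == "S") |>
    dplyr::select("Plate", "Well", "Reagent_ID", "GeneSymbol", "Strain",
                  "RF_R1", "RF_R2", "RF_Avg") |>
    tidyr::pivot_wider(names_from = "Strain",
                       values_from = c("RF_R1", "RF_R2", "RF_Avg"))
  for (col in c("RF_R1_control", "RF_R2_control", "RF_Avg_control",
                "RF_R1_mutant", "RF_R2_mutant", "RF_Avg_mutant")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  wide <- wide |>
    dplyr::left_join(baselines$per_plate, by = "Plate") |>
    dplyr::mutate(
      baseline = dplyr::coalesce(.data$baseline, baselines$global),
      rf_ratio = rf_ratio(.data$RF_Avg_mutant, .data$RF_Avg_control)
    )
  # lethality against the plate-local baseline
  wide$lethal <- purrr::pmap_chr(
    list(wide$RF_Avg_control, wide$baseline),
    function(rfc, base) lethality_filter(rfc, base, config)
  )
  wide <- wide |>
    dplyr::mutate(
      status = dplyr::case_when(
        !is.na(.data$lethal) & .data$lethal == "lethal_excluded" ~ "lethal_excluded",
        is.na(.data$rf_ratio) ~ "undetermined",
        TRUE ~ "scored"
      ),
      # excluded clones do not report a ratio
      rf_ratio = ifelse(.data$status == "lethal_excluded", NA_real_,
                        .data$rf_ratio),
      is_hit = .data$status == "scored" & .data$rf_ratio <= config$hit_cutoff
    ) |>
    dplyr::select(-"lethal", -"baseline")
  flag_suppressors(wide, config)
}

#' Score a secondary-screen table into per-biological-replicate RF ratios
#'
#' Each biological replicate contributes one RF ratio per clone, built from
#' that replicate's own technical-replicate RF averages in the two strains.
#'
#' @param screen_tbl canonical screen table with an additional `BioRep`
#'   column (integer biological-replicate index).
#' @param config a [screen_config()].
#' @return A tibble with one row per (clone, biological replicate):
#'   `Reagent_ID`, `GeneSymbol`, `bio_rep`, `rf_ratio` (`NA` when
#'   undetermined).
#' @export
score_secondary <- function(screen_tbl, config = screen_config()) {
  if (!"BioRep" %in% names(screen_tbl)) {
    abort("secondary screen table needs a `BioRep` column.")
  }
  scored <- add_rf_columns(screen_tbl, config)
  scored |>
    dplyr::filter(.data$WellType == "S") |>
    dplyr::select("Reagent_ID", "GeneSymbol", "BioRep", "Strain", "RF_Avg") |>
    tidyr::pivot_wider(names_from = "Strain", values_from = "RF_Avg",
                       names_prefix = "RF_Avg_") |>
    dplyr::mutate(rf_ratio = rf_ratio(.data$RF_Avg_mutant,
                                      .data$RF_Avg_control)) |>
    dplyr::select("Reagent_ID", "GeneSymbol", bio_rep = "BioRep", "rf_ratio")
}
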