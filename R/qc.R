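#' Pearson correlation between matched replicate RF vectors
#'
#' Technical-validation statistic of the screen: the Pearson correlation of
#' per-well RF values between two replicates, with the two-sided p-value from
#' the exact t transform on n - 2 degrees of freedom. Pairs where either
#' replicate is `OUT` or missing are dropped listwise before the correlation.
#'
#' @param x,y matched numeric vectors of per-well RF values.
#' @param pair_label label describing the comparison (e.g.
#'   `"control R1 vs R2"`).
#' @return A one-row tibble (`CorrelationReport`): `pair_label`, `r`,
#'   `p_value`, `n`.
#' @examples
#' replicate_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8.5))
#' @export
replicate_correlation <- function(x, y, pair_label = "R1 vs R2") {
  if (length(x) != length(y)) abort("`x` and `y` must be matched (same length).")
  ok <- !is.na(x) & !is.na(y)  # drops OUT (NaN) and missing
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    abort("need at least 3 usable pairs for a replicate correlation.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in one replicate.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(pair_label = pair_label,
                 r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = length(x))
}

#' Format a p-value the way screening reports print it
#'
#' @param p p-value.
#' @param floor values below the floor print as `"< floor"`; use `NULL` for
#'   exact formatting.
#' @return Character scalar.
#' @export
format_p_value <- function(p, floor = 1e-4) {
  if (!is.null(floor) && p < floor) {
    paste0("< ", format(floor, scientific = FALSE))
  } else {
    format(signif(p, 3), scientific = TRUE)
  }
}

#' Technical-replicate correlations of a screen table
#'
#' Runs [replicate_correlation()] on the two technical replicates' RF values,
#' one report per strain (and per biological replicate when a `BioRep` column
#' is present).
#'
#' @param screen_tbl canonical screen table.
#' @param config a [screen_config()].
#' @return A tibble of correlation reports.
#' @export
screen_replicate_correlations <- function(screen_tbl, config = screen_config()) {
  scored <- add_rf_columns(screen_tbl, config)
  if (!"BioRep" %in% names(scored)) scored$BioRep <- 1L
  scored |>
    dplyr::group_by(.data$Strain, .data$BioRep) |>
    dplyr::group_modify(function(d, key) {
      replicate_correlation(d$RF_R1, d$RF_R2, pair_label = "tech R1 vs R2")
    }) |>
    dplyr::ungroup()
}

#' Per-plate control separation
#'
#' For each plate, computes the RF ratio of every control well (empty vector
#' `CN1`, \emph{hil-5} `CN2`, \emph{lis-1} `CP`, \emph{plk-1} `C`) and flags
#' the plate as separated when all its determinate negative-control ratios lie
#' above the hit cutoff and all its determinate positive-control ratios at or
#' below it. Plates missing a control type report `NA` for it and an `NA`
#' separation flag.
#'
#' @param screen_tbl canonical screen table with both strains.
#' @param config a [screen_config()].
#' @return A tibble with one row per (plate, control well): `Plate`, `Well`,
#'   `WellType`, `rf_ratio`, plus a per-plate `separated` flag.
#' @export
control_separation <- function(screen_tbl, config = screen_config()) {
  scored <- add_rf_columns(screen_tbl, config)
  ctl <- scored |>
    dplyr::filter(.data$WellType %in% c("CN1", "CN2", "CP", "C")) |>
    dplyr::select("Plate", "Well", "WellType", "Strain", "RF_Avg") |>
    tidyr::pivot_wider(names_from = "Strain", values_from = "RF_Avg",
                       names_prefix = "RF_Avg_") |>
    dplyr::mutate(rf_ratio = rf_ratio(.data$RF_Avg_mutant,
                                      .data$RF_Avg_control))
  flags <- ctl |>
    dplyr::group_by(.data$Plate) |>
    dplyr::summarise(
      separated = {
        neg <- .data$rf_ratio[.data$WellType %in% c("CN1", "CN2")]
        pos <- .data$rf_ratio[.data$WellType == "CP"]
        neg <- neg[!is.na(neg)]
        pos <- pos[!is.na(pos)]
        if (length(neg) == 0 || length(pos) == 0) NA
        else all(neg > config$hit_cutoff) && all(pos <= config$hit_cutoff)
      },
      .groups = "drop"
    )
  dplyr::left_join(ctl, flags, by = "Plate") |>
    dplyr::select("Plate", "Well", "WellType", "rf_ratio", "separated")
}
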