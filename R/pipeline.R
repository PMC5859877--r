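manifest_counts <- function(results) {
  tibble::tibble(
    clones_in = nrow(results),
    scored = sum(results$status == "scored"),
    undetermined = sum(results$status == "undetermined"),
    lethal_excluded = sum(results$status == "lethal_excluded")
  )
}

#' Run the primary-screen scoring stage
#'
#' Scores a two-strain, two-technical-replicate screen table end to end:
#' per-replicate RF values, replicate averages, RF ratios, the lethality
#' exclusion, the scored/undetermined/lethal_excluded partition, primary hit
#' selection at the configured cutoff, suppressor flagging, and the
#' control-derived diagnostic threshold (mean + 2 SD of the
#' positive-control ratios). The run manifest reconciles the partition:
#' clones in = scored + undetermined + lethal excluded.
#'
#' @param screen_tbl canonical screen table (see [read_screen_table()]) with
#'   both strains and both technical replicates.
#' @param config a [screen_config()].
#' @return An object of class `primary_screen`: list with `results` (per-clone
#'   tibble), `hits`, `control_threshold`, `control_ratios`, `config` and
#'   `manifest`.
#' @seealso [run_secondary()], [tidy.primary_screen()],
#'   [autoplot.primary_screen()]
#' @export
run_primary <- function(screen_tbl, config = screen_config()) {
  for (strain in strain_codes) {
    sub <- screen_tbl[screen_tbl$Strain == strain & screen_tbl$WellType == "S", ]
    if (nrow(sub) == 0 || all(is.na(sub$Ad_R1)) || all(is.na(sub$Ad_R2))) {
      abort(paste0("strain '", strain,
                   "' is missing a technical replicate (or absent)."))
    }
  }
  results <- score_primary(screen_tbl, config)
  hits <- select_primary_hits(results, config)
  ctl <- control_separation(screen_tbl, config)
  cp_ratios <- ctl$rf_ratio[ctl$WellType == "CP" & !is.na(ctl$rf_ratio)]
  threshold <- if (length(cp_ratios) >= 2) {
    compute_threshold(cp_ratios, config)
  } else {
    NA_real_
  }
  manifest <- dplyr::bind_cols(
    manifest_counts(results),
    tibble::tibble(
      wells_read = nrow(screen_tbl),
      wells_out = sum(is_out(compute_rf(screen_tbl$Ad_R1, screen_tbl$Prg_R1,
                                        config))) +
        sum(is_out(compute_rf(screen_tbl$Ad_R2, screen_tbl$Prg_R2, config))),
      primary_hits = nrow(hits),
      suppressors_flagged = sum(results$is_suppressor),
      control_threshold = threshold,
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )
  structure(
    list(results = results, hits = hits,
         control_threshold = threshold, control_ratios = cp_ratios,
         control_separation = ctl, config = config, manifest = manifest),
    class = "primary_screen"
  )
}

#' Run the secondary-screen scoring stage
#'
#' Scores a three-biological-replicate secondary screen (two technical
#' replicates each) restricted to the re-arrayed primary hits: one RF ratio
#' per clone and biological replicate, then final interactor selection on the
#' mean over determinate replicate ratios.
#'
#' @param primary_hits character vector of primary-hit `Reagent_ID`s (or the
#'   hits tibble of [run_primary()]).
#' @param screen_tbl canonical secondary screen table with a `BioRep` column.
#' @param config a [screen_config()].
#' @return An object of class `secondary_screen`: list with `ratios` (per
#'   clone x biological replicate), `results` (per clone, with `is_final`),
#'   `final_hits`, `config` and `manifest`.
#' @export
run_secondary <- function(primary_hits, screen_tbl, config = screen_config()) {
  if (is.data.frame(primary_hits)) primary_hits <- primary_hits$Reagent_ID
  ratios <- score_secondary(screen_tbl, config)
  stray <- setdiff(unique(ratios$Reagent_ID), primary_hits)
  if (length(stray) > 0) {
    warn(paste0(length(stray), " clone(s) in the secondary tables were not ",
                "primary hits; scored anyway."))
  }
  results <- select_final_hits(ratios, config)
  final_hits <- dplyr::filter(results, .data$is_final)
  manifest <- tibble::tibble(
    clones_in = nrow(results),
    scored = sum(results$status == "scored"),
    undetermined = sum(results$status == "undetermined"),
    lethal_excluded = 0L,
    bio_reps = length(unique(ratios$bio_rep)),
    final_hits = nrow(final_hits),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(
    list(ratios = ratios, results = results, final_hits = final_hits,
         config = config, manifest = manifest),
    class = "secondary_screen"
  )
}

#' Simulate and score a full two-stage screen
#'
#' Convenience wrapper reproducing the published screen design on synthetic
#' data: generate a primary screen (two technical replicates), score it,
#' re-array the primary hits onto fresh plates, generate three independent
#' biological replicates of the secondary screen for those clones, and select
#' the final interactor list.
#'
#' @param model a [screen_model()] (its `n_biological_reps` is ignored; the
#'   primary stage uses one biological replicate and the secondary three).
#' @param config a [screen_config()].
#' @return A list with `primary` (a `primary_screen`), `secondary` (a
#'   `secondary_screen`), and `truth` (the generator's ground-truth table).
#' @export
run_two_stage <- function(model, config = screen_config()) {
  scr <- generate_screen(model)
  primary <- run_primary(scr$tbl, config)
  hit_ids <- primary$hits$Reagent_ID
  if (length(hit_ids) == 0) {
    return(list(primary = primary, secondary = NULL, truth = scr$truth))
  }
  sec_tbls <- purrr::map(1:3, function(b) {
    rep_scr <- generate_screen(model, genes = hit_ids,
                               seed = model$seed + 1000L * b)
    dplyr::mutate(rep_scr$tbl, BioRep = b)
  })
  secondary <- run_secondary(hit_ids, dplyr::bind_rows(sec_tbls), config)
  list(primary = primary, secondary = secondary, truth = scr$truth)
}

#' @export
print.primary_screen <- function(x, ...) {
  m <- x$manifest
  cat("<primary_screen>", m$clones_in, "clones:", m$scored, "scored,",
      m$undetermined, "undetermined,", m$lethal_excluded, "lethal-excluded\n")
  cat("  primary hits (RF ratio <=", x$config$hit_cutoff, "):",
      m$primary_hits, "\n")
  cat("  control-derived threshold (mean + ",
      x$config$threshold_sigma_multiplier, " SD): ",
      round(x$control_threshold, 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.secondary_screen <- function(x, ...) {
  m <- x$manifest
  cat("<secondary_screen>", m$clones_in, "clones over", m$bio_reps,
      "biological replicates;", m$final_hits, "final interactor(s)\n")
  invisible(x)
}

#' Write a run manifest as JSON
#'
#' @param run a `primary_screen` or `secondary_screen` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  stopifnot(inherits(run, c("primary_screen", "secondary_screen")))
  jsonlite::write_json(as.list(run$manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- broom-style accessors ---------------------------------------------------

#' Tidy per-clone results of a screen run
#'
#' @param x a `primary_screen` or `secondary_screen` object.
#' @param ... unused.
#' @return A tibble with one row per clone.
#' @export
tidy.primary_screen <- function(x, ...) x$results

#' @rdname tidy.primary_screen
#' @export
tidy.secondary_screen <- function(x, ...) x$results

#' One-row run summary of a screen run
#'
#' @param x a `primary_screen` or `secondary_screen` object.
#' @param ... unused.
#' @return The run manifest as a one-row tibble.
#' @export
glance.primary_screen <- function(x, ...) x$manifest

#' @rdname glance.primary_screen
#' @export
glance.secondary_screen <- function(x, ...) x$manifest
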