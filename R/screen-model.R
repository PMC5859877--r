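#' Ground-truth model of a synthetic two-strain RNAi screen
#'
#' Describes the statistical structure of a simulated modifier screen: plate
#' count and library size, founder worms per well, baseline reproductive
#' fitness (progeny per parent) in the control and sensitized mutant strains,
#' overdispersion of the progeny-count noise, and per-gene effect multipliers
#' with planted enhancers, suppressors and lethal clones. A gene's true RF
#' ratio is `multiplier_mutant / multiplier_control` (the baseline ratio
#' cancels when comparing to the screen's own negative controls).
#'
#' Unplanted library genes share a lognormal fertility multiplier between the
#' two strains (`effect_sdlog`), emulating the natural spread of fertility
#' phenotypes across an RNAi library; this shared spread leaves RF ratios
#' centred on the baseline ratio while giving technical replicates the
#' realistic correlation structure of a real screen.
#'
#' @param n_plates number of 96-well library plates.
#' @param genes_per_plate library clones per plate (at most 88; column 1 is
#'   reserved for controls).
#' @param founder_mean expected number of founder (parent) worms dispensed per
#'   well. Default 7.
#' @param baseline_rf_control,baseline_rf_mutant mean progeny per parent on
#'   empty-vector RNAi in the two strains. Defaults 10 and 9 (the mutant's
#'   fertility is only mildly reduced).
#' @param dispersion negative-binomial size parameter of the progeny-count
#'   noise (variance m + m^2/dispersion); smaller values mean more
#'   overdispersion. Default 15.
#' @param effect_sdlog lognormal SD of the shared per-gene fertility
#'   multiplier for unplanted genes. Default 0.45. Set 0 for a null screen
#'   where every multiplier is exactly 1.
#' @param n_enhancers,enhancer_ratio number of planted enhancer clones and
#'   their true RF ratio (mutant multiplier = `enhancer_ratio` x control
#'   multiplier). Defaults 0 and 0.3.
#' @param n_suppressors,suppressor_ratio planted suppressors and their true
#'   ratio (> 1). Defaults 0 and 1.6.
#' @param n_lethals,lethal_multiplier planted broadly lethal clones; the
#'   multiplier (both strains) must be at most 0.15 so the clone trips the
#'   85 % lethality exclusion. Defaults 0 and 0.05.
#' @param gene_effects optional explicit effect table overriding the planted
#'   sets: tibble with columns `Reagent_ID`, `GeneSymbol`,
#'   `multiplier_control`, `multiplier_mutant`, `role`.
#' @param n_technical_reps technical replicates per strain. Default 2.
#' @param n_biological_reps biological replicates. Default 1 (primary screen).
#' @param control_template column-1 layout passed to [default_layout()].
#' @param deterministic if `TRUE`, all noise is switched off: adult counts are
#'   `round(founder_mean)` and progeny counts their exact expectations.
#' @param seed integer seed; the same model generates bit-identical screens.
#'
#' @return An object of class `screen_model`.
#' @seealso [generate_screen()]
#' @export
screen_model <- function(n_plates = 5,
                         genes_per_plate = 88,
                         founder_mean = 7,
                         baseline_rf_control = 10,
                         baseline_rf_mutant = 9,
                         dispersion = 15,
                         effect_sdlog = 0.45,
                         n_enhancers = 0, enhancer_ratio = 0.3,
                         n_suppressors = 0, suppressor_ratio = 1.6,
                         n_lethals = 0, lethal_multiplier = 0.05,
                         gene_effects = NULL,
                         n_technical_reps = 2,
                         n_biological_reps = 1,
                         control_template = c("CN1", "CN2", "CP", "C",
                                              "CN1", "CN2", "CP", "E"),
                         deterministic = FALSE,
                         seed = 1L) {
  if (genes_per_plate > 88) {
    abort("`genes_per_plate` must be <= 88: column 1 is reserved for controls.")
  }
  if (enhancer_ratio > 0.5) {
    abort("planted enhancers must have a true RF ratio <= 0.5.")
  }
  if (suppressor_ratio <= 1) {
    abort("planted suppressors must have a true RF ratio > 1.")
  }
  if (lethal_multiplier > 0.15) {
    abort("planted lethal clones must have a control-strain multiplier <= 0.15.")
  }
  n_genes <- n_plates * genes_per_plate
  n_planted <- n_enhancers + n_suppressors + n_lethals
  if (is.null(gene_effects)) {
    if (n_planted > n_genes) abort("more planted genes than library wells.")
    role <- rep("neutral", n_genes)
    if (n_planted > 0) {
      # spread planted genes across the library deterministically
      slots <- unique(round(seq(1, n_genes, length.out = max(n_planted, 2))))
      slots <- slots[seq_len(n_planted)]
      role[slots] <- rep(c("enhancer", "suppressor", "lethal"),
                         c(n_enhancers, n_suppressors, n_lethals))
    }
    gene_effects <- tibble::tibble(
      Reagent_ID = sprintf("SG%05d", seq_len(n_genes)),
      GeneSymbol = sprintf("sim-%d", seq_len(n_genes)),
      role = role,
      multiplier_control = 1,
      multiplier_mutant = 1
    )
    gene_effects$multiplier_control[role == "lethal"] <- lethal_multiplier
    gene_effects$multiplier_mutant[role == "lethal"] <- lethal_multiplier
    gene_effects$multiplier_mutant[role == "enhancer"] <- enhancer_ratio
    gene_effects$multiplier_mutant[role == "suppressor"] <- suppressor_ratio
  } else {
    needed <- c("Reagent_ID", "GeneSymbol", "multiplier_control",
                "multiplier_mutant", "role")
    if (!all(needed %in% names(gene_effects))) {
      abort(paste0("`gene_effects` needs columns: ",
                   paste(needed, collapse = ", ")))
    }
    if (nrow(gene_effects) != n_genes) {
      abort("`gene_effects` must have one row per library well.")
    }
  }
  if (any(gene_effects$multiplier_control < 0 |
          gene_effects$multiplier_mutant < 0)) {
    abort("effect multipliers must be >= 0.")
  }
  bad_lethal <- gene_effects$role == "lethal" &
    gene_effects$multiplier_control > 0.15
  if (any(bad_lethal)) {
    abort("lethal genes must have multiplier_control <= 0.15.")
  }
  structure(
    list(
      n_plates = as.integer(n_plates),
      genes_per_plate = as.integer(genes_per_plate),
      founder_mean = founder_mean,
      baseline_rf_control = baseline_rf_control,
      baseline_rf_mutant = baseline_rf_mutant,
      dispersion = dispersion,
      effect_sdlog = effect_sdlog,
      gene_effects = gene_effects,
      n_technical_reps = as.integer(n_technical_reps),
      n_biological_reps = as.integer(n_biological_reps),
      control_template = control_template,
      deterministic = isTRUE(deterministic),
      seed = as.integer(seed)
    ),
    class = "screen_model"
  )
}

#' @export
print.screen_model <- function(x, ...) {
  cat("<screen_model>", x$n_plates, "plate(s) x", x$genes_per_plate,
      "library clones,", x$n_biological_reps, "biological x",
      x$n_technical_reps, "technical replicate(s)\n")
  cat("  baselines (control/mutant):", x$baseline_rf_control, "/",
      x$baseline_rf_mutant, "progeny per parent; dispersion",
      x$dispersion, "\n")
  cat("  planted:", sum(x$gene_effects$role == "enhancer"), "enhancer(s),",
      sum(x$gene_effects$role == "suppressor"), "suppressor(s),",
      sum(x$gene_effects$role == "lethal"), "lethal(s); seed", x$seed, "\n")
  invisible(x)
}

# multipliers of the four control well types, by strain. lis-1 RNAi reduces
# fertility in both strains but far more in the sensitized mutant; hil-5 RNAi
# causes 10-20 % embryonic lethality in the mutant only; plk-1 RNAi is fully
# lethal in both.
control_effects <- function() {
  tibble::tibble(
    WellType = c("CN1", "CN2", "CP", "C"),
    Reagent_ID = c("CTRL_empty", "CTRL_hil-5", "CTRL_lis-1", "CTRL_plk-1"),
    GeneSymbol = c("empty", "hil-5", "lis-1", "plk-1"),
    multiplier_control = c(1, 1, 0.5, 0),
    multiplier_mutant = c(1, 0.85, 0.15, 0)
  )
}

#' Generate a synthetic two-strain screen
#'
#' Simulates per-well adult and progeny counts for every
#' (plate, well, strain, biological replicate, technical replicate)
#' combination of the model. Adult counts are Poisson around the founder mean
#' (capped at three times the mean), so occasional wells fall outside the 3-13
#' validity window; progeny counts are negative-binomial with mean
#' `adults x baseline RF x multiplier`. Column 1 of every plate carries the
#' control wells of the model's template.
#'
#' @param model a [screen_model()].
#' @param genes optional character vector of `Reagent_ID`s to restrict the
#'   library to (re-arrayed onto fresh plates in order), e.g. for a secondary
#'   screen of primary hits.
#' @param seed optional seed overriding `model$seed` (used to make biological
#'   re-runs independent).
#' @return A list with `tbl` — the screen table (canonical columns plus
#'   `BioRep`) — and `truth` — the ground-truth effect table with each
#'   clone's role, multipliers and `true_ratio`
#'   (`multiplier_mutant / multiplier_control`).
#' @examples
#' scr <- generate_screen(screen_model(n_plates = 1, seed = 42))
#' head(scr$tbl)
#' @export
generate_screen <- function(model, genes = NULL, seed = NULL) {
  stopifnot(inherits(model, "screen_model"))
  withr::with_seed(seed %||% model$seed, {
  effects <- model$gene_effects
  if (!is.null(genes)) {
    effects <- effects[match(genes, effects$Reagent_ID), ]
    if (anyNA(effects$Reagent_ID)) abort("unknown Reagent_ID in `genes`.")
  }
  n_genes <- nrow(effects)
  n_plates <- ceiling(n_genes / model$genes_per_plate)

  # shared lognormal fertility spread for unplanted genes
  spread <- rep(1, n_genes)
  if (model$effect_sdlog > 0 && !model$deterministic) {
    neutral <- effects$role == "neutral"
    spread[neutral] <- exp(rnorm(sum(neutral), 0, model$effect_sdlog))
  }
  effects$multiplier_control <- effects$multiplier_control * spread
  effects$multiplier_mutant <- effects$multiplier_mutant * spread

  layout <- default_layout(model$control_template)
  lib_wells <- layout$Well[layout$WellType == "S"]
  plate_of <- rep(seq_len(n_plates), each = model$genes_per_plate)[seq_len(n_genes)]
  well_of <- rep(lib_wells[seq_len(model$genes_per_plate)],
                 times = n_plates)[seq_len(n_genes)]

  gene_rows <- tibble::tibble(
    Plate = sprintf("P%02d", plate_of),
    Well = well_of,
    WellType = "S",
    Reagent_ID = effects$Reagent_ID,
    GeneSymbol = effects$GeneSymbol,
    multiplier_control = effects$multiplier_control,
    multiplier_mutant = effects$multiplier_mutant
  )
  ctl <- control_effects()
  ctl_rows <- layout |>
    dplyr::filter(.data$WellType != "S") |>
    dplyr::cross_join(tibble::tibble(Plate = sprintf("P%02d", seq_len(n_plates)))) |>
    dplyr::left_join(ctl, by = "WellType") |>
    dplyr::select("Plate", "Well", "WellType", "Reagent_ID", "GeneSymbol",
                  "multiplier_control", "multiplier_mutant")
  wells <- dplyr::bind_rows(gene_rows, ctl_rows) |>
    dplyr::arrange(.data$Plate, .data$Well)

  reps <- tidyr::expand_grid(
    BioRep = seq_len(model$n_biological_reps),
    Strain = strain_codes
  )
  long <- dplyr::cross_join(wells, reps)
  baseline <- ifelse(long$Strain == "control",
                     model$baseline_rf_control, model$baseline_rf_mutant)
  multiplier <- ifelse(long$Strain == "control",
                       long$multiplier_control, long$multiplier_mutant)
  empty <- long$WellType == "E"

  draw_counts <- function(n) {
    if (model$deterministic) {
      adults <- rep(round(model$founder_mean), n)
    } else {
      adults <- pmin(rpois(n, model$founder_mean),
                     ceiling(3 * model$founder_mean))
    }
    mu <- adults * baseline * multiplier
    mu[is.na(mu)] <- 0
    if (model$deterministic) {
      progeny <- round(mu)
    } else {
      progeny <- rnbinom(n, size = model$dispersion, mu = mu)
    }
    adults[empty] <- NA_integer_
    progeny[empty] <- NA_integer_
    list(adults = as.integer(adults), progeny = as.integer(progeny))
  }
  if (model$n_technical_reps != 2) {
    abort("the screen-record schema carries exactly two technical replicates.")
  }
  n <- nrow(long)
  r1 <- draw_counts(n)
  r2 <- draw_counts(n)

  tbl <- long |>
    dplyr::transmute(
      Plate = .data$Plate, Well = .data$Well, WellType = .data$WellType,
      Reagent_ID = ifelse(empty, NA_character_, .data$Reagent_ID),
      Strain = .data$Strain,
      Ad_R1 = r1$adults, Prg_R1 = r1$progeny,
      Ad_R2 = r2$adults, Prg_R2 = r2$progeny,
      RF_R1 = NA_real_, RF_R2 = NA_real_, RF_Avg = NA_real_,
      RF_ratio = NA_real_,
      GeneSymbol = ifelse(empty, NA_character_, .data$GeneSymbol),
      BioRep = .data$BioRep
    )
  truth <- effects |>
    dplyr::mutate(true_ratio = ifelse(.data$multiplier_control > 0,
                                      .data$multiplier_mutant /
                                        .data$multiplier_control, NA_real_),
                  Plate = gene_rows$Plate, Well = gene_rows$Well)
  list(tbl = tbl, truth = truth, seed = seed %||% model$seed)
  })
}
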