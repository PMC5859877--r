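# Small hand-built screen tables used across test files.

# one plate, two library clones + one CN1 control, both strains; counts chosen
# so RF values are simple fractions
tiny_screen_table <- function() {
  tibble::tibble(
    Plate = "P01",
    Well = c("A1", "A2", "A3", "A1", "A2", "A3"),
    WellType = c("CN1", "S", "S", "CN1", "S", "S"),
    Reagent_ID = c("CTRL_empty", "G1", "G2", "CTRL_empty", "G1", "G2"),
    Strain = rep(c("control", "mutant"), each = 3),
    Ad_R1 = c(7L, 7L, 7L, 7L, 7L, 7L),
    Prg_R1 = c(70L, 70L, 70L, 70L, 35L, 7L),
    Ad_R2 = c(7L, 7L, 2L, 7L, 7L, 2L),
    Prg_R2 = c(70L, 70L, 99L, 70L, 35L, 99L),
    RF_R1 = NA_real_, RF_R2 = NA_real_, RF_Avg = NA_real_,
    RF_ratio = NA_real_,
    GeneSymbol = c("empty", "gene-1", "gene-2", "empty", "gene-1", "gene-2")
  )
}

# expand a per-clone count spec into a two-strain screen table with a healthy
# CN1 baseline (RF 10 in both strains)
counts_to_table <- function(counts) {
  # counts: tibble(Reagent_ID, ad1_c, pr1_c, ad2_c, pr2_c, ad1_m, pr1_m, ad2_m, pr2_m)
  n <- nrow(counts)
  wells <- default_layout()$Well[default_layout()$WellType == "S"][seq_len(n)]
  lib <- tibble::tibble(
    Plate = "P01", Well = rep(wells, 2), WellType = "S",
    Reagent_ID = rep(counts$Reagent_ID, 2),
    Strain = rep(c("control", "mutant"), each = n),
    Ad_R1 = c(counts$ad1_c, counts$ad1_m),
    Prg_R1 = c(counts$pr1_c, counts$pr1_m),
    Ad_R2 = c(counts$ad2_c, counts$ad2_m),
    Prg_R2 = c(counts$pr2_c, counts$pr2_m),
    RF_R1 = NA_real_, RF_R2 = NA_real_, RF_Avg = NA_real_,
    RF_ratio = NA_real_, GeneSymbol = rep(counts$Reagent_ID, 2)
  )
  ctl <- tibble::tibble(
    Plate = "P01", Well = "A1", WellType = "CN1",
    Reagent_ID = "CTRL_empty",
    Strain = c("control", "mutant"),
    Ad_R1 = 7L, Prg_R1 = 70L, Ad_R2 = 7L, Prg_R2 = 70L,
    RF_R1 = NA_real_, RF_R2 = NA_real_, RF_Avg = NA_real_,
    RF_ratio = NA_real_, GeneSymbol = "empty"
  )
  dplyr::bind_rows(lib, ctl)
}

# straight-line re-derivation of primary hits from raw counts, independent of
# the package's scoring path (used as the oracle on small screens)
brute_force_primary_hits <- function(tbl, cutoff = 0.5, window = c(3, 13),
                                     lethal_frac = 0.85) {
  rf1 <- function(ad, pr) {
    if (is.na(ad) || is.na(pr)) return(NA_real_)
    if (ad < window[1] || ad > window[2]) return(NaN)
    pr / ad
  }
  avg1 <- function(a, b) {
    v <- c(a, b); v <- v[!is.na(v)]
    if (length(v) == 0) NaN else mean(v)
  }
  baselines <- list()
  for (p in unique(tbl$Plate)) {
    rows <- tbl[tbl$Plate == p & tbl$WellType == "CN1" &
                  tbl$Strain == "control", ]
    vals <- c()
    for (i in seq_len(nrow(rows))) {
      a <- avg1(rf1(rows$Ad_R1[i], rows$Prg_R1[i]),
                rf1(rows$Ad_R2[i], rows$Prg_R2[i]))
      if (!is.na(a)) vals <- c(vals, a)
    }
    baselines[[p]] <- if (length(vals)) mean(vals) else NA_real_
  }
  hits <- character(0)
  s_rows <- tbl[tbl$WellType == "S" & tbl$Strain == "control", ]
  for (i in seq_len(nrow(s_rows))) {
    key <- s_rows[i, c("Plate", "Well")]
    crow <- s_rows[i, ]
    mrow <- tbl[tbl$Plate == key$Plate & tbl$Well == key$Well &
                  tbl$Strain == "mutant" & tbl$WellType == "S", ]
    if (nrow(mrow) != 1) next
    rfc <- avg1(rf1(crow$Ad_R1, crow$Prg_R1), rf1(crow$Ad_R2, crow$Prg_R2))
    rfm <- avg1(rf1(mrow$Ad_R1, mrow$Prg_R1), rf1(mrow$Ad_R2, mrow$Prg_R2))
    if (is.na(rfc)) next                       # undetermined
    base <- baselines[[crow$Plate]]
    if (1 - rfc / base > lethal_frac) next     # lethal excluded
    if (is.na(rfm) || rfc <= 0) next           # undetermined
    if (rfm / rfc <= cutoff) hits <- c(hits, crow$Reagent_ID)
  }
  sort(hits)
}

# override fields of a params/spec object in place (NULL removes the field)
modifyList2 <- function(p, ...) {
  v <- list(...)
  for (n in names(v)) p[[n]] <- v[[n]]
  p
}

scene_counts <- function(truth) {
  c(parents = sum(truth$expected_label == "parent"),
    larvae = sum(truth$expected_label == "progeny"),
    rejected = sum(truth$expected_label == "rejected"))
}
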