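test_that("reproductive fitness is progeny per parent inside the 3-13 window", {
  expect_equal(compute_rf(7, 70), 10)
  expect_true(is_out(compute_rf(2, 50)))   # too few parents
  expect_true(is_out(compute_rf(14, 50)))  # too many parents
  expect_equal(compute_rf(13, 0), 0)       # boundary parents, zero progeny
  expect_equal(compute_rf(3, 30), 10)      # lower boundary is inclusive
  expect_true(is.na(compute_rf(NA, 10)) && !is_out(compute_rf(NA, 10)))
  expect_error(compute_rf(-1, 5), "non-negative")
  # vectorized
  expect_equal(compute_rf(c(7, 2, 13), c(70, 50, 13)),
               c(10, rf_out(), 1))
})

test_that("replicate averaging skips OUT and keeps the single replicate that worked", {
  expect_equal(average_rf(c(10, 20)), 15)
  expect_equal(average_rf(c(10, rf_out())), 10)
  expect_true(is_out(average_rf(c(rf_out(), rf_out()))))
  expect_error(average_rf(numeric(0)), "at least one")
})

test_that("RF ratio divides mutant by control and is undetermined otherwise", {
  expect_equal(rf_ratio(5, 10), 0.5)
  for (x in c(0.3, 1, 7.5)) expect_equal(rf_ratio(x, x), 1)
  expect_true(is.na(rf_ratio(4, rf_out())))
  expect_true(is.na(rf_ratio(rf_out(), 4)))
  expect_true(is.na(rf_ratio(4, 0)))  # zero control RF
})

test_that("lethality exclusion is strict at the 85 % reduction bound", {
  expect_equal(lethality_filter(1.0, 10), "lethal_excluded")  # 90 % reduction
  expect_equal(lethality_filter(1.5, 10), "retain")           # exactly 85 %
  expect_equal(lethality_filter(10, 10), "retain")            # no reduction
  expect_true(is.na(lethality_filter(rf_out(), 10)))
  expect_error(lethality_filter(1, baseline_control_rf = 0), "positive")
})

test_that("control threshold equals mean + 2 SD against an independent oracle", {
  # zero variance: threshold collapses to the common value
  expect_equal(compute_threshold(c(0.4, 0.4, 0.4)), 0.4)
  # sample SD of {0.2, 0.3, 0.4} is 0.1, so mean + 2 SD = 0.5
  expect_equal(compute_threshold(c(0.2, 0.3, 0.4)), 0.5)
  # random inputs vs straight-line arithmetic
  set.seed(401)
  for (i in 1:25) {
    x <- runif(sample(2:40, 1), 0, 2)
    n <- length(x)
    mu <- sum(x) / n
    s_sample <- sqrt(sum((x - mu)^2) / (n - 1))
    expect_equal(compute_threshold(x), mu + 2 * s_sample,
                 tolerance = 1e-12)
    expect_equal(
      compute_threshold(x, screen_config(sd_flavor = "population")),
      mu + 2 * sqrt(sum((x - mu)^2) / n),
      tolerance = 1e-12)
  }
  expect_error(compute_threshold(0.4), "at least two")
  expect_error(compute_threshold(c(0.4, rf_out())), "at least two")
})

test_that("primary hit selection is inclusive at the cutoff and excludes non-scored clones", {
  results <- tibble::tibble(
    Reagent_ID = c("a", "b", "c", "d"),
    rf_ratio = c(0.5, 0.51, NA, 0.1),
    status = c("scored", "scored", "undetermined", "lethal_excluded")
  )
  hits <- select_primary_hits(results)
  expect_equal(hits$Reagent_ID, "a")
})

test_that("final selection averages over available biological replicates", {
  ratios <- tibble::tibble(
    Reagent_ID = rep(c("a", "b", "c", "d"), each = 3),
    bio_rep = rep(1:3, 4),
    rf_ratio = c(0.4, 0.5, 0.6,    # mean 0.5 -> final (inclusive)
                 0.4, 0.9, 0.9,    # mean 0.733 -> not final
                 0.3, NA, 0.5,     # mean over the two scored = 0.4 -> final
                 NA, NA, NA)       # undetermined
  )
  out <- select_final_hits(ratios)
  out <- out[match(c("a", "b", "c", "d"), out$Reagent_ID), ]
  expect_equal(out$is_final, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$status, c("scored", "scored", "scored", "undetermined"))
  expect_equal(out$mean_rf_ratio[3], 0.4)
  expect_equal(out$n_bio_reps, c(3, 3, 2, 0))
  # cross-check the skip-missing averaging by brute force over inclusion
  x <- c(0.3, NA, 0.5)
  expect_equal(mean(x[!is.na(x)]), 0.4)
})

test_that("suppressor flagging is strict at ratio 1", {
  results <- tibble::tibble(rf_ratio = c(1.0, 1.6, NA),
                            status = c("scored", "scored", "undetermined"))
  out <- flag_suppressors(results)
  expect_equal(out$is_suppressor, c(FALSE, TRUE, FALSE))
})

test_that("scoring a small hand-built table gives the hand-computed results", {
  res <- score_primary(tiny_screen_table())
  res <- res[match(c("G1", "G2"), res$Reagent_ID), ]
  # G1: control RF 10/10 -> 10; mutant 5/5 -> 5; ratio 0.5 -> hit
  expect_equal(res$rf_ratio[1], 0.5)
  expect_true(res$is_hit[1])
  # G2: R2 has 2 adults in both strains -> OUT; single-replicate averages
  expect_true(is_out(res$RF_R2_control[2]))
  expect_equal(res$RF_Avg_control[2], 10)
  expect_equal(res$rf_ratio[2], 0.1)
})

test_that("hit sets are monotone in the cutoff", {
  counts <- tibble::tibble(
    Reagent_ID = sprintf("g%02d", 1:20),
    ad1_c = 7L, pr1_c = 70L, ad2_c = 7L, pr2_c = 70L,
    ad1_m = 7L, pr1_m = as.integer(seq(0, 95, by = 5)), ad2_m = 7L,
    pr2_m = as.integer(seq(0, 95, by = 5))
  )
  tbl <- counts_to_table(counts)
  cuts <- c(0.2, 0.5, 0.8, 1.2)
  hit_sets <- lapply(cuts, function(cc) {
    sort(select_primary_hits(score_primary(tbl, screen_config(hit_cutoff = cc)),
                             screen_config(hit_cutoff = cc))$Reagent_ID)
  })
  for (i in 1:(length(cuts) - 1)) {
    expect_true(all(hit_sets[[i]] %in% hit_sets[[i + 1]]))
  }
})

test_that("RF ratios are invariant under a common progeny rescaling", {
  scr <- generate_screen(screen_model(n_plates = 1, seed = 21))
  tbl <- scr$tbl
  scaled <- dplyr::mutate(tbl, Prg_R1 = Prg_R1 * 3L, Prg_R2 = Prg_R2 * 3L)
  r1 <- score_primary(tbl)
  r2 <- score_primary(scaled)
  expect_equal(r2$rf_ratio, r1$rf_ratio)
  expect_equal(r2$status, r1$status)
})

test_that("supplying the control strain as both strains gives ratio 1 everywhere", {
  scr <- generate_screen(screen_model(n_plates = 2, seed = 22))
  ctl <- dplyr::filter(scr$tbl, Strain == "control")
  both <- dplyr::bind_rows(ctl, dplyr::mutate(ctl, Strain = "mutant"))
  res <- score_primary(both)
  determinate <- res$status == "scored"
  expect_true(all(res$rf_ratio[determinate] == 1))
  expect_equal(nrow(select_primary_hits(res)), 0)
})

test_that("every clone lands in exactly one partition and matches the brute-force oracle", {
  # small screens with planted lethals and enhancers, vs straight-line oracle
  for (s in 1:5) {
    m <- screen_model(n_plates = 1, genes_per_plate = 18, n_enhancers = 3,
                      n_lethals = 2, seed = 100 + s)
    tbl <- generate_screen(m)$tbl
    res <- score_primary(tbl)
    expect_true(all(res$status %in%
                      c("scored", "undetermined", "lethal_excluded")))
    expect_equal(nrow(res),
                 sum(res$status == "scored") + sum(res$status == "undetermined") +
                   sum(res$status == "lethal_excluded"))
    expect_equal(sort(select_primary_hits(res)$Reagent_ID),
                 brute_force_primary_hits(tbl))
  }
})
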