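test_that("the same seed reproduces screens and images bit-identically", {
  m <- screen_model(n_plates = 1, n_enhancers = 2, seed = 61)
  s1 <- generate_screen(m)
  s2 <- generate_screen(m)
  expect_identical(s1$tbl, s2$tbl)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_screen(screen_model(n_plates = 1, n_enhancers = 2, seed = 62))
  expect_false(identical(s1$tbl$Prg_R1, s3$tbl$Prg_R1))

  spec <- image_scene_spec(seed = 61)
  i1 <- generate_well_image(spec)
  i2 <- generate_well_image(spec)
  expect_identical(i1$image, i2$image)
  expect_identical(i1$truth, i2$truth)
  i3 <- generate_well_image(image_scene_spec(seed = 63))
  expect_false(identical(i1$image, i3$image))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_screen(screen_model(n_plates = 1, seed = 99)))
  expect_identical(runif(1), before)
})

test_that("plk-1 efficiency-control wells have zero progeny in every replicate", {
  tbl <- generate_screen(screen_model(n_plates = 3, seed = 64))$tbl
  c_wells <- dplyr::filter(tbl, WellType == "C")
  expect_gt(nrow(c_wells), 0)
  expect_true(all(c_wells$Prg_R1 == 0))
  expect_true(all(c_wells$Prg_R2 == 0))
})

test_that("a null model with identical baselines centres RF ratios on 1", {
  m <- screen_model(n_plates = 5, effect_sdlog = 0,
                    baseline_rf_control = 10, baseline_rf_mutant = 10,
                    seed = 65)
  res <- score_primary(generate_screen(m)$tbl)
  ratios <- res$rf_ratio[res$status == "scored"]
  # Monte-Carlo check: mean within 3 standard errors of 1
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se + 0.01)
})

test_that("model invariants are enforced", {
  expect_error(screen_model(genes_per_plate = 89), "column 1")
  expect_error(screen_model(n_enhancers = 1, enhancer_ratio = 0.6), "0.5")
  expect_error(screen_model(n_suppressors = 1, suppressor_ratio = 0.9), "> 1")
  expect_error(screen_model(n_lethals = 1, lethal_multiplier = 0.2), "0.15")
  bad <- screen_model(n_plates = 1)$gene_effects
  bad$multiplier_mutant[1] <- -0.1
  expect_error(screen_model(n_plates = 1, gene_effects = bad), ">= 0")
})

test_that("ground truth records planted roles and true ratios", {
  m <- screen_model(n_plates = 2, n_enhancers = 4, n_suppressors = 2,
                    n_lethals = 2, seed = 66)
  truth <- generate_screen(m)$truth
  expect_equal(sum(truth$role == "enhancer"), 4)
  expect_equal(sum(truth$role == "suppressor"), 2)
  expect_equal(sum(truth$role == "lethal"), 2)
  expect_true(all(abs(truth$true_ratio[truth$role == "enhancer"] - 0.3) < 1e-12))
  expect_true(all(truth$true_ratio[truth$role == "suppressor"] > 1))
  # the ratio definition is the mutant/control multiplier quotient
  expect_equal(truth$true_ratio,
               truth$multiplier_mutant / truth$multiplier_control)
})

test_that("adults are centred on the founder mean with occasional out-of-window wells", {
  tbl <- generate_screen(screen_model(n_plates = 5, seed = 67))$tbl
  adults <- c(tbl$Ad_R1, tbl$Ad_R2)
  adults <- adults[!is.na(adults)]
  expect_lt(abs(mean(adults) - 7), 0.3)
  frac_out <- mean(adults < 3 | adults > 13)
  expect_gt(frac_out, 0)      # the validity filter is exercised
  expect_lt(frac_out, 0.25)   # but only occasionally
})

test_that("an empty scene is pure background with empty ground truth", {
  scn <- generate_well_image(image_scene_spec(n_parents = 0, n_larvae = 0,
                                              n_debris = 0, seed = 68))
  expect_equal(nrow(scn$truth), 0)
  expect_true(all(scn$image < scn$spec$fg_threshold))
  wc <- count_well(scn$image, modifyList2(scene_segmentation_params(scn$spec)))
  expect_equal(c(wc$n_adults, wc$n_larvae, wc$n_rejected), c(0, 0, 0))
})

test_that("parent and larva mass bands are separated by construction", {
  for (s in 1:10) {
    truth <- generate_well_image(image_scene_spec(n_debris = 0,
                                                  seed = 700 + s))$truth
    expect_gt(min(truth$mass[truth$class == "parent"]),
              max(truth$mass[truth$class == "larva"]))
  }
})

test_that("ground truth pixel sets match the rendered image exactly", {
  scn <- generate_well_image(image_scene_spec(seed = 71))
  thr <- scn$spec$fg_threshold
  fg <- which(scn$image >= thr)
  truth_px <- do.call(rbind, scn$truth$pixels)
  lin <- (truth_px[, "col"]) * nrow(scn$image) + truth_px[, "row"] + 1L
  expect_setequal(fg, lin)
})

test_that("impossible non-overlapping placement raises a placement error", {
  spec <- image_scene_spec(image_size = c(190, 190), n_parents = 60,
                           n_larvae = 0, n_debris = 0, seed = 72)
  expect_error(generate_well_image(spec), "place")
})

test_that("overcrowded layouts are rejected", {
  expect_error(generate_screen(screen_model(n_plates = 1),
                               genes = "not-a-gene"), "unknown")
})
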