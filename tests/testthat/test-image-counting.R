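fixed_params <- function(...) {
  segmentation_params(binarization = "fixed", binarization_value = 50,
                      pixel_size = 2, intensity_class_threshold = 5000, ...)
}

test_that("candidate extraction measures area, mass and perimeter on a known square", {
  img <- matrix(0, 40, 40)
  img[11:20, 11:20] <- 100  # 10x10 uniform square
  cand <- extract_candidates(img, fixed_params())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_px, 100L)
  expect_equal(cand$mass, 10000)          # 100 pixels x intensity 100
  expect_equal(cand$area, 100 * 2^2)      # pixel count x pixel_size^2
  expect_equal(cand$perimeter, 40 * 2)    # 4 x 10 boundary steps x pixel_size
  expect_equal(cand$centroid_row, mean(10:19))  # 0-based
  # blank image -> no candidates
  expect_equal(nrow(extract_candidates(matrix(0, 20, 20), fixed_params())), 0)
  # non-2-D input is a shape error
  expect_error(extract_candidates(array(0, c(4, 4, 2)), fixed_params()),
               "matrix")
  expect_error(extract_candidates(matrix(c(1, Inf, 0, 0), 2), fixed_params()),
               "finite")
})

test_that("diagonally touching blobs split under 4-connectivity and merge under 8", {
  img <- matrix(0, 10, 10)
  img[3, 3] <- 100
  img[4, 4] <- 100
  expect_equal(nrow(extract_candidates(img, fixed_params(connectivity = 4))), 2)
  expect_equal(nrow(extract_candidates(img, fixed_params(connectivity = 8))), 1)
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel on random masks", {
  for (s in 1:5) {
    set.seed(500 + s)
    img <- matrix(0, 60, 60)
    for (k in 1:6) {
      r <- sample(5:55, 1); c <- sample(5:55, 1)
      img[max(1, r - 2):min(60, r + 2), max(1, c - 2):min(60, c + 2)] <- 100
    }
    mine <- extract_candidates(img, fixed_params(connectivity = 4))
    ref <- EBImage::bwlabel(matrix(as.integer(img >= 50), 60))
    expect_equal(nrow(mine), max(ref))
    expect_equal(sort(mine$n_px), sort(as.integer(table(ref[ref > 0]))))
  }
})

test_that("holes are filled before mass is computed", {
  img <- matrix(0, 20, 20)
  img[5:10, 5:10] <- 100
  img[7, 7] <- 0  # a hole inside the shape
  cand <- extract_candidates(img, fixed_params())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_px, 36L)     # filled shape
  expect_equal(cand$mass, 3500)    # 35 bright pixels + the dark hole pixel
})

test_that("detection filters are strict at the printed bounds", {
  params <- segmentation_params(binarization = "fixed", binarization_value = 50,
                                min_area = 0.383, area_unit = "um2",
                                max_mass = 300000,
                                max_perimeter = 1, perimeter_unit = "mm",
                                pixel_size = 3.25,
                                intensity_class_threshold = 5000)
  base <- tibble::tibble(
    candidate_id = 1L, n_px = 10L, centroid_row = 0, centroid_col = 0,
    area = 100, mass = 1000, perimeter = 100, pixels = list(NULL),
    label = "unclassified", rejection_reason = NA_character_
  )
  at_bound <- dplyr::bind_rows(
    dplyr::mutate(base, area = 0.383),        # exactly the area bound
    dplyr::mutate(base, mass = 300000),       # exactly the mass bound
    dplyr::mutate(base, perimeter = 1000)     # exactly 1 mm in um
  )
  res <- apply_filters(at_bound, params)
  expect_equal(res$label, rep("rejected", 3))
  expect_equal(res$rejection_reason, c("area", "mass", "perimeter"))
  inside <- dplyr::bind_rows(
    dplyr::mutate(base, area = 0.383 + 1e-9),
    dplyr::mutate(base, mass = 299999),
    dplyr::mutate(base, perimeter = 999)
  )
  res2 <- apply_filters(inside, params)
  expect_true(all(is.na(res2$rejection_reason)))
  expect_true(all(res2$label != "rejected"))
})

test_that("the kept set is the order-free conjunction of the three rules", {
  set.seed(77)
  cand <- tibble::tibble(
    candidate_id = 1:50, n_px = 10L, centroid_row = 0, centroid_col = 0,
    area = runif(50, 0, 1), mass = runif(50, 0, 600000),
    perimeter = runif(50, 0, 2000), pixels = replicate(50, NULL, FALSE),
    label = "unclassified", rejection_reason = NA_character_
  )
  params <- segmentation_params(binarization = "fixed", binarization_value = 50,
                                min_area = 0.5, area_unit = "um2",
                                max_mass = 300000, max_perimeter = 1000,
                                perimeter_unit = "um",
                                intensity_class_threshold = 1)
  res <- apply_filters(cand, params)
  direct_kept <- cand$area > 0.5 & cand$mass < 300000 & cand$perimeter < 1000
  expect_equal(res$label != "rejected", direct_kept)
})

test_that("classification by mass is degenerate at extreme thresholds", {
  scn <- generate_well_image(image_scene_spec(n_parents = 3, n_larvae = 6,
                                              n_debris = 0, seed = 41))
  params <- scene_segmentation_params(scn$spec)
  all_parent <- count_well(scn$image,
                           modifyList2(params, intensity_class_threshold = 0))
  expect_equal(all_parent$n_adults, 9)
  expect_equal(all_parent$n_larvae, 0)
  all_progeny <- count_well(scn$image,
                            modifyList2(params, intensity_class_threshold = 1e12))
  expect_equal(all_progeny$n_adults, 0)
  expect_equal(all_progeny$n_larvae, 9)
  expect_error(count_well(scn$image,
                          modifyList2(params, intensity_class_threshold = NULL)),
               "class")
})

test_that("count_well matches generator ground truth, debris landing in rejected", {
  scn <- generate_well_image(image_scene_spec(seed = 91))
  params <- scene_segmentation_params(scn$spec)
  wc <- count_well(scn$image, params)
  truth <- scene_counts(scn$truth)
  expect_equal(wc$n_adults, unname(truth["parents"]))
  expect_equal(wc$n_larvae, unname(truth["larvae"]))
  expect_equal(wc$n_rejected, unname(truth["rejected"]))
  expect_equal(wc$n_rejected, 3)  # one debris object per filter flavour
  reasons <- sort(wc$candidates$rejection_reason[!is.na(wc$candidates$rejection_reason)])
  expect_equal(reasons, c("area", "mass", "perimeter"))
  # blank image
  blank <- count_well(matrix(0, 30, 30), fixed_params())
  expect_equal(c(blank$n_adults, blank$n_larvae, blank$n_rejected), c(0, 0, 0))
})

test_that("raising bounds is monotone in the expected direction", {
  scn <- generate_well_image(image_scene_spec(seed = 55))
  params <- scene_segmentation_params(scn$spec)
  kept_area <- sapply(c(50, 120, 400, 700), function(a) {
    cand <- apply_filters(extract_candidates(scn$image, params),
                          modifyList2(params, min_area = a))
    sum(cand$label != "rejected")
  })
  expect_true(all(diff(kept_area) <= 0))
  adults <- sapply(c(0, 3e4, 7e4, 2e5, 1e12), function(thr) {
    count_well(scn$image,
               modifyList2(params, intensity_class_threshold = thr))$n_adults
  })
  expect_true(all(diff(adults) <= 0))
})

test_that("candidate masses never exceed the image's total foreground intensity", {
  for (s in 1:5) {
    scn <- generate_well_image(image_scene_spec(seed = 600 + s))
    params <- scene_segmentation_params(scn$spec)
    cand <- extract_candidates(scn$image, params)
    fg_total <- sum(scn$image[scn$image >= scn$spec$fg_threshold])
    expect_lte(sum(cand$mass), fg_total)
  }
})

test_that("the class threshold calibrates to the midpoint of separated bands", {
  train <- tibble::tibble(mass = c(100, 200, 1000),
                          class = c("larva", "larva", "parent"))
  expect_equal(calibrate_class_threshold(train), 600)
  overlap <- tibble::tibble(mass = c(100, 90), class = c("larva", "parent"))
  expect_error(calibrate_class_threshold(overlap), "overlap.*100.*90")
  expect_error(calibrate_class_threshold(
    tibble::tibble(mass = 1, class = "larva")), "at least one")
  # generator scenes always leave a positive margin
  scn <- generate_well_image(image_scene_spec(n_debris = 0, seed = 77))
  train2 <- dplyr::transmute(scn$truth, mass = mass, class = class)
  thr <- calibrate_class_threshold(train2)
  expect_true(thr > max(train2$mass[train2$class == "larva"]))
  expect_true(thr < min(train2$mass[train2$class == "parent"]))
})

test_that("well images round-trip through 16-bit TIFF and a directory can be counted", {
  dir <- withr::local_tempdir()
  scn <- generate_well_image(image_scene_spec(n_parents = 2, n_larvae = 3,
                                              n_debris = 0, seed = 9))
  write_well_image(scn$image, file.path(dir, "P01_A2.tif"))
  back <- read_well_image(file.path(dir, "P01_A2.tif"))
  expect_equal(back, scn$image)
  counted <- count_wells(dir, scene_segmentation_params(scn$spec))
  expect_equal(counted$Plate, "P01")
  expect_equal(counted$Well, "A2")
  expect_equal(counted$n_adults, 2)
  expect_equal(counted$n_larvae, 3)
})
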