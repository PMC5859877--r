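#' Specification of a synthetic well-image scene
#'
#' Describes a fluorescence image of one 96-well screening well: GFP-marked
#' pharynxes of parent worms (large, bright elongated blobs) and larval
#' progeny (small, dimmer blobs) over a noisy background, plus optional
#' debris objects designed to violate the detection filters. Blobs are
#' anisotropic Gaussian intensity profiles truncated at the foreground
#' threshold, so each object's pixel set is known exactly and segmentation
#' ground truth can be recorded per object.
#'
#' By construction every parent pixel is at least `fg_threshold` bright, so a
#' parent's mass is at least `min(parent area) x fg_threshold` (default
#' 100000), while a larva's mass is at most
#' `max(larva area) x max(larva peak)` (default 42000): the two mass bands are
#' separated by a guaranteed margin and a classification threshold always
#' exists.
#'
#' Debris comes in three flavours, one per detection rule: `small` (area
#' below any reasonable area bound), `massive` (summed intensity above the
#' mass bound) and `elongated` (a thin filament whose perimeter exceeds the
#' perimeter bound). `n_debris` cycles through the flavours in that order.
#'
#' @param image_size integer (height, width) in pixels. Default c(384, 384).
#' @param pixel_size physical pixel size in microns. Default 3.25.
#' @param n_parents,n_larvae,n_debris object counts. Defaults 5, 20, 3.
#' @param parent_blob,larva_blob lists with `area` (pixel-count range) and
#'   `peak` (peak-intensity range).
#' @param background_noise_sd SD of the background intensity fluctuation
#'   (truncated so background never crosses `fg_threshold`). Default 60.
#' @param fg_threshold intensity at or above which a pixel belongs to an
#'   object. Default 500.
#' @param overlap_allowed if `FALSE` (default) placement retries until no two
#'   objects touch (8-neighbourhood).
#' @param seed integer seed; the same spec generates bit-identical scenes.
#' @return An object of class `image_scene_spec`.
#' @seealso [generate_well_image()]
#' @export
image_scene_spec <- function(image_size = c(384L, 384L),
                             pixel_size = 3.25,
                             n_parents = 5, n_larvae = 20, n_debris = 3,
                             parent_blob = list(area = c(200, 300),
                                                peak = c(700, 900)),
                             larva_blob = list(area = c(30, 60),
                                               peak = c(600, 700)),
                             background_noise_sd = 60,
                             fg_threshold = 500,
                             overlap_allowed = FALSE,
                             seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            pixel_size > 0, n_parents >= 0, n_larvae >= 0, n_debris >= 0)
  if (min(parent_blob$peak) <= fg_threshold ||
      min(larva_blob$peak) <= fg_threshold) {
    abort("blob peak intensities must exceed `fg_threshold`.")
  }
  parent_min_mass <- min(parent_blob$area) * fg_threshold
  larva_max_mass <- max(larva_blob$area) * max(larva_blob$peak)
  if (parent_min_mass <= larva_max_mass) {
    abort("parent and larva mass bands must not overlap: increase parent area or decrease larva area/peak.")
  }
  structure(
    list(image_size = as.integer(image_size), pixel_size = pixel_size,
         n_parents = n_parents, n_larvae = n_larvae, n_debris = n_debris,
         parent_blob = parent_blob, larva_blob = larva_blob,
         background_noise_sd = background_noise_sd,
         fg_threshold = fg_threshold,
         overlap_allowed = isTRUE(overlap_allowed),
         seed = as.integer(seed)),
    class = "image_scene_spec"
  )
}

#' Segmentation parameters matched to a synthetic scene
#'
#' Convenience constructor for counting synthetic scenes: fixed binarization
#' at the scene's foreground threshold, the published mass (300000) and
#' perimeter (1 mm) bounds, an area bound of 120 um^2 (large enough that the
#' `small` debris flavour is rejected, far below any larva), and a class
#' threshold in the guaranteed gap between the larva and parent mass bands.
#'
#' @param spec an [image_scene_spec()].
#' @return A [segmentation_params()].
#' @export
scene_segmentation_params <- function(spec) {
  segmentation_params(
    binarization = "fixed",
    binarization_value = spec$fg_threshold,
    min_area = 120, area_unit = "um2",
    max_mass = 300000,
    max_perimeter = 1, perimeter_unit = "mm",
    intensity_class_threshold =
      (min(spec$parent_blob$area) * spec$fg_threshold +
         max(spec$larva_blob$area) * max(spec$larva_blob$peak)) / 2,
    pixel_size = spec$pixel_size,
    connectivity = 8
  )
}

# pixel set + values of an elliptical Gaussian blob truncated at `threshold`,
# targeting a given above-threshold pixel area
gaussian_blob <- function(center, area_px, peak, aspect, theta, threshold) {
  sigma_v <- sqrt(area_px / (2 * pi * aspect * log(peak / threshold)))
  sigma_u <- aspect * sigma_v
  half <- ceiling(sigma_u * sqrt(2 * log(peak / threshold))) + 1L
  dr <- rep(-half:half, times = 2 * half + 1)
  dc <- rep(-half:half, each = 2 * half + 1)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  val <- peak * exp(-(u^2 / (2 * sigma_u^2) + v^2 / (2 * sigma_v^2)))
  keep <- val >= threshold
  list(rows = center[1] + dr[keep], cols = center[2] + dc[keep],
       values = round(val[keep]))
}

flat_blob <- function(center, rows_rel, cols_rel, value) {
  list(rows = center[1] + rows_rel, cols = center[2] + cols_rel,
       values = rep(value, length(rows_rel)))
}

# one debris object per flavour; returns the blob plus its flavour tag
debris_blob <- function(flavour, center, threshold) {
  switch(flavour,
    small = flat_blob(center, rep(0:1, 2), rep(0:1, each = 2),
                      value = threshold + 300),
    massive = gaussian_blob(center, area_px = 80, peak = 25000, aspect = 1,
                            theta = 0, threshold = threshold),
    elongated = {
      len <- 170L
      if (runif(1) < 0.5) {
        flat_blob(center, rows_rel = rep(0L, len), cols_rel = seq_len(len) - 85L,
                  value = threshold + 100)
      } else {
        flat_blob(center, rows_rel = seq_len(len) - 85L, cols_rel = rep(0L, len),
                  value = threshold + 100)
      }
    }
  )
}

# independent per-object measurements used for the ground-truth table: the
# object's pixels are known by construction, adjacency is counted directly on
# the coordinate list
truth_measurements <- function(rows, cols, values, pixel_size) {
  n <- length(rows)
  key <- paste(rows, cols)
  adj <- 0L
  for (s in list(c(1L, 0L), c(0L, 1L))) {
    adj <- adj + sum(paste(rows + s[1], cols + s[2]) %in% key)
  }
  list(area = n * pixel_size^2, mass = sum(values),
       perimeter = (4L * n - 2L * adj) * pixel_size,
       centroid_row = mean(rows) - 1, centroid_col = mean(cols) - 1)
}

#' Generate a synthetic well image with ground truth
#'
#' Renders the scene described by an [image_scene_spec()]: a truncated-normal
#' noise background (always below the foreground threshold) with parent,
#' larva and debris blobs added on top, every blob pixel at or above the
#' threshold. The returned ground truth records, per object, its class,
#' centroid, pixel set, measured area/mass/perimeter and the expected filter
#' and classification outcome under `params` — the oracle against which the
#' counting module is tested.
#'
#' @param spec an [image_scene_spec()].
#' @param params a [segmentation_params()] used to pre-compute each object's
#'   expected outcome. Default [scene_segmentation_params()] of the spec.
#' @return A list with `image` (integer intensity matrix, 16-bit range),
#'   `truth` (per-object tibble with `object_id`, `class`, `flavour`,
#'   `centroid_row`/`centroid_col`, `n_px`, `area`, `mass`, `perimeter`,
#'   `expected_label`, `expected_reason`, `pixels`), and the `spec`.
#' @examples
#' scn <- generate_well_image(image_scene_spec(n_parents = 3, n_larvae = 8,
#'                                             n_debris = 3, seed = 11))
#' scn$truth[, c("class", "expected_label")]
#' @export
generate_well_image <- function(spec, params = scene_segmentation_params(spec)) {
  stopifnot(inherits(spec, "image_scene_spec"))
  withr::with_seed(spec$seed, {
  nr <- spec$image_size[1]
  nc <- spec$image_size[2]
  thr <- spec$fg_threshold

  # background: baseline 100 plus folded-normal noise, capped below threshold
  bg <- matrix(100 + pmin(round(abs(rnorm(nr * nc, 0, spec$background_noise_sd))),
                          thr - 101), nr, nc)

  flavours <- rep(c("small", "massive", "elongated"),
                  length.out = max(spec$n_debris, 1))[seq_len(spec$n_debris)]
  classes <- c(rep("parent", spec$n_parents), rep("larva", spec$n_larvae),
               flavours)
  if (length(classes) == 0) {
    return(list(image = bg,
                truth = empty_truth(),
                spec = spec))
  }

  occupied <- matrix(FALSE, nr, nc)  # placed pixels dilated by one
  margin <- 90L  # keeps every blob (incl. the 170 px filament) inside
  objects <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    placed <- FALSE
    for (try in seq_len(200)) {
      center <- c(sample(seq(margin, nr - margin), 1),
                  sample(seq(margin, nc - margin), 1))
      blob <- switch(cls,
        parent = gaussian_blob(center,
                               area_px = runif(1, spec$parent_blob$area[1],
                                               spec$parent_blob$area[2]),
                               peak = runif(1, spec$parent_blob$peak[1],
                                            spec$parent_blob$peak[2]),
                               aspect = runif(1, 2.5, 3.5),
                               theta = runif(1, 0, pi), threshold = thr),
        larva = gaussian_blob(center,
                              area_px = runif(1, spec$larva_blob$area[1],
                                              spec$larva_blob$area[2]),
                              peak = runif(1, spec$larva_blob$peak[1],
                                           spec$larva_blob$peak[2]),
                              aspect = runif(1, 2, 3),
                              theta = runif(1, 0, pi), threshold = thr),
        debris_blob(cls, center, thr)
      )
      inside <- blob$rows >= 1 & blob$rows <= nr & blob$cols >= 1 &
        blob$cols <= nc
      if (!all(inside)) next
      lin <- (blob$cols - 1L) * nr + blob$rows
      if (!spec$overlap_allowed && any(occupied[lin])) next
      # dilate by one pixel (8-neighbourhood) so later objects cannot touch
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- pmin(pmax(blob$rows + dr, 1L), nr)
        c2 <- pmin(pmax(blob$cols + dc, 1L), nc)
        occupied[(c2 - 1L) * nr + r2] <- TRUE
      }
      objects[[i]] <- c(blob, list(class = if (cls %in% c("parent", "larva"))
        cls else "debris", flavour = cls, lin = lin))
      placed <- TRUE
      break
    }
    if (!placed) {
      abort("could not place all requested non-overlapping objects; enlarge the image or reduce object counts.")
    }
  }

  image <- bg
  for (ob in objects) image[ob$lin] <- pmin(bg[ob$lin] + ob$values, 65535)

  truth <- purrr::imap_dfr(objects, function(ob, i) {
    m <- truth_measurements(ob$rows, ob$cols, image[ob$lin], spec$pixel_size)
    expected <- expected_outcome(m, ob$class, params)
    tibble::tibble(
      object_id = i, class = ob$class, flavour = ob$flavour,
      centroid_row = m$centroid_row, centroid_col = m$centroid_col,
      n_px = length(ob$lin), area = m$area, mass = m$mass,
      perimeter = m$perimeter,
      expected_label = expected$label, expected_reason = expected$reason,
      pixels = list(cbind(row = ob$rows - 1L, col = ob$cols - 1L))
    )
  })
  list(image = image, truth = truth, spec = spec)
  })
}

empty_truth <- function() {
  tibble::tibble(
    object_id = integer(), class = character(), flavour = character(),
    centroid_row = double(), centroid_col = double(), n_px = integer(),
    area = double(), mass = double(), perimeter = double(),
    expected_label = character(), expected_reason = character(),
    pixels = list()
  )
}

# expected detection/classification outcome of one object under the printed
# rules (strict inequalities, area -> mass -> perimeter order)
expected_outcome <- function(m, class, params) {
  if (!(m$area > min_area_um2(params))) {
    return(list(label = "rejected", reason = "area"))
  }
  if (!(m$mass < params$max_mass)) {
    return(list(label = "rejected", reason = "mass"))
  }
  if (!(m$perimeter < max_perimeter_um(params))) {
    return(list(label = "rejected", reason = "perimeter"))
  }
  list(label = if (m$mass >= params$intensity_class_threshold) "parent"
       else "progeny", reason = NA_character_)
}
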