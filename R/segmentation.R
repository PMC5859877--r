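#' Segmentation and classification parameters for well images
#'
#' Parameters of the two-step counting algorithm: (1) detect pharynx-like
#' objects as connected foreground components and keep those with an area
#' strictly larger than `min_area`, a mass (sum of pixel intensities over the
#' filled shape) strictly smaller than `max_mass`, and a perimeter strictly
#' smaller than `max_perimeter`; (2) classify each kept object as parent
#' (adult) or progeny (larva) by comparing its mass to
#' `intensity_class_threshold`.
#'
#' The default numeric bounds are the published rules, kept verbatim together
#' with explicit unit fields: the published area bound of 0.383 square microns
#' is smaller than a single pixel at the 2x acquisition scale (a pixel of
#' 3.25 um covers ~10.6 um^2), so under the default it rejects nothing; it is
#' retained as printed and fully overridable (see the package vignette for the
#' calibrated value used with synthetic scenes).
#'
#' @param binarization `"otsu"` (global automatic threshold) or `"fixed"`.
#' @param binarization_value intensity cutoff when `binarization = "fixed"`;
#'   pixels at or above it are foreground.
#' @param min_area strict lower area bound, in `area_unit`. Default 0.383.
#' @param area_unit `"um2"`, `"mm2"` or `"px"`. Default `"um2"`.
#' @param max_mass strict upper bound on summed intensity. Default 300000.
#' @param max_perimeter strict upper perimeter bound, in `perimeter_unit`.
#'   Default 1.
#' @param perimeter_unit `"mm"`, `"um"` or `"px"`. Default `"mm"`.
#' @param intensity_class_threshold mass value separating progeny (below)
#'   from parents (at or above). No published value exists; calibrate with
#'   [calibrate_class_threshold()].
#' @param pixel_size physical pixel size in microns. Default 3.25 (2x
#'   objective, whole well in one frame).
#' @param connectivity pixel neighbourhood, 4 or 8. Default 8 (elongated dim
#'   pharynxes fragment under 4-connectivity).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(binarization = c("otsu", "fixed"),
                                binarization_value = NULL,
                                min_area = 0.383,
                                area_unit = c("um2", "mm2", "px"),
                                max_mass = 300000,
                                max_perimeter = 1,
                                perimeter_unit = c("mm", "um", "px"),
                                intensity_class_threshold = NULL,
                                pixel_size = 3.25,
                                connectivity = 8) {
  binarization <- match.arg(binarization)
  area_unit <- match.arg(area_unit)
  perimeter_unit <- match.arg(perimeter_unit)
  if (binarization == "fixed" && is.null(binarization_value)) {
    abort("fixed binarization needs `binarization_value`.")
  }
  if (min_area <= 0 || max_mass <= 0 || max_perimeter <= 0 || pixel_size <= 0) {
    abort("`min_area`, `max_mass`, `max_perimeter` and `pixel_size` must be > 0.")
  }
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  structure(
    list(binarization = binarization,
         binarization_value = binarization_value,
         min_area = min_area, area_unit = area_unit,
         max_mass = max_mass,
         max_perimeter = max_perimeter, perimeter_unit = perimeter_unit,
         intensity_class_threshold = intensity_class_threshold,
         pixel_size = pixel_size,
         connectivity = as.integer(connectivity)),
    class = "segmentation_params"
  )
}

# physical bounds converted to the image's native units
min_area_um2 <- function(p) {
  switch(p$area_unit, um2 = p$min_area, mm2 = p$min_area * 1e6,
         px = p$min_area * p$pixel_size^2)
}
max_perimeter_um <- function(p) {
  switch(p$perimeter_unit, um = p$max_perimeter, mm = p$max_perimeter * 1e3,
         px = p$max_perimeter * p$pixel_size)
}

binarize_image <- function(image, params) {
  thr <- switch(params$binarization,
    fixed = params$binarization_value,
    otsu = EBImage::otsu(image, range = c(0, max(image, 1)), levels = 256L)
  )
  image >= thr
}

# connected-component labeling on a logical mask; igraph components over the
# pixel-adjacency graph so both 4- and 8-neighbourhoods are supported
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  edge_list <- lapply(shifts, function(s) {
    r2 <- row + s[1]
    c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- id[(c2[ok] - 1L) * nr + r2[ok]]
    keep <- nb > 0L
    rbind(id[fg[ok]][keep], nb[keep])
  })
  em <- do.call(cbind, edge_list)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (ncol(em) > 0) g <- igraph::add_edges(g, as.vector(em))
  lab[fg] <- as.integer(igraph::components(g)$membership)
  lab
}

# boundary pixel-step length: every pixel edge shared with background (or the
# image border) counts one step
perimeter_steps <- function(rows, cols, lab, object) {
  nr <- nrow(lab)
  nc <- ncol(lab)
  steps <- 0L
  for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- rows + s[1]
    c2 <- cols + s[2]
    inside <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    same <- logical(length(rows))
    same[inside] <- lab[(c2[inside] - 1L) * nr + r2[inside]] == object
    steps <- steps + sum(!same)
  }
  steps
}

#' Detect candidate pharynx objects in a well image
#'
#' Step one of the counting algorithm: binarize the image, fill holes, label
#' connected components and measure each component's area, mass and perimeter.
#' No filtering or classification happens here.
#'
#' @param image 2-D numeric matrix of pixel intensities (single channel).
#' @param params a [segmentation_params()].
#' @return A tibble with one row per candidate: `candidate_id`, `n_px`,
#'   `centroid_row`/`centroid_col` (0-based), `area` (um^2), `mass` (summed
#'   intensity over the filled shape), `perimeter` (um), `label`
#'   (`"unclassified"`), `rejection_reason` (`NA`), and a `pixels` list-column
#'   of 0-based (row, col) matrices.
#' @seealso [apply_filters()], [classify_candidates()], [count_well()]
#' @export
extract_candidates <- function(image, params = segmentation_params()) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a 2-D numeric matrix.")
  }
  if (any(!is.finite(image))) abort("`image` must contain only finite values.")
  mask <- binarize_image(image, params)
  filled <- EBImage::fillHull(matrix(as.integer(mask), nrow(mask))) > 0
  lab <- label_components(filled, params$connectivity)
  n_obj <- max(lab)
  if (n_obj == 0) return(empty_candidates())
  px_area <- params$pixel_size^2
  cand <- purrr::map(seq_len(n_obj), function(k) {
    lin <- which(lab == k)
    rows <- ((lin - 1L) %% nrow(lab)) + 1L
    cols <- ((lin - 1L) %/% nrow(lab)) + 1L
    tibble::tibble(
      candidate_id = k,
      n_px = length(lin),
      centroid_row = mean(rows) - 1,
      centroid_col = mean(cols) - 1,
      area = length(lin) * px_area,
      mass = sum(image[lin]),
      perimeter = perimeter_steps(rows, cols, lab, k) * params$pixel_size,
      pixels = list(cbind(row = rows - 1L, col = cols - 1L))
    )
  })
  out <- dplyr::bind_rows(cand)
  out$label <- "unclassified"
  out$rejection_reason <- NA_character_
  out
}

empty_candidates <- function() {
  tibble::tibble(
    candidate_id = integer(), n_px = integer(),
    centroid_row = double(), centroid_col = double(),
    area = double(), mass = double(), perimeter = double(),
    pixels = list(), label = character(), rejection_reason = character()
  )
}

#' Apply the area/mass/perimeter detection filters
#'
#' A candidate is kept if and only if its area is strictly larger than the
#' area bound, its mass strictly smaller than the mass bound, and its
#' perimeter strictly smaller than the perimeter bound. Rejected candidates
#' record the first violated rule, checked in the order area, mass, perimeter.
#'
#' @param candidates tibble from [extract_candidates()].
#' @param params a [segmentation_params()].
#' @return `candidates` with `label` set to `"rejected"` (and
#'   `rejection_reason` filled) for failing objects.
#' @export
apply_filters <- function(candidates, params = segmentation_params()) {
  if (nrow(candidates) == 0) return(candidates)
  a_min <- min_area_um2(params)
  p_max <- max_perimeter_um(params)
  reason <- dplyr::case_when(
    !(candidates$area > a_min) ~ "area",
    !(candidates$mass < params$max_mass) ~ "mass",
    !(candidates$perimeter < p_max) ~ "perimeter",
    TRUE ~ NA_character_
  )
  candidates$rejection_reason <- reason
  candidates$label <- ifelse(is.na(reason), candidates$label, "rejected")
  candidates
}

#' Classify kept candidates as parents or progeny
#'
#' Step two of the counting algorithm: a kept object whose mass (total pixel
#' intensity) is at or above the class threshold is a parent (adult); below
#' it, progeny (larva). Adults carry larger, brighter pharynxes.
#'
#' @param candidates tibble with filters already applied.
#' @param params a [segmentation_params()] with a non-`NULL`
#'   `intensity_class_threshold`.
#' @return `candidates` with `label` set to `"parent"` or `"progeny"` for
#'   kept objects.
#' @export
classify_candidates <- function(candidates, params = segmentation_params()) {
  if (is.null(params$intensity_class_threshold)) {
    abort("`intensity_class_threshold` is not set; see calibrate_class_threshold().")
  }
  if (nrow(candidates) == 0) return(candidates)
  kept <- candidates$label != "rejected"
  candidates$label[kept] <- ifelse(
    candidates$mass[kept] >= params$intensity_class_threshold,
    "parent", "progeny")
  candidates
}

#' Count parents and progeny in a well image
#'
#' Composition of [extract_candidates()], [apply_filters()] and
#' [classify_candidates()].
#'
#' @param image 2-D numeric intensity matrix.
#' @param params a [segmentation_params()] with a class threshold set.
#' @return An object of class `well_count`: a list with `n_adults`,
#'   `n_larvae`, `n_rejected` and the per-candidate tibble `candidates`.
#' @examples
#' scn <- generate_well_image(image_scene_spec(n_parents = 2, n_larvae = 4,
#'                                             n_debris = 0, seed = 7))
#' count_well(scn$image, scene_segmentation_params(scn$spec))
#' @export
count_well <- function(image, params = segmentation_params()) {
  cand <- extract_candidates(image, params) |>
    apply_filters(params) |>
    classify_candidates(params)
  structure(
    list(n_adults = sum(cand$label == "parent"),
         n_larvae = sum(cand$label == "progeny"),
         n_rejected = sum(cand$label == "rejected"),
         candidates = cand),
    class = "well_count"
  )
}

#' @export
print.well_count <- function(x, ...) {
  cat("<well_count>", x$n_adults, "adult(s),", x$n_larvae, "progeny,",
      x$n_rejected, "rejected object(s)\n")
  invisible(x)
}

#' Calibrate the adult/larva mass threshold from labelled examples
#'
#' The published pipeline applies an unstated intensity threshold to separate
#' adults from larvae; here the threshold is a calibrated parameter: the
#' midpoint between the largest larva mass and the smallest parent mass in a
#' labelled training set. Calibration fails when the two mass bands overlap.
#'
#' @param training tibble with columns `mass` and `class` (values `"parent"`
#'   and `"larva"`), e.g. the ground-truth table of [generate_well_image()].
#' @return The threshold (a single number).
#' @examples
#' calibrate_class_threshold(
#'   tibble::tibble(mass = c(100, 200, 1000),
#'                  class = c("larva", "larva", "parent")))  # 600
#' @export
calibrate_class_threshold <- function(training) {
  stopifnot(all(c("mass", "class") %in% names(training)))
  larva <- training$mass[training$class == "larva"]
  parent <- training$mass[training$class == "parent"]
  if (length(larva) == 0 || length(parent) == 0) {
    abort("need at least one parent and one larva example.")
  }
  lo <- max(larva)
  hi <- min(parent)
  if (lo >= hi) {
    abort(sprintf(
      "mass bands overlap: largest larva mass %g >= smallest parent mass %g.",
      lo, hi))
  }
  (lo + hi) / 2
}

#' Read or write a well image as single-channel 16-bit TIFF
#'
#' @param image integer-valued intensity matrix in 0..65535.
#' @param path TIFF file path.
#' @return `read_well_image()` returns the intensity matrix on the original
#'   0..65535 scale; `write_well_image()` returns `path` invisibly.
#' @export
write_well_image <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 65535))
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_well_image
#' @export
read_well_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Count a directory of well images
#'
#' Counts every TIFF named `<plate>_<well>.tif` in a directory, one row per
#' well.
#'
#' @param dir directory of TIFF images.
#' @param params a [segmentation_params()].
#' @return A tibble with `Plate`, `Well`, `n_adults`, `n_larvae`,
#'   `n_rejected`.
#' @export
count_wells <- function(dir, params = segmentation_params()) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no TIFF images in ", dir))
  purrr::map_dfr(files, function(f) {
    stem <- sub("\\.tiff?$", "", basename(f))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    wc <- count_well(read_well_image(f), params)
    tibble::tibble(
      Plate = parts[1],
      Well = if (length(parts) > 1) parts[2] else NA_character_,
      n_adults = wc$n_adults, n_larvae = wc$n_larvae,
      n_rejected = wc$n_rejected
    )
  })
}
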