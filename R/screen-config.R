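#' Numeric rules of the screen
#'
#' Bundles every tunable rule used to turn raw well counts into a hit list:
#' the parent-count validity window, the lethality exclusion, the hit cutoff
#' on the RF ratio, the positive-control threshold formula and the suppressor
#' bound. The defaults reproduce the published screen design.
#'
#' @param parent_window inclusive integer interval of parent counts for which
#'   a well is scoreable (progeny counts correlate linearly with parents only
#'   in this range). Default `c(3, 13)`.
#' @param lethality_fraction clones whose RF in the control strain is reduced,
#'   relative to the plate's negative-control baseline, by strictly more than
#'   this fraction are excluded as lethal (their RF ratio is unreliable).
#'   Default 0.85.
#' @param hit_cutoff RF-ratio bound for hit selection, inclusive
#'   (ratio <= cutoff is a hit). Default 0.5.
#' @param threshold_sigma_multiplier multiplier k in the control-derived
#'   diagnostic threshold mean + k * SD of positive-control RF ratios.
#'   Default 2.
#' @param suppressor_bound RF-ratio bound above which (strictly) a clone is
#'   flagged as a putative suppressor. Default 1.
#' @param sd_flavor `"sample"` (n - 1 denominator, default) or `"population"`
#'   standard deviation for the control threshold.
#'
#' @return An object of class `screen_config` (a named list).
#' @examples
#' cfg <- screen_config()
#' cfg$parent_window
#' @export
screen_config <- function(parent_window = c(3L, 13L),
                          lethality_fraction = 0.85,
                          hit_cutoff = 0.5,
                          threshold_sigma_multiplier = 2,
                          suppressor_bound = 1,
                          sd_flavor = c("sample", "population")) {
  sd_flavor <- match.arg(sd_flavor)
  parent_window <- as.integer(parent_window)
  if (length(parent_window) != 2 || anyNA(parent_window) ||
      parent_window[1] > parent_window[2]) {
    abort("`parent_window` must be an inclusive integer interval c(lo, hi).")
  }
  if (parent_window[1] < 1) abort("`parent_window` lower bound must be >= 1.")
  if (!is.numeric(lethality_fraction) || lethality_fraction <= 0 ||
      lethality_fraction >= 1) {
    abort("`lethality_fraction` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(hit_cutoff) || hit_cutoff <= 0) {
    abort("`hit_cutoff` must be > 0.")
  }
  structure(
    list(
      parent_window = parent_window,
      lethality_fraction = lethality_fraction,
      hit_cutoff = hit_cutoff,
      threshold_sigma_multiplier = threshold_sigma_multiplier,
      suppressor_bound = suppressor_bound,
      sd_flavor = sd_flavor
    ),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat("  parent window: [", x$parent_window[1], ", ", x$parent_window[2],
      "] parents\n", sep = "")
  cat("  lethality exclusion: control RF reduced by >",
      100 * x$lethality_fraction, "%\n")
  cat("  hit cutoff: RF ratio <=", x$hit_cutoff, "\n")
  cat("  control threshold: mean +", x$threshold_sigma_multiplier, "x",
      x$sd_flavor, "SD of positive-control ratios\n")
  cat("  suppressor bound: RF ratio >", x$suppressor_bound, "\n")
  invisible(x)
}

#' Read or write a screen configuration as YAML
#'
#' @param path file path.
#' @return `read_screen_config()` returns a [screen_config()];
#'   `write_screen_config()` returns `path` invisibly.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown config fields: ",
                paste(extra, collapse = ", ")))
  }
  do.call(screen_config, raw[intersect(names(raw), known)])
}

#' @rdname read_screen_config
#' @param config a [screen_config()].
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
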