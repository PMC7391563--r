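#' Percentage of turned-over (black) sand area in an image
#'
#' Counts the fraction of pixels at or below the brightness threshold on
#' the 0-255 scale. The default cut of 80 separates the black bottom-layer
#' sand from the beige surface sand in the two-layer assay.
#'
#' @param image Single-channel brightness matrix (0-255), e.g. from
#'   [simulate_sand_images()] or [read_sand_image()].
#' @param threshold Brightness threshold (default 80).
#' @return Percentage in `[0, 100]`.
#' @export
quantify_sand_area <- function(image, threshold = 80) {
  .check(is.matrix(image) && length(image) > 0, "image must be a nonempty matrix")
  .check(threshold >= 0 && threshold <= 255, "threshold must be on 0-255 scale")
  100 * mean(image <= threshold)
}

#' Read a PNG or TIFF sand image as a brightness matrix
#'
#' Multi-channel images are averaged to one channel; values are rescaled
#' from `[0, 1]` to the 0-255 brightness scale.
#'
#' @param path Image file (.png or .tif/.tiff).
#' @return Brightness matrix.
#' @export
read_sand_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' required to read PNG images")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to read TIFF images")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                          c(1, 2), mean)
  img * 255
}

#' Net turned-over area, corrected for scraping
#'
#' The before-trial black-area percentage is subtracted from the
#' after-trial percentage (floored at zero, with a warning when the
#' difference is negative), then multiplied by `(1 - e)` where `e` is the
#' scored fraction of blackened area attributable to body scraping rather
#' than strikes. `scrape_mode = "off"` disables the correction.
#'
#' @param before_pct,after_pct Area percentages in `[0, 100]`.
#' @param scrape_effect Scrape-effect score, one of 0, 0.1, 0.25, 0.5,
#'   0.75, 0.9.
#' @param scrape_mode `"complement"` (multiply by 1 - e) or `"off"`.
#' @return Corrected percentage in `[0, 100]`.
#' @export
net_turned_area <- function(before_pct, after_pct, scrape_effect = 0,
                            scrape_mode = c("complement", "off")) {
  scrape_mode <- match.arg(scrape_mode)
  .check(all(before_pct >= 0 & before_pct <= 100) &&
           all(after_pct >= 0 & after_pct <= 100),
         "percentages must be in [0, 100]")
  .check(all(scrape_effect %in% c(0, 0.1, 0.25, 0.5, 0.75, 0.9)),
         "scrape_effect must be one of 0, 0.1, 0.25, 0.5, 0.75, 0.9")
  d <- after_pct - before_pct
  if (any(d < 0)) {
    warning("after-trial area below before-trial area; floored at 0")
    d <- pmax(d, 0)
  }
  if (scrape_mode == "complement") d <- d * (1 - scrape_effect)
  d
}

#' Sand-sifting efficiency score
#'
#' Turned-over area percentage divided by the number of strikes, plus
#' 0.001 so zero-area trials remain log-transformable. Not computable for
#' trials without a strike (returns `NA`; such trials still contribute to
#' strike-count analyses).
#'
#' @param area_pct Net turned-over area percentage.
#' @param strikes Strike count (>= 0).
#' @return data.frame with `raw` (`area/strikes + 0.001`) and `log10`.
#' @export
efficiency <- function(area_pct, strikes) {
  .check(all(strikes >= 0), "strikes must be >= 0")
  raw <- ifelse(strikes >= 1, area_pct / strikes + 0.001, NA_real_)
  data.frame(raw = raw, log10 = log10(raw))
}

#' Exclude unusable trials
#'
#' A trial with zero strikes combined with a hiding or interaction score of
#' 5 (the fish hid or displayed the whole time) carries no information
#' about sifting propensity and is excluded.
#'
#' @param trials data.frame with columns `strikes`, `hiding`,
#'   `interaction` (ordinal 1-5).
#' @return List `valid`, `excluded` (both data.frames).
#' @export
exclude_trials <- function(trials) {
  .check(all(c("strikes", "hiding", "interaction") %in% names(trials)),
         "trials must have strikes, hiding, interaction columns")
  .check(all(trials$hiding %in% 1:5) && all(trials$interaction %in% 1:5),
         "ordinal scores must be in 1..5")
  bad <- trials$strikes == 0 & (trials$hiding == 5 | trials$interaction == 5)
  list(valid = trials[!bad, , drop = FALSE],
       excluded = trials[bad, , drop = FALSE])
}

#' Aggregate trials per individual
#'
#' Summarizes strike counts and efficiency over each individual's valid
#' trials. Efficiency statistics use only trials where efficiency is
#' computable (at least one strike).
#'
#' @param trials data.frame with columns `individual`, `strikes`, and
#'   optionally `efficiency` (raw scores).
#' @param statistic `"max"`, `"mean"`, or `"per_trial"`.
#' @return With `"per_trial"`, the input; otherwise one row per individual
#'   with `strikes` and (if present) `efficiency`.
#' @export
aggregate_individual <- function(trials, statistic = c("max", "mean",
                                                       "per_trial")) {
  statistic <- match.arg(statistic)
  if (statistic == "per_trial") return(trials)
  f <- if (statistic == "max") max else mean
  ids <- unique(trials$individual)
  out <- data.frame(individual = ids)
  out$strikes <- vapply(ids, function(i)
    f(trials$strikes[trials$individual == i]), numeric(1))
  if ("efficiency" %in% names(trials))
    out$efficiency <- vapply(ids, function(i) {
      e <- trials$efficiency[trials$individual == i]
      e <- e[!is.na(e)]
      if (length(e) == 0) NA_real_ else f(e)
    }, numeric(1))
  out
}

#' Group-level efficiency for female trials
#'
#' Females were tested in shoals of three; the turned-over area belongs to
#' the group, so efficiency uses the summed strike counts of the group
#' members, and group standard length is the mean of the members' SL.
#'
#' @param strikes Vector of member strike counts.
#' @param area_pct Net turned-over area percentage for the group's tray.
#' @param SL Optional vector of member standard lengths (mm).
#' @return One-row data.frame `strikes`, `raw`, `log10`, `SL`.
#' @export
group_efficiency <- function(strikes, area_pct, SL = NULL) {
  tot <- sum(strikes)
  e <- efficiency(area_pct, tot)
  data.frame(strikes = tot, raw = e$raw, log10 = e$log10,
             SL = if (is.null(SL)) NA_real_ else mean(SL))
}
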