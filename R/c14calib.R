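# Radiocarbon age calibration against an IntCal-format curve, with
# highest-posterior-density (HPD) ranges found by descending-density
# inclusion — the construction that yields multiple disjoint ranges with
# per-range probabilities, as calibration software prints them.

#' Load an IntCal-format calibration curve
#'
#' Reads the published `.14c` delimited layout: comment lines starting with
#' `#`, then rows of calendar age (cal BP), radiocarbon age (14C BP) and its
#' 1-sigma uncertainty (further columns are ignored). Both ascending and
#' descending calendar grids are accepted and normalised to descending cal BP
#' internally.
#'
#' @param path curve file.
#' @param curve_id identifier recorded in reports (defaults to the filename).
#' @return A `calibration_curve`: `cal_bp`, `c14_age`, `c14_sigma`.
#' @export
load_curve <- function(path, curve_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in curve file ", path)
  sep <- if (grepl(",", lines[1])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (ncol(tab) < 3L)
    stop("curve file must have at least 3 columns (cal BP, 14C age, sigma): ",
         path)
  calibration_curve(tab[[1]], tab[[2]], tab[[3]], curve_id)
}

#' Construct a calibration curve from vectors
#'
#' @param cal_bp calendar ages (years BP), strictly monotone.
#' @param c14_age radiocarbon ages (BP) of the curve.
#' @param c14_sigma curve 1-sigma uncertainties (years), all >= 0.
#' @param curve_id identifier.
#' @return A `calibration_curve` with a descending cal BP grid.
#' @export
calibration_curve <- function(cal_bp, c14_age, c14_sigma,
                              curve_id = "custom") {
  cal_bp <- as.numeric(cal_bp); c14_age <- as.numeric(c14_age)
  c14_sigma <- as.numeric(c14_sigma)
  d <- diff(cal_bp)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("calendar grid must be strictly monotone")
  if (cal_bp[1] < cal_bp[length(cal_bp)]) {  # normalise to descending
    cal_bp <- rev(cal_bp); c14_age <- rev(c14_age); c14_sigma <- rev(c14_sigma)
  }
  if (any(c14_sigma < 0)) stop("curve sigmas must be >= 0")
  structure(list(cal_bp = cal_bp, c14_age = c14_age, c14_sigma = c14_sigma,
                 curve_id = curve_id),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: %d knots, cal %.0f-%.0f BP\n",
              x$curve_id, length(x$cal_bp), max(x$cal_bp), min(x$cal_bp)))
  invisible(x)
}

#' Calibrate a conventional radiocarbon age
#'
#' Evaluates, on a 1-year calendar grid spanning the curve, the posterior
#' `p(t) ~ exp(-(age_bp - mu(t))^2 / (2 (sigma^2 + sigma_curve(t)^2)))`
#' under a uniform prior, normalised to sum to 1. Curve mean and sigma are
#' linearly interpolated to the yearly grid.
#'
#' @param age_bp conventional radiocarbon age (years BP).
#' @param sigma its 1-sigma measurement uncertainty (> 0).
#' @param curve a `calibration_curve`.
#' @return A `calibrated_date`: `cal_bp` grid, `posterior`, inputs.
#' @export
calibrate_c14 <- function(age_bp, sigma, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (age_bp > max(curve$c14_age) + 5 * sigma ||
      age_bp < min(curve$c14_age) - 5 * sigma)
    stop(sprintf("age %g BP lies outside the curve's radiocarbon span [%g, %g] +/- 5 sigma",
                 age_bp, min(curve$c14_age), max(curve$c14_age)))
  grid <- seq(max(curve$cal_bp), min(curve$cal_bp), by = -1)
  mu <- approx(curve$cal_bp, curve$c14_age, xout = grid)$y
  sg <- approx(curve$cal_bp, curve$c14_sigma, xout = grid)$y
  var_tot <- sigma^2 + sg^2
  logp <- -(age_bp - mu)^2 / (2 * var_tot) - 0.5 * log(var_tot)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  structure(list(age_bp = age_bp, sigma = sigma, cal_bp = grid,
                 posterior = p, curve_id = curve$curve_id),
            class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  cat(sprintf("<calibrated_date> %g +/- %g BP on %s\n", x$age_bp, x$sigma,
              x$curve_id))
  r <- hpd_ranges(x, "1 sigma")
  for (i in seq_len(nrow(r)))
    cat(sprintf("  1σ %d-%d cal %s (p = %.3f)\n", r$start[i], r$end[i],
                r$era[i], r$probability[i]))
  invisible(x)
}

level_from_label <- function(level) {
  if (is.character(level)) {
    level <- switch(gsub("\\s+", "", tolower(level)),
                    "1sigma" = 0.6827, "2sigma" = 0.9545,
                    stop("unknown level label; use \"1 sigma\", \"2 sigma\" or a number"))
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  level
}

#' Highest-posterior-density calendar ranges
#'
#' The smallest set of calendar years whose total posterior mass reaches the
#' level, found by including years in order of descending density; contiguous
#' runs are merged into ranges and each range carries its own mass (rounded
#' to 3 decimals). Calendar years are reported in the cal BC/AD convention
#' (cal BC = cal BP - 1950 for pre-common-era years, as positive numbers with
#' an era flag), ranges sorted oldest first.
#'
#' @param calibrated a `calibrated_date`.
#' @param level confidence level in (0,1), or `"1 sigma"` / `"2 sigma"`
#'   (0.6827 / 0.9545).
#' @return data.frame with columns `start`, `end` (calendar years, start the
#'   older bound), `era` (`"BC"`/`"AD"`), `start_cal_bp`, `end_cal_bp`,
#'   `probability` (the range's share of the level's total mass, rounded to
#'   3 decimals — the convention calibration software prints, so the shares
#'   of one level sum to 1), and `mass` (the range's absolute posterior
#'   mass). The total selected mass is attached as attribute `level_mass`.
#' @export
hpd_ranges <- function(calibrated, level = "1 sigma") {
  stopifnot(inherits(calibrated, "calibrated_date"))
  level <- level_from_label(level)
  p <- calibrated$posterior
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(p)
  sel <- sort(ord[seq_len(k)])
  total <- sum(p[sel])
  runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
  grid <- calibrated$cal_bp  # descending
  out <- do.call(rbind, lapply(runs, function(idx) {
    bp_hi <- grid[idx[1]]               # older bound
    bp_lo <- grid[idx[length(idx)]]     # younger bound
    data.frame(start = bp_to_calendar(bp_hi)$year,
               end = bp_to_calendar(bp_lo)$year,
               era = bp_to_calendar(bp_hi)$era,
               start_cal_bp = bp_hi, end_cal_bp = bp_lo,
               probability = round(sum(p[idx]) / total, 3),
               mass = sum(p[idx]))
  }))
  out <- out[order(-out$start_cal_bp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "level_mass") <- total
  out
}

bp_to_calendar <- function(cal_bp) {
  if (cal_bp >= 1950) list(year = cal_bp - 1950, era = "BC")
  else list(year = 1950 - cal_bp, era = "AD")
}

#' JSON report of a calibrated date
#'
#' @param calibrated a `calibrated_date`.
#' @param path output file.
#' @param levels levels to report (default 1 sigma and 2 sigma).
#' @return Invisibly, `path`.
#' @export
write_calibration_report <- function(calibrated, path,
                                     levels = c("1 sigma", "2 sigma")) {
  ranges <- lapply(levels, function(lv) {
    r <- hpd_ranges(calibrated, lv)
    lapply(seq_len(nrow(r)), function(i)
      list(start = r$start[i], end = r$end[i], era = r$era[i],
           probability = r$probability[i]))
  })
  names(ranges) <- as.character(levels)
  jsonlite::write_json(list(input = list(age_bp = calibrated$age_bp,
                                         sigma = calibrated$sigma),
                            curve_id = calibrated$curve_id,
                            levels = ranges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
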