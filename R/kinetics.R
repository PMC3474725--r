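# Whole-cell biosensor kinetics: normalization by cell density and
# induction-onset calling.
#
# A reporter strain carrying a candidate catabolic gene cluster emits
# bioluminescence when the cluster's enzymes convert the fed substrate into
# the biosensor's inducer.  Raw luminescence scales with culture density,
# so the quantitative readout is relative bioluminescence: luminescence
# divided by optical density, per well and time point.

#' Construct a kinetic series
#'
#' @param well_id Well identifier.
#' @param time Time points in minutes, strictly increasing.
#' @param lum Luminescence, arbitrary units, >= 0.
#' @param od Optical density (OD600), > 0 at every point.
#' @param condition `"induced"` or `"vehicle_control"`.
#' @return A `kinetic_series` data frame.
#' @export
kinetic_series <- function(well_id, time, lum, od,
                           condition = c("induced", "vehicle_control")) {
  condition <- match.arg(condition)
  n <- length(time)
  if (length(lum) != n || length(od) != n) {
    stop("time, lum and od must have equal length", call. = FALSE)
  }
  if (n < 2L || any(diff(time) <= 0)) {
    stop("time must be strictly increasing with at least two points",
         call. = FALSE)
  }
  if (any(lum < 0)) stop("luminescence must be >= 0", call. = FALSE)
  if (any(od <= 0)) {
    stop("well '", well_id, "' has non-positive OD; unusable well",
         call. = FALSE)
  }
  structure(data.frame(well_id = well_id, time = as.numeric(time),
                       lum = as.numeric(lum), od = as.numeric(od),
                       condition = condition, stringsAsFactors = FALSE),
            class = c("kinetic_series", "data.frame"))
}

#' Relative bioluminescence: luminescence / OD, elementwise
#'
#' @param series A [kinetic_series()] (or data frame with `lum` and `od`).
#' @return The series with a `rel_lum` column added.
#' @export
relative_bioluminescence <- function(series) {
  if (any(series$od <= 0)) stop("non-positive OD; unusable well",
                                call. = FALSE)
  series$rel_lum <- series$lum / series$od
  series
}

#' Average replicate wells per time point
#'
#' @param series_list List of [kinetic_series()] sharing a time grid and
#'   condition (typically 4 replicate wells).
#' @return Data frame `time`, `rel_lum` (mean), `rel_lum_sd`, `condition`.
#' @export
average_replicates <- function(series_list) {
  norm <- lapply(series_list, relative_bioluminescence)
  t0 <- norm[[1L]]$time
  for (s in norm[-1L]) {
    if (!isTRUE(all.equal(s$time, t0))) {
      stop("replicate wells are on different time grids", call. = FALSE)
    }
  }
  m <- vapply(norm, function(s) s$rel_lum, numeric(length(t0)))
  m <- matrix(m, nrow = length(t0))
  data.frame(time = t0,
             rel_lum = rowMeans(m),
             rel_lum_sd = apply(m, 1L, stats::sd),
             condition = norm[[1L]]$condition[1L],
             stringsAsFactors = FALSE)
}

#' Call induction onset against a vehicle control
#'
#' Onset is the earliest time at which the induced signal reaches
#' `fold_threshold` times the control AND the condition also holds at the
#' next point (two consecutive points, guarding single-point spikes).
#'
#' @param induced,control Normalized series: numeric vectors on the same
#'   time grid, or data frames with `time` and `rel_lum`.
#' @param times Time grid (required when vectors are given).
#' @param fold_threshold Fold over control defining induction.
#' @return List: `induced` (logical) and `onset_time` (minutes, `NA` when
#'   never induced).
#' @export
call_induction <- function(induced, control, times = NULL,
                           fold_threshold = 2) {
  grab <- function(x) {
    if (is.data.frame(x)) list(t = x$time, v = x$rel_lum)
    else list(t = times, v = as.numeric(x))
  }
  a <- grab(induced); b <- grab(control)
  if (is.null(a$t) || is.null(b$t)) {
    stop("supply `times` when passing plain vectors", call. = FALSE)
  }
  if (length(a$v) != length(b$v) || !isTRUE(all.equal(a$t, b$t))) {
    stop("induced and control series are on different time grids",
         call. = FALSE)
  }
  above <- a$v >= fold_threshold * b$v
  n <- length(above)
  ok <- above[-n] & above[-1L] # two consecutive points
  hit <- which(ok)
  if (length(hit) == 0L) {
    return(list(induced = FALSE, onset_time = NA_real_))
  }
  list(induced = TRUE, onset_time = as.numeric(a$t[hit[[1L]]]))
}

#' Read a plate-reader export (long CSV)
#'
#' Expected columns: `well`, `time_min`, `lum`, `od600`, `condition`.
#'
#' @param path CSV path.
#' @return Named list of [kinetic_series()], one per well.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_min", "lum", "od600", "condition")
  if (!all(need %in% names(df))) {
    stop("plate CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_min), ]
    kinetic_series(d$well[1L], d$time_min, d$lum, d$od600, d$condition[1L])
  })
  out[unique(df$well)]
}
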