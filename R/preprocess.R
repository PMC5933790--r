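#' Aggregate an event stream into fixed-width daily slots
#'
#' Bins sensor observations into half-open time slots `[t, t + interval)`
#' within each calendar day (local midnight boundaries) and sums the `value`
#' column per (day, slot, sensor). With the default 10-minute interval each
#' day becomes a 24 x 6 = 144-slot window. Missing slots are zero: absence
#' of data is treated as zero activity, not missingness, because data loss
#' is itself a pattern the downstream detector should see.
#'
#' @param events data.frame with `timestamp` (POSIXct or ISO 8601 string),
#'   `sensor_id`, `value`. Unparseable timestamps are dropped with a warning
#'   reporting the count.
#' @param days number of days in the grid; default spans the data.
#' @param interval_minutes slot width; must divide 1440. Default 10.
#' @param origin date of day 1; default the first event's date.
#' @param sensor_index sensor ordering for the third dimension; default the
#'   sorted sensors present.
#' @return object of class `raw_grid`: list with `values` (days x slots x n
#'   array of sums), `origin`, `sensor_index`, `interval_minutes`.
#' @export
aggregate_windows <- function(events, days = NULL, interval_minutes = 10,
                              origin = NULL, sensor_index = NULL) {
  if (1440 %% interval_minutes != 0)
    validation_error("interval_minutes must divide 1440")
  ts <- parse_timestamps(events$timestamp)
  bad <- is.na(ts)
  if (any(bad)) {
    warning(sum(bad), " event(s) with unparseable timestamps were dropped")
    events <- events[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  slots <- 1440L %/% as.integer(interval_minutes)
  origin <- as.Date(origin %||% min(as.Date(ts, tz = "UTC")))
  day <- as.integer(as.Date(ts, tz = "UTC") - origin) + 1L
  if (is.null(days)) days <- max(day, 1L)
  sensor_index <- sensor_index %||% sort(unique(as.character(events$sensor_id)))
  inside <- day >= 1L & day <= days & events$sensor_id %in% sensor_index
  secs <- as.numeric(ts) %% 86400
  slot <- pmin(floor(secs / (interval_minutes * 60)) + 1L, slots)
  values <- tapply(events$value[inside],
                   list(factor(day[inside], seq_len(days)),
                        factor(slot[inside], seq_len(slots)),
                        factor(as.character(events$sensor_id[inside]), sensor_index)),
                   sum)
  values[is.na(values)] <- 0
  dimnames(values) <- list(NULL, NULL, sensor_index)
  structure(list(values = values, origin = origin, sensor_index = sensor_index,
                 interval_minutes = interval_minutes),
            class = "raw_grid")
}

#' Normalise a raw activity grid to the 0-10 activity scale
#'
#' Per-sensor affine rescaling `10 * (x - min) / (max - min)` clipped to
#' \[0, 10\], so every sensor contributes on the same scale regardless of its
#' sampling rate or measurement type. The scaling is learned once (on the
#' training grid) and must be reused unchanged for verification and test
#' data; pass the training grid's `scaling` for that. A robust variant uses
#' inner percentiles instead of the extremes.
#'
#' @param raw a `raw_grid` from [aggregate_windows()].
#' @param scaling data.frame (`sensor_id`, `min`, `max`) learned previously,
#'   or NULL to learn from `raw`.
#' @param probs probabilities defining the learned (min, max) per sensor;
#'   `c(0, 1)` is plain min-max, e.g. `c(0.01, 0.99)` is the robust variant.
#' @return object of class `activity_grid`: `values` (days x slots x n in
#'   \[0, 10\]), `scaling`, plus the `raw_grid` metadata. A sensor whose
#'   learned max equals its min is mapped to all zeros with a warning.
#' @export
normalise_grid <- function(raw, scaling = NULL, probs = c(0, 1)) {
  stopifnot(inherits(raw, "raw_grid"))
  n <- length(raw$sensor_index)
  if (is.null(scaling)) {
    qs <- t(apply(matrix(raw$values, ncol = n), 2, stats::quantile,
                  probs = probs, names = FALSE))
    scaling <- data.frame(sensor_id = raw$sensor_index,
                          min = qs[, 1], max = qs[, 2],
                          stringsAsFactors = FALSE)
  }
  if (any(scaling$max < scaling$min))
    validation_error("scaling must have max >= min for every sensor")
  idx <- match(raw$sensor_index, scaling$sensor_id)
  if (anyNA(idx)) validation_error("scaling is missing sensors present in the grid")
  values <- raw$values
  for (s in seq_len(n)) {
    lo <- scaling$min[idx[s]]; hi <- scaling$max[idx[s]]
    if (hi == lo) {
      warning("sensor ", raw$sensor_index[s],
              " has a degenerate (constant) scaling; mapped to 0")
      values[, , s] <- 0
    } else {
      values[, , s] <- pmin(pmax(10 * (values[, , s] - lo) / (hi - lo), 0), 10)
    }
  }
  structure(list(values = values, scaling = scaling[idx, , drop = FALSE],
                 origin = raw$origin, sensor_index = raw$sensor_index,
                 interval_minutes = raw$interval_minutes),
            class = "activity_grid")
}

#' @export
print.activity_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<activity_grid> ", d[1], " days x ", d[2], " slots x ", d[3],
      " sensors, values in [0, 10]\n", sep = "")
  invisible(x)
}

#' Inclusion filter: homes with enough continuously reporting sensors
#'
#' A home is eligible when at least `min_sensors` of its sensors each report
#' on at least `coverage * min_days` distinct days within the trailing
#' `min_days`-day window (ending at the home's last event). "Continuously"
#' is operationalised as 90% daily coverage by default, tolerating the brief
#' outages real deployments exhibit.
#'
#' @param homes named list of event data.frames (`timestamp`, `sensor_id`).
#' @param min_sensors minimum number of continuously reporting sensors.
#'   Default 3.
#' @param min_days trailing window length in days. Default 90.
#' @param coverage fraction of window days a sensor must report on.
#'   Default 0.9.
#' @return character vector of eligible home names.
#' @export
inclusion_filter <- function(homes, min_sensors = 3, min_days = 90,
                             coverage = 0.9) {
  stopifnot(is.list(homes))
  ok <- vapply(homes, function(ev) {
    if (!nrow(ev)) return(FALSE)
    d <- as.Date(ev$timestamp, tz = "UTC")
    last <- max(d)
    win <- d > last - min_days
    rep_days <- tapply(d[win], as.character(ev$sensor_id[win]),
                       function(x) length(unique(x)))
    sum(rep_days >= coverage * min_days) >= min_sensors
  }, logical(1))
  names(homes)[ok]
}

#' Hourly per-sensor aggregation for the micro track
#'
#' Sums each mapped sensor's values over half-open hour bins
#' `[h:00, h+1:00)`, producing exactly one record per (sensor, day, hour)
#' with silent hours zero-filled. Every movement-class sensor (PIR, motion,
#' pressure) present in the events must be assigned to a group; door,
#' energy and physiological sources are outside the micro movement groups
#' and are ignored.
#'
#' @param events event data.frame (`timestamp`, `sensor_id`, optionally
#'   `sensor_type`, `value`).
#' @param group_map named character vector `sensor_id -> "G2"/"G3"`; a
#'   movement sensor deliberately outside both groups is declared with
#'   `"none"` (an undeclared movement sensor is a configuration error).
#' @param days,origin horizon; defaults span the data.
#' @return data.frame `group`, `sensor_id`, `day`, `hour` (0-23), `p_x`.
#' @export
hourly_aggregate <- function(events, group_map, days = NULL, origin = NULL) {
  if (is.null(names(group_map)) || !all(group_map %in% c("G2", "G3", "none")))
    validation_error("group_map must be a named vector with values G2/G3/none")
  if (!is.null(events$sensor_type)) {
    movement <- unique(as.character(
      events$sensor_id[events$sensor_type %in% c("PIR", "motion", "pressure")]))
    missing <- setdiff(movement, names(group_map))
    if (length(missing))
      validation_error("movement sensor absent from group_map: ",
                       paste(missing, collapse = ", "))
  }
  group_map <- group_map[group_map != "none"]
  ev <- events[events$sensor_id %in% names(group_map), , drop = FALSE]
  ts <- parse_timestamps(ev$timestamp)
  origin <- as.Date(origin %||% if (nrow(ev)) min(as.Date(ts, tz = "UTC")) else Sys.Date())
  day <- as.integer(as.Date(ts, tz = "UTC") - origin) + 1L
  if (is.null(days)) days <- max(day, 1L)
  hour <- as.integer(floor((as.numeric(ts) %% 86400) / 3600))
  sensors <- names(group_map)
  inside <- day >= 1L & day <= days
  agg <- tapply(ev$value[inside],
                list(factor(as.character(ev$sensor_id[inside]), sensors),
                     factor(day[inside], seq_len(days)),
                     factor(hour[inside], 0:23)),
                sum)
  agg[is.na(agg)] <- 0
  out <- expand.grid(hour = 0:23, day = seq_len(days), sensor_id = sensors,
                     stringsAsFactors = FALSE)
  out$p_x <- as.vector(aperm(agg, c(3, 2, 1)))
  out$group <- unname(group_map[out$sensor_id])
  out[, c("group", "sensor_id", "day", "hour", "p_x")]
}
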