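#' Micro decision layer I: threshold scoring and label sequences
#'
#' Physiological observations are scored against clinical thresholds (group
#' G1), while hourly movement aggregates from the participant-proximal (G2)
#' and ambient multi-occupancy (G3) sensors are mapped to normal/abnormal
#' labels via adjusted box-plot bounds and concatenated into hourly symbol
#' sequences for the hidden-Markov layer.
#'
#' @name micro_scoring
NULL

#' Expert decision score over physiological observations
#'
#' Counts the observed vitals falling strictly outside their clinical
#' thresholds: the score starts at 0 and is incremented once per vital with
#' `O < T_L` or `O > T_H` (a value exactly on a threshold is in range).
#'
#' @param observations named numeric vector of vital readings; NA readings
#'   are skipped with a message.
#' @param thresholds data.frame (`vital`, `lower`, `upper`), e.g.
#'   [default_clinical_thresholds()]. Every observed vital must have a row.
#' @return integer score in `0..length(observations)`.
#' @export
expert_decision_score <- function(observations, thresholds) {
  stopifnot(!is.null(names(observations)))
  missing <- setdiff(names(observations), thresholds$vital)
  if (length(missing))
    validation_error("no clinical thresholds for vital: ",
                     paste(missing, collapse = ", "))
  na <- is.na(observations)
  if (any(na)) {
    message("skipping ", sum(na), " missing observation(s): ",
            paste(names(observations)[na], collapse = ", "))
    observations <- observations[!na]
  }
  th <- thresholds[match(names(observations), thresholds$vital), ]
  sum(observations < th$lower | observations > th$upper)
}

#' Medcouple: a robust measure of skewness
#'
#' The median of the kernel
#' `h(x_i, x_j) = ((x_j - m) - (m - x_i)) / (x_j - x_i)` over all pairs with
#' `x_i <= m <= x_j` and `x_i != x_j`, where `m` is the sample median.
#' Ranges over \[-1, 1\]; 0 for symmetric samples, positive for
#' right-skewed. The O(n^2) kernel evaluation is used directly; the hourly
#' samples this is applied to number at most a few thousand points.
#'
#' @param sample numeric vector, length >= 3.
#' @return the medcouple; 0 with a warning if all values are equal.
#' @export
medcouple <- function(sample) {
  x <- sort(as.numeric(sample))
  if (length(x) < 3) validation_error("medcouple needs at least 3 values")
  m <- stats::median(x)
  lo <- x[x <= m]
  hi <- x[x >= m]
  vals <- outer(hi, lo, function(xj, xi) ((xj - m) - (m - xi)) / (xj - xi))
  vals <- vals[!outer(hi, lo, "==")]  # pairs with x_i == x_j are excluded
  if (!length(vals)) {
    warning("all values equal; medcouple set to 0")
    return(0)
  }
  stats::median(vals)
}

#' Adjusted box-plot outlier fences for skewed data
#'
#' Skewness-adjusted whiskers: with quartiles Q1, Q3, `IQR = Q3 - Q1` and
#' medcouple MC, the fences are
#' `[Q1 - 1.5 exp(-4 MC) IQR, Q3 + 1.5 exp(3 MC) IQR]` when `MC >= 0` and
#' `[Q1 - 1.5 exp(-3 MC) IQR, Q3 + 1.5 exp(4 MC) IQR]` otherwise. For a
#' symmetric sample (MC = 0) they reduce to Tukey's fences. Used to learn
#' per-sensor normal/abnormal bounds from historical hourly activity.
#'
#' @param sample numeric vector, length >= 4.
#' @param quartile_type quantile algorithm passed to [stats::quantile()].
#'   Default 7 (linear interpolation).
#' @return named numeric `c(lower, upper)`; collapses to `c(Q1, Q3)` with a
#'   warning when IQR is 0.
#' @export
adjusted_boxplot_bounds <- function(sample, quartile_type = 7) {
  x <- as.numeric(sample)
  if (length(x) < 4) validation_error("need at least 4 values for fences")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = quartile_type)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    warning("zero IQR; fences collapse to [Q1, Q3]")
    return(c(lower = q[1], upper = q[2]))
  }
  mc <- medcouple(x)
  if (mc >= 0) {
    c(lower = q[1] - 1.5 * exp(-4 * mc) * iqr,
      upper = q[2] + 1.5 * exp(3 * mc) * iqr)
  } else {
    c(lower = q[1] - 1.5 * exp(-3 * mc) * iqr,
      upper = q[2] + 1.5 * exp(4 * mc) * iqr)
  }
}

#' Build per-sensor label sets from training hourly features
#'
#' Each sensor receives a globally unique (normal, abnormal) label pair
#' (so any composite symbol decodes uniquely) and adjusted box-plot bounds
#' learned from its training-period hourly aggregates.
#'
#' @param features training data.frame from [hourly_aggregate()].
#' @param sensors sensor ordering; default the sorted sensors present.
#' @return named list of label sets: each has `normal`, `abnormal`,
#'   `bounds`, `group`.
#' @export
make_labelsets <- function(features, sensors = NULL) {
  sensors <- sensors %||% sort(unique(features$sensor_id))
  if (2 * length(sensors) > 26)
    validation_error("label alphabet supports at most 13 sensors")
  out <- lapply(seq_along(sensors), function(i) {
    s <- sensors[i]
    rows <- features[features$sensor_id == s, ]
    if (!nrow(rows)) validation_error("no training features for sensor ", s)
    list(sensor_id = s,
         normal = letters[2 * i - 1],
         abnormal = letters[2 * i],
         bounds = adjusted_boxplot_bounds(rows$p_x),
         group = rows$group[1])
  })
  stats::setNames(out, sensors)
}

#' Categorise hourly features into per-group label sequences
#'
#' Per sensor-hour, the aggregate `P_x` is assigned the sensor's normal
#' label when `B_l <= P_x <= B_u` and its abnormal label otherwise; per
#' hour, the member sensors' labels (in fixed label-set order) are
#' concatenated into one composite symbol, yielding one observation
#' sequence per group (S_G2, S_G3).
#'
#' @param features data.frame from [hourly_aggregate()].
#' @param labelsets per-sensor label sets from [make_labelsets()]; every
#'   sensor in `features` must be present.
#' @return named list per group of data.frames (`day`, `hour`, `symbol`),
#'   each carrying the group's full symbol `alphabet` as an attribute.
#' @export
categorise <- function(features, labelsets) {
  missing <- setdiff(unique(features$sensor_id), names(labelsets))
  if (length(missing))
    validation_error("no label set for sensor: ", paste(missing, collapse = ", "))
  groups <- unique(features$group)
  out <- lapply(groups, function(g) {
    members <- names(labelsets)[vapply(labelsets, function(l)
      identical(l$group, g), logical(1))]
    members <- members[members %in% unique(features$sensor_id[features$group == g])]
    cols <- lapply(members, function(s) {
      ls <- labelsets[[s]]
      rows <- features[features$sensor_id == s, ]
      rows <- rows[order(rows$day, rows$hour), ]
      lab <- ifelse(rows$p_x >= ls$bounds[1] & rows$p_x <= ls$bounds[2],
                    ls$normal, ls$abnormal)
      data.frame(day = rows$day, hour = rows$hour, lab = lab)
    })
    base <- cols[[1]][, c("day", "hour")]
    sym <- do.call(paste0, lapply(cols, `[[`, "lab"))
    df <- data.frame(day = base$day, hour = base$hour, symbol = sym,
                     stringsAsFactors = FALSE)
    combos <- do.call(expand.grid, c(lapply(members, function(s)
      c(labelsets[[s]]$normal, labelsets[[s]]$abnormal)),
      list(stringsAsFactors = FALSE)))
    attr(df, "alphabet") <- sort(do.call(paste0, combos))
    attr(df, "members") <- members
    df
  })
  stats::setNames(out, groups)
}

#' Decode composite symbols back to per-sensor labels
#'
#' @param symbols character vector of composite symbols.
#' @param labelsets the label sets that produced them.
#' @param members member-sensor order used at encoding time.
#' @return character matrix, one row per symbol, columns named by sensor.
#' @export
decode_symbols <- function(symbols, labelsets, members) {
  out <- t(vapply(strsplit(symbols, ""), identity,
                  character(length(members))))
  colnames(out) <- members
  for (j in seq_along(members)) {
    ls <- labelsets[[members[j]]]
    ok <- out[, j] %in% c(ls$normal, ls$abnormal)
    if (!all(ok)) validation_error("symbol position ", j,
                                   " carries a label outside sensor ",
                                   members[j], "'s label set")
  }
  out
}

#' MAD-based outlier flags
#'
#' Flags `x_i` when `|x_i - median| > k * MAD / 0.6745`, the
#' normal-consistent robust z-score rule with MAD the raw median absolute
#' deviation. Used to seed candidate agitation event flags from training
#' data. When MAD is 0 any value differing from the median is flagged,
#' with a warning.
#'
#' @param series numeric vector, length >= 3.
#' @param k threshold multiplier. Default 3.
#' @return logical vector of flags.
#' @export
mad_flag <- function(series, k = 3.0) {
  x <- as.numeric(series)
  if (length(x) < 3) validation_error("need at least 3 values")
  med <- stats::median(x)
  mad_raw <- stats::mad(x, constant = 1)
  dev <- abs(x - med)
  if (mad_raw == 0) {
    if (any(dev > 0)) warning("zero MAD; flagging every value off the median")
    return(dev > 0)
  }
  dev > k * mad_raw / 0.6745
}
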