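test_that("10-minute binning places events in the right slots", {
  ev <- make_events(c("2024-01-01 00:01:00", "2024-01-01 00:05:30",
                      "2024-01-01 00:09:59"), "pir")
  g <- aggregate_windows(ev, days = 1)
  expect_equal(dim(g$values), c(1, 144, 1))
  expect_equal(unname(g$values[1, 1, 1]), 3)
  expect_equal(sum(g$values), 3)

  # empty stream over a declared horizon is an all-zero grid
  empty <- make_events(character(0), character(0))
  g0 <- aggregate_windows(empty, days = 2, origin = as.Date("2024-01-01"),
                          sensor_index = c("a", "b"))
  expect_equal(dim(g0$values), c(2, 144, 2))
  expect_true(all(g0$values == 0))

  # uniform one event per minute: every slot 10, day total 1440
  times <- as.POSIXct("2024-01-01", tz = "UTC") + 60 * (0:1439) + 1
  gu <- aggregate_windows(data.frame(timestamp = times, sensor_id = "pir",
                                     value = 1), days = 1)
  expect_true(all(gu$values[1, , 1] == 10))
  expect_equal(sum(gu$values), 1440)

  # unparseable timestamps are dropped with a warning, others kept
  bad <- data.frame(timestamp = c("2024-01-01 10:00:00", "not a time"),
                    sensor_id = "pir", value = 1)
  expect_warning(gb <- aggregate_windows(bad, days = 1), "unparseable")
  expect_equal(sum(gb$values), 1)
})

test_that("grid aggregation conserves event counts per sensor", {
  set.seed(11)
  n <- 500
  ev <- data.frame(
    timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
      runif(n, 0, 3 * 86400 - 1),
    sensor_id = sample(c("a", "b", "c"), n, replace = TRUE),
    value = 1)
  g <- aggregate_windows(ev, days = 3)
  per_sensor <- apply(g$values, 3, sum)
  expect_equal(per_sensor, c(a = sum(ev$sensor_id == "a"),
                             b = sum(ev$sensor_id == "b"),
                             c = sum(ev$sensor_id == "c")))
})

test_that("normalisation maps the training range onto [0, 10] and clips", {
  ev <- make_events(c("2024-01-01 08:01:00", "2024-01-01 08:02:00",
                      "2024-01-01 09:01:00"), "pir")
  raw <- aggregate_windows(ev, days = 1)
  norm <- normalise_grid(raw)
  expect_equal(max(norm$values), 10)  # training max -> 10
  expect_equal(min(norm$values), 0)

  # frozen scaling: values above the training max are clipped to 10
  ev2 <- make_events(rep("2024-01-01 08:01:00", 7), "pir")
  raw2 <- aggregate_windows(ev2, days = 1)
  norm2 <- normalise_grid(raw2, scaling = norm$scaling)
  expect_equal(max(norm2$values), 10)
  expect_equal(unname(norm2$values[1, 49, 1]), 10)  # 7 events > max of 2

  # re-normalising with the same scaling is idempotent on the raw grid
  again <- normalise_grid(raw, scaling = norm$scaling)
  expect_equal(again$values, norm$values)

  # constant sensor collapses to zero with a warning
  const <- raw
  const$values[] <- 4
  expect_warning(nc <- normalise_grid(const), "degenerate")
  expect_true(all(nc$values == 0))
})

test_that("inclusion filter requires enough continuously reporting sensors", {
  daily_events <- function(sensors, days, start = as.Date("2024-01-01")) {
    do.call(rbind, lapply(sensors, function(s)
      data.frame(timestamp = as.POSIXct(start, tz = "UTC") +
                   (seq_len(days) - 1) * 86400 + 3600,
                 sensor_id = s, value = 1)))
  }
  full <- daily_events(paste0("s", 1:5), 90)
  two <- daily_events(c("s1", "s2"), 90)
  # third sensor silent for the trailing 30 of 90 days: coverage 0.67
  partial <- rbind(daily_events(c("s1", "s2"), 90),
                   daily_events("s3", 60))
  partial <- partial[!(partial$sensor_id == "s3") |
                       partial$timestamp < as.POSIXct("2024-03-01", tz = "UTC"), ]
  homes <- list(full = full, two = two, partial = partial)
  expect_equal(inclusion_filter(homes), "full")

  # monotone: adding events can only add homes
  partial_plus <- rbind(partial, daily_events("s3", 90))
  expect_setequal(
    inclusion_filter(list(full = full, two = two, partial = partial_plus)),
    c("full", "partial"))
})

test_that("hourly aggregation zero-fills and respects hour boundaries", {
  ev <- make_events(c(rep("2024-01-01 14:10:00", 6), "2024-01-01 13:59:59",
                      "2024-01-01 14:00:00"), "chair", type = "pressure")
  gm <- c(chair = "G2")
  hf <- hourly_aggregate(ev, gm, days = 1)
  expect_equal(nrow(hf), 24)
  expect_equal(hf$p_x[hf$hour == 14], 7)  # 6 + the on-the-hour event
  expect_equal(hf$p_x[hf$hour == 13], 1)  # 13:59:59 stays in hour 13
  expect_equal(hf$p_x[hf$hour == 3], 0)   # silent hour present as zero

  # a movement sensor missing from the map is a configuration error
  ev2 <- rbind(ev, make_events("2024-01-01 10:00:00", "bed", type = "pressure"))
  expect_error(hourly_aggregate(ev2, gm, days = 1), "absent from group_map")
  # unless it is declared deliberately ungrouped
  hf2 <- hourly_aggregate(ev2, c(chair = "G2", bed = "none"), days = 1)
  expect_equal(sort(unique(hf2$sensor_id)), "chair")
})
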