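#' Reference evaluation scenarios and stage runners
#'
#' High-level runners chaining the preprocessing, macro and micro stages
#' for one home, plus the two reference synthetic scenarios used for
#' simulation-based evaluation of the detectors.
#'
#' @name scenarios
NULL

#' Subset the days of a grid
#'
#' @param grid a `raw_grid` or `activity_grid`.
#' @param days integer day indices to keep.
#' @return a grid of the same class restricted to those days.
#' @export
subset_grid <- function(grid, days) {
  grid$values <- grid$values[days, , , drop = FALSE]
  grid
}

#' Run the macro routine-analysis pipeline for one home
#'
#' Aggregates the event stream into normalised 10-minute activity grids,
#' learns the day categories, state codebook and per-category Markov models
#' on the training days, derives entropy-rate deviation boundaries from the
#' verification days, and flags test days whose entropy rate leaves the
#' boundaries. All learned state (scaling, centroids, codebook, transition
#' matrices) is frozen after training.
#'
#' @param events event data.frame for one home.
#' @param n_train,n_verify,n_test consecutive day counts partitioning the
#'   horizon (training, verification, test).
#' @param mu confidence coefficient for the deviation boundaries.
#'   Default 2.
#' @param n_states number of activity states; default the sensor count.
#' @param seed integer seed (clustering initialisation).
#' @param sensor_index sensor ordering; default sorted sensors present.
#' @param origin date of day 1.
#' @param mode,method passed to [detect_anomalous_days()].
#' @return list: `flags` (per-test-day data.frame), `categories`,
#'   `codebook`, `models`, `profiles`, `scaling`.
#' @export
run_macro <- function(events, n_train, n_verify, n_test, mu = 2.0,
                      n_states = NULL, seed = 1, sensor_index = NULL,
                      origin = NULL, mode = "two_sided", method = "cross") {
  total <- n_train + n_verify + n_test
  raw <- aggregate_windows(events, days = total, origin = origin,
                           sensor_index = sensor_index)
  train_idx <- seq_len(n_train)
  verify_idx <- n_train + seq_len(n_verify)
  test_idx <- n_train + n_verify + seq_len(n_test)

  train_raw <- subset_grid(raw, train_idx)
  scaling <- normalise_grid(train_raw)$scaling
  norm_all <- normalise_grid(raw, scaling = scaling)
  train_grid <- subset_grid(norm_all, train_idx)
  verify_grid <- subset_grid(norm_all, verify_idx)
  test_grid <- subset_grid(norm_all, test_idx)

  categories <- cluster_days(train_grid, k = 2, seed = seed)
  codebook <- map_states(train_grid, n_states = n_states, seed = seed)
  state_set <- as.character(seq_len(codebook$n_states))

  train_seqs <- apply_codebook(codebook, train_grid)
  models <- list()
  for (cat in c("D1", "D2")) {
    rows <- which(categories$assignment == cat)
    if (length(rows)) {
      models[[cat]] <- fit_markov(
        lapply(rows, function(d) as.character(train_seqs[d, ])),
        states = state_set, category = cat)
    }
  }

  verify_seqs <- apply_codebook(codebook, verify_grid)
  verify_cats <- assign_day_categories(categories, verify_grid)
  xi_verify <- vapply(seq_len(nrow(verify_seqs)), function(d)
    day_entropy_rate(as.character(verify_seqs[d, ]), state_set,
                     method = method, trained = models[[verify_cats[d]]]),
    numeric(1))
  profiles <- list()
  for (cat in names(models)) {
    xi_t <- entropy_rate(models[[cat]])
    xi_v <- xi_verify[verify_cats == cat]
    if (!length(xi_v)) {
      warning("no verification days in category ", cat,
              "; using the pooled verification set")
      xi_v <- xi_verify
    }
    profiles[[cat]] <- deviation_bounds(xi_t, xi_v, mu = mu)
  }
  # a category with no training days inherits the other's model/profile
  for (cat in c("D1", "D2")) {
    if (is.null(models[[cat]])) {
      other <- setdiff(c("D1", "D2"), cat)
      models[[cat]] <- models[[other]]
      profiles[[cat]] <- profiles[[other]]
    }
  }

  flags <- detect_anomalous_days(test_grid, categories, codebook, models,
                                 profiles, mode = mode, method = method)
  list(flags = flags, categories = categories, codebook = codebook,
       models = models, profiles = profiles, scaling = scaling,
       test_idx = test_idx)
}

#' Default micro-track sensor grouping
#'
#' Participant-proximal sensors (G2: chair pressure, bed pressure, bedroom
#' door motion) versus ambient multi-occupancy sensors (G3: living room,
#' hallway, kitchen), taken from a sensor roster's `group` column.
#'
#' The bathroom-door sensor belongs to neither group and is declared
#' `"none"` (deliberately ungrouped).
#'
#' @param sensors roster data.frame; default [default_sensors()].
#' @return named character vector `sensor_id -> group`.
#' @export
default_group_map <- function(sensors = default_sensors()) {
  movement <- sensors$type %in% c("PIR", "motion", "pressure")
  g <- ifelse(is.na(sensors$group[movement]), "none", sensors$group[movement])
  stats::setNames(g, sensors$sensor_id[movement])
}

# Per-day G1 score: the worst (largest) expert decision score among the
# day's reading times, as a fraction of the number of G1 vitals. The
# physiological group covers blood pressure, heart rate and body
# temperature; weight and hydration are monitored but sit outside the
# agitation-scoring group.
physio_day_scores <- function(physio, thresholds, days,
                              g1_vitals = c("systolic", "diastolic",
                                            "heart_rate", "temperature")) {
  physio <- physio[physio$vital %in% g1_vitals, ]
  n_vitals <- length(unique(physio$vital))
  vapply(days, function(d) {
    rows <- physio[physio$day == d, ]
    if (!nrow(rows)) return(NA_real_)
    per_time <- vapply(split(rows, format(rows$timestamp, "%H")), function(r)
      expert_decision_score(stats::setNames(r$value, r$vital), thresholds),
      numeric(1))
    max(per_time) / n_vitals
  }, numeric(1))
}

#' Run the micro AIA-detection pipeline for one home
#'
#' Hourly aggregation, adjusted box-plot label sets learned on the training
#' days, supervised HMM estimation per movement group from the training
#' portion's hidden-state labels, day-level scoring of the test days
#' (G1 threshold score, G2/G3 mean HMM posterior), cross-validated
#' reliability weights and decision fusion, with ROC/AUC evaluation against
#' ground truth.
#'
#' @param events event data.frame.
#' @param truth `ground_truth` from [simulate_home()] (hidden hour labels
#'   stand in for clinician-annotated seed data).
#' @param physio physiology data.frame from [simulate_physiology()].
#' @param n_train number of leading training days.
#' @param days total horizon.
#' @param group_map sensor grouping; default [default_group_map()].
#' @param thresholds clinical thresholds; default
#'   [default_clinical_thresholds()].
#' @param k cross-validation folds. Default 10.
#' @param seed integer seed.
#' @param origin date of day 1.
#' @return list: `scores` (per-test-day data.frame with group scores,
#'   fused score, label and truth), `auc` (named: G1/G2/G3/fused),
#'   `reliability`, `report`, `labelsets`, `hmms`.
#' @export
run_micro <- function(events, truth, physio, n_train, days,
                      group_map = default_group_map(),
                      thresholds = default_clinical_thresholds(),
                      k = 10, seed = 1, origin = NULL) {
  hf <- hourly_aggregate(events, group_map, days = days, origin = origin)
  labelsets <- make_labelsets(hf[hf$day <= n_train, ])
  seqs <- categorise(hf, labelsets)
  test_days <- (n_train + 1):days

  hmms <- list()
  group_scores <- list()
  for (g in names(seqs)) {
    df <- seqs[[g]]
    alphabet <- attr(df, "alphabet")
    split_days <- function(d) {
      sub <- df[df$day %in% d, ]
      lapply(split(sub, sub$day), function(x) x$symbol[order(x$hour)])
    }
    obs_train <- split_days(seq_len(n_train))
    state_train <- lapply(seq_len(n_train), function(d)
      truth$hour_labels[d, ])
    hmms[[g]] <- hmm_fit_supervised(obs_train, state_train, alphabet)
    obs_test <- split_days(test_days)
    group_scores[[g]] <- vapply(obs_test, function(s)
      score_group(hmms[[g]], s)[["AIA"]], numeric(1))
  }

  g1 <- physio_day_scores(physio, thresholds, test_days)
  probs <- cbind(G1 = g1, G2 = group_scores$G2, G3 = group_scores$G3)
  day_truth <- ifelse(apply(truth$hour_labels[test_days, , drop = FALSE] == "AIA",
                            1, any), "AIA", "normal")

  rs <- crossval_reliability(probs, day_truth, k = k, seed = seed)
  fused <- lapply(seq_along(test_days), function(i) {
    p <- unname(probs[i, ])
    fuse(list(G1 = c(AIA = p[1], normal = 1 - p[1]),
              G2 = c(AIA = p[2], normal = 1 - p[2]),
              G3 = c(AIA = p[3], normal = 1 - p[3])), rs)
  })
  fused_score <- vapply(fused, function(f) f$class_scores[["AIA"]], numeric(1))
  fused_label <- vapply(fused, `[[`, character(1), "label")

  auc <- c(G1 = roc_auc(probs[, "G1"], day_truth)$auc,
           G2 = roc_auc(probs[, "G2"], day_truth)$auc,
           G3 = roc_auc(probs[, "G3"], day_truth)$auc,
           fused = roc_auc(fused_score, day_truth)$auc)
  scores <- data.frame(day = test_days, P_G1 = probs[, "G1"],
                       P_G2 = probs[, "G2"], P_G3 = probs[, "G3"],
                       fused_AIA_score = fused_score, label = fused_label,
                       truth = day_truth, stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  list(scores = scores, auc = auc, reliability = rs,
       report = classification_report(fused_label, day_truth,
                                      classes = c("AIA", "normal")),
       labelsets = labelsets, hmms = hmms)
}

#' Reference macro anomaly-recovery scenario
#'
#' One simulated home with 60 training, 14 verification and 60 test days;
#' 10 anomalous days (4 visitor, 3 away, 3 agitation) injected among the
#' test days. The macro detector runs with mu = 2 and the result is scored
#' against ground truth at the day level.
#'
#' @param seed integer seed driving both the simulation and the pipeline.
#' @param n_train,n_verify,n_test partition sizes.
#' @param n_visitor,n_away,n_aia anomalous test-day counts.
#' @param mu confidence coefficient. Default 2.
#' @return list: `sensitivity`, `fpr`, `flags`, `truth_labels`,
#'   `weekly_rho`, `n_flagged`.
#' @export
reference_macro_scenario <- function(seed, n_train = 60, n_verify = 14,
                                     n_test = 60, n_visitor = 4, n_away = 3,
                                     n_aia = 3, mu = 2.0) {
  total <- n_train + n_verify + n_test
  test_days <- (n_train + n_verify + 1):total
  profile <- home_profile()
  schedule <- random_schedule(test_days, n_visitor = n_visitor,
                              n_away = n_away, n_aia = n_aia, seed = seed)
  sim <- simulate_home(profile, schedule, days = total, seed = seed)
  fit <- run_macro(sim$events, n_train, n_verify, n_test, mu = mu,
                   seed = seed, sensor_index = profile$sensors$sensor_id)
  truth_test <- sim$truth$day_labels[test_days]
  anom <- truth_test != "normal"
  flagged <- fit$flags$flagged
  list(sensitivity = sum(flagged & anom) / sum(anom),
       fpr = sum(flagged & !anom) / sum(!anom),
       flags = fit$flags, truth_labels = truth_test,
       weekly_rho = weekly_sensitivity(flagged, truth_test),
       n_flagged = sum(flagged))
}

#' Reference micro fusion scenario
#'
#' One simulated home with 60 training days (12 seeded agitation days, so
#' the supervised HMMs see both hidden states) and 120 test days containing
#' 30 agitation days; 15 visitor days among the normal test days make the
#' multi-occupancy group noisy, and only about half the agitation episodes
#' show a physiological excursion, leaving G1 weakly informative. Returns
#' the per-group and fused AUCs.
#'
#' @param seed integer seed.
#' @param n_train,n_test partition sizes.
#' @param n_aia_train,n_aia_test,n_visitor_test scheduled day counts.
#' @return the [run_micro()] result plus `schedule`.
#' @export
reference_micro_scenario <- function(seed, n_train = 60, n_test = 120,
                                     n_aia_train = 12, n_aia_test = 30,
                                     n_visitor_test = 15) {
  total <- n_train + n_test
  profile <- home_profile()
  sched_train <- random_schedule(seq_len(n_train), n_aia = n_aia_train,
                                 seed = derive_seed(seed, 31L))
  sched_test <- random_schedule((n_train + 1):total, n_visitor = n_visitor_test,
                                n_aia = n_aia_test,
                                seed = derive_seed(seed, 32L))
  eps <- rbind(sched_train$aia_episodes, sched_test$aia_episodes)
  schedule <- anomaly_schedule(visitor_days = sched_test$visitor_days,
                               aia_episodes = eps)
  sim <- simulate_home(profile, schedule, days = total, seed = seed)
  physio <- simulate_physiology(profile, schedule, days = total, seed = seed)
  out <- run_micro(sim$events, sim$truth, physio, n_train = n_train,
                   days = total, seed = seed)
  out$schedule <- schedule
  out
}
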