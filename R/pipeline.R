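#' Reproducible multi-home pipeline runs
#'
#' File-level stage runners tying the simulator, preprocessing, macro and
#' micro tracks into reproducible runs driven by a single YAML config and a
#' single master seed. Every stage writes plain-text artifacts (CSV/JSON)
#' plus a manifest recording the package version, the config hash and every
#' seed, so a run can be replayed bit-identically.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' @return nested list with `run`, `simulate`, `macro` and `micro`
#'   sections; see the fields for the tunable stage parameters.
#' @export
default_config <- function() {
  list(
    run = list(out_dir = "homewatch_out", seed = 1L),
    simulate = list(n_homes = 12L, days = 120L,
                    n_aia_train = 8L,
                    max_visitor = 6L, max_away = 4L, max_aia = 5L),
    macro = list(n_train = 60L, n_verify = 14L, mu = 2.0,
                 n_states = NULL, mode = "two_sided", method = "cross"),
    micro = list(n_train = 60L, k = 10L)
  )
}

#' Read a run configuration, merging over the defaults
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) validation_error("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate the configured homes and write their artifacts
#'
#' Per home: `events_<id>.csv`, `physio_<id>.csv`, `truth_<id>.json`. Each
#' home gets its own derived seed and a randomly sized anomaly schedule
#' (agitation days seeded into the training period so the supervised micro
#' models see both hidden states; visitor/away/agitation days injected
#' after the macro training + verification period).
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return data.frame of written files (invisibly used by the manifest).
#' @export
cmd_simulate <- function(config = default_config(),
                         out_dir = config$run$out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$simulate
  seed <- config$run$seed
  test_start <- config$macro$n_train + config$macro$n_verify + 1L
  if (test_start > sc$days)
    validation_error("horizon (", sc$days, " days) too short for the macro ",
                     "training + verification period")
  files <- character()
  for (h in seq_len(sc$n_homes)) {
    hseed <- derive_seed(seed, 100L + h)
    hid <- sprintf("home_%02d", h)
    profile <- home_profile(home_id = hid)
    counts <- with_seed(derive_seed(hseed, 41L), c(
      visitor = sample.int(sc$max_visitor + 1L, 1L) - 1L,
      away = sample.int(sc$max_away + 1L, 1L) - 1L,
      aia = max(2L, sample.int(sc$max_aia + 1L, 1L) - 1L)))
    sched_train <- random_schedule(seq_len(config$micro$n_train),
                                   n_aia = sc$n_aia_train,
                                   seed = derive_seed(hseed, 42L))
    sched_test <- random_schedule(test_start:sc$days,
                                  n_visitor = counts[["visitor"]],
                                  n_away = counts[["away"]],
                                  n_aia = counts[["aia"]],
                                  seed = derive_seed(hseed, 43L))
    schedule <- anomaly_schedule(
      visitor_days = sched_test$visitor_days,
      away_days = sched_test$away_days,
      aia_episodes = rbind(sched_train$aia_episodes, sched_test$aia_episodes))
    sim <- simulate_home(profile, schedule, days = sc$days, seed = hseed)
    physio <- simulate_physiology(profile, schedule, days = sc$days,
                                  seed = hseed)
    ev_path <- file.path(out_dir, paste0("events_", hid, ".csv"))
    ph_path <- file.path(out_dir, paste0("physio_", hid, ".csv"))
    tr_path <- file.path(out_dir, paste0("truth_", hid, ".json"))
    ev <- sim$events
    ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(ev, ev_path, row.names = FALSE)
    ph <- physio
    ph$timestamp <- format(ph$timestamp, "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(ph, ph_path, row.names = FALSE)
    write_json_artifact(list(
      home_id = hid, seed = hseed,
      day_labels = sim$truth$day_labels,
      hour_labels = apply(sim$truth$hour_labels, 1, paste, collapse = ","),
      day_type = sim$truth$day_type,
      origin = as.character(sim$truth$origin)), tr_path)
    files <- c(files, ev_path, ph_path, tr_path)
  }
  invisible(files)
}

read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$hour_labels <- do.call(rbind, strsplit(tr$hour_labels, ","))
  tr$origin <- as.Date(tr$origin)
  class(tr) <- "ground_truth"
  tr
}

list_home_ids <- function(out_dir) {
  f <- list.files(out_dir, pattern = "^events_.*\\.csv$")
  sub("^events_(.*)\\.csv$", "\\1", f)
}

#' Run the macro stage over every simulated home
#'
#' Writes `macro_flags.csv` (home, day, category, entropy rate, boundaries,
#' flag) and one `macro_model_<id>.json` artifact (codebook centroids,
#' transition matrices, state probabilities, boundaries, seeds) per home.
#'
#' @inheritParams cmd_simulate
#' @return the combined flags data.frame, invisibly.
#' @export
cmd_macro <- function(config = default_config(),
                      out_dir = config$run$out_dir) {
  mc <- config$macro
  homes <- list_home_ids(out_dir)
  if (!length(homes)) validation_error("no simulated homes found in ", out_dir)
  all_flags <- list()
  for (hid in homes) {
    ev <- utils::read.csv(file.path(out_dir, paste0("events_", hid, ".csv")),
                          stringsAsFactors = FALSE)
    n_test <- config$simulate$days - mc$n_train - mc$n_verify
    fit <- run_macro(ev, mc$n_train, mc$n_verify, n_test, mu = mc$mu,
                     n_states = mc$n_states,
                     seed = derive_seed(config$run$seed, 200L),
                     mode = mc$mode, method = mc$method)
    fl <- fit$flags
    fl$day <- fit$test_idx
    fl <- cbind(home_id = hid, fl)
    all_flags[[hid]] <- fl
    write_json_artifact(list(
      home_id = hid, mu = mc$mu, mode = mc$mode, method = mc$method,
      codebook = fit$codebook$centroids,
      day_centroid_totals = fit$categories$totals,
      models = lapply(fit$models, function(m)
        list(category = m$category, trans = m$trans,
             state_probs = m$state_probs)),
      profiles = lapply(fit$profiles, function(p)
        list(xi_t = p$xi_t, sigma = p$sigma, mu = p$mu, delta = p$delta)),
      scaling = fit$scaling),
      file.path(out_dir, paste0("macro_model_", hid, ".json")))
  }
  flags <- do.call(rbind, all_flags)
  rownames(flags) <- NULL
  utils::write.csv(flags, file.path(out_dir, "macro_flags.csv"),
                   row.names = FALSE)
  invisible(flags)
}

#' Run the micro stage (scores) over every simulated home
#'
#' Writes `micro_scores.csv` with the per-test-day group scores (P_G1,
#' P_G2, P_G3), the fused score and label, and the ground truth, plus one
#' `hmm_<id>.json` parameter artifact per home.
#'
#' @inheritParams cmd_simulate
#' @return the combined scores data.frame, invisibly.
#' @export
cmd_micro <- function(config = default_config(),
                      out_dir = config$run$out_dir) {
  homes <- list_home_ids(out_dir)
  if (!length(homes)) validation_error("no simulated homes found in ", out_dir)
  all_scores <- list()
  for (hid in homes) {
    ev <- utils::read.csv(file.path(out_dir, paste0("events_", hid, ".csv")),
                          stringsAsFactors = FALSE)
    ph <- utils::read.csv(file.path(out_dir, paste0("physio_", hid, ".csv")),
                          stringsAsFactors = FALSE)
    ph$timestamp <- as.POSIXct(ph$timestamp, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S")
    tr <- read_truth_json(file.path(out_dir, paste0("truth_", hid, ".json")))
    res <- run_micro(ev, tr, ph, n_train = config$micro$n_train,
                     days = config$simulate$days, k = config$micro$k,
                     seed = derive_seed(config$run$seed, 300L))
    all_scores[[hid]] <- cbind(home_id = hid, res$scores)
    write_json_artifact(lapply(res$hmms, function(m)
      list(states = m$states, trans = m$trans, emis = m$emis,
           init = m$init, alphabet = m$alphabet,
           provenance = "supervised counts from simulator ground truth")),
      file.path(out_dir, paste0("hmm_", hid, ".json")))
  }
  scores <- do.call(rbind, all_scores)
  rownames(scores) <- NULL
  utils::write.csv(scores, file.path(out_dir, "micro_scores.csv"),
                   row.names = FALSE)
  invisible(scores)
}

#' Fuse pooled micro scores and evaluate both tracks
#'
#' Reads the macro flags and micro scores, re-learns the reliability
#' matrix on the pooled test windows, fuses, and writes `fusion.csv` and
#' `evaluation.json` (per-model AUCs, per-class report, per-home weekly
#' sensitivity and the anomaly/notification correlation across homes).
#'
#' @inheritParams cmd_simulate
#' @return the evaluation list, invisibly.
#' @export
cmd_fuse <- function(config = default_config(),
                     out_dir = config$run$out_dir) {
  sc_path <- file.path(out_dir, "micro_scores.csv")
  fl_path <- file.path(out_dir, "macro_flags.csv")
  if (!file.exists(sc_path) || !file.exists(fl_path))
    validation_error("missing upstream artifact: run the macro and micro stages first")
  scores <- utils::read.csv(sc_path, stringsAsFactors = FALSE)
  flags <- utils::read.csv(fl_path, stringsAsFactors = FALSE)
  need <- c("P_G1", "P_G2", "P_G3", "truth")
  if (!all(need %in% names(scores)))
    stop(structure(class = c("homewatch_schema_error", "error", "condition"),
                   list(message = paste0("micro_scores.csv lacks columns: ",
                                         paste(setdiff(need, names(scores)),
                                               collapse = ", ")),
                        call = NULL)))
  probs <- as.matrix(scores[, c("P_G1", "P_G2", "P_G3")])
  colnames(probs) <- c("G1", "G2", "G3")
  rs <- crossval_reliability(probs, scores$truth, k = config$micro$k,
                             seed = derive_seed(config$run$seed, 400L))
  fused <- lapply(seq_len(nrow(probs)), function(i) {
    p <- unname(probs[i, ])
    fuse(list(G1 = c(AIA = p[1], normal = 1 - p[1]),
              G2 = c(AIA = p[2], normal = 1 - p[2]),
              G3 = c(AIA = p[3], normal = 1 - p[3])), rs)
  })
  scores$fused_AIA_score <- vapply(fused, function(f)
    f$class_scores[["AIA"]], numeric(1))
  scores$label <- vapply(fused, `[[`, character(1), "label")
  utils::write.csv(scores, file.path(out_dir, "fusion.csv"),
                   row.names = FALSE)

  auc <- list(G1 = roc_auc(probs[, 1], scores$truth)$auc,
              G2 = roc_auc(probs[, 2], scores$truth)$auc,
              G3 = roc_auc(probs[, 3], scores$truth)$auc,
              fused = roc_auc(scores$fused_AIA_score, scores$truth)$auc)

  homes <- unique(flags$home_id)
  per_home <- lapply(homes, function(hid) {
    fl <- flags[flags$home_id == hid, ]
    tr <- read_truth_json(file.path(out_dir, paste0("truth_", hid, ".json")))
    truth_test <- tr$day_labels[fl$day]
    list(home_id = hid,
         n_flagged = sum(fl$flagged),
         n_true_anomalous = sum(truth_test != "normal"),
         weekly_rho = suppressWarnings(
           weekly_sensitivity(fl$flagged, truth_test)))
  })
  n_a <- vapply(per_home, `[[`, numeric(1), "n_flagged")
  n_n <- vapply(per_home, `[[`, numeric(1), "n_true_anomalous")
  corr <- if (length(homes) >= 2 && stats::var(n_a) > 0 && stats::var(n_n) > 0)
    anomaly_notification_correlation(n_a, n_n) else NA_real_
  evaluation <- list(
    auc = auc,
    fusion_report = classification_report(scores$label, scores$truth,
                                          classes = c("AIA", "normal")),
    reliability = as.matrix(rs)[, , drop = FALSE],
    macro_per_home = per_home,
    anomaly_notification_correlation = corr)
  write_json_artifact(evaluation, file.path(out_dir, "evaluation.json"))
  invisible(evaluation)
}

#' Run the full pipeline and write a replayable manifest
#'
#' Simulate, macro, micro, fuse/evaluate, then write `manifest.json`
#' recording the package version, the resolved config (and its hash), the
#' master seed and the MD5 of every artifact. Re-running with the same
#' manifest config reproduces every file bit-identically.
#'
#' @param config config list or path to a YAML file.
#' @param out_dir output directory override.
#' @param seed master seed override.
#' @return the evaluation list, invisibly.
#' @export
run_all <- function(config = default_config(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$run$seed <- as.integer(seed)
  if (!is.null(out_dir)) config$run$out_dir <- out_dir
  out_dir <- config$run$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config, cfg_path)

  message("[simulate] ", config$simulate$n_homes, " homes x ",
          config$simulate$days, " days")
  cmd_simulate(config, out_dir)
  message("[macro] flagging anomalous days")
  cmd_macro(config, out_dir)
  message("[micro] scoring agitation")
  cmd_micro(config, out_dir)
  message("[fuse] reliability-weighted fusion + evaluation")
  evaluation <- cmd_fuse(config, out_dir)

  artifacts <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "homewatch",
    version = as.character(utils::packageVersion("homewatch")),
    seed = config$run$seed,
    config = config,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = lapply(artifacts, function(f)
      list(file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  write_json_artifact(manifest, file.path(out_dir, "manifest.json"))
  invisible(evaluation)
}
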