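#' Scenario parameters for a simulated cohort
#'
#' Per-timepoint ground-truth settings for one experimental group. The
#' control scenario raises theta gain, evoked amplitude, and dmPFC-BLA
#' coupling (with a +20 ms dmPFC lead) at fear recall, reverting theta and
#' AEP towards baseline at extinction recall while coupling stays elevated.
#' The CIS (chronic immobilization stress) scenario keeps BLA theta elevated
#' at both recall timepoints, leaves the dmPFC AEP flat, and abolishes
#' coupling and lead throughout.
#'
#' @param name `"control"` or `"CIS"`.
#' @return Named list (one element per timepoint) of ground-truth settings:
#'   `theta_gain` and `aep_uv` per region, `coupling`, `lag`, `freeze_frac`.
#' @export
scenario_params <- function(name = c("control", "CIS")) {
  name <- match.arg(name)
  tg <- function(d, b) list(dmPFC = d, BLA = b)
  if (name == "control") {
    list(
      before_conditioning = list(theta_gain = tg(1, 1), aep_uv = tg(75, 75),
                                 coupling = 0.3, lag = 0.02,
                                 freeze_frac = 0.05),
      fear_recall = list(theta_gain = tg(2.5, 2.5), aep_uv = tg(120, 120),
                         coupling = 0.9, lag = 0.02, freeze_frac = 0.7),
      extinction_recall = list(theta_gain = tg(1, 1), aep_uv = tg(80, 80),
                               coupling = 0.9, lag = 0.02, freeze_frac = 0.3)
    )
  } else {
    list(
      before_conditioning = list(theta_gain = tg(1, 1), aep_uv = tg(75, 75),
                                 coupling = 0, lag = 0, freeze_frac = 0.05),
      fear_recall = list(theta_gain = tg(2.5, 2.5), aep_uv = tg(75, 115),
                         coupling = 0, lag = 0, freeze_frac = 0.7),
      extinction_recall = list(theta_gain = tg(1, 2.5), aep_uv = tg(75, 115),
                               coupling = 0, lag = 0, freeze_frac = 0.3)
    )
  }
}

#' Configuration for an end-to-end simulated experiment
#'
#' @param n_control,n_cis Animals per group.
#' @param seed Master seed; per-animal child seeds are spawned as
#'   `seed * 1000 + animal index` (recorded in the manifest).
#' @param n_tones_habituation,n_tones_recall Tones per simulated session.
#'   The analyses use two trials per timepoint, so the recall sessions are
#'   simulated at two tones by default to keep runs desk-sized; the full
#'   protocol (5/15) can be requested.
#' @param params Baseline [sim_params()] shared by all animals (coupling,
#'   lag, gains are overridden per scenario/timepoint).
#' @param animal_jitter_sd Log-normal SD of per-animal multipliers applied
#'   to theta gain and AEP amplitude (biological variability).
#' @param n_surrogates Surrogates per segment for the lead/lag test.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_control = 7, n_cis = 8, seed = 1L,
                       n_tones_habituation = 5, n_tones_recall = 2,
                       params = sim_params(), animal_jitter_sd = 0.08,
                       n_surrogates = 100) {
  structure(list(n_control = n_control, n_cis = n_cis, seed = as.integer(seed),
                 n_tones_habituation = n_tones_habituation,
                 n_tones_recall = n_tones_recall, params = params,
                 animal_jitter_sd = animal_jitter_sd,
                 n_surrogates = n_surrogates),
            class = "run_config")
}

timepoint_session <- function(timepoint) {
  switch(timepoint,
         before_conditioning = "tone_habituation",
         fear_recall = "fear_recall_extinction",
         extinction_recall = "extinction_recall")
}

# Simulate and analyse one animal across the three recorded timepoints.
analyze_animal <- function(animal_id, group, scen, config, child_seed) {
  tps <- names(scen)
  rows <- list()
  amp0 <- list()
  theta0 <- list()
  jit <- with_seed(child_seed, {
    stats::rlnorm(2, 0, config$animal_jitter_sd)
  })
  for (ti in seq_along(tps)) {
    tp <- tps[[ti]]
    sc <- scen[[tp]]
    label <- timepoint_session(tp)
    n_tones <- if (label == "tone_habituation") config$n_tones_habituation
               else config$n_tones_recall
    des <- session_design(label, n_tones = n_tones)
    p <- config$params
    p$coupling <- sc$coupling
    p$lag <- sc$lag
    p$region_theta_gain <- list(dmPFC = jit[1] * sc$theta_gain$dmPFC,
                                BLA = jit[1] * sc$theta_gain$BLA)
    p$aep_amplitude <- list(dmPFC = jit[2] * sc$aep_uv$dmPFC,
                            BLA = jit[2] * sc$aep_uv$BLA)
    p$seed <- child_seed * 10L + ti
    rec <- simulate_session(des, p, animal_id = animal_id, group = group)
    trials <- select_block_trials(rec, tp)

    fr <- simulate_freezing(rep(sc$freeze_frac, nrow(rec$trials)),
                            rec$trials$tone_onset_s,
                            mode = "stochastic", seed = p$seed + 1L)
    fz <- session_freezing(fr, rec$trials$tone_onset_s[trials])

    meas <- list(freezing = mean(fz$per_trial))
    for (rg in c("dmPFC", "BLA")) {
      segs <- epoch_pips(rec, rg, trials)
      ev <- average_aep(segs)
      ev <- score_amplitude(ev)
      tf <- zscore_baseline(morlet_tfr(ev, rate = rec$rate))
      meas[[paste0("aep_", rg)]] <- ev$amplitude_uv
      meas[[paste0("theta_", rg)]] <- evoked_theta_power(tf)
    }
    co <- vapply(trials, function(tr) {
      on <- rec$trials$tone_onset_s[rec$trials$trial_index == tr]
      idx <- (round(on * rec$rate) + 1L):(round((on + 30) * rec$rate))
      coherence_spectrum(rec$channels$dmPFC[idx], rec$channels$BLA[idx],
                         rec$rate)$theta_coherence
    }, numeric(1))
    meas$coherence <- mean(co)
    ll <- lead_lag_session(rec, tp, n_surrogates = config$n_surrogates,
                           seed = p$seed + 2L)
    meas$lag_s <- ll$summary_lag_s
    meas$lag_significant <- ll$significant
    if (tp == "before_conditioning") {
      amp0$dmPFC <- meas$aep_dmPFC
      amp0$BLA <- meas$aep_BLA
      theta0$dmPFC <- meas$theta_dmPFC
      theta0$BLA <- meas$theta_BLA
    }
    rows[[tp]] <- meas
  }
  out <- list()
  for (tp in tps) {
    m <- rows[[tp]]
    for (rg in c("dmPFC", "BLA")) {
      a0 <- amp0[[rg]]
      t0 <- theta0[[rg]]
      m[[paste0("aep_pct_", rg)]] <- normalize_percent(m[[paste0("aep_", rg)]],
                                                       a0)
      th <- m[[paste0("theta_", rg)]]
      if (is.finite(t0) && t0 > 0) {
        m[[paste0("theta_pct_", rg)]] <- normalize_percent(th, t0)
        m[[paste0("theta_pct_flag_", rg)]] <- "percent"
      } else {
        m[[paste0("theta_pct_", rg)]] <- th - t0
        m[[paste0("theta_pct_flag_", rg)]] <- "difference"
      }
    }
    out[[tp]] <- data.frame(animal_id = animal_id, group = group,
                            timepoint = tp, m, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run a full simulated experiment
#'
#' Simulates a cohort (control and CIS groups under their scenarios),
#' computes every per-animal measure at the three recorded timepoints
#' (freezing, AEP amplitude and percent of the before-conditioning baseline,
#' evoked theta power and its normalization, theta coherence, envelope
#' lead/lag with surrogate significance), and fits the group statistics:
#' one-way repeated-measures ANOVAs across timepoints per group for the
#' normalized AEP, theta power and coherence, and a mixed two-way ANOVA for
#' freezing.
#'
#' @param config A [run_config()].
#' @return List of class `fearlfp_run`: `summary` (long per-animal table),
#'   `anovas`, `manifest` (seeds and configuration).
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  plan <- rbind(
    data.frame(group = "control", idx = seq_len(config$n_control)),
    data.frame(group = "CIS", idx = config$n_control +
                 seq_len(config$n_cis))
  )
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    g <- plan$group[i]
    child <- config$seed * 1000L + plan$idx[i]
    rows[[i]] <- analyze_animal(sprintf("%s%02d", tolower(g), plan$idx[i]),
                                g, scenario_params(g), config, child)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  anovas <- list()
  for (g in c("control", "CIS")) {
    dg <- summary[summary$group == g, ]
    for (ms in c("aep_pct_dmPFC", "aep_pct_BLA", "theta_pct_dmPFC",
                 "theta_pct_BLA", "coherence")) {
      key <- paste(g, ms, sep = ".")
      anovas[[key]] <- tryCatch(
        rm_anova_1way(data.frame(value = dg[[ms]], subject = dg$animal_id,
                                 level = dg$timepoint)),
        error = function(e) e)
    }
  }
  anovas$freezing_mixed <- rm_anova_mixed(
    data.frame(value = summary$freezing, subject = summary$animal_id,
               group = summary$group, level = summary$timepoint))

  manifest <- list(seed = config$seed,
                   child_seed_rule = "seed * 1000 + animal index",
                   n_control = config$n_control, n_cis = config$n_cis,
                   n_tones = c(habituation = config$n_tones_habituation,
                               recall = config$n_tones_recall),
                   n_surrogates = config$n_surrogates,
                   package_version = as.character(utils::packageVersion("fearlfp")))
  structure(list(summary = summary, anovas = anovas, manifest = manifest),
            class = "fearlfp_run")
}

#' @export
print.fearlfp_run <- function(x, ...) {
  cat(sprintf("<fearlfp_run> %d animals x %d timepoints (seed %d)\n",
              length(unique(x$summary$animal_id)),
              length(unique(x$summary$timepoint)), x$manifest$seed))
  agg <- stats::aggregate(cbind(freezing, aep_pct_BLA, theta_pct_BLA,
                                coherence, lag_s) ~ group + timepoint,
                          data = x$summary, FUN = stats::median)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write a run's results bundle to a directory
#'
#' Writes the per-animal summary CSV, one CSV per ANOVA table, and a JSON
#' manifest carrying the seeds, the configuration echo and the MD5 hash of
#' the configuration serialization.
#'
#' @param run A `fearlfp_run` from [run_experiment()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_results <- function(run, path) {
  stopifnot(inherits(run, "fearlfp_run"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$summary, file.path(path, "summary.csv"),
                   row.names = FALSE)
  for (nm in names(run$anovas)) {
    a <- run$anovas[[nm]]
    if (inherits(a, "rm_anova")) {
      utils::write.csv(a$table,
                       file.path(path, paste0("anova_", gsub("[^A-Za-z0-9_.]",
                                                             "_", nm), ".csv")),
                       row.names = FALSE)
    }
  }
  cfg_file <- file.path(path, "manifest.json")
  jsonlite::write_json(run$manifest, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- run$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  jsonlite::write_json(manifest, cfg_file, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a wide per-animal summary table into the long analysis format
#'
#' One-shot importer for per-figure summary tables: a CSV with one row per
#' animal, an animal-id column, a group column, and one column per repeated
#' level. The level mapping must be given explicitly (`level_cols`), so no
#' column is guessed; unknown or missing columns abort with no partial
#' output.
#'
#' @param path CSV file (convert spreadsheet workbooks to CSV first).
#' @param measure Name of the measure (e.g. `"freezing"`).
#' @param level_cols Named character vector mapping level labels to column
#'   names, in within-factor order.
#' @param id_col,group_col Column names for animal id and group.
#' @return Long data.frame: `animal_id`, `group`, `measure`, `level`,
#'   `value`.
#' @export
import_source_data <- function(path, measure, level_cols,
                               id_col = "animal_id", group_col = "group") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(names(level_cols)) || any(names(level_cols) == "")) {
    stop("level_cols must be a named vector (level label -> column name)")
  }
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(id_col, group_col, unname(level_cols))
  miss <- setdiff(need, names(wide))
  if (length(miss)) {
    stop("schema mismatch: column(s) ", paste(miss, collapse = ", "),
         " absent from ", path, "; available: ",
         paste(names(wide), collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_along(level_cols), function(k) {
    data.frame(animal_id = wide[[id_col]], group = wide[[group_col]],
               measure = measure, level = names(level_cols)[k],
               value = as.numeric(wide[[level_cols[k]]]),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(out$value)) stop("non-numeric values in measure columns")
  rownames(out) <- NULL
  out
}
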