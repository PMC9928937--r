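#' Write a session to the plain-text container format
#'
#' A session is a directory of CSV tables - `units.csv` (unit_id, subject,
#' region, channel), `spikes.csv` (unit_id, time_s), `trials.csv` (trial,
#' cs_type, cs_onset_s, us_onset_s), `licks.csv` (time_s), `laser.csv`
#' (onset_s, width_s, freq_hz) - plus `metadata.json` (format version,
#' generator seed, tone duration). All times are seconds from session start.
#'
#' @param session an `ephys_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                  scientific = FALSE))
    utils::write.csv(df, file.path(path, name), row.names = FALSE,
                     quote = FALSE)
  }
  wr(session$units, "units.csv")
  sp <- data.frame(
    unit_id = rep(names(session$spikes),
                  vapply(session$spikes, length, integer(1))),
    time_s = unlist(session$spikes, use.names = FALSE))
  wr(sp, "spikes.csv")
  wr(session$trials, "trials.csv")
  wr(data.frame(time_s = session$licks), "licks.csv")
  wr(session$laser, "laser.csv")
  meta <- session$metadata
  meta$subject_id <- session$subject_id
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_table <- function(path, name, cols) {
  f <- file.path(path, name)
  if (!file.exists(f)) stop_input("missing session table: %s", f)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  missing <- setdiff(names(cols), names(df))
  if (length(missing)) {
    stop_input("%s: missing column(s) %s", f, paste(missing, collapse = ", "))
  }
  for (cn in names(cols)) {
    if (cols[[cn]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (nrow(df) && anyNA(v)) {
        stop_input("%s: non-numeric value in column '%s' (row %d)",
                   f, cn, which(is.na(v))[1])
      }
      df[[cn]] <- v
    }
  }
  df
}

#' Read a session from the container format
#'
#' Validates the table schemas, that all times are non-negative and finite,
#' and that every spike references a known unit.
#'
#' @param path session directory written by [write_session()].
#' @return an `ephys_session`.
#' @export
read_session <- function(path) {
  units <- .read_table(path, "units.csv",
                       c(unit_id = "character", subject = "character",
                         region = "character", channel = "numeric"))
  sp <- .read_table(path, "spikes.csv",
                    c(unit_id = "character", time_s = "numeric"))
  trials <- .read_table(path, "trials.csv",
                        c(trial = "numeric", cs_type = "character",
                          cs_onset_s = "numeric", us_onset_s = "numeric"))
  licks <- .read_table(path, "licks.csv", c(time_s = "numeric"))
  laser <- .read_table(path, "laser.csv",
                       c(onset_s = "numeric", width_s = "numeric",
                         freq_hz = "numeric"))
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  unknown <- setdiff(unique(sp$unit_id), units$unit_id)
  if (length(unknown)) {
    stop_input("spikes.csv references unknown unit_id(s): %s",
               paste(utils::head(unknown, 5), collapse = ", "))
  }
  times <- c(sp$time_s, trials$cs_onset_s, trials$us_onset_s, licks$time_s,
             laser$onset_s)
  if (length(times) && (any(!is.finite(times)) || any(times < 0))) {
    stop_input("event times must be finite and >= 0")
  }
  spikes <- lapply(stats::setNames(units$unit_id, units$unit_id),
                   function(u) sort(sp$time_s[sp$unit_id == u]))
  attr(trials, "tone_duration_s") <- meta$tone_duration_s %||% 4
  structure(list(subject_id = meta$subject_id %||% basename(path),
                 trials = trials, units = units, spikes = spikes,
                 licks = licks$time_s, laser = laser,
                 metadata = meta),
            class = "ephys_session")
}

# CS onsets of one type across a session
.cs_onsets <- function(session, type) {
  session$trials$cs_onset_s[session$trials$cs_type == type]
}

#' Run the full analysis pipeline on a simulated or loaded study
#'
#' Executes, in order: simulation (or session loading), behavioural learning
#' assessment, phototagging, valence categorisation, trajectory geometry,
#' phasic clustering, and tonic clustering; writes the stage tables as CSV
#' under `out_dir` together with a machine-readable `summary.json` echoing
#' the configuration seed.
#'
#' @param config a [sim_config()]; ignored when `sessions` is given.
#' @param sessions optional list of `ephys_session` objects to analyse
#'   instead of simulating.
#' @param out_dir output directory; NULL skips all file output.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), sessions = NULL,
                         out_dir = NULL) {
  simulated <- is.null(sessions)
  if (simulated) {
    sim <- simulate_study(config)
    sessions <- sim$sessions
    ground_truth <- sim$ground_truth
  } else {
    ground_truth <- NULL
    if (!length(sessions)) stop_input("no input sessions and no simulation config")
  }
  stages <- character(0)
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c(stages, "simulate")

  # --- behaviour ---------------------------------------------------------
  behavior <- list(); outcomes <- list()
  for (s in sessions) {
    counts <- per_trial_lick_counts(s$licks, s$trials)
    lo <- assess_learning(counts[counts$cs_type == "E", ],
                          counts[counts$cs_type == "A", ],
                          mode = "discrimination",
                          seed = s$metadata$seed %||% 1L)
    behavior[[s$subject_id]] <- cbind(subject = s$subject_id, lo$subsets,
                                      learned = lo$learned,
                                      anticipatory_rate = lo$anticipatory_rate)
    outcomes[[s$subject_id]] <- data.frame(
      subject = s$subject_id, trial = s$trials$trial,
      outcome = classify_trial_outcomes(s$licks, s$trials))
  }
  behavior_tab <- do.call(rbind, behavior)
  emit(behavior_tab, "behavior_learning.csv")
  emit(do.call(rbind, outcomes), "trial_outcomes.csv")
  stages <- c(stages, "behavior")

  # --- phototagging ------------------------------------------------------
  tags <- do.call(rbind, lapply(sessions, tag_session))
  emit(tags, "phototag.csv")
  stages <- c(stages, "phototag")

  # unit metadata across the study
  units <- do.call(rbind, lapply(sessions, `[[`, "units"))
  subj_of <- stats::setNames(units$subject, units$unit_id)
  region_of <- stats::setNames(units$region, units$unit_id)

  # --- valence categorisation -------------------------------------------
  val <- do.call(rbind, lapply(sessions, function(s) {
    cbind(unit_id = s$units$unit_id, do.call(rbind, lapply(
      s$units$unit_id, function(u) {
        classify_valence_category(s$spikes[[u]], .cs_onsets(s, "E"),
                                  .cs_onsets(s, "A"))
      })))
  }))
  emit(val, "valence_categories.csv")
  emit(as.data.frame(table(region = region_of[val$unit_id],
                           category = val$label)),
       "valence_category_counts.csv")
  prev <- lapply(c("MGN", "BLA"), function(rg) {
    sel <- region_of[val$unit_id] == rg
    prevalence_test(loo_counts(val$label[sel], subj_of[val$unit_id][sel]))
  })
  names(prev) <- c("MGN", "BLA")
  stages <- c(stages, "categorize")

  # --- trajectories ------------------------------------------------------
  traj_summary <- list()
  for (rg in c("MGN", "BLA")) {
    uid <- units$unit_id[units$region == rg]
    zmats <- list()
    for (cond in c("E", "A")) {
      mats <- lapply(sessions, function(s) {
        u <- intersect(uid, s$units$unit_id)
        z <- zscore_smooth(compute_psth(s$spikes[u], .cs_onsets(s, cond),
                                        bin_width_s = 0.05, window = c(-2, 4)),
                           smooth_bins = 0)
        z$values
      })
      zmats[[cond]] <- do.call(rbind, mats)
    }
    shared <- Reduce(intersect, lapply(zmats, rownames))
    zmats <- lapply(zmats, function(m) m[shared, , drop = FALSE])
    ts <- compute_trajectories(zmats, n_components = 3, smooth_bins = 25)
    bin_times <- seq(-2, 4 - 0.05, by = 0.05)
    geom <- trajectory_geometry(zmats, subj_of[shared], bin_times,
                                n_components = 3, smooth_bins = 25)
    cmp <- compare_geometry(geom)
    traj_summary[[rg]] <- list(
      var_explained_pc12 = sum(ts$explained[1:2]),
      length_p = cmp$length_test$omnibus_p,
      pre_vs_post_p = cmp$pre_vs_post[[1]]$omnibus_p)
    emit(geom$lengths, sprintf("trajectory_lengths_%s.csv", rg))
  }
  stages <- c(stages, "trajectories")

  # --- phasic clustering -------------------------------------------------
  # per-session events differ; build per-session features and stack
  feats <- lapply(sessions, function(s) {
    build_feature_matrix(s$spikes, list(E = .cs_onsets(s, "E"),
                                        A = .cs_onsets(s, "A")))
  })
  fmat <- do.call(rbind, lapply(feats, function(f) f$features))
  phasic <- ward_cut(fmat, cutoff_fraction = 0.23)
  phasic_stats <- cluster_prevalence_stats(
    phasic, subj_of[rownames(fmat)], region_of[rownames(fmat)],
    groups = if (!is.null(ground_truth)) {
      stats::setNames(ground_truth$subpopulation,
                      ground_truth$unit_id)[rownames(fmat)]
    } else NULL)
  emit(data.frame(unit_id = names(phasic$labels), cluster = phasic$labels),
       "phasic_clusters.csv")
  stages <- c(stages, "cluster_phasic")

  # --- tonic clustering --------------------------------------------------
  tonic_tabs <- list(); tmats <- list(); tcounts <- list()
  for (s in sessions) {
    tm <- build_tonic_matrix(s$spikes, s$trials)
    tmats[[s$subject_id]] <- tm$features
    tcounts <- c(tcounts, tm$counts)
  }
  tmat <- do.call(rbind, tmats)
  tonic_cl <- cluster_trial_series(tmat)
  tonic_tab <- tonic_change_report(tcounts, tonic_cl)
  emit(tonic_tab, "tonic_regressions.csv")
  emit(data.frame(unit_id = names(tonic_cl$labels), cluster = tonic_cl$labels),
       "tonic_clusters.csv")
  stages <- c(stages, "cluster_tonic")

  summary <- list(
    stages_completed = stages,
    seed = if (simulated) config$seed else NA,
    n_sessions = length(sessions),
    n_units = nrow(units),
    n_learned = sum(vapply(behavior, function(b) b$learned[1], logical(1))),
    n_tagged_mgn = sum(tags$class == "MGN_to_BLA"),
    n_bla_in_network = sum(tags$class == "BLA_in"),
    valence_counts = as.list(table(val$label)),
    category_prevalence_p = lapply(prev, function(x) x$omnibus_p),
    trajectory = traj_summary,
    n_phasic_clusters = length(phasic$sizes),
    n_phasic_discarded = length(phasic$discarded),
    n_tonic_clusters = length(tonic_cl$sizes),
    n_tonic_flagged = sum(tonic_tab$change),
    tonic_flagged_clusters =
      sort(unique(tonic_tab$cluster[tonic_tab$change]))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
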