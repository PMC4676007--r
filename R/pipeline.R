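#' Analyze one recording into measure samples and graph statistics
#'
#' Stage order: unit QC, zero-phase band-limiting, epoch selection (central
#' rest epoch, or the 500 ms evoked epochs when a stimulus schedule is
#' present), windowing, windowed PLV, percentile thresholding,
#' admissibility and ensemble outlier filtering, and per-graph statistics.
#'
#' @param rec a [recording()].
#' @param win_length,overlap PLV window parameters (s, fraction).
#' @param band analysis band `c(low, high)` Hz.
#' @param percentile graph threshold percentile.
#' @param edge_guard fraction of phase samples discarded at each epoch end.
#' @return list with `measures` (long data.frame: measure, group,
#'   condition, region, epoch_type, value), `graph_stats` (per kept graph),
#'   `qc` (per-unit decisions) and `manifest` (stage counts).
#' @export
analyze_recording <- function(rec, win_length = 0.5, overlap = 0.5,
                              band = c(1, 120), percentile = 75,
                              edge_guard = 0.05) {
  validate_recording(rec)
  meta <- rec$session_meta
  evoked <- !is.null(rec$schedule) &&
    length(rec$schedule$first_pulse_times) > 0
  epoch_type <- if (evoked) "evoked" else "rest"
  dur <- meta$duration
  rest_epoch <- if (dur >= 180) trim_rest_epoch(rec) else c(0, dur)

  qc <- do.call(rbind, lapply(rec$spike_trains, unit_qc,
                              analysis_duration = dur))
  accepted <- if (is.null(qc)) character(0) else
    qc$unit_id[qc$decision == "accepted"]
  rec_qc <- rec
  rec_qc$spike_trains <- Filter(function(st) st$unit_id %in% accepted,
                                rec$spike_trains)

  fr <- if (length(rec_qc$spike_trains))
    rate_samples(rec_qc, epoch = rest_epoch, win_length = win_length,
                 evoked = evoked) else NULL
  measures <- if (is.null(fr))
    data.frame(measure = character(), group = character(),
               condition = character(), region = character(),
               epoch_type = character(), value = numeric(),
               stringsAsFactors = FALSE)
  else
    data.frame(measure = "FR", group = meta$group,
               condition = meta$condition, region = fr$region,
               epoch_type = epoch_type, value = fr$rate,
               stringsAsFactors = FALSE)

  lfp <- bandlimit_lfp(rec$lfp, rec$fs_lfp, band[1], band[2])
  if (evoked) {
    starts <- extract_evoked_epochs(rec)$start
    plv_arr <- windowed_plv(lfp, rec$fs_lfp, win_length = win_length,
                            starts = starts, edge_guard = edge_guard)
  } else {
    i0 <- floor(rest_epoch[1] * rec$fs_lfp) + 1
    i1 <- floor(rest_epoch[2] * rec$fs_lfp)
    plv_arr <- windowed_plv(lfp[, i0:i1, drop = FALSE], rec$fs_lfp,
                            win_length = win_length, overlap = overlap,
                            edge_guard = edge_guard)
  }
  ut <- upper.tri(plv_arr[, , 1])
  nw <- dim(plv_arr)[3]
  # sampling unit for comparisons: per-window average synchrony (the mean
  # over channel pairs); pair-level values share one trajectory per window
  # and pooling them as independent badly over-states the evidence
  plv_vals <- apply(plv_arr, 3, function(M) mean(M[ut]))
  measures <- rbind(measures, data.frame(
    measure = "PLV", group = meta$group, condition = meta$condition,
    region = NA_character_, epoch_type = epoch_type, value = plv_vals,
    stringsAsFactors = FALSE))

  wstarts <- attr(plv_arr, "window_starts")
  graphs <- lapply(seq_len(nw), function(w)
    threshold_graph(plv_arr[, , w], percentile,
                    labels = rec$channel_meta$channel,
                    window = c(wstarts[w], wstarts[w] + win_length)))
  adm <- vapply(graphs, is_admissible_connectivity, logical(1))
  kept <- suppressWarnings(filter_outlier_graphs(graphs[adm]))
  n_outlier <- attr(kept, "n_removed")
  stats <- if (length(kept)) ensemble_stats(kept) else NULL
  if (!is.null(stats)) {
    stats$group <- meta$group
    stats$condition <- meta$condition
    stats$epoch_type <- epoch_type
    measures <- rbind(measures,
      data.frame(measure = "C", group = meta$group,
                 condition = meta$condition, region = NA_character_,
                 epoch_type = epoch_type, value = stats$C,
                 stringsAsFactors = FALSE),
      data.frame(measure = "L", group = meta$group,
                 condition = meta$condition, region = NA_character_,
                 epoch_type = epoch_type, value = stats$L,
                 stringsAsFactors = FALSE))
  }
  manifest <- data.frame(
    group = meta$group, condition = meta$condition,
    units_total = length(rec$spike_trains),
    units_accepted = if (is.null(qc)) 0L else
      sum(qc$decision == "accepted"),
    units_rejected_rate = if (is.null(qc)) 0L else
      sum(qc$decision == "rejected_rate"),
    units_rejected_isi = if (is.null(qc)) 0L else
      sum(qc$decision == "rejected_isi"),
    windows = nw, graphs_inadmissible = sum(!adm),
    graphs_outlier_removed = n_outlier,
    graphs_kept = length(kept), stringsAsFactors = FALSE)
  list(measures = measures, graph_stats = stats, qc = qc,
       manifest = manifest)
}

#' The default comparison grid
#'
#' The families mirror the study's simultaneous contrasts: tactile-evoked
#' versus rest firing rate per group and region; REAC versus no-REAC firing
#' rate per group and region (spontaneous and tactile families); group
#' differences in resting firing rate and PLV; tactile and REAC effects on
#' PLV; and group/condition contrasts of the network statistics C and L.
#'
#' @return list of [comparison_spec()] objects.
#' @export
default_comparison_grid <- function() {
  grid <- list()
  cell <- function(group, condition, region = NA, epoch_type = NA)
    list(group = group, condition = condition, region = region,
         epoch_type = epoch_type)
  for (g in c("CR", "CCI")) for (r in c("VPL", "S1")) {
    grid <- c(grid, list(
      comparison_spec("FR", cell(g, "rest", r, "rest"),
                      cell(g, "tactile", r, "evoked"), "FR_tactile_vs_rest",
                      sprintf("FR %s %s tactile vs rest", g, r)),
      comparison_spec("FR", cell(g, "rest", r, "rest"),
                      cell(g, "reac_rest", r, "rest"), "FR_reac_rest",
                      sprintf("FR %s %s REAC rest vs rest", g, r)),
      comparison_spec("FR", cell(g, "tactile", r, "evoked"),
                      cell(g, "reac_tactile", r, "evoked"),
                      "FR_reac_tactile",
                      sprintf("FR %s %s REAC tactile vs tactile", g, r))))
  }
  for (r in c("VPL", "S1"))
    grid <- c(grid, list(
      comparison_spec("FR", cell("CR", "rest", r, "rest"),
                      cell("CCI", "rest", r, "rest"), "FR_group_rest",
                      sprintf("FR rest CR vs CCI %s", r))))
  grid <- c(grid, list(
    comparison_spec("PLV", cell("CR", "rest", NA, "rest"),
                    cell("CCI", "rest", NA, "rest"), "PLV_group_rest",
                    "PLV rest CR vs CCI")))
  for (g in c("CR", "CCI"))
    grid <- c(grid, list(
      comparison_spec("PLV", cell(g, "rest", NA, "rest"),
                      cell(g, "tactile", NA, "evoked"),
                      "PLV_tactile_vs_rest",
                      sprintf("PLV %s tactile vs rest", g)),
      comparison_spec("PLV", cell(g, "rest", NA, "rest"),
                      cell(g, "reac_rest", NA, "rest"), "PLV_reac_rest",
                      sprintf("PLV %s REAC rest vs rest", g))))
  for (m in c("C", "L")) {
    grid <- c(grid, list(
      comparison_spec(m, cell("CR", "rest", NA, "rest"),
                      cell("CCI", "rest", NA, "rest"), "NET_group_rest",
                      sprintf("%s rest CR vs CCI", m))))
    for (g in c("CR", "CCI"))
      grid <- c(grid, list(
        comparison_spec(m, cell(g, "rest", NA, "rest"),
                        cell(g, "tactile", NA, "evoked"), "NET_tactile",
                        sprintf("%s %s tactile vs rest", g, m))))
  }
  grid
}

#' Run the full synthetic study end to end
#'
#' For each group a base configuration is drawn (shared across that group's
#' conditions, as the same animals are recorded under every condition);
#' each group x condition cell is simulated with its preset, analysed with
#' [analyze_recording()], and the pooled measures are compared with
#' [run_comparison_grid()]. Re-running with the same seed reproduces every
#' numeric output bit-exactly.
#'
#' @param duration session length, seconds.
#' @param seed integer master seed.
#' @param groups,conditions cells to simulate.
#' @param win_length,overlap,band,percentile analysis parameters.
#' @param config_fn function `(duration, seed, ...)` building the per-group
#'   base [synth_config()]; default [thalamocortical_config()].
#' @param grid comparison grid; default [default_comparison_grid()].
#' @param out_dir optional directory to write CSV/JSON outputs into.
#' @return object of class `plvnet_run`: list with `measures`,
#'   `comparisons`, `graph_stats`, `tables` (the two 2 x 4 network-statistic
#'   tables), `percent_changes` (REAC firing-rate percent changes),
#'   `manifest`, `qc`, `seed`.
#' @export
run_full <- function(duration = 600, seed = 1L,
                     groups = c("CR", "CCI"),
                     conditions = c("rest", "tactile", "reac_rest",
                                    "reac_tactile"),
                     win_length = 0.5, overlap = 0.5, band = c(1, 120),
                     percentile = 75, config_fn = thalamocortical_config,
                     grid = default_comparison_grid(), out_dir = NULL) {
  measures <- list(); stats <- list(); manifest <- list(); qc <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    cfg <- config_fn(duration = duration, seed = derive_seed(seed, 200 + gi))
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      sim <- synth_recording(cfg, g, cond,
                             seed = derive_seed(seed, 300 + 10 * gi + ci))
      an <- analyze_recording(sim$recording, win_length, overlap, band,
                              percentile)
      key <- paste(g, cond, sep = "/")
      measures[[key]] <- an$measures
      if (!is.null(an$graph_stats)) stats[[key]] <- an$graph_stats
      manifest[[key]] <- an$manifest
      qc[[key]] <- cbind(group = g, condition = cond, an$qc)
    }
  }
  measures <- do.call(rbind, c(measures, make.row.names = FALSE))
  stats <- do.call(rbind, c(stats, make.row.names = FALSE))
  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  qc <- do.call(rbind, c(qc, make.row.names = FALSE))
  comparisons <- run_comparison_grid(measures, grid)
  tables <- report_tables(stats)
  pc <- reac_percent_changes(measures)
  run <- structure(list(measures = measures, comparisons = comparisons,
                        graph_stats = stats, tables = tables,
                        percent_changes = pc, manifest = manifest, qc = qc,
                        seed = seed),
                   class = "plvnet_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

cell_mean <- function(measures, measure, group, condition, epoch_type) {
  v <- measures$value[measures$measure == measure &
                        measures$group == group &
                        measures$condition == condition &
                        measures$epoch_type == epoch_type]
  mean(v)
}

#' REAC firing-rate percent changes realised in a run
#'
#' Percent change of the mean firing rate under REAC relative to the
#' matching no-REAC cell, per group, for the spontaneous and tactile
#' regimes (the four headline rate contrasts of the design).
#'
#' @param measures the long measures frame of a run.
#' @return data.frame: `group`, `regime`, `percent_change`.
#' @export
reac_percent_changes <- function(measures) {
  rows <- list()
  for (g in intersect(c("CR", "CCI"), unique(measures$group))) {
    if (all(c("rest", "reac_rest") %in% measures$condition))
      rows <- c(rows, list(data.frame(
        group = g, regime = "rest",
        percent_change = percent_change(
          cell_mean(measures, "FR", g, "rest", "rest"),
          cell_mean(measures, "FR", g, "reac_rest", "rest")))))
    if (all(c("tactile", "reac_tactile") %in% measures$condition))
      rows <- c(rows, list(data.frame(
        group = g, regime = "tactile",
        percent_change = percent_change(
          cell_mean(measures, "FR", g, "tactile", "evoked"),
          cell_mean(measures, "FR", g, "reac_tactile", "evoked")))))
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Network-statistic summary tables
#'
#' Mean and SD of the clustering coefficient C and characteristic path
#' length L per group, for resting and tactile-evoked graphs, in two
#' blocks: without and with REAC. Missing cells are left `NA`.
#'
#' @param stats combined per-graph statistics with `group`, `condition`,
#'   `C`, `L` columns.
#' @return data.frame, one row per block x group.
#' @export
report_tables <- function(stats) {
  blocks <- list(no_reac = c(resting = "rest", evoked = "tactile"),
                 reac = c(resting = "reac_rest", evoked = "reac_tactile"))
  rows <- list()
  for (b in names(blocks)) for (g in c("CR", "CCI")) {
    row <- list(block = b, group = g)
    for (e in names(blocks[[b]])) {
      sub <- stats[stats$group == g & stats$condition == blocks[[b]][[e]], ]
      for (m in c("C", "L")) {
        v <- if (is.null(sub) || nrow(sub) == 0) NA_real_ else sub[[m]]
        row[[paste0(m, "_", e, "_mean")]] <- mean(v)
        row[[paste0(m, "_", e, "_sd")]] <- if (length(v) > 1) sd(v) else
          NA_real_
      }
    }
    rows <- c(rows, list(as.data.frame(row)))
  }
  do.call(rbind, rows)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)
  write.csv(run$graph_stats, file.path(out_dir, "graph_stats.csv"),
            row.names = FALSE)
  write.csv(run$tables, file.path(out_dir, "network_tables.csv"),
            row.names = FALSE)
  if (!is.null(run$percent_changes))
    write.csv(run$percent_changes,
              file.path(out_dir, "fr_percent_changes.csv"),
              row.names = FALSE)
  write.csv(run$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  write.csv(run$qc, file.path(out_dir, "unit_qc.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.plvnet_run <- function(x, ...) {
  cat(sprintf("<plvnet_run> seed %d: %d sessions, %d measure samples, %d comparisons\n",
              x$seed, nrow(x$manifest), nrow(x$measures),
              nrow(x$comparisons)))
  invisible(x)
}

#' Null run: identical presets, independent realisations
#'
#' Simulates two rest sessions from the *same* base configuration (same
#' oscillators, coupling and unit rates) with identity presets, differing
#' only in realisation noise, and compares them on firing rate (per
#' region), PLV, C and L. Under this null the two samples are exchangeable,
#' so corrected p-values should exceed 0.05 in the large majority of seeds.
#'
#' @param duration seconds per session.
#' @param seed integer master seed.
#' @param ... analysis parameters passed to [analyze_recording()].
#' @return comparison data.frame (family `"null"`).
#' @export
run_null <- function(duration = 120, seed = 1L, ...) {
  cfg <- thalamocortical_config(duration = duration,
                                seed = derive_seed(seed, 400))
  sims <- lapply(1:2, function(i)
    synth_recording(cfg, "CR", "rest", seed = derive_seed(seed, 410 + i)))
  ms <- lapply(1:2, function(i) {
    m <- analyze_recording(sims[[i]]$recording, ...)$measures
    m$group <- c("A", "B")[i]
    m
  })
  measures <- rbind(ms[[1]], ms[[2]])
  cell <- function(group, region = NA)
    list(group = group, condition = "rest", region = region,
         epoch_type = "rest")
  grid <- list(
    comparison_spec("FR", cell("A", "VPL"), cell("B", "VPL"), "null",
                    "null FR VPL"),
    comparison_spec("FR", cell("A", "S1"), cell("B", "S1"), "null",
                    "null FR S1"),
    comparison_spec("PLV", cell("A"), cell("B"), "null", "null PLV"),
    comparison_spec("C", cell("A"), cell("B"), "null", "null C"),
    comparison_spec("L", cell("A"), cell("B"), "null", "null L"))
  run_comparison_grid(measures, grid)
}
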