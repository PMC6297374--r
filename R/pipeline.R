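#' Per-synergy stability analysis of an activation matrix
#'
#' For each activation row: embedding delay from the first AMI minimum,
#' unified embedding dimension (default 6), short-term maximum Lyapunov
#' exponent over the 0-1 stride window, and Floquet summary over the 100
#' Poincare sections.
#'
#' @param C Synergies x T activation matrix (100 points per cycle).
#' @param unified_d Embedding dimension override (default 6); `NULL` for
#'   FNN-based selection per activation.
#' @param theiler_window,horizon Lyapunov controls (defaults 100 and 1000).
#' @param fm_policy Floquet summary policy (default `"mean"`).
#' @return Data frame with one row per synergy: `synergy`, `tau`, `d`,
#'   `lambda`, `lambda_r2`, `fm_mean`, `fm_max`, `lambda_units`.
#' @export
activation_stability <- function(C, unified_d = 6L, theiler_window = 100L,
                                 horizon = 1000L, fm_policy = "mean") {
  C <- as.matrix(C)
  do.call(rbind, lapply(seq_len(nrow(C)), function(i) {
    x <- C[i, ]
    emb <- select_embedding(x, unified_d = unified_d)
    ly <- lyapunov_exponent(x, emb$tau, emb$d, theiler_window, horizon)
    fm <- floquet_analysis(x, emb$tau, emb$d, policy = fm_policy)
    data.frame(synergy = i, tau = emb$tau, d = emb$d,
               lambda = ly$lambda, lambda_r2 = ly$r_squared,
               fm_mean = fm$mean, fm_max = fm$max,
               lambda_units = "nats/stride")
  }))
}

#' Pipeline configuration
#'
#' Collects every stage's parameters into one object; all effective values
#' are echoed into the run manifest.  Input is either a synthetic preset
#' (`preset = "gait"`, with `n_levels` jitter levels standing in for
#' walking-speed conditions) or a pair of EMG/event files.
#'
#' @param preset `"gait"` for synthetic input, or `NULL` with files.
#' @param emg_file,events_file,fs,events_unit File input (see
#'   [read_emg_recording()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; per-stage seeds derive from it.
#' @param n_levels Synthetic jitter levels standing in for speeds
#'   (default 3).
#' @param jitter_range Range of the phase-jitter sweep in % cycle
#'   (default `c(1, 2.5)`).
#' @param highpass,lowpass,drop_head,drop_tail,keep Preprocessing.
#' @param n_range,n_repeats,n_restarts,max_iter,tol NMF / selection.
#' @param global_threshold,muscle_threshold VAF selection thresholds.
#' @param unified_d,theiler_window,horizon,fm_policy Stability stage.
#' @param slow_band,fast_band Trend bands in km/h equivalents.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "gait", emg_file = NULL,
                            events_file = NULL, fs = 1000,
                            events_unit = "samples0",
                            out_dir = tempfile("synstab_run_"), seed = 1L,
                            n_levels = 3L, jitter_range = c(1, 2.5),
                            highpass = 40, lowpass = 10,
                            drop_head = 10L, drop_tail = 10L, keep = 30L,
                            n_range = 1:12, n_repeats = 10L, n_restarts = 3L,
                            max_iter = 500L, tol = 1e-5,
                            global_threshold = 90, muscle_threshold = 75,
                            unified_d = 6L, theiler_window = 100L,
                            horizon = 1000L, fm_policy = "mean",
                            slow_band = c(2, 5), fast_band = c(5, 8)) {
  structure(as.list(environment()), class = "pipeline_config")
}

.write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = !is.null(rownames(m)))
  path
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, synergies (cross-validated selection, shuffle
#' control, final factorization), embedding, Lyapunov, Floquet and trend
#' stages, writing CSV/JSON results plus a versioned run manifest
#' (parameters, seeds, per-file checksums).  Runs are deterministic given
#' an identical configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  outputs <- character(0)
  record <- function(stage, files) {
    stages[[stage]] <<- list(status = "completed", files = basename(files))
    outputs <<- c(outputs, files)
  }
  fail <- function(stage, msg) stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)

  # conditions: synthetic jitter levels stand in for walking speeds, or a
  # single recorded condition from files
  if (!is.null(config$preset) && config$preset == "gait") {
    jit <- seq(config$jitter_range[1L], config$jitter_range[2L],
               length.out = config$n_levels)
    speeds <- seq(config$slow_band[1L], config$fast_band[2L],
                  length.out = config$n_levels)
    conditions <- lapply(seq_len(config$n_levels), function(l) {
      cfg <- synth_config(phase_jitter_sd = jit[l],
                          seed = config$seed * 100L + l)
      sim <- simulate_gait_emg(cfg, raw = TRUE)
      list(label = sprintf("level%d", l), speed = speeds[l],
           recording = sim$recording, truth = sim)
    })
    sim_files <- vapply(conditions, function(cond) {
      f <- file.path(config$out_dir, paste0("simulated_", cond$label, ".csv"))
      .write_matrix_csv(cond$truth$M, f)
    }, character(1L))
    record("simulate", sim_files)
  } else {
    if (is.null(config$emg_file) || !file.exists(config$emg_file))
      fail("preprocess", paste("EMG file not found:", config$emg_file))
    if (is.null(config$events_file) || !file.exists(config$events_file))
      fail("preprocess", paste("events file not found:", config$events_file))
    rec <- read_emg_recording(config$emg_file, config$events_file,
                              config$fs, config$events_unit)
    conditions <- list(list(label = "trial1", speed = NA_real_,
                            recording = rec, truth = NULL))
  }

  stab_rows <- list()
  for (cond in conditions) {
    lab <- cond$label
    mat <- tryCatch(
      preprocess_emg(cond$recording, highpass = config$highpass,
                     lowpass = config$lowpass, drop_head = config$drop_head,
                     drop_tail = config$drop_tail, keep = config$keep),
      error = function(e) fail("preprocess", conditionMessage(e)))
    pp_file <- file.path(config$out_dir, paste0("preprocessed_", lab, ".csv"))
    .write_matrix_csv(mat$values, pp_file)
    norm_file <- file.path(config$out_dir, paste0("normalization_", lab, ".json"))
    jsonlite::write_json(mat$normalization, norm_file, auto_unbox = TRUE,
                         digits = NA)
    record(paste0("preprocess_", lab), c(pp_file, norm_file))

    vt <- cross_validated_vaf(mat, n_range = config$n_range,
                              n_repeats = config$n_repeats,
                              seed = config$seed,
                              n_restarts = config$n_restarts,
                              max_iter = config$max_iter, tol = config$tol)
    n_sel <- select_num_synergies(vt, config$global_threshold,
                                  config$muscle_threshold)
    fit <- nmf(mat$values, n_sel, seed = config$seed,
               max_iter = config$max_iter, tol = config$tol,
               n_restarts = max(config$n_restarts, 5L))
    shuf <- shuffle_control(mat$values, seed = config$seed)
    vt_shuf <- cross_validated_vaf(shuf, n_range = n_sel,
                                   n_repeats = config$n_repeats,
                                   seed = config$seed,
                                   n_restarts = config$n_restarts,
                                   max_iter = config$max_iter, tol = config$tol)
    syn_files <- c(
      .write_matrix_csv(fit$W, file.path(config$out_dir, paste0("W_", lab, ".csv"))),
      .write_matrix_csv(fit$C, file.path(config$out_dir, paste0("C_", lab, ".csv"))),
      .write_matrix_csv(vt$summary, file.path(config$out_dir, paste0("vaf_", lab, ".csv"))))
    sel_file <- file.path(config$out_dir, paste0("selection_", lab, ".json"))
    jsonlite::write_json(list(n_synergies = n_sel,
                              global_vaf = fit$vaf_global,
                              shuffled_global_vaf_mean =
                                vt_shuf$summary$global_mean[1L]),
                         sel_file, auto_unbox = TRUE, digits = NA)
    record(paste0("synergies_", lab), c(syn_files, sel_file))

    stab <- activation_stability(fit$C, unified_d = config$unified_d,
                                 theiler_window = config$theiler_window,
                                 horizon = config$horizon,
                                 fm_policy = config$fm_policy)
    emb_file <- file.path(config$out_dir, paste0("embedding_", lab, ".json"))
    jsonlite::write_json(stab[, c("synergy", "tau", "d")], emb_file,
                         digits = NA)
    record(paste0("embedding_", lab), emb_file)
    stab$trial <- lab
    stab$speed <- cond$speed
    stab_file <- file.path(config$out_dir, paste0("stability_", lab, ".csv"))
    .write_matrix_csv(stab, stab_file)
    record(paste0("stability_", lab), stab_file)
    stab_rows[[lab]] <- stab
  }

  all_stab <- do.call(rbind, stab_rows)
  stab_all_file <- file.path(config$out_dir, "stability.csv")
  .write_matrix_csv(all_stab, stab_all_file)

  if (length(conditions) >= 2L) {
    trend_in <- data.frame(subject = 1L, synergy = all_stab$synergy,
                           speed = all_stab$speed, value = all_stab$lambda)
    trends <- increasing_rates(trend_in, config$slow_band, config$fast_band)
    trend_file <- file.path(config$out_dir, "trends.csv")
    .write_matrix_csv(as.data.frame(trends), trend_file)
    record("trends", c(stab_all_file, trend_file))
  } else {
    stages[["trends"]] <- list(status = "skipped (single condition)",
                               files = basename(stab_all_file))
    outputs <- c(outputs, stab_all_file)
  }

  # collapse per-condition stage entries into the six pipeline stages
  stage_names <- c("simulate", "preprocess", "synergies", "embedding",
                   "stability", "trends")
  manifest <- list(
    package = "synstab",
    version = as.character(utils::packageVersion("synstab")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    stages = lapply(stage_names, function(s) {
      hit <- stages[grepl(paste0("^", s), names(stages))]
      if (length(hit) == 0L) return(list(stage = s, status = "not run"))
      list(stage = s,
           status = unique(vapply(hit, `[[`, character(1L), "status")),
           files = unlist(lapply(hit, `[[`, "files"), use.names = FALSE))
    }),
    checksums = as.list(tools::md5sum(sort(outputs))))
  names(manifest$checksums) <- basename(sort(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
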