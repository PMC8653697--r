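# Seeded fixture generation: the full simulated condition grid plus two
# animal-like presets that stand in for real recordings when exercising the
# projection protocol end to end.

#' Generate a directory of simulated ECG and RR fixtures
#'
#' Writes, for every combination of the four conditions, four
#' tachogram-noise levels and four LF/HF ratios, an RR file
#' (`rr_<cond>_n<noise>_r<lfhf>.txt`) and an ECG CSV
#' (`ecg_<cond>_n<noise>_r<lfhf>.csv`), plus two synthetic presets:
#' `pd-like` (bradycardic, low-variability, AF morphology, emulating the
#' depressed heart rate variability of a parkinsonian rat) and `sham-like`
#' (standard rat settings, DET morphology).  A `manifest.json` records the
#' configuration, per-file seeds and file names.  All output derives
#' deterministically from `seed`, so the suite is byte-reproducible.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param conditions,noise_levels,lf_hf_ratios Grid axes.
#' @param n_beats Beats per grid recording.
#' @param fs Sampling rate of the rendered ECGs (Hz).
#' @param mean_hr,sd_hr Grid heart-rate settings (bpm).
#' @param overwrite Refuse to write into an existing directory unless
#'   `TRUE`.
#' @return The manifest as a list, invisibly.
#' @export
make_fixture_suite <- function(dir, seed = 1,
                               conditions = c("DET", "AF", "LQT", "NSE"),
                               noise_levels = c(0, 0.33, 0.66, 0.99),
                               lf_hf_ratios = c(0, 0.5, 1, 1.5),
                               n_beats = 60, fs = 500,
                               mean_hr = 350, sd_hr = 50,
                               overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite) {
    stop_input("directory '%s' exists; use overwrite = TRUE", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(condition = conditions, noise = noise_levels,
                      lf_hf = lf_hf_ratios, stringsAsFactors = FALSE)
  files <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    s <- child_seed(seed, i)
    tac <- build_tachogram(tachogram_spec(
      mean_hr = mean_hr, sd_hr = sd_hr, lf_hf_ratio = g$lf_hf,
      n_beats = n_beats, seed = s))
    tac <- add_tachogram_noise(tac, g$noise, seed = child_seed(seed, 1000L + i))
    ecg <- suppressWarnings(synthesize_ecg(
      condition_params(g$condition), tac, fs = fs,
      seed = child_seed(seed, 2000L + i)))
    stem <- sprintf("%s_n%02.0f_r%g", tolower(g$condition), 100 * g$noise,
                    g$lf_hf)
    rr_file <- sprintf("rr_%s.txt", stem)
    ecg_file <- sprintf("ecg_%s.csv", stem)
    write_rr(tac, file.path(dir, rr_file))
    write_ecg_csv(ecg, file.path(dir, ecg_file))
    files[[i]] <- list(condition = g$condition, noise = g$noise,
                       lf_hf = g$lf_hf, seed = s, rr = rr_file,
                       ecg = ecg_file)
  }
  presets <- list(
    list(name = "pd-like", mean_hr = 280, sd_hr = 15, condition = "AF",
         lf_hf = 1.5),
    list(name = "sham-like", mean_hr = 350, sd_hr = 50, condition = "DET",
         lf_hf = 0.5)
  )
  preset_entries <- list()
  for (p in seq_along(presets)) {
    ps <- presets[[p]]
    s <- child_seed(seed, 9000L + p)
    tac <- build_tachogram(tachogram_spec(
      mean_hr = ps$mean_hr, sd_hr = ps$sd_hr, lf_hf_ratio = ps$lf_hf,
      n_beats = n_beats, seed = s))
    ecg <- suppressWarnings(synthesize_ecg(
      condition_params(ps$condition), tac, fs = fs,
      seed = child_seed(seed, 9100L + p)))
    rr_file <- sprintf("rr_%s.txt", ps$name)
    ecg_file <- sprintf("ecg_%s.csv", ps$name)
    write_rr(tac, file.path(dir, rr_file))
    write_ecg_csv(ecg, file.path(dir, ecg_file))
    preset_entries[[p]] <- c(ps, list(seed = s, rr = rr_file,
                                      ecg = ecg_file))
  }
  manifest <- list(
    seed = seed,
    config = list(conditions = conditions, noise_levels = noise_levels,
                  lf_hf_ratios = lf_hf_ratios, n_beats = n_beats, fs = fs,
                  mean_hr = mean_hr, sd_hr = sd_hr),
    n_grid_recordings = nrow(grid),
    n_presets = length(presets),
    grid = files,
    presets = preset_entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
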