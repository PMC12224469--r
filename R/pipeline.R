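#' Study-default configuration snapshot
#'
#' All analysis defaults in one place: the local-likelihood window,
#' revision step and Laguerre orders of the point-process model, the
#' fMRI acquisition grid, the PPG sampling rate, and the cluster
#' inference settings.
#'
#' @return Named list of defaults.
#' @export
saipai_defaults <- function() {
  list(W = 70, step = 0.005, P_symp = 2, P_parasymp = 9, alpha = 0.2,
       tr = 0.72, n_vols = 1200L, fs = 400,
       cluster_threshold = 2.3, alpha_level = 0.05)
}

#' End-to-end synthetic pipeline: PPG to central autonomic network maps
#'
#' Runs the complete analysis chain on a cohort of synthetic subjects:
#' pulse-waveform beat detection, artifact correction, sliding-window
#' point-process fit, SAI/PAI computation, resampling to the fMRI volume
#' grid with double-gamma HRF convolution, run-level GLMs (two runs per
#' subject), within-subject fixed-effects combination, group
#' mixed-effects analysis, and sign-flip cluster correction of the
#' positive-SAI and negative-PAI contrasts.  BOLD data are synthesized
#' with a planted active region positively coupled to the sympathetic
#' arousal epoch (and therefore negatively to the parasympathetic
#' index), so detection can be scored against ground truth by Dice
#' overlap.
#'
#' @param n_subjects Cohort size; default 6.
#' @param seed Base RNG seed; subject s, run r uses
#'   `seed + 97 * s + 11 * r`.
#' @param duration Recording length per run (s); default 950 (the fit warm-up consumes one window length W before the first usable index sample, and 1200 volumes need 864 s of coverage).
#' @param n_vols fMRI volumes per run; default 1200 (the study's
#'   acquisition length).
#' @param tr Repetition time (s); default 0.72.
#' @param dims BOLD grid; default `c(20, 20, 10)`.
#' @param effect Planted BOLD effect amplitude (per unit standardized
#'   regressor, in noise-SD units); default 0.35.
#' @param step Fit revision step (s); default 0.005.
#' @param n_perm Sign-flip permutations; default 500.
#' @param scenario_name Scenario preset used for every run; default
#'   `"arousal"`.
#' @param from_ppg Run beat detection on synthesized PPG (default
#'   `TRUE`); `FALSE` starts from the true event series (faster).
#' @param verbose Print progress.
#' @return List with `clusters_sai_pos`, `clusters_pai_neg`
#'   ([cluster_correct()] tables), `dice_sai`, `dice_pai` (Dice overlap
#'   of the largest significant cluster with the planted region),
#'   `group_sai`, `group_pai` (`level_result`s), `truth_voxels`, and
#'   `config`.
#' @export
run_pipeline <- function(n_subjects = 6, seed = 1, duration = 950,
                         n_vols = 1200, tr = 0.72, dims = c(20, 20, 10),
                         effect = 0.35, step = 0.005, n_perm = 500,
                         scenario_name = "arousal", from_ppg = TRUE,
                         verbose = FALSE) {
  active <- array(FALSE, dims)
  cx <- pmax(1, round(dims / 2) - 2)
  active[cx[1]:(cx[1] + 4), cx[2]:(cx[2] + 4), cx[3]:(cx[3] + 3)] <- TRUE
  truth_voxels <- which(active)

  subj_sai <- vector("list", n_subjects)
  subj_pai <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    runs_sai <- runs_pai <- vector("list", 2L)
    for (r in 1:2) {
      run_seed <- seed + 97L * s + 11L * r
      sc <- scenario(scenario_name, seed = run_seed, duration = duration,
                     ppg = from_ppg)
      ev <- if (from_ppg) {
        correct_artifacts(detect_beats(sc$ppg, fs = attr(sc$ppg, "fs")))
      } else sc$events
      fit <- pphrv(ev, step = step)
      idx <- index_series(fit)
      reg_sai <- convolve_regressor(resample_at_volumes(
        idx, "sai", tr = tr, n_vols = n_vols))
      reg_pai <- convolve_regressor(resample_at_volumes(
        idx, "pai", tr = tr, n_vols = n_vols))
      # planted coupling follows the true arousal epoch, not the estimate
      boxcar <- epoch_regressor(sc$epoch, tr = tr, n_vols = n_vols,
                                offset = idx$time[which(idx$converged)[1]])
      set.seed(run_seed + 5000L)
      bold <- synth_bold(boxcar, dims = dims, active_mask = active,
                         effect = effect)
      runs_sai[[r]] <- first_level(bold, reg_sai)
      runs_pai[[r]] <- first_level(bold, reg_pai)
      if (verbose)
        message(sprintf("subject %d run %d: %d beats, %d converged states",
                        s, r, length(ev$u), sum(fit$converged)))
    }
    subj_sai[[s]] <- second_level_fixed(runs_sai[[1]], runs_sai[[2]])
    subj_pai[[s]] <- second_level_fixed(runs_pai[[1]], runs_pai[[2]])
  }
  grp_sai <- group_mixed_effects(subj_sai)
  grp_pai <- group_mixed_effects(subj_pai)
  ct_sai <- cluster_correct(grp_sai, n_perm = n_perm, seed = seed)
  ct_pai <- cluster_correct(grp_pai, n_perm = n_perm, seed = seed,
                            negative = TRUE)
  dice_of <- function(ct) {
    sig <- which(ct$significant)
    if (length(sig) == 0L) return(0)
    dice_overlap(attr(ct, "voxels")[[sig[1L]]], truth_voxels)
  }
  list(clusters_sai_pos = ct_sai, clusters_pai_neg = ct_pai,
       dice_sai = dice_of(ct_sai), dice_pai = dice_of(ct_pai),
       group_sai = grp_sai, group_pai = grp_pai,
       truth_voxels = truth_voxels,
       config = list(n_subjects = n_subjects, seed = seed,
                     duration = duration, n_vols = n_vols, tr = tr,
                     dims = dims, effect = effect, step = step,
                     n_perm = n_perm, scenario = scenario_name,
                     from_ppg = from_ppg))
}

#' HRF-convolved epoch (boxcar) regressor
#'
#' Convenience constructor of the "true" task-like regressor tracking a
#' modulated epoch; used to plant BOLD coupling in synthetic datasets.
#'
#' @param epoch `c(start, end)` of the epoch (s, in the recording
#'   clock).
#' @param tr,n_vols Volume grid.
#' @param offset Time of volume 0 in the recording clock (s).
#' @return A convolved, standardized [regressor_series()].
#' @export
epoch_regressor <- function(epoch, tr = 0.72, n_vols = 1200, offset = 0) {
  vt <- offset + (seq_len(n_vols) - 1L) * tr
  box <- as.numeric(vt >= epoch[1] & vt < epoch[2])
  convolve_regressor(regressor_series(box, tr = tr), standardize = TRUE)
}
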