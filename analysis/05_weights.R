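#!/usr/bin/env Rscript
# How the read-out distributes labor across neurons: normalized pooling
# weights for every well-decoded lag, their histogram, the modulation of
# each neuron's contribution across lags, and the cross-lag consistency of
# the weighting template.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

sweep <- if (file.exists("scratch/lag_sweep.rds")) {
  readRDS("scratch/lag_sweep.rds")
} else {
  ses <- study_session()
  lag_sweep(bin_rates(ses), lags = STUDY$lags, gamma = STUDY$gamma,
            n_sets = STUDY$n_sets, seed = STUDY$cv_seed)
}

pw <- pooling_weights(sweep, r2_threshold = 0.75)
cat("admissible lags (peri-saccadic R^2 > 0.75):",
    paste(colnames(pw), collapse = " "), "\n")

hist_w <- weight_histogram(pw)
modul <- weight_modulation(pw)
consist <- weight_consistency(pw)
cat(sprintf("weight modulation across lags: mean %.0f%% (SE %.0f%%)\n",
            modul$mean, modul$se))
cat(sprintf("cross-lag weight correlation: mean %.2f (SE %.2f)\n",
            consist$mean, consist$se))

out <- results_dir()
utils::write.csv(cbind(neuron = seq_len(nrow(pw)), as.data.frame(pw)),
                 file.path(out, "pooling_weights.csv"), row.names = FALSE)
utils::write.csv(
  data.frame(bin_mid = hist_w$mids, mean_count = hist_w$mean,
             sd_count = hist_w$sd),
  file.path(out, "weight_histogram.csv"), row.names = FALSE)
jsonlite::write_json(
  list(modulation_mean_pct = modul$mean, modulation_se_pct = modul$se,
       consistency_mean = consist$mean, consistency_se = consist$se,
       admissible_lags = as.numeric(colnames(pw))),
  file.path(out, "weight_summary.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", file.path(out, "weight_summary.json"), "\n")
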