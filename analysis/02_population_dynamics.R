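#!/usr/bin/env Rscript
# Direction-specific population dynamics: subtract the rightward from the
# downward trial-averaged time courses per neuron and summarize the
# population with PCA, with a neuron-resampling bootstrap for pointwise
# standard errors on the component time courses.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ses <- study_session()
tensor <- bin_rates(ses)
rm_all <- condition_average(tensor)
D <- differential_timecourses(rm_all)

pca <- bootstrap_pca(D, k = 3, n_boot = 200, seed = STUDY$cv_seed)
cat(sprintf("top-3 variance fractions: %.2f %.2f %.2f (sum %.2f)\n",
            pca$variance_fraction[1], pca$variance_fraction[2],
            pca$variance_fraction[3], sum(pca$variance_fraction[1:3])))

out <- results_dir()
tab <- data.frame(time = tensor$times, pca$components, pca$boot_se)
names(tab) <- c("time_ms", paste0("pc", 1:3), paste0("pc", 1:3, "_se"))
utils::write.csv(tab, file.path(out, "pca_components.csv"),
                 row.names = FALSE)
utils::write.csv(
  data.frame(component = seq_along(pca$variance_fraction),
             variance_fraction = pca$variance_fraction),
  file.path(out, "pca_variance_fractions.csv"), row.names = FALSE)
cat("wrote", file.path(out, "pca_components.csv"), "\n")
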