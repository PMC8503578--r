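#!/usr/bin/env Rscript
# Full single-session analysis of the shallow demo session - the synthetic
# analog of a patient example: ICA on the filtered 30 s ictal scalp epoch,
# automatic component screening (outlier electrodes, dipolarity), wavelet
# coherence of the selected component against every bipolar SEEG pair with
# the calibrated thresholds, outlier-pair detection, and the spatial
# profile. Writes a full report bundle under results/session_shallow/.

suppressMessages(library(seizcoh))

res <- run_pipeline(list(
  simulation = list(eccentricity = 0.85, seed = 11, amplitude = 100),
  ica_seed = 7, n_surrogates = 200L, surrogate_seed = 42,
  out_dir = "results/session_shallow"))

message(sprintf("retained candidates: %s; selected component %d (GOF %.1f%%)",
                paste(res$candidates, collapse = ", "), res$selected,
                res$screens$gof[res$selected]))
message(sprintf("dipole at (%.1f, %.1f, %.1f) mm; d_SOZ = %.1f mm",
                res$dipole$position[1], res$dipole$position[2],
                res$dipole$position[3], res$spatial$d_soz))
message(sprintf("SOZ pair %s: SNA = %.3f; outlier pairs: %s",
                res$spatial$soz_pair, res$spatial$sna_soz,
                paste(res$outliers$selected_pairs, collapse = ", ")))
message(sprintf("coherence vs distance: r = %.2f, rho = %.2f",
                res$spatial$correlations$pearson_r,
                res$spatial$correlations$spearman_rho))
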