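#!/usr/bin/env Rscript
# Generate the two reference synthetic sessions used throughout the
# analysis: a shallow (0.85 R) and a deep (0.45 R) ictal generator, each a
# 30 mm cortical patch emitting low-voltage fast activity at 60 Hz over a
# 1/f background, recorded by two independently clocked amplifiers with an
# imposed inter-stream lag and clock drift. Writes one EDF per stream plus
# sensor coordinates (TSV) and the ground truth (JSON) under
# results/sessions/.

suppressMessages(library(seizcoh))
out <- "results/sessions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (cfg in list(list(name = "shallow", ecc = 0.85, seed = 11),
                 list(name = "deep", ecc = 0.45, seed = 11))) {
  demo <- make_demo_session(eccentricity = cfg$ecc, seed = cfg$seed,
                            imposed_lag = 1234.25, clock_drift_ppm = 100)
  paths <- write_session(demo$session, out, demo$sensors, stem = cfg$name)
  tr <- demo$session$truth
  message(sprintf(
    "%s: source at eccentricity %.2f (|r| = %.1f mm), SOZ contacts %s, SOZ pair %s",
    cfg$name, cfg$ecc, sqrt(sum(tr$source$position^2)),
    paste(tr$soz_labels, collapse = "+"), tr$soz_pair))
  message("  files: ", paste(basename(paths), collapse = ", "))
}
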