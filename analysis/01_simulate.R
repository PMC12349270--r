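#!/usr/bin/env Rscript
# Stage 1: simulate the default data-collection protocol (8 participants x
# 18 handling tasks x 6 sensor positions, 15 s at 100 Hz) and write the
# session to disk. Large per-recording CSVs go under scratch/ (not a
# deliverable); the bookkeeping summary goes under results/.

suppressMessages(library(sbsdetect))

seed <- 1L
out_dir <- "scratch/session"
dir.create("results", showWarnings = FALSE)

message("Simulating the default protocol (seed ", seed, ") ...")
session <- simulate_session(default_protocol(), motion_params(), seed = seed,
                            dir = out_dir)
counts <- session_counts(session)
message(sprintf(
  "Performed %d tasks (%d aggressive, %d non-aggressive); %d recordings.",
  counts$n_tasks, counts$n_aggressive, counts$n_non_aggressive,
  counts$n_recordings))

jsonlite::write_json(
  c(list(seed = seed, manifest = attr(session, "manifest")), counts),
  "results/01_session_counts.json", auto_unbox = TRUE, pretty = TRUE)
message("Session written to ", out_dir,
        "; counts to results/01_session_counts.json")
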