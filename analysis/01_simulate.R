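#!/usr/bin/env Rscript
# Generate the synthetic study material: a rendered single-worm escape
# recording (bright-field stack + stimulus log + ground truth) and the
# cohort of scripted locomotion schedules used by the phenotyping analysis.

suppressMessages(library(wormescape))
out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# one fully rendered escape recording (stimulus at t = 6 s, 15 Hz)
sch <- escape_schedule(pre_s = 6, rev_s = 3, turn_s = 1.5, post_s = 9.5,
                       frame_rate = 15, seed = 101L)
write_schedule(sch, file.path(out, "escape_schedule.yaml"))
tr <- script_stimuli(generate_track(sch), 6)
rec <- render_frames(tr, render_optics(img_px = c(128, 128)))
write_recording(rec, file.path(out, "escape_recording"))
cat(sprintf("rendered escape recording: %d frames at %g Hz, %d stimuli, %d frames flagged out-of-view\n",
            length(rec$stack), rec$frame_rate, nrow(rec$stimuli),
            length(rec$flagged_frames)))
print(table(tr$frames$state))

# cohort schedules for the phenotyping analysis (ground truth only;
# regenerated deterministically from their seeds by 03_phenotype.R)
seeds <- 2001:2020
for (s in seeds)
  write_schedule(random_schedule(duration_s = 120, seed = s),
                 file.path(out, sprintf("cohort_schedule_%d.yaml", s)))
cat(sprintf("wrote %d cohort schedules (120 s each, escape motif at 60 s)\n",
            length(seeds)))
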