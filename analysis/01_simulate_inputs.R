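#!/usr/bin/env Rscript
# Stage 1 — generate every input the downstream stages consume, with known
# ground truth: a precloacal vertebral series scaled to the giant-taxon
# measurement ranges, an extant-style comparative width/length dataset, a
# discrete character matrix evolved on a known tree, and stratigraphic
# ranges for its taxa. All seeded; outputs under results/inputs/.

suppressPackageStartupMessages(library(paleosnake))

seed <- 20240418L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# vertebral series: 22 precloacals, anterior quarter bearing hypapophyses,
# sizes spanning cL 37.5-62.7 mm / prW 62.4-111.4 mm
series <- sim_vertebral_series(n_vertebrae = 22, atv_fraction = 0.25,
                               noise_cv = 0, seed = seed)
write_measurements_csv(series, file.path(out, "vertebral_series.csv"))
message("wrote vertebral_series.csv: ", length(series), " vertebrae, prW ",
        paste(range(vapply(series, function(s) s$lengths_mm[["prW"]], 0)),
              collapse = "-"), " mm")

# comparative dataset: 21 taxa from the built-in log-log model + noise
comp <- sim_allometric(n = 21, slope = 1.0739, intercept = 1.9842,
                       noise_sd = 0.02, seed = seed + 1)
utils::write.csv(as.data.frame(comp)[c("taxon", "width_mm", "tbl_mm")],
                 file.path(out, "comparative_allometry.csv"),
                 row.names = FALSE)
message("wrote comparative_allometry.csv: n = ", nrow(comp))

# character matrix: 22 taxa (the ingroup-analysis scale) on a known tree
tree <- sim_tree(22, seed = seed + 2)
cm <- sim_matrix(tree, n_char = 120, k_states = 3, change_rate = 0.3,
                 missing_frac = 0.15, seed = seed + 3)
cm$outgroup <- tree$tip.label[1]
write_tnt(cm, file.path(out, "character_matrix.tnt"),
          title = sprintf("synthetic Mk matrix, seed %d", seed + 3))
write_nexus(cm, file.path(out, "character_matrix.nex"))
write_newick(attr(cm, "true_tree"), file.path(out, "true_tree.nwk"))
message("wrote character_matrix.{tnt,nex}: ", length(cm$taxa), " taxa x ",
        cm$n_char, " characters (+ generating tree)")

# stratigraphic ranges for the matrix taxa (synthetic, for calibration)
rg <- sim_strat_ranges(cm$taxa, fad_window_ma = c(35, 100),
                       mean_duration_myr = 5, seed = seed + 4)
utils::write.csv(as.data.frame(rg), file.path(out, "strat_ranges.csv"),
                 row.names = FALSE)
message("wrote strat_ranges.csv: FADs ",
        paste(round(range(rg$fad_ma), 1), collapse = "-"), " Ma")
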