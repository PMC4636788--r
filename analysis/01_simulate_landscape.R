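#!/usr/bin/env Rscript
## Generate the reference synthetic landscapes used by the downstream drivers:
## a three-condition (A/B/C) enhancer landscape with planted super-enhancer
## clusters, and a two-state (rest/stim) macrophage-style transition.
## Everything is written under results/sim/ in standard formats together with
## the ground-truth manifests.

library(secaller)

dir.create("results", showWarnings = FALSE)

cat("== Three-condition landscape ==\n")
cfg <- sim_config(seed = 20260901)
sim <- simulate_landscape(cfg, out_dir = "results/sim/landscape")
tr <- sim$truth$loci
cat(sprintf("genome: %d x %s bp; loci: %d CE + %d planted SE clusters\n",
            cfg$n_chrom, format(cfg$chrom_length, big.mark = ","),
            sum(tr$class == "CE"), sum(tr$class == "SE")))
cat("planted SE module plan:\n")
print(table(tr$module[tr$class == "SE"]))
cat(sprintf("genes: %d; eQTL LD regions: %d (planted in %.0f%% of SEs, %.0f%% of CEs)\n",
            length(sim$genes), length(sim$ld),
            100 * cfg$eqtl_rates[["se"]], 100 * cfg$eqtl_rates[["ce"]]))

cat("\n== Two-state transition (rest -> stim) ==\n")
cfg2 <- sim_config(seed = 20260902, n_ce = 500, n_se = 20, se_multiplier = 10)
sim2 <- simulate_state_transition(cfg2, induced_fraction = 0.5,
                                  repressed_fraction = 0.25,
                                  out_dir = "results/sim/transition")
cat("planted directions:\n")
print(table(sim2$truth$loci$direction, useNA = "no"))
cat("\nwritten: results/sim/landscape, results/sim/transition\n")
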