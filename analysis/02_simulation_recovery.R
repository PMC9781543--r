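#!/usr/bin/env Rscript
# Parameter recovery on synthetic central-nucleus tissue, at a reduced
# problem size for a quick interactive run (the acceptance script runs the
# full-volume versions): a CN-shaped region at one tenth of the study
# volume, populated at the printed densities, sampled with the study's IC
# design. Writes results/simulation_recovery.tsv.

suppressPackageStartupMessages(library(stereofract))
set.seed(20221109)

v_mm3 <- 136.2  # one tenth of the 1362 mm^3 Cavalieri reference volume
base_ax <- c(9000, 5500, 13740)
ax <- base_ax * (v_mm3 * 1e9 / (4 / 3 * pi * prod(base_ax)))^(1 / 3)
cn <- make_region("CN-small", list(type = "ellipsoid", semi_axes_um = ax))
ic <- ic_design()
shr <- shrinkage_model(1, 0.4, 0)
n_seeds <- 5

## optical fractionator at the printed density ----------------------------
mix <- c(nuclear = 0.71, cytoplasmic = 0.009, both = 0.14, none = 0.141)
n_true <- 3561 * um3_to_mm3(cn$true_volume_um3)
frac <- vapply(seq_len(n_seeds), function(i) {
  pts <- simulate_neuron_field(cn, 3561, mix, seed = 10 + i)
  st <- section_stack(cn, points = pts, cut_thickness_um = 50, shrinkage = shr)
  tot <- run_probe(st, ic, probe = "fractionator", seed = 40 + i)
  nuc <- run_probe(st, ic, item_filter = list(compartment = "nuclear"),
                   probe = "fractionator", seed = 40 + i)
  c(est = optical_fractionator(tot, ic)$value,
    nuclear_pct = 100 * sum(nuc$tally) / sum(tot$tally))
}, numeric(2))

## Spaceballs at the printed length density --------------------------------
sb <- sampling_design(30, mounted_thickness_um = 50, grid_um = c(2000, 2000))
l_true <- 1.69 * um3_to_mm3(cn$true_volume_um3)
lens <- vapply(seq_len(n_seeds), function(i) {
  fib <- simulate_fiber_field(cn, 1.69, 100, seed = 70 + i, dilate_um = 40)
  st <- section_stack(cn, fibers = fib, cut_thickness_um = 50)
  cnt <- run_probe(st, sb, probe = "spaceballs", seed = 100 + i)
  um_to_m(spaceballs_length(cnt, sb,
                            reference_volume_um3 = cn$true_volume_um3)$value)
}, numeric(1))

## Cavalieri volume and its CE ---------------------------------------------
stc <- section_stack(cn, cut_thickness_um = 50)
cav <- lapply(seq_len(n_seeds), function(i) run_cavalieri(stc, ic, seed = 130 + i))
cav_v <- vapply(cav, function(e) um3_to_mm3(e$value), numeric(1))
cav_ce <- vapply(cav, function(e) e$ce, numeric(1))

out <- data.frame(
  quantity = c("fractionator_total", "nuclear_only_pct",
               "spaceballs_length_m", "cavalieri_volume_mm3", "cavalieri_ce"),
  truth = c(n_true, 71, l_true, um3_to_mm3(cn$true_volume_um3), NA),
  mean = c(mean(frac["est", ]), mean(frac["nuclear_pct", ]), mean(lens),
           mean(cav_v), median(cav_ce)),
  sd = c(sd(frac["est", ]), sd(frac["nuclear_pct", ]), sd(lens),
         sd(cav_v), NA),
  n_seeds = n_seeds
)
dir.create("results", showWarnings = FALSE)
utils::write.table(out, "results/simulation_recovery.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(out, digits = 5)
message("every probe mean should sit within a few percent of its truth column")
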