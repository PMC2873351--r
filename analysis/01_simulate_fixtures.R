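#!/usr/bin/env Rscript
# Generate the study's synthetic inputs and write them to results/fixtures/:
# a futile-cycle network, an unknown-metabolite network, the deterministic
# acetate-fed core network with planted reaction classes, and a synthetic
# expression compendium (21 experiments) whose per-class dispersions follow
# the planted classes.  Everything downstream (02-04) reads these files
# back through the package's public readers.

suppressMessages(library(thermoflux))
seed <- 1L
out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (kind in c("futile_cycle", "unknown_metabolite", "mini_core")) {
  fx <- make_network_fixture(kind, seed = seed)
  write_network_fixture(fx, file.path(out, kind))
  cat(sprintf("%-18s m=%2d n=%2d -> %s\n", kind, nrow(fx$network$mets),
              nrow(fx$network$rxns), file.path(out, kind)))
}

core <- make_network_fixture("mini_core", seed = seed)
truth <- core$truth$expected_classes
genes <- lapply(stats::setNames(nm = names(truth)), function(r)
  genes_for_reaction(core$network, r))
efx <- make_expression_fixture(
  n_experiments = 21, dispersion_regulated = 3, dispersion_bottleneck = 1,
  cv_noise = 0.25, seed = seed + 1L,
  genes_regulated = unique(unlist(genes[names(truth)[truth != "bottleneck"]])),
  genes_bottleneck = unique(unlist(genes[names(truth)[truth == "bottleneck"]])))
write_expression(efx$expr, file.path(out, "expression"))
cat(sprintf("expression: %d genes x %d experiments -> %s\n",
            length(unique(efx$expr$data$gene)), length(efx$expr$experiments),
            file.path(out, "expression")))
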