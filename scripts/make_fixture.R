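#!/usr/bin/env Rscript
# Regenerates the committed 20-protein fixture proteome under
# inst/extdata/fixture/. Run from the repository root after changing the
# generator; the fixture is part of the test contract.
library(lcrsurvey)

cfg <- synth_config(n_proteomes = 1L, proteome_size_range = c(20L, 20L),
                    lcr_per_protein_rate = 1.2, seed = 101L)
sim <- simulate_proteomes(cfg)
write_simulation(sim, "inst/extdata/fixture")
# keep relative paths out of the committed manifest; tests build their own
file.remove("inst/extdata/fixture/manifest.tsv")
cat("fixture written:", nrow(sim$records), "proteins,",
    nrow(sim$truth), "planted LCRs\n")
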