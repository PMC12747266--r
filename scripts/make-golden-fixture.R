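#!/usr/bin/env Rscript
# Regenerates the committed golden fixture: a small synthetic activity table
# (dirty rows, duplicates, mixed units) used by the test suite. Run from the
# repository root after installing the package.

library(ic50net)

spec <- fixture_spec(n_molecules = 150, n_targets = 3,
                     target_size_ratios = c(3, 2, 1),
                     noise_sd = 0.3, dirty_fraction = 0.1,
                     dup_fraction = 0.05, seed = 2026)
tab <- generate_activity_table(spec)
stopifnot(nrow(tab) <= 200)
utils::write.csv(tab, "inst/extdata/golden_activities_synthetic.csv",
                 row.names = FALSE)
cat(sprintf("wrote %d rows\n", nrow(tab)))
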