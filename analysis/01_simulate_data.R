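#!/usr/bin/env Rscript
# Simulate the synthetic study inputs: a demo dataset (sequence families,
# annotations, stub profile flags, drug-target interactions) and the
# degree-fixture tables realizing the printed approved-drug network.

suppressMessages(library(dtprofiler))

seed <- 20160728L
demo_dir <- "results/data/demo"
fix_dir <- "results/data/degree_fixtures"

paths <- simulate_dataset(demo_dir, seed = seed)
message("demo dataset (seed ", seed, "):")
for (p in paths) message("  ", p)
targets <- read.delim(paths[["targets"]])
message("cohort sizes: ",
        paste(names(table(targets$phase)), table(targets$phase),
              sep = "=", collapse = ", "))

fix <- simulate_dataset(fix_dir, preset = "degree-fixtures")
net <- build_network(read.delim(fix[["drugs"]]), read.delim(fix[["targets"]]),
                     read.delim(fix[["interactions"]]))
message("degree-fixture network: ", nrow(net$drugs), " drugs, ",
        nrow(net$targets), " targets, ", nrow(net$interactions),
        " interactions")
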