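#!/usr/bin/env Rscript
# Build the directed penis-reach graph (edge i -> j when the gap between the
# two opercula is at most 1.82 x individual i's penis length) and count each
# individual's mating group size in both sexual roles.

suppressPackageStartupMessages(library(mgsalloc))

records <- read_individuals("results/individuals.csv")
cfg <- study_config()

graph <- build_mating_graph(records, cfg)
mgs <- compute_mgs(graph)
flags <- apply_inclusion_filter(records, mgs, cfg)

write_edge_list(graph, "results/edge_list.csv")
utils::write.csv(flags, "results/mgs.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("%d directed reach edges among %d individuals\n",
            nrow(graph$edges), nrow(records)))
cat(sprintf("  MGSm range %d-%d, MGSf range %d-%d\n",
            min(mgs$mgs_m), max(mgs$mgs_m), min(mgs$mgs_f), max(mgs$mgs_f)))
cat(sprintf("  excluded: %d isolated, %d with missing organs\n",
            sum(grepl("isolated", flags$exclusion_reason)),
            sum(grepl("missing_organ", flags$exclusion_reason))))
cat("wrote results/edge_list.csv and results/mgs.csv\n")
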