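#!/usr/bin/env Rscript
# Stage 3: graph descriptives of the estimated network.
#
# Binarizes the weighted network (any nonzero weight, either sign, is a
# connection) and reports connectedness, the clustering coefficient under
# all three conventions, the average shortest path length, and the degree
# distribution summary, as a JSON report.

suppressPackageStartupMessages(library(symptomnet))

network <- read_weight_matrix("results/network.csv")
desc <- network_descriptives(network)

cat(sprintf("nodes: %d  edges: %d  connected: %s\n",
            desc$nodes, desc$edges, desc$connected))
cat(sprintf("clustering: %.3f (avg local, isolates 0) / %.3f (avg local, deg>=2) / %.3f (transitivity)\n",
            desc$clustering[["average_local_zero"]],
            desc$clustering[["average_local_exclude"]],
            desc$clustering[["transitivity"]]))
cat(sprintf("average shortest path length: %s\n",
            ifelse(is.na(desc$aspl), "undefined (disconnected)",
                   sprintf("%.2f", desc$aspl))))
cat(sprintf("degree: min %d, mean %.1f, max %d\n",
            desc$degree[["min"]], desc$degree[["mean"]],
            desc$degree[["max"]]))

jsonlite::write_json(desc, "results/descriptives.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/descriptives.json\n")
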