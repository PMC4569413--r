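#!/usr/bin/env Rscript
# Stage 5: force-directed figure.
#
# Fruchterman-Reingold layout with |weight| as attraction (strongly and
# densely connected symptoms end up close), then the standard visual
# grammar: green positive / red negative edges, stroke width proportional
# to |weight|, node color by diagnosis, node label = within-diagnosis
# number.

suppressPackageStartupMessages(library(symptomnet))

catalog <- load_catalog("results/catalog.tsv")
network <- read_weight_matrix("results/network.csv")

layout <- fruchterman_reingold(network, seed = 20260905, iterations = 500)
for (ext in c("svg", "pdf")) {
  f <- file.path("results", paste0("network.", ext))
  render_network(network, catalog, layout, f)
  cat("wrote", f, "\n")
}
utils::write.csv(data.frame(symptom = rownames(layout$positions),
                            layout$positions),
                 "results/layout.csv", row.names = FALSE)
cat("wrote results/layout.csv\n")
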