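#!/usr/bin/env Rscript
# Stage 4: within/between-diagnosis connectivity table.
#
# Partitions the estimated edges by diagnosis block, computes realized vs
# potential connection counts and percentages (the published table's
# structure, including its n_dx x p "all other diagnoses" denominator), and
# writes both the formatted lower-triangular table and a tidy long format.

suppressPackageStartupMessages(library(symptomnet))

catalog <- load_catalog("results/catalog.tsv")
network <- read_weight_matrix("results/network.csv")
bs <- summarize_blocks(network, catalog)

within <- transform(bs$within, percent = round_half_up(percent, 1))
cat("within-diagnosis connectivity:\n")
print(within, row.names = FALSE)
cat(sprintf("\nsegregation: within %% exceeds the all-other %% for %d of %d diagnoses\n",
            sum(bs$within$percent > bs$all_other$percent),
            nrow(bs$within)))
cat("diagnosis partners (other diagnoses with >= 1 connecting edge):\n")
print(bs$diagnosis_partners)

format_table1(bs, "results/block_table.tsv")
long <- rbind(
  data.frame(dx1 = bs$within$diagnosis, dx2 = bs$within$diagnosis,
             bs$within[c("realized", "potential", "percent")]),
  bs$between[c("dx1", "dx2", "realized", "potential", "percent")])
utils::write.table(long, "results/block_table_long.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/block_table.tsv, results/block_table_long.tsv\n")
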