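#!/usr/bin/env Rscript
# Map the satellite probe monomers onto the simulated genome, summarise
# them as 500 kb / 100 kb sliding-window covered-fraction tracks, and
# screen the chromosome ends for the telomere motif.

library(centroscape)

out <- "results/tracks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta("results/sim/genome.fa")
probes <- read.table("results/sim/probes.tsv", header = TRUE, sep = "\t")

hits <- map_probes(genome, probes)
write_hits_tsv(hits, file.path(out, "probe_hits.tsv"))
cat("probe hits by role:\n")
print(table(hits$role))

for (role in c("centromeric", "pericentromeric")) {
  tr <- density_track(hits[hits$role == role, ], nchar(genome[[1]]),
                      window_size = 5e5, step = 1e5)
  attr(tr, "role") <- role
  write_bedgraph(tr, file.path(out, paste0(role, ".bedgraph")))
  cat(sprintf("%s: peak window density %.2f at %d kb\n", role,
              max(tr$value), tr$start[which.max(tr$value)] / 1000))
}

tel <- detect_telomeres(genome, probes$seq[probes$role == "telomeric"][1])
write.table(tel, file.path(out, "telomeres.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("telomeric ends: %d of %d\n", sum(tel$telomeric), nrow(tel)))
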