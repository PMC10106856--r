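#!/usr/bin/env Rscript
# Call centromere and pericentromere intervals from the probe density
# signal (threshold 0.1, runs >= 2 windows, gaps <= 2 windows merged,
# boundaries snapped to the outermost probe hits) and compare them with the
# planted truth.

library(centroscape)

out <- "results/regions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta("results/sim/genome.fa")
probes <- read.table("results/sim/probes.tsv", header = TRUE, sep = "\t")
raw <- read.table("results/tracks/probe_hits.tsv", header = TRUE, sep = "\t")
hits <- data.frame(target_id = raw$target, tstart = raw$tstart,
                   tend = raw$tend,
                   role = probes$role[match(raw$query, probes$id)],
                   stringsAsFactors = FALSE)

regions <- call_compartments(hits, nchar(genome[[1]]))
write_regions_bed(regions, file.path(out, "regions.bed"))
print(as.data.frame(regions))

truth <- read.table("results/sim/regions.bed", sep = "\t",
                    col.names = c("chrom", "start", "end", "role", "score"))
tc <- truth[truth$role == "centromere", ]
cc <- regions[regions$role == "centromere", ]
cat(sprintf("centromere boundary error: start %+d bp, end %+d bp\n",
            cc$start - tc$start, cc$end - tc$end))
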