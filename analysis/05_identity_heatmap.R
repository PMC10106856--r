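#!/usr/bin/env Rscript
# Pairwise sequence identity between all non-overlapping 10 kb bins of the
# called centromere, written as TSV (and PNG when a plotting backend is
# available), plus a block segmentation of the matrix.

library(centroscape)

out <- "results/identity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta("results/sim/genome.fa")
regions <- read.table("results/regions/regions.bed", sep = "\t",
                      col.names = c("chrom", "start", "end", "role",
                                    "score"))
cc <- regions[regions$role == "centromere", ][1, ]
cent_seq <- substr(genome[[cc$chrom]], cc$start + 1, cc$end)
cat(sprintf("centromere %s:%d-%d (%d kb)\n", cc$chrom, cc$start, cc$end,
            round((cc$end - cc$start) / 1000)))

im <- identity_matrix(cent_seq, bin_size = 1e4)
write_identity_tsv(im, file.path(out, "centromere_identity.tsv"))
blocks <- segment_blocks(im)
write.table(blocks, file.path(out, "centromere_blocks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("bins: %d; mean off-diagonal identity %.3f; %d block(s)\n",
            nrow(im$bins), mean(im$matrix[upper.tri(im$matrix)]),
            nrow(blocks)))
try(plot_identity_matrix(im, file.path(out, "centromere_identity.png")),
    silent = TRUE)
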