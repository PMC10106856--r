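#!/usr/bin/env Rscript
# Date every full-length LTR element from its 5'/3' LTR divergence
# (T = K / 2 mu, JC69-corrected, mu = 1.5e-8), classify young (<= 0.5 MYA)
# vs old, detect nested insertions, and contrast insertion ages between the
# called compartments -- the centromere-young / pericentromere-old pattern.

library(centroscape)

out <- "results/chronology"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta("results/sim/genome.fa")
elements <- read_ltr_annotations("results/sim/elements.gff3", genome)
regions_bed <- read.table("results/regions/regions.bed", sep = "\t",
                          col.names = c("chrom", "start", "end", "role",
                                        "score"))

elements <- estimate_age(elements, genome, mu = 1.5e-8, model = "JC69")
elements$compartment <- assign_compartments(elements, regions_bed)
write.table(elements, file.path(out, "elements_dated.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

nested <- detect_nested(elements)
write.table(nested, file.path(out, "nested_insertions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("nested insertion events: %d (%d age-consistent)\n",
            nrow(nested), sum(nested$consistent)))

comp <- composition_table(elements, by = "superfamily")
write.table(comp, file.path(out, "composition_superfamily.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(comp)

ages <- split(elements$age_mya[elements$reliable],
              elements$compartment[elements$reliable])
ct <- age_contrast(ages$centromere, ages$pericentromere)
cat(sprintf(paste0("centromere %.3f MYA (n=%d) vs pericentromere %.3f MYA",
                   " (n=%d): Welch t = %.2f, two-sided p = %.3g\n"),
            ct$mean_a, ct$n_a, ct$mean_b, ct$n_b, ct$t, ct$p))
cat(sprintf("young fraction: centromere %.2f, pericentromere %.2f\n",
            mean(ages$centromere <= 0.5), mean(ages$pericentromere <= 0.5)))
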