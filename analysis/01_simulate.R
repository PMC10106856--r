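#!/usr/bin/env Rscript
# Build the study genome: one 3 Mb chromosome with telomeres, gene-poor
# satellite-rich centromere (176 bp monomer), two pericentromeres (238 bp
# and 1022 bp monomers plus a hidden 630 bp repeat), and aged LTR elements
# planted per compartment (centromere young ~0.14 MYA, pericentromere old
# ~0.51 MYA, arms ~0.32 MYA).  Everything downstream reads these files.

library(centroscape)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1L)
sim <- simulate_chromosome(cfg)

write_genome_fasta(sim$seq, file.path(out, "genome.fa"))
write_truth(sim$truth, out)
write_ltr_gff3(sim$truth$elements, file.path(out, "elements.gff3"))

cat(sprintf("chromosome: %s, %d bp\n", names(sim$seq), nchar(sim$seq[[1]])))
cat(sprintf("planted elements: %d (%d nested pairs)\n",
            nrow(sim$truth$elements), nrow(sim$truth$nested_pairs)))
print(table(sim$truth$elements$compartment, sim$truth$elements$superfamily))
cat(sprintf("hidden repeat: %d bp, %d pericentromeric copies + %d embedded\n",
            nchar(sim$truth$hidden_seq),
            sum(sim$truth$hidden_copies$where == "pericentromere"),
            sum(sim$truth$hidden_copies$where == "element")))
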