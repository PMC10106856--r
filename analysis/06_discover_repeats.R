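#!/usr/bin/env Rscript
# The novel-pericentromeric-repeat filter: all-vs-all alignment of the
# pericentromeric elements, keep repeated units occurring in >= 50
# elements, keep those with > 1000 merged hits on the pericentromere
# sequences, drop anything similar to the known Peri-SR monomers.  Run on a
# discovery-profile genome (1200 planted copies of a 630 bp hidden unit,
# 60 element embeddings) and checked against the planted unit.

library(centroscape)

out <- "results/discovery"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_chromosome(discovery_config(seed = 2L))
el <- sim$truth$elements
peri_el <- el[el$compartment == "pericentromere", ]
el_seqs <- setNames(substring(sim$seq, peri_el$start + 1, peri_el$end),
                    peri_el$id)
rg <- sim$truth$regions
peri_rg <- rg[rg$role == "pericentromere", ]
peri_seqs <- setNames(substring(sim$seq, peri_rg$start + 1, peri_rg$end),
                      c("peri1", "peri2"))
known <- setNames(sim$truth$probes$seq[sim$truth$probes$role ==
                                       "pericentromeric"],
                  sim$truth$probes$id[sim$truth$probes$role ==
                                      "pericentromeric"])

cat(sprintf("self-clustering %d pericentromeric elements...\n",
            length(el_seqs)))
novel <- discover_repeats(el_seqs, peri_seqs, known,
                          min_self = 50L, min_peri_hits = 1000L)
write_candidates(novel, file.path(out, "novel_repeats"))
print(as.data.frame(novel[, c("unit_id", "length", "self_occurrences",
                              "peri_hits", "known_overlap")]))

if (nrow(novel) == 1) {
  h <- local_align(novel$seq[1], sim$truth$hidden_seq, min_identity = 0.8,
                   min_length = 100)
  cat(sprintf("planted unit: %d bp; recovered unit covers %.1f%% of it\n",
              nchar(sim$truth$hidden_seq),
              100 * max(h$aligned_columns) / nchar(sim$truth$hidden_seq)))
}
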