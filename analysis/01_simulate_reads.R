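#!/usr/bin/env Rscript
# Simulate amplicon sequencing libraries for the bundled synthetic reporter
# target: a 30% intended-edit / 5% cut-site-byproduct mixture with
# 0.1%/base sequencing error, one library per replicate seed.

library(peartools)

dir.create("results", showWarnings = FALSE)

spec <- read_target_spec(
  system.file("extdata", "example_target.json", package = "peartools"),
  system.file("extdata", "example_amplicon.fa", package = "peartools")
)
print(spec)

byproducts <- list(list(edit = edit_spec(
  "deletion", spec$cut_site,
  ref_allele = substr(spec$ref_seq, spec$cut_site + 1, spec$cut_site + 1)
), prop = 0.05))

for (seed in 1:3) {
  sim <- simulate_reads(spec, n_reads = 10000, frac_intended = 0.30,
                        byproducts = byproducts, per_base_error = 0.001,
                        seed = seed)
  fq <- file.path("results", sprintf("reads_rep%d.fastq", seed))
  tt <- file.path("results", sprintf("truth_rep%d.tsv", seed))
  write_fastq(sim$reads, fq)
  write.table(sim$reads[, c("id", "truth")], tt, sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("rep %d: %d reads -> %s (truth: %s)\n",
              seed, nrow(sim$reads), fq, tt))
  print(table(sim$reads$truth))
}
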