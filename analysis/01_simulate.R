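#!/usr/bin/env Rscript
# Step 1: generate the synthetic study system.
#
# Two 10 Mb chromosomes emulating the comparison setting: a contiguous,
# error-prone assembly A (1.06 errors/kb, half clustered in
# high-methylation / low-shotgun-depth windows) versus a fragmented but
# accurate assembly B broken at every repeat longer than the 20 kb
# consensus-read span (tandem arrays of 14/23 kb units, dispersed 48 kb
# duplications). Writes all fixtures plus the planted-event ledgers.

suppressMessages(library(duoasm))

seed <- as.integer(Sys.getenv("DUOASM_SEED", "1"))
outdir <- "results/fixtures"

cfg <- sim_config(seed = seed)
sim <- make_fixtures(cfg, outdir)

cat("Wrote fixtures to", outdir, "\n")
cat(sprintf("Truth genome: %d chromosomes x %s bp\n",
            cfg$n_chromosomes, format(cfg$chromosome_len_bp, big.mark = ",")))
cat(sprintf("Assembly B contigs: %d\n", length(sim$assembly_b)))
cat(sprintf("Planted structural events: %d (%s)\n",
            nrow(sim$planted_structural),
            paste(names(table(sim$planted_structural$call_kind)),
                  table(sim$planted_structural$call_kind), collapse = ", ")))
cat(sprintf("Planted errors: %d (%.3f per kb)\n", nrow(sim$planted_errors),
            nrow(sim$planted_errors) /
              (cfg$n_chromosomes * cfg$chromosome_len_bp) * 1000))
cat(sprintf("Heterozygous sites: %d; filter-failing records: %d\n",
            sum(sim$truth_vcf$genotype == "0/1"),
            sum(sim$truth_vcf$genotype == "1/1") - nrow(sim$planted_errors)))
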