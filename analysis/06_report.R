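#!/usr/bin/env Rscript
# Step 6: the full pipeline in one call, with the consolidated report and
# a scoring of every caller against the planted-event ledgers.

suppressMessages(library(duoasm))

fx <- "results/fixtures"
rc <- run_config(
  assembly_a = file.path(fx, "assembly_a.fasta"),
  assembly_b = file.path(fx, "assembly_b.fasta"),
  paf = file.path(fx, "b_vs_a.paf"),
  vcf = file.path(fx, "calls.vcf"),
  gff3 = file.path(fx, "genes_a.gff3"),
  self_paf = file.path(fx, "a_self.paf"),
  methylation = file.path(fx, "methylation.tsv"),
  depth_shotgun = file.path(fx, "depth_shotgun.tsv"),
  depth_consensus = file.path(fx, "depth_consensus.tsv"),
  centromere_consensus = file.path(fx, "centromere_consensus.fasta"))
rep <- run_compare(rc, outdir = "results/report")

ledger_s <- read.delim(file.path(fx, "ledger_structural.tsv"))
ledger_e <- read.delim(file.path(fx, "ledger_errors.tsv"))

ovf <- function(s1, e1, s2, e2)
  max(0, min(e1, e2) - max(s1, s2)) / max(e1 - s1, e2 - s2)
calls <- rep$tables$calls
hit <- vapply(seq_len(nrow(ledger_s)), function(i) {
  k <- if (ledger_s$expected_redundant[i]) "redundancy" else ledger_s$call_kind[i]
  cand <- calls[calls$call_kind == k & calls$target_id == ledger_s$contig[i], ]
  nrow(cand) > 0 && any(vapply(seq_len(nrow(cand)), function(j)
    ovf(cand$start[j], cand$end[j], ledger_s$start[i], ledger_s$end[i]) >= 0.9,
    logical(1)))
}, logical(1))

cat(readLines("results/report/report.txt"), sep = "\n")
cat(sprintf("\nStructural recall vs planted ledger: %d/%d\n",
            sum(hit), length(hit)))
cat(sprintf("Error set vs planted ledger: %d called / %d planted, exact match: %s\n",
            rep$errors$n_errors, nrow(ledger_e),
            identical(sort(paste(rep$tables$errors$contig, rep$tables$errors$pos)),
                      sort(paste(ledger_e$contig, ledger_e$pos)))))
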