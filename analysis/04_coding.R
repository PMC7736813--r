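#!/usr/bin/env Rscript
# Step 4: translation impact of assembly errors on annotated genes.
#
# Each error overlapping CDS is classified by comparing the translation of
# the error-bearing assembly against the corrected sequence: frameshift,
# stop-gain, stop-loss, missense or synonymous. Affected exons and genes
# are counted once, under both the missense-inclusive and the
# disruption-only criterion.

suppressMessages(library(duoasm))

fx <- "results/fixtures"
genome_a <- read_assembly_fasta(file.path(fx, "assembly_a.fasta"))
genes <- read_gff3(file.path(fx, "genes_a.gff3"))
errors <- read.delim("results/errors.tsv", stringsAsFactors = FALSE)

out <- count_affected(errors, genes, genome_a)
write.table(out$per_error, "results/coding_impact.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Impact tally over error x gene pairs:\n")
print(out$impact_tally)
cat(sprintf("Affected exons/genes (incl. missense): %d / %d\n",
            out$affected_exons, out$affected_genes))
cat(sprintf("Affected exons/genes (frameshift/stop only): %d / %d\n",
            out$affected_exons_strict, out$affected_genes_strict))
n_genes <- length(unique(genes$gene_id))
cat(sprintf("Annotated genes: %d; fraction affected: %.2f%%\n", n_genes,
            100 * out$affected_genes / n_genes))
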