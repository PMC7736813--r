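#!/usr/bin/env Rscript
# Step 5: telomeres, centromeres and T2T status for both assemblies.
#
# Telomere arrays are maximal tandem runs of the AAACCCT motif (or its
# reverse complement) near contig ends; centromeres are merged full-unit
# matches of the centromeric repeat consensus. A contig is T2T when it has
# a telomere at each end and no Ns.

suppressMessages(library(duoasm))

fx <- "results/fixtures"
cen_unit <- as.character(
  read_assembly_fasta(file.path(fx, "centromere_consensus.fasta"))[[1]])

assess_assembly <- function(path, label) {
  genome <- read_assembly_fasta(path)
  rows <- lapply(names(genome), function(nm) {
    tel <- find_telomere_arrays(genome[[nm]], contig = nm)
    cen <- find_centromere(genome[[nm]], cen_unit, contig = nm)
    v <- assess_t2t(genome[[nm]], tel, cen)
    data.frame(assembly = label, contig = nm,
               len = length(genome[[nm]]),
               n_telomeres = nrow(tel), n_centromeres = nrow(cen),
               is_t2t = v$is_t2t,
               reasons = paste(v$reasons, collapse = "; "))
  })
  do.call(rbind, rows)
}

tab <- rbind(assess_assembly(file.path(fx, "assembly_a.fasta"), "A"),
             assess_assembly(file.path(fx, "assembly_b.fasta"), "B"))
write.table(tab, "results/t2t.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("\nT2T contigs: %d of %d (A), %d of %d (B)\n",
            sum(tab$is_t2t[tab$assembly == "A"]), sum(tab$assembly == "A"),
            sum(tab$is_t2t[tab$assembly == "B"]), sum(tab$assembly == "B")))
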