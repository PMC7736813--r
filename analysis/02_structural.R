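#!/usr/bin/env Rscript
# Step 2: structural arbitration of assembly B against assembly A.
#
# Projects the B-onto-A alignments, calls uncovered gaps and contig
# overlaps, classifies overlaps as redundancies by the similarity >= 97%
# and depth (< 60 total, < 40 each) rule, splits gaps into losses vs.
# double-covered redundancies, annotates repeat context from A
# self-alignments and counts genes in redundant/lost regions.

suppressMessages(library(duoasm))

fx <- "results/fixtures"
dir.create("results", showWarnings = FALSE)

aln <- select_primary(read_paf(file.path(fx, "b_vs_a.paf")))
proj <- project_to_target(aln)
genome_a <- read_assembly_fasta(file.path(fx, "assembly_a.fasta"))
genes <- read_gff3(file.path(fx, "genes_a.gff3"))
self_aln <- read_paf(file.path(fx, "a_self.paf"))
dep <- read_depth_track(file.path(fx, "depth_consensus.tsv"))

calls <- list()
for (tid in names(genome_a)) {
  len <- Biostrings::width(genome_a)[match(tid, names(genome_a))]
  gaps <- call_gaps(proj, tid, len)
  ovl <- call_overlaps(proj[proj$target_id == tid, ])
  if (nrow(ovl)) for (i in seq_len(nrow(ovl))) {
    pr <- proj[proj$target_id == tid &
                 proj$query_id %in% c(ovl$left_query[i], ovl$right_query[i]), ]
    ovl$similarity[i] <- mean(pr$identity)
    d <- mean(dep$depth[dep$contig == tid & dep$end > ovl$start[i] &
                          dep$start < ovl$end[i]])
    ovl$depth_a[i] <- d / 2; ovl$depth_b[i] <- d / 2
    if (classify_redundancy(ovl$similarity[i], d / 2, d / 2) == "redundancy")
      ovl$call_kind[i] <- "redundancy"
  }
  calls[[tid]] <- rbind(gaps, ovl, call_loss_and_double_cover(proj, gaps))
}
calls <- annotate_repeat_context(do.call(rbind, calls), self_aln)
gg <- count_gene_gain_loss(calls, genes)

write.table(calls, "results/structural_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Structural calls by kind:\n")
print(table(calls$call_kind))
cat("Total bp by kind:\n")
print(tapply(calls$end - calls$start, calls$call_kind, sum))
cat(sprintf("Genes in redundancies: %d; genes in losses: %d\n",
            gg$redundancy_genes, gg$loss_genes))
cat("Repeat context of calls:\n")
print(table(calls$repeat_context))
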