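#!/usr/bin/env Rscript
# Step 3: consensus-error definition and characterization on assembly A.
#
# Applies the per-class hard filters, keeps homozygous (1/1) records as
# assembly errors, then characterizes InDel lengths, adjacent-distance
# clustering against the exponential null, 1 kb / 500 bp sliding-window
# enrichment (>= 5 errors), shotgun depth at error sites, and the GC /
# methylation contrast between enriched and other windows.

suppressMessages(library(duoasm))

fx <- "results/fixtures"
genome_a <- read_assembly_fasta(file.path(fx, "assembly_a.fasta"))
lens <- setNames(Biostrings::width(genome_a), names(genome_a))

errors <- select_assembly_errors(
  apply_hard_filters(read_vcf(file.path(fx, "calls.vcf"))))
write.table(errors, "results/errors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rate <- error_rate_per_kb(errors, sum(lens))
cat(sprintf("Errors: %d (%.3f per kb over %s bp)\n", nrow(errors), rate,
            format(sum(lens), big.mark = ",")))
ist <- indel_length_stats(errors)
cat(sprintf("InDels: %d, mean length %.2f bp\n", ist$n_indels, ist$mean_bp))

d <- adjacent_distances(errors)
cl <- clustering_test(d, rate)
null <- random_placement_null(rate, sum(lens), seed = 1)
cat(sprintf("Observed median spacing %.0f bp vs %.0f bp under random placement (mean %.0f)\n",
            median(d), median(null$distances), null$mean_bp))
cat(sprintf("Clustering: %s (KS D = %.3f, p = %.3g)\n",
            cl$verdict, cl$ks_statistic, cl$p_value))

meth <- read_methylation_table(file.path(fx, "methylation.tsv"))
w <- window_error_scan(errors, lens, genome = genome_a, methylation = meth)
write.table(w, "results/windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Error-enriched windows (>=5 errors): %d of %d\n",
            sum(w$enriched), nrow(w)))
ct <- contrast_enriched_windows(w)
cat(sprintf("Methylation in enriched windows: %s (p = %.3g; medians %.3f vs %.3f)\n",
            ct$methylation_test$direction, ct$methylation_test$p_value,
            ct$methylation_test$median_enriched,
            ct$methylation_test$median_other))
cat(sprintf("GC in enriched windows: %s (p = %.3g)\n",
            ct$gc_test$direction, ct$gc_test$p_value))

dep <- read_depth_track(file.path(fx, "depth_shotgun.tsv"))
ds <- error_site_depth_summary(errors, dep)
cat(sprintf("Error sites at shotgun depth <= 5: %.1f%%\n",
            100 * ds$fraction_at_or_below))
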