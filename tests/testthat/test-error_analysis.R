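var_row <- function(class = "substitution", genotype = "1/1", QD = 10, FS = 5,
                    SOR = 1, MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
                    pos = 100L, ref = "A", alt = "G") {
  if (class == "insertion") alt <- "AG"
  if (class == "deletion") ref <- "AG"
  data.frame(contig = "c1", pos = pos, ref_allele = ref, alt_allele = alt,
             genotype = genotype, QD = QD, FS = FS, SOR = SOR, MQ = MQ,
             MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
             variant_class = class, stringsAsFactors = FALSE)
}

test_that("hard filters apply the per-class conditions", {
  expect_equal(nrow(apply_hard_filters(var_row(QD = 1.5))), 0L)            # SNP QD < 2
  expect_equal(nrow(apply_hard_filters(var_row(MQ = 39))), 0L)             # SNP MQ < 40
  expect_equal(nrow(apply_hard_filters(var_row(FS = 61))), 0L)
  expect_equal(nrow(apply_hard_filters(var_row(SOR = 3.1))), 0L)
  expect_equal(nrow(apply_hard_filters(var_row(MQRankSum = -13))), 0L)
  expect_equal(nrow(apply_hard_filters(var_row(ReadPosRankSum = -9))), 0L)
  expect_equal(nrow(apply_hard_filters(var_row())), 1L)                    # all pass
  expect_equal(nrow(apply_hard_filters(var_row("insertion", FS = 250))), 0L)  # InDel FS > 200
  expect_equal(nrow(apply_hard_filters(var_row("insertion", FS = 100))), 1L)  # but 100 passes InDels
  expect_equal(nrow(apply_hard_filters(var_row("deletion", SOR = 11))), 0L)
  # MQ is not an InDel condition
  expect_equal(nrow(apply_hard_filters(var_row("deletion", MQ = 10))), 1L)
})

test_that("missing annotations pass the conditions that reference them", {
  v <- var_row(); v$QD <- NA; v$MQ <- NA
  expect_equal(nrow(apply_hard_filters(v)), 1L)
})

test_that("only homozygous derived alleles become assembly errors", {
  v <- rbind(var_row(genotype = "1/1", pos = 10L),
             var_row(genotype = "0/1", pos = 20L),
             var_row(genotype = "0/0", pos = 30L),
             var_row(genotype = "missing", pos = 40L),
             var_row("deletion", genotype = "1/1", pos = 50L))
  e <- select_assembly_errors(v)
  expect_equal(e$pos, c(9L, 49L))     # converted to 0-based
  expect_equal(e$error_kind, c("substitution", "deletion"))
  expect_equal(e$length, c(1L, 1L))
  expect_equal(nrow(select_assembly_errors(v[0, ])), 0L)
})

test_that("InDel length statistics handle means, caps and absence", {
  e <- data.frame(contig = "c1", pos = c(1L, 2L, 3L, 4L),
                  error_kind = c("insertion", "deletion", "insertion",
                                 "substitution"),
                  length = c(1L, 1L, 2L, 1L),
                  assembly_allele = "A", evidence_allele = "T")
  s <- indel_length_stats(e)
  expect_equal(s$mean_bp, 4 / 3)
  expect_equal(unname(s$histogram[1:2]), c(2L, 1L))
  one <- indel_length_stats(data.frame(contig = "c", pos = 1L,
                                       error_kind = "deletion", length = 5L,
                                       assembly_allele = "A",
                                       evidence_allele = "T"))
  expect_equal(one$mean_bp, 5)
  subs <- indel_length_stats(e[e$error_kind == "substitution", ])
  expect_true(is.na(subs$mean_bp))
  # overflow bucket collects lengths beyond the cap
  big <- indel_length_stats(data.frame(contig = "c", pos = 1L,
                                       error_kind = "deletion", length = 30L,
                                       assembly_allele = "A",
                                       evidence_allele = "T"))
  expect_equal(unname(big$histogram[">20"]), 1L)
})

test_that("adjacent distances stay within contigs", {
  e <- data.frame(contig = c("c1", "c1", "c1", "c2"),
                  pos = c(0L, 1000L, 2000L, 500L))
  expect_equal(adjacent_distances(e), c(1000L, 1000L))
  e2 <- data.frame(contig = c("c1", "c2"), pos = c(5L, 8L))
  expect_equal(length(adjacent_distances(e2)), 0L)
  e3 <- data.frame(contig = "c1", pos = c(5L, 8L, 20L))
  expect_equal(adjacent_distances(e3), c(3L, 12L))
})

test_that("random placement yields exponential spacings with mean 1000/rate", {
  r1 <- random_placement_null(1.0, 5e6, seed = 1L)
  se <- 1000 / sqrt(r1$n_errors)
  expect_lt(abs(r1$mean_bp - 1000), 3 * se)
  r2 <- random_placement_null(2.0, 5e6, seed = 2L)
  expect_lt(abs(r2$mean_bp - 500), 3 * 500 / sqrt(r2$n_errors))
  # determinism under a fixed seed
  expect_identical(random_placement_null(1.0, 1e6, seed = 9L),
                   random_placement_null(1.0, 1e6, seed = 9L))
})

test_that("clustering verdicts cover extreme, null and undetermined cases", {
  expect_equal(clustering_test(rep(10, 100), 1.0)$verdict, "clustered")
  expect_equal(clustering_test(rep(10, 5), 1.0)$verdict, "undetermined")
  set.seed(5)
  null_d <- rexp(500, rate = 1 / 1000)
  expect_equal(clustering_test(null_d, 1.0)$verdict, "not_clustered")
})

test_that("window scan matches brute-force counting and the enrichment rule", {
  set.seed(21)
  len <- 100000L
  pos <- sort(sample.int(len, 400L) - 1L)
  err <- data.frame(contig = "c1", pos = pos)
  w <- window_error_scan(err, c(c1 = len))
  expect_equal(w$error_count, oracle_window_counts(pos, len, 1000L, 500L))
  expect_equal(w$enriched, w$error_count >= 5L)
  # each error lands in exactly window_bp/step_bp interior windows
  expect_equal(sum(w$error_count),
               sum(vapply(pos, function(p)
                 sum(w$start <= p & p < w$end), integer(1))))
  # boundary membership: 990 and 1010 share [500,1500); only 1010 in [1000,2000)
  e2 <- data.frame(contig = "c1", pos = c(990L, 1010L))
  w2 <- window_error_scan(e2, c(c1 = 3000L))
  expect_equal(w2$error_count[w2$start == 500], 2L)
  expect_equal(w2$error_count[w2$start == 1000], 1L)
  # enrichment boundary: 5 errors in, 4 out
  e5 <- data.frame(contig = "c1", pos = c(10L, 20L, 30L, 40L, 50L))
  expect_true(window_error_scan(e5, c(c1 = 2000L))$enriched[1])
  expect_false(window_error_scan(e5[1:4, ], c(c1 = 2000L))$enriched[1])
  # final short window kept and flagged
  w3 <- window_error_scan(e5, c(c1 = 1250L))
  expect_true(any(w3$short_window))
  expect_equal(max(w3$end), 1250L)
})

test_that("window GC and methylation summaries come from the right spans", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste0(strrep("G", 1000),
                                                   strrep("A", 1000))))
  meth <- data.frame(contig = "c1", pos = c(100L, 300L, 1500L),
                     called_sites = 20L,
                     methylated_fraction = c(0.8, 0.6, 0.1))
  w <- window_error_scan(data.frame(contig = character(), pos = integer()),
                         c(c1 = 2000L), genome = genome, methylation = meth)
  expect_equal(w$gc_fraction[w$start == 0], 1.0)
  expect_equal(w$gc_fraction[w$start == 1000], 0.0)
  expect_equal(w$gc_fraction[w$start == 500], 0.5)
  expect_equal(w$methylation_level[w$start == 0], 0.7)
  expect_equal(w$methylation_level[w$start == 1000], 0.1)
})

test_that("enriched-window contrasts report direction and skip small groups", {
  w <- data.frame(contig = "c1", start = 0:19 * 500L, end = 0:19 * 500L + 1000L,
                  error_count = c(rep(6L, 5), rep(0L, 15)),
                  gc_fraction = c(rep(0.6, 5), rep(0.4, 15)),
                  methylation_level = c(rep(0.9, 5), rep(0.1, 15)),
                  enriched = c(rep(TRUE, 5), rep(FALSE, 15)),
                  short_window = FALSE)
  ct <- contrast_enriched_windows(w)
  expect_lt(ct$methylation_test$p_value, 0.05)
  expect_equal(ct$methylation_test$direction, "higher_in_enriched")
  expect_lt(ct$gc_test$p_value, 0.05)
  w1 <- w; w1$enriched <- c(TRUE, rep(FALSE, 19))
  expect_true(contrast_enriched_windows(w1)$gc_test$skipped)
})

test_that("error-site depth summary is inclusive at the cutoff", {
  tr <- data.frame(contig = "c1", start = c(0L, 100L, 200L),
                   end = c(100L, 200L, 300L), depth = c(3, 10, 5))
  e <- data.frame(contig = "c1", pos = c(50L, 150L))
  expect_equal(error_site_depth_summary(e, tr)$fraction_at_or_below, 0.5)
  e2 <- data.frame(contig = "c1", pos = 250L)
  expect_equal(error_site_depth_summary(e2, tr)$fraction_at_or_below, 1.0)
  e3 <- data.frame(contig = "c1", pos = c(50L, 999L))
  s <- error_site_depth_summary(e3, tr)
  expect_equal(s$n_missing_depth, 1L)
})
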