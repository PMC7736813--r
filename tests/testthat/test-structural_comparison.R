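proj_df <- function(query_id, start, end, target_id = "t1", identity = 0.99) {
  data.frame(query_id = query_id, target_id = target_id, start = start,
             end = end, identity = identity, stringsAsFactors = FALSE)
}

test_that("gap calling returns the complement of the projected union", {
  p <- proj_df(c("q1", "q2"), c(0L, 25000L), c(10000L, 60000L))
  g <- call_gaps(p, "t1", 60000L)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end), c(10000L, 25000L))
  expect_equal(g$left_query, "q1")
  expect_equal(g$right_query, "q2")
  expect_equal(nrow(call_gaps(proj_df("q1", 0L, 60000L), "t1", 60000L)), 0L)
  # terminal gap has a one-sided flank
  gt <- call_gaps(proj_df("q1", 5000L, 60000L), "t1", 60000L)
  expect_true(is.na(gt$left_query))
  expect_equal(gt$right_query, "q1")
})

test_that("gap union is disjoint from the projected union on random cases", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:6, 1L)
    st <- sort(sample(seq(0L, 90000L, by = 100L), n))
    p <- proj_df(paste0("q", seq_len(n)), st,
                 pmin(st + sample(3000:20000, n, replace = TRUE), 100000L))
    g <- call_gaps(p, "t1", 100000L, min_gap_bp = 1L)
    cov <- oracle_depth(p, 100000L)
    gapmask <- logical(100000L)
    for (i in seq_len(nrow(g))) gapmask[(g$start[i] + 1L):g$end[i]] <- TRUE
    expect_true(all(cov[gapmask] == 0L))
    expect_true(all(cov[!gapmask] > 0L | !any(!gapmask)))
  }
})

test_that("overlap calling intersects projections pairwise", {
  p <- proj_df(c("q1", "q2"), c(0L, 20000L), c(30000L, 50000L))
  ov <- call_overlaps(p)
  expect_equal(nrow(ov), 1L)
  expect_equal(c(ov$start, ov$end), c(20000L, 30000L))
  expect_setequal(c(ov$left_query, ov$right_query), c("q1", "q2"))
  expect_equal(nrow(call_overlaps(proj_df(c("q1", "q2"), c(0L, 5000L),
                                          c(4000L, 9000L)))), 0L)
  # three mutually overlapping queries -> three pairwise calls
  p3 <- proj_df(c("q1", "q2", "q3"), c(0L, 500L, 900L), c(1000L, 1500L, 1900L))
  expect_equal(nrow(call_overlaps(p3)), 3L)
})

test_that("redundancy classification applies the similarity and depth rule", {
  expect_equal(classify_redundancy(0.9967, 28, 26), "redundancy")
  expect_equal(classify_redundancy(0.96, 10, 10), "not_redundancy")
  expect_equal(classify_redundancy(0.99, 45, 10), "not_redundancy")  # each < 40
  expect_equal(classify_redundancy(0.99, 35, 30), "not_redundancy")  # total < 60
  expect_equal(classify_redundancy(0.97, 29.9, 29.9), "redundancy")  # boundaries
  expect_equal(classify_redundancy(0.99, NA, 10), "unknown")
})

test_that("redundancy classification is monotone in similarity and depth", {
  set.seed(3)
  for (rep in 1:200) {
    s <- runif(1, 0.9, 1); da <- runif(1, 0, 50); db <- runif(1, 0, 50)
    v <- classify_redundancy(s, da, db)
    if (v == "redundancy") {
      expect_equal(classify_redundancy(min(s + runif(1, 0, 0.05), 1), da, db),
                   "redundancy")
      expect_equal(classify_redundancy(s, da * runif(1), db * runif(1)),
                   "redundancy")
    }
  }
})

test_that("gaps split into losses and double-covered redundancies", {
  gaps <- rbind(
    data.frame(target_id = "t1", start = 100L, end = 200L,
               call_kind = "gap_uncovered", left_query = NA, right_query = NA,
               similarity = NA, depth_a = NA, depth_b = NA,
               repeat_context = "unknown"),
    data.frame(target_id = "t1", start = 300L, end = 400L,
               call_kind = "gap_uncovered", left_query = NA, right_query = NA,
               similarity = NA, depth_a = NA, depth_b = NA,
               repeat_context = "unknown"),
    data.frame(target_id = "t1", start = 500L, end = 600L,
               call_kind = "gap_uncovered", left_query = NA, right_query = NA,
               similarity = NA, depth_a = NA, depth_b = NA,
               repeat_context = "unknown"))
  p <- proj_df(c("qa", "qb", "qc"), c(300L, 300L, 500L), c(400L, 400L, 600L))
  out <- call_loss_and_double_cover(p, gaps)
  expect_equal(out$call_kind[out$start == 100], "loss")        # depth 0
  expect_equal(out$call_kind[out$start == 300], "redundancy")  # depth 2
  expect_false(500 %in% out$start)                             # depth 1: no call
})

test_that("repeat context distinguishes tandem, dispersed and none", {
  call <- data.frame(target_id = "c1", start = 50000L, end = 64000L,
                     call_kind = "gap_uncovered", left_query = NA,
                     right_query = NA, similarity = NA, depth_a = NA,
                     depth_b = NA, repeat_context = "unknown",
                     stringsAsFactors = FALSE)
  # two same-contig copies 14 kb long flanking the call
  tandem_aln <- data.frame(
    query_id = "c1", query_len = 1000000L, query_start = 36000L,
    query_end = 50000L, strand = "+", target_id = "c1",
    target_len = 1000000L, target_start = 64000L, target_end = 78000L,
    n_matches = 13900L, block_len = 14000L, mapq = 60L, is_primary = TRUE,
    cigar = NA_character_, stringsAsFactors = FALSE)
  expect_equal(annotate_repeat_context(call, tandem_aln)$repeat_context,
               "tandem")
  # a second-contig match at 99% identity over the call
  disp_aln <- data.frame(
    query_id = "c2", query_len = 1000000L, query_start = 100000L,
    query_end = 114000L, strand = "+", target_id = "c1",
    target_len = 1000000L, target_start = 50000L, target_end = 64000L,
    n_matches = 13860L, block_len = 14000L, mapq = 60L, is_primary = TRUE,
    cigar = NA_character_, stringsAsFactors = FALSE)
  expect_equal(annotate_repeat_context(call, disp_aln)$repeat_context,
               "dispersed")
  # a far-away tandem pair must not label an unrelated call
  far_call <- call; far_call$start <- 140000L; far_call$end <- 150000L
  expect_equal(annotate_repeat_context(far_call, tandem_aln)$repeat_context,
               "none")
  expect_equal(annotate_repeat_context(call, NULL)$repeat_context, "unknown")
})

test_that("gene accounting deduplicates within and across call kinds", {
  calls <- rbind(
    data.frame(target_id = "c1", start = 0L, end = 1000L,
               call_kind = "redundancy", left_query = NA, right_query = NA,
               similarity = 0.99, depth_a = 20, depth_b = 20,
               repeat_context = "none"),
    data.frame(target_id = "c1", start = 800L, end = 2000L,
               call_kind = "loss", left_query = NA, right_query = NA,
               similarity = NA, depth_a = NA, depth_b = NA,
               repeat_context = "none"))
  genes <- data.frame(gene_id = c("g1", "g1", "g2"), contig = "c1",
                      strand = "+", start = c(100L, 850L, 5000L),
                      end = c(300L, 950L, 5300L), exon_index = c(1L, 2L, 1L))
  out <- count_gene_gain_loss(calls, genes)
  # g1 overlaps both kinds: once in each; g2 overlaps nothing
  expect_equal(out$redundancy_genes, 1L)
  expect_equal(out$loss_genes, 1L)
  expect_equal(count_gene_gain_loss(calls[0, ], genes)$redundancy_genes, 0L)
})
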