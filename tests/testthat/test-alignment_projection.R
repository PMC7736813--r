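make_aln <- function(query_id, target_id = "t1", qs = 0L, qe = 100L,
                     ts = 0L, te = 100L, nm = 90L, bl = 100L,
                     primary = TRUE, cigar = NA_character_,
                     qlen = 1000L, tlen = 100000L) {
  data.frame(query_id = query_id, query_len = qlen, query_start = qs,
             query_end = qe, strand = "+", target_id = target_id,
             target_len = tlen, target_start = ts, target_end = te,
             n_matches = nm, block_len = bl, mapq = 60L,
             is_primary = primary, cigar = cigar, stringsAsFactors = FALSE)
}

test_that("primary selection keeps flagged hits and falls back to best block", {
  a <- rbind(make_aln("q1", primary = TRUE), make_aln("q1", primary = FALSE))
  expect_equal(nrow(select_primary(a)), 1L)
  expect_true(select_primary(a)$is_primary)
  # no flagged hit: keep the largest block (500 beats 400)
  b <- rbind(make_aln("q2", primary = FALSE, bl = 500L, nm = 450L, qe = 500L, te = 500L),
             make_aln("q2", primary = FALSE, bl = 400L, nm = 390L, qe = 400L, te = 400L))
  kept <- select_primary(b)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$block_len, 500L)
  expect_equal(nrow(select_primary(make_aln("x")[0, ])), 0L)
})

test_that("reciprocal-match filtering requires the span on both sequences", {
  a <- rbind(
    make_aln("q1", qs = 0L, qe = 1200000L, ts = 0L, te = 1200000L,
             nm = 1100000L, bl = 1200000L, qlen = 2000000L, tlen = 2000000L),
    make_aln("q2", qs = 0L, qe = 1200000L, ts = 0L, te = 900000L,
             nm = 800000L, bl = 1200000L, qlen = 2000000L, tlen = 2000000L))
  kept <- filter_reciprocal_matches(a, 1e6)
  expect_equal(kept$query_id, "q1")
  expect_equal(nrow(filter_reciprocal_matches(a, 0)), 2L)
})

test_that("projection merges same-query intervals and respects queries", {
  a <- rbind(make_aln("q1", ts = 0L, te = 10000L, nm = 9000L, bl = 10000L),
             make_aln("q1", ts = 9500L, te = 20000L, nm = 10000L, bl = 10500L))
  p <- project_to_target(a)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(0L, 20000L))
  expect_equal(p$identity, (9000 + 10000) / (10000 + 10500))
  # distinct queries stay unmerged
  b <- rbind(make_aln("q1", ts = 0L, te = 10000L),
             make_aln("q2", ts = 5000L, te = 15000L))
  expect_equal(nrow(project_to_target(b)), 2L)
  # one query on two targets in one group is an error
  d <- rbind(make_aln("q1", target_id = "t1"), make_aln("q1", target_id = "t2"))
  expect_error(project_to_target(d), "multiple targets")
})

test_that("projected intervals never double-count within a query", {
  sim <- get_small_sim()
  proj <- project_to_target(select_primary(sim$true_alignments))
  for (q in unique(proj$query_id)) {
    p <- proj[proj$query_id == q, ]
    ir <- IRanges::IRanges(p$start + 1L, p$end)
    expect_equal(sum(p$end - p$start), sum(IRanges::width(IRanges::reduce(ir))))
  }
})

test_that("coverage depth equals a brute-force per-base counter", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:8, 1L)
    st <- sample(0:900, n)
    iv <- data.frame(query_id = paste0("q", seq_len(n)), target_id = "t1",
                     start = st, end = st + sample(20:100, n, replace = TRUE),
                     identity = 1)
    len <- 1000L
    iv$end <- pmin(iv$end, len)
    prof <- coverage_depth(iv, "t1", len)
    d <- integer(len)
    for (i in seq_len(nrow(prof)))
      if (prof$end[i] > prof$start[i])
        d[(prof$start[i] + 1L):prof$end[i]] <- prof$depth[i]
    expect_equal(d, oracle_depth(iv, len))
  }
  # two queries [0,100) and [50,150): depth 2 exactly on [50,100)
  iv <- data.frame(query_id = c("a", "b"), target_id = "t1",
                   start = c(0L, 50L), end = c(100L, 150L), identity = 1)
  prof <- coverage_depth(iv, "t1", 200L)
  expect_equal(prof$depth[prof$start == 50 & prof$end == 100], 2L)
  empty <- coverage_depth(iv[0, ], "t1", 100L)
  expect_equal(empty$depth, 0L)
})

test_that("mismatch extraction categorizes runs around the 85 bp boundary", {
  r <- make_aln("q1", qs = 0L, qe = 110L, ts = 0L, te = 200L,
                nm = 110L, bl = 200L, cigar = "50=90D60=")
  mm <- extract_mismatches(r)
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$kind, "deletion")
  expect_equal(mm$target_pos, 50L)
  expect_equal(mm$category, "local")          # 90 > 85
  r2 <- make_aln("q1", qs = 0L, qe = 103L, ts = 0L, te = 100L,
                 nm = 100L, bl = 103L, cigar = "40=3I60=")
  mm2 <- extract_mismatches(r2)
  expect_equal(mm2$kind, "insertion")
  expect_equal(mm2$category, "small_scale")
  # an 85 bp run is still small-scale; 86 is local
  r3 <- make_aln("q1", qs = 0L, qe = 20L, ts = 0L, te = 105L,
                 nm = 20L, bl = 105L, cigar = "10=85D10=")
  expect_equal(extract_mismatches(r3)$category, "small_scale")
  # all-match cigar yields nothing
  r4 <- make_aln("q1", qs = 0L, qe = 100L, ts = 0L, te = 100L, cigar = "100=")
  expect_equal(nrow(extract_mismatches(r4)), 0L)
  # plain M runs cannot expose substitutions
  r5 <- make_aln("q1", qs = 0L, qe = 100L, ts = 0L, te = 100L, cigar = "100M")
  expect_false(attr(extract_mismatches(r5), "substitutions_available"))
  # inconsistent cigar
  r6 <- make_aln("q1", qs = 0L, qe = 100L, ts = 0L, te = 100L, cigar = "99=")
  expect_error(extract_mismatches(r6), "inconsistent")
})

test_that("mismatch extraction recovers the planted error set exactly", {
  sim <- get_small_sim()
  aln <- sim$true_alignments
  found <- do.call(rbind, lapply(seq_len(nrow(aln)), function(i)
    cbind(contig = aln$target_id[i], extract_mismatches(aln[i, ]))))
  found <- unique(found[, c("contig", "target_pos", "kind", "length")])
  planted <- sim$planted_errors
  # alignment-space kinds are inverted relative to VCF convention:
  # an error where A misses bases (VCF insertion) appears as a query
  # insertion; where A carries extra bases, as a deletion-consuming run
  key_found <- paste(found$contig, found$target_pos, found$kind, found$length)
  key_planted <- with(planted, paste(
    contig, ifelse(error_kind == "substitution", pos, pos + 1L),
    ifelse(error_kind == "substitution", "substitution",
           ifelse(error_kind == "insertion", "insertion", "deletion")),
    length))
  ## errors inside gap-mode repeats are absent from assembly B, hence
  ## not visible to any alignment; drop them from the expectation
  gaps <- sim$planted_structural[sim$planted_structural$call_kind == "gap_uncovered", ]
  in_gap <- rep(FALSE, nrow(planted))
  for (i in seq_len(nrow(gaps)))
    in_gap <- in_gap | (planted$contig == gaps$contig[i] &
                          planted$pos >= gaps$start[i] &
                          planted$pos < gaps$end[i])
  expect_setequal(key_found, key_planted[!in_gap])
})
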