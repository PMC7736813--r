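gene_df <- function(starts, ends, strand = "+", contig = "c1", id = "g1") {
  data.frame(gene_id = id, contig = contig, strand = strand, start = starts,
             end = ends, exon_index = seq_along(starts),
             stringsAsFactors = FALSE)
}

err_row <- function(pos, ref, alt) {
  data.frame(contig = "c1", pos = pos,
             error_kind = variantkind(ref, alt),
             length = max(1L, abs(nchar(ref) - nchar(alt))),
             assembly_allele = ref, evidence_allele = alt,
             stringsAsFactors = FALSE)
}

test_that("CDS building splices exons and honours strand", {
  expect_equal(build_cds(gene_df(0L, 6L), "ATGTAACC"), "ATGTAA")
  expect_equal(build_cds(gene_df(0L, 6L, strand = "-"), "ATGTAACC"), "TTACAT")
  expect_equal(build_cds(gene_df(c(0L, 6L), c(3L, 9L)), "ATGCCCTAAG"), "ATGTAA")
  expect_error(build_cds(gene_df(0L, 99L), "ATGTAA"), "bounds")
})

test_that("translation stops at the first stop and flags anomalies", {
  t1 <- translate_cds("ATGTAA")
  expect_equal(t1$protein, "M")
  expect_true(t1$terminal_stop)
  t2 <- translate_cds("ATGGCC")
  expect_equal(t2$protein, "MA")
  expect_false(t2$terminal_stop)
  t3 <- translate_cds("ATGTAGGGG")
  expect_equal(t3$protein, "M")
  expect_true(t3$internal_stop)
  expect_true(translate_cds("ATGGC")$partial_codon)
  expect_error(translate_cds("AT"), "codon")
})

test_that("canonical impact classes come out of hand-built cases", {
  # contig: ATG GCT TGG GCT TAA  (M A W A *), CDS on [4, 19)
  seq <- paste0("CCCC", "ATGGCTTGGGCTTAA", "CCCC")
  g <- gene_df(4L, 19L)
  # 1-base deletion inside CDS (assembly carries an extra base) -> frameshift
  seq_fs <- paste0("CCCC", "ATGGCCTTGGGCTTAA", "CCCC")
  fs <- classify_error_impact(err_row(9L, "CT", "C"), gene_df(4L, 20L), seq_fs)
  expect_equal(fs$impact, "frameshift")
  # TGG -> TGA mid-CDS: assembly carries a premature stop -> stop_gain
  seq_sg <- seq; substr(seq_sg, 13L, 13L) <- "A"
  sg <- classify_error_impact(err_row(12L, "A", "G"), g, seq_sg)
  expect_equal(sg$impact, "stop_gain")
  expect_lt(nchar(sg$protein_before), nchar(sg$protein_after))
  # third-position GCT -> GCC is synonymous
  syn <- classify_error_impact(err_row(9L, "T", "C"), g, seq)
  expect_equal(syn$impact, "synonymous")
  expect_identical(syn$protein_before, syn$protein_after)
  # destroying the annotated stop -> stop_loss
  seq_sl <- seq; substr(seq_sl, 17L, 17L) <- "C"
  sl <- classify_error_impact(err_row(16L, "C", "T"), gene_df(4L, 19L), seq_sl)
  expect_equal(sl$impact, "stop_loss")
  # missense: GCT -> GTT on the corrected side
  ms <- classify_error_impact(err_row(8L, "C", "T"), g, seq)
  expect_equal(ms$impact, "missense")
  # outside CDS
  nc <- classify_error_impact(err_row(1L, "C", "A"), g, seq)
  expect_equal(nc$impact, "noncoding")
  # allele inconsistent with the contig is a coordinate mismatch
  expect_error(classify_error_impact(err_row(4L, "T", "C"), g, seq),
               "inconsistent")
})

test_that("intronic errors near junctions are flagged but stay noncoding", {
  seq <- paste0("ATGGCT", strrep("C", 50), "TGGTAA")
  g <- gene_df(c(0L, 56L), c(6L, 62L))
  near <- classify_error_impact(err_row(7L, "C", "A"), g, seq)
  expect_equal(near$impact, "noncoding")
  expect_true(near$splice_adjacent)
  far <- classify_error_impact(err_row(30L, "C", "A"), g, seq)
  expect_false(far$splice_adjacent)
})

test_that("classification agrees with the rebuild-and-translate oracle", {
  set.seed(99)
  n_agree <- 0L
  for (i in 1:300) {
    cs <- random_gene_case()
    got <- classify_error_impact(cs$error, cs$gene, cs$seq)$impact
    want <- oracle_classify(cs$error, cs$gene, cs$seq)
    if (!identical(got, want))
      fail(sprintf("case %d: got %s, oracle %s (pos %d %s>%s strand %s)",
                   i, got, want, cs$error$pos, cs$error$assembly_allele,
                   cs$error$evidence_allele, cs$gene$strand[1]))
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 300L)
})

test_that("reversing an edit inverts the impact relationship", {
  seq <- paste0("CCCC", "ATGGCTTGGGCTTAA", "CCCC")
  g <- gene_df(4L, 19L)
  seq_sg <- seq; substr(seq_sg, 13L, 13L) <- "A"
  fwd <- classify_error_impact(err_row(12L, "A", "G"), g, seq_sg)
  rev <- classify_error_impact(err_row(12L, "G", "A"), g, seq)
  expect_equal(fwd$impact, "stop_gain")
  expect_equal(rev$impact, "stop_loss")
  # frameshift reverses to frameshift
  seq_fs <- paste0("CCCC", "ATGGCCTTGGGCTTAA", "CCCC")
  f1 <- classify_error_impact(err_row(9L, "CT", "C"), gene_df(4L, 20L), seq_fs)
  f2 <- classify_error_impact(err_row(8L, "C", "CT"), gene_df(4L, 19L), seq)
  expect_equal(f1$impact, "frameshift")
  expect_equal(f2$impact, "frameshift")
})

test_that("affected exon and gene tallies deduplicate correctly", {
  # gene with three exons; missense in exon 1, stop gain in exon 3
  seq <- paste0("ATGGCT", "gggg", "TGGGCTAAA", "gggg", "TGGTATTAA")
  seq <- toupper(seq)
  g <- gene_df(c(0L, 10L, 23L), c(6L, 19L, 32L))
  errs <- rbind(err_row(4L, "C", "A"),    # exon 1 missense (GCT -> GAT reversed)
                err_row(24L, "G", "C"))   # exon 3 change
  out <- count_affected(errs, g, c(c1 = seq))
  expect_equal(out$affected_genes, 1L)
  expect_equal(out$affected_exons, 2L)
  # two synonymous errors affect nothing
  syn <- rbind(err_row(5L, "T", "C"))     # GCT -> GCC
  out2 <- count_affected(syn, g, c(c1 = seq))
  expect_equal(out2$affected_genes, 0L)
  expect_equal(out2$affected_exons, 0L)
  # strict mode drops missense
  expect_lte(out$affected_exons_strict, out$affected_exons)
  # no errors, no genes
  expect_equal(count_affected(errs[0, ], g, c(c1 = seq))$affected_genes, 0L)
})
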