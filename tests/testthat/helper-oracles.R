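# Independent brute-force oracles used to check the package's
# implementations. They share no code path with the package internals.

# standard genetic code, hardcoded
.codon_tab <- local({
  aa <- "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVVXYXYSSSSXCWCLFLF"
  aa <- chartr("X", "*", aa)
  b <- c("A", "C", "G", "T")
  names4 <- as.vector(sapply(b, function(x) sapply(b, function(y)
    paste0(x, y, b))))
  stats::setNames(strsplit(aa, "")[[1]], names4)
})

oracle_translate_full <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(.codon_tab[codons], collapse = "")
}

oracle_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# rebuild the CDS from exon substrings (own string code)
oracle_cds <- function(gene, seq) {
  gene <- gene[order(gene$start), ]
  s <- paste(substring(seq, gene$start + 1L, gene$end), collapse = "")
  if (gene$strand[1] == "-") s <- oracle_revcomp(s) else s
}

# classify one error by rebuilding both full CDS strings and comparing
# codon-by-codon translations
oracle_classify <- function(error, gene, seq) {
  gene <- gene[order(gene$start), ]
  ref <- error$assembly_allele; alt <- error$evidence_allele
  pos <- error$pos
  ref_end <- pos + nchar(ref)
  # changed bases on the assembly
  chg <- if (nchar(ref) == nchar(alt)) seq.int(pos, ref_end - 1L)
         else if (nchar(ref) > nchar(alt)) seq.int(pos + 1L, ref_end - 1L)
         else pos  # insertion point, coding only if strictly inside an exon
  hit <- if (nchar(alt) > nchar(ref))
    any(gene$start <= pos & pos + 1L < gene$end)
  else any(vapply(chg, function(p) any(gene$start <= p & p < gene$end),
                  logical(1)))
  if (!hit) return("noncoding")
  delta <- nchar(alt) - nchar(ref)
  if (delta != 0L && abs(delta) %% 3L != 0L) return("frameshift")
  seq2 <- paste0(substr(seq, 1L, pos), alt,
                 substr(seq, ref_end + 1L, nchar(seq)))
  g2 <- gene
  for (i in seq_len(nrow(g2))) {
    if (g2$end[i] <= pos) next
    if (g2$start[i] >= ref_end) {
      g2$start[i] <- g2$start[i] + delta; g2$end[i] <- g2$end[i] + delta
    } else g2$end[i] <- g2$end[i] + delta
  }
  p_before <- oracle_translate_full(oracle_cds(gene, seq))
  p_after <- oracle_translate_full(oracle_cds(g2, seq2))
  stop_at <- function(p) {
    s <- regexpr("*", p, fixed = TRUE)
    if (s == -1L) Inf else as.integer(s)
  }
  sb <- stop_at(p_before); sa <- stop_at(p_after)
  trunc_at <- function(p, s) if (is.infinite(s)) p else substr(p, 1L, s - 1L)
  if (sb < sa) "stop_gain"
  else if (sb > sa) "stop_loss"
  else if (identical(trunc_at(p_before, sb), trunc_at(p_after, sa)))
    "synonymous"
  else "missense"
}

# brute-force per-base projection depth counter
oracle_depth <- function(intervals, len) {
  d <- integer(len)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e > s) d[(s + 1L):e] <- d[(s + 1L):e] + 1L
  }
  d
}

# brute-force window error counter
oracle_window_counts <- function(pos, len, window, step) {
  starts <- seq(0L, max(len - 1L, 0L), by = step)
  vapply(starts, function(s)
    sum(pos >= s & pos < min(s + window, len)), integer(1))
}

interval_overlap_frac <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  ov / max(e1 - s1, e2 - s2)
}
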