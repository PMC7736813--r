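## Classification of each assembly error overlapping annotated CDS by its
## effect on translation: frameshift, stop-gain, stop-loss, missense,
## synonymous. The comparison direction follows the study design: the
## "before" protein comes from the error-bearing assembly, the "after"
## protein from the corrected sequence (evidence allele applied).

#' Build the coding sequence of one gene model
#'
#' Exon substrings are concatenated in genomic order; minus-strand models
#' are reverse-complemented as one unit.
#'
#' @param gene CDS rows (one gene) from [read_gff3()].
#' @param contig_seq The contig sequence (character or DNAString).
#' @return The coding sequence as a character string.
#' @export
build_cds <- function(gene, contig_seq) {
  seq <- as.character(contig_seq)
  gene <- gene[order(gene$start), , drop = FALSE]
  if (any(gene$start < 0) || any(gene$end > nchar(seq)))
    stop("CDS interval outside contig bounds")
  parts <- substring(seq, gene$start + 1L, gene$end)
  cds <- paste(parts, collapse = "")
  if (gene$strand[1] == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

#' Translate a coding sequence (standard genetic code)
#'
#' Translation stops at the first stop codon; a trailing partial codon is
#' flagged and dropped.
#'
#' @param cds Coding sequence (length >= 3).
#' @return list `protein` (up to but excluding the first stop),
#'   `stop_index` (codon index of the first stop, Inf when none),
#'   `terminal_stop` (first stop is the final codon), `internal_stop`,
#'   `partial_codon`.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3L) stop("coding sequence shorter than one codon")
  partial <- nchar(cds) %% 3L != 0L
  trimmed <- substr(cds, 1L, nchar(cds) %/% 3L * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(trimmed),
                                           no.init.codon = TRUE))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  n_codons <- nchar(aa)
  if (stops[1] == -1L) {
    list(protein = aa, stop_index = Inf, terminal_stop = FALSE,
         internal_stop = FALSE, partial_codon = partial)
  } else {
    first <- stops[1]
    list(protein = substr(aa, 1L, first - 1L), stop_index = first,
         terminal_stop = first == n_codons, internal_stop = first < n_codons,
         partial_codon = partial)
  }
}

apply_edit <- function(seq, pos0, ref, alt) {
  if (substr(seq, pos0 + 1L, pos0 + nchar(ref)) != ref)
    stop("assembly allele inconsistent with contig sequence at position ",
         pos0, " (coordinate mismatch?)")
  paste0(substr(seq, 1L, pos0), alt,
         substr(seq, pos0 + nchar(ref) + 1L, nchar(seq)))
}

shift_intervals <- function(gene, pos0, ref_len, delta) {
  edit_end <- pos0 + ref_len
  g <- gene
  for (i in seq_len(nrow(g))) {
    if (g$end[i] <= pos0) next
    if (g$start[i] >= edit_end) {
      g$start[i] <- g$start[i] + delta
      g$end[i] <- g$end[i] + delta
    } else {
      g$end[i] <- g$end[i] + delta
    }
  }
  g
}

#' Classify one error's impact on one gene's translation
#'
#' The evidence allele replaces the assembly allele; translations of the
#' annotated CDS before and after the correction are compared. An InDel
#' with length not divisible by 3 inside CDS is a frameshift regardless of
#' downstream sequence. A substitution that created a premature stop in the
#' assembly is a stop-gain (the corrected protein is longer); one that
#' destroyed the annotated stop is a stop-loss. Intronic errors within 2 bp
#' of a junction are flagged `splice_adjacent` but remain noncoding (splice
#' sites are not modeled).
#'
#' @param error One AssemblyError row.
#' @param gene CDS rows of one gene model on the same contig.
#' @param contig_seq The (error-bearing) contig sequence.
#' @return list `gene_id`, `impact`, `affected_exon_index`,
#'   `protein_before`, `protein_after`, `splice_adjacent`.
#' @export
classify_error_impact <- function(error, gene, contig_seq) {
  seq <- as.character(contig_seq)
  gene <- gene[order(gene$start), , drop = FALSE]
  ref <- error$assembly_allele; alt <- error$evidence_allele
  pos0 <- error$pos
  if (substr(seq, pos0 + 1L, pos0 + nchar(ref)) != ref)
    stop("assembly allele inconsistent with contig sequence at position ",
         pos0, " (coordinate mismatch?)")
  is_indel <- nchar(ref) != nchar(alt)
  ## changed genomic positions on the assembly: for substitutions the
  ## substituted bases; for InDels the non-anchor bases / insertion point
  if (!is_indel) {
    changed <- seq.int(pos0, pos0 + nchar(ref) - 1L)
    in_cds <- any(vapply(changed, function(p)
      any(gene$start <= p & p < gene$end), logical(1)))
  } else if (nchar(ref) > nchar(alt)) {
    changed <- seq.int(pos0 + 1L, pos0 + nchar(ref) - 1L)  # bases removed by the fix
    in_cds <- any(vapply(changed, function(p)
      any(gene$start <= p & p < gene$end), logical(1)))
  } else {
    changed <- pos0  # insertion point: between pos0 and pos0+1
    in_cds <- any(gene$start <= pos0 & (pos0 + 1L) < gene$end)
  }
  exon_idx <- NA_integer_
  hit <- which(gene$start <= changed[1] & changed[1] < gene$end)
  if (length(hit)) exon_idx <- gene$exon_index[hit[1]]
  if (!in_cds) {
    near <- any(abs(changed[1] - gene$start) <= 2L | abs(changed[1] - gene$end) <= 2L)
    return(list(gene_id = gene$gene_id[1], impact = "noncoding",
                affected_exon_index = NA_integer_, protein_before = NA_character_,
                protein_after = NA_character_, splice_adjacent = near))
  }
  delta <- nchar(alt) - nchar(ref)
  if (is_indel && abs(delta) %% 3L != 0L)
    return(list(gene_id = gene$gene_id[1], impact = "frameshift",
                affected_exon_index = exon_idx, protein_before = NA_character_,
                protein_after = NA_character_, splice_adjacent = FALSE))
  before <- translate_cds(build_cds(gene, seq))
  seq2 <- apply_edit(seq, pos0, ref, alt)
  gene2 <- shift_intervals(gene, pos0, nchar(ref), delta)
  after <- translate_cds(build_cds(gene2, seq2))
  impact <-
    if (before$stop_index < after$stop_index) "stop_gain"
    else if (before$stop_index > after$stop_index) "stop_loss"
    else if (identical(before$protein, after$protein)) "synonymous"
    else "missense"
  list(gene_id = gene$gene_id[1], impact = impact,
       affected_exon_index = exon_idx, protein_before = before$protein,
       protein_after = after$protein, splice_adjacent = FALSE)
}

#' Count exons and genes whose translation is affected by errors
#'
#' An exon or gene is affected when it carries at least one error whose
#' impact prevents correct translation. With `include_missense = TRUE` (the
#' default) the criterion is any of frameshift / stop-gain / stop-loss /
#' missense; strict mode counts only frameshift and stop events. Both
#' tallies are always reported. Each exon and gene is counted once.
#'
#' @param errors AssemblyError data.frame.
#' @param genes CDS data.frame from [read_gff3()].
#' @param genome Named [Biostrings::DNAStringSet] (or character vector) of
#'   contig sequences.
#' @param include_missense Whether missense counts as "affected" in the
#'   headline tally.
#' @return list `affected_exons`, `affected_genes` (under the chosen
#'   criterion), `affected_exons_strict`, `affected_genes_strict`,
#'   `impact_tally`, `per_error` data.frame.
#' @export
count_affected <- function(errors, genes, genome, include_missense = TRUE) {
  seqs <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  rows <- list()
  if (nrow(errors) && nrow(genes)) {
    spans <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g)
      data.frame(gene_id = g$gene_id[1], contig = g$contig[1],
                 start = min(g$start), end = max(g$end),
                 stringsAsFactors = FALSE)))
    for (i in seq_len(nrow(errors))) {
      e <- errors[i, ]
      e_end <- e$pos + nchar(e$assembly_allele)
      cand <- spans[spans$contig == e$contig & spans$start < e_end &
                      spans$end > e$pos, , drop = FALSE]
      for (gid in cand$gene_id) {
        g <- genes[genes$gene_id == gid, , drop = FALSE]
        cl <- classify_error_impact(e, g, seqs[[e$contig]])
        rows[[length(rows) + 1L]] <-
          data.frame(error_index = i, contig = e$contig, pos = e$pos,
                     gene_id = gid, impact = cl$impact,
                     exon_index = cl$affected_exon_index,
                     stringsAsFactors = FALSE)
      }
    }
  }
  per_error <- if (length(rows)) do.call(rbind, rows) else
    data.frame(error_index = integer(), contig = character(), pos = integer(),
               gene_id = character(), impact = character(),
               exon_index = integer(), stringsAsFactors = FALSE)
  disrupt_any <- c("frameshift", "stop_gain", "stop_loss", "missense")
  disrupt_strict <- c("frameshift", "stop_gain", "stop_loss")
  crit <- if (include_missense) disrupt_any else disrupt_strict
  count_under <- function(set) {
    aff <- per_error[per_error$impact %in% set, , drop = FALSE]
    c(exons = nrow(unique(aff[, c("gene_id", "exon_index")])),
      genes = length(unique(aff$gene_id)))
  }
  main <- count_under(crit); strict <- count_under(disrupt_strict)
  list(affected_exons = unname(main["exons"]),
       affected_genes = unname(main["genes"]),
       affected_exons_strict = unname(strict["exons"]),
       affected_genes_strict = unname(strict["genes"]),
       impact_tally = table(per_error$impact), per_error = per_error)
}
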