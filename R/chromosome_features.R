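## Telomere motif arrays, centromeric repeat regions and per-contig
## telomere-to-telomere assessment.

feature_hit <- function(contig, start, end, feature, unit_count,
                        mean_identity, contig_end) {
  data.frame(contig = contig, start = start, end = end, feature = feature,
             unit_count = unit_count, mean_identity = mean_identity,
             contig_end = contig_end, stringsAsFactors = FALSE)
}

empty_hits <- function() feature_hit(character(), integer(), integer(),
                                     character(), integer(), numeric(),
                                     character())[0, ]

classify_end <- function(start, end, len, end_window_bp) {
  ifelse(start < end_window_bp, "five_prime",
         ifelse(end > len - end_window_bp, "three_prime", "internal"))
}

tandem_runs <- function(starts, unit_len) {
  ## chain match starts into maximal runs advancing by exactly one unit;
  ## shifted overlapping matches inside a run are skipped
  runs <- list()
  starts <- sort(unique(starts))
  i <- 1L
  while (i <= length(starts)) {
    s0 <- starts[i]; cur <- s0; n <- 1L; j <- i + 1L
    while (j <= length(starts)) {
      if (starts[j] == cur + unit_len) { cur <- starts[j]; n <- n + 1L; j <- j + 1L }
      else if (starts[j] < cur + unit_len) j <- j + 1L
      else break
    }
    runs[[length(runs) + 1L]] <- c(start = s0, end = cur + unit_len, n = n)
    i <- j
  }
  runs
}

unit_identity <- function(seq_chr, start0, n, unit, unit_len) {
  ident <- vapply(seq_len(n), function(k) {
    u <- substr(seq_chr, start0 + (k - 1L) * unit_len + 1L,
                start0 + k * unit_len)
    mean(strsplit(u, "")[[1]] == strsplit(unit, "")[[1]])
  }, numeric(1))
  mean(ident)
}

#' Find telomere motif arrays on a contig
#'
#' Maximal runs of at least `min_units` tandem copies of the motif or its
#' reverse complement, allowing a per-unit mismatch fraction up to
#' `max_mismatch_fraction`. Hits are classified by proximity to the contig
#' ends (`end_window_bp`), which is what feeds the T2T assessment.
#'
#' @param seq Contig sequence (DNAString or character).
#' @param motif Telomere repeat unit (default the plant motif `AAACCCT`).
#' @param min_units Minimum tandem copies (default 10).
#' @param max_mismatch_fraction Per-unit mismatch tolerance (default 0.1).
#' @param end_window_bp Window defining "at a contig end" (default 10 kb).
#' @param contig Contig id recorded in the output.
#' @return FeatureHit data.frame.
#' @export
find_telomere_arrays <- function(seq, motif = "AAACCCT", min_units = 10L,
                                 max_mismatch_fraction = 0.1,
                                 end_window_bp = 10000L, contig = "contig") {
  stopifnot(nchar(motif) >= 4L)
  dna <- if (is.character(seq)) Biostrings::DNAString(seq) else seq
  seq_chr <- as.character(dna)
  len <- nchar(seq_chr)
  unit_len <- nchar(motif)
  mm <- floor(unit_len * max_mismatch_fraction)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  hits <- list()
  for (pat in unique(c(motif, rc))) {
    m <- Biostrings::matchPattern(pat, dna, max.mismatch = mm)
    if (length(m) == 0L) next
    for (run in tandem_runs(Biostrings::start(m) - 1L, unit_len)) {
      if (run[["n"]] < min_units) next
      hits[[length(hits) + 1L]] <- feature_hit(
        contig, run[["start"]], run[["end"]], "telomere", run[["n"]],
        unit_identity(seq_chr, run[["start"]], run[["n"]], pat, unit_len),
        classify_end(run[["start"]], run[["end"]], len, end_window_bp))
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  ## merge hits from the two orientations that cover the same array
  ir <- IRanges::IRanges(out$start + 1L, out$end)
  grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, IRanges::reduce(ir)))
  out <- do.call(rbind, lapply(split(out, grp), function(h) h[which.max(h$unit_count), ]))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find centromeric repeat regions by full-unit consensus matching
#'
#' Locates full-length approximate matches of the repeat-unit consensus
#' (identity over the entire unit at least `min_identity`) by exact seeding
#' with short words from the consensus followed by whole-unit alignment
#' verification, then merges matches within `merge_gap_bp` into centromere
#' regions. Partial (sub-unit) matches never found a region: full units are
#' required.
#'
#' @param seq Contig sequence (DNAString or character).
#' @param unit_consensus Repeat unit consensus sequence (>= 50 bp), or NULL
#'   to skip.
#' @param min_identity Per-unit identity floor (default 0.8).
#' @param min_full_units Minimum full-unit matches per region (default 1).
#' @param merge_gap_bp Merge distance between unit matches (default 10 kb).
#' @param contig Contig id recorded in the output.
#' @param seed_len Exact seed word length (default 15).
#' @return FeatureHit data.frame (`unit_count` = full-unit matches). When
#'   no consensus is given, an empty frame with attribute
#'   `skipped_reason`.
#' @export
find_centromere <- function(seq, unit_consensus, min_identity = 0.8,
                            min_full_units = 1L, merge_gap_bp = 10000L,
                            contig = "contig", seed_len = 15L) {
  if (is.null(unit_consensus) || !nzchar(unit_consensus)) {
    out <- empty_hits()
    attr(out, "skipped_reason") <- "no centromeric consensus provided"
    return(out)
  }
  unit <- toupper(as.character(unit_consensus))
  stopifnot(nchar(unit) >= 50L)
  dna <- if (is.character(seq)) Biostrings::DNAString(seq) else seq
  len <- length(dna)
  ulen <- nchar(unit)
  offsets <- unique(pmin(c(0L, ulen %/% 3L, 2L * (ulen %/% 3L), ulen - seed_len),
                         ulen - seed_len))
  cand <- integer()
  for (off in offsets) {
    word <- substr(unit, off + 1L, off + seed_len)
    m <- Biostrings::matchPattern(word, dna)
    cand <- c(cand, Biostrings::start(m) - 1L - off)
  }
  cand <- sort(unique(cand))
  cand <- cand[cand >= 0L & cand + ulen <= len]
  if (!length(cand)) return(empty_hits())
  wins <- Biostrings::DNAStringSet(Biostrings::Views(dna, start = cand + 1L,
                                                     width = ulen))
  pa <- Biostrings::pairwiseAlignment(wins, Biostrings::DNAString(unit),
                                      type = "global")
  ident <- Biostrings::pid(pa) / 100
  keep <- ident >= min_identity
  cand <- cand[keep]; ident <- ident[keep]
  if (!length(cand)) return(empty_hits())
  ## drop overlapping duplicate units (same copy seeded at shifted offsets)
  ord <- order(cand)
  cand <- cand[ord]; ident <- ident[ord]
  sel <- rep(TRUE, length(cand)); last_end <- -1L
  for (i in seq_along(cand)) {
    if (cand[i] < last_end - ulen %/% 2L) sel[i] <- FALSE
    else last_end <- cand[i] + ulen
  }
  cand <- cand[sel]; ident <- ident[sel]
  ir <- IRanges::IRanges(cand + 1L, cand + ulen)
  reg <- IRanges::reduce(ir, min.gapwidth = merge_gap_bp + 1L)
  hits <- IRanges::findOverlaps(ir, reg)
  out <- do.call(rbind, lapply(seq_along(reg), function(j) {
    src <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == j]
    feature_hit(contig, IRanges::start(reg)[j] - 1L, IRanges::end(reg)[j],
                "centromere", length(src), mean(ident[src]),
                classify_end(IRanges::start(reg)[j] - 1L, IRanges::end(reg)[j],
                             len, 10000L))
  }))
  out <- out[out$unit_count >= min_full_units, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess telomere-to-telomere status of one contig
#'
#' T2T requires a telomere array at each end (`five_prime` and
#' `three_prime` hits) and zero N characters in the sequence. Centromere
#' presence is reported and optionally required.
#'
#' @param seq Contig sequence.
#' @param telomere_hits FeatureHit rows for this contig.
#' @param centromere_hits FeatureHit rows for this contig (may be empty).
#' @param require_centromere Also require a centromere region.
#' @return list `is_t2t`, `reasons` (character vector of failures),
#'   `has_centromere`.
#' @export
assess_t2t <- function(seq, telomere_hits, centromere_hits = NULL,
                       require_centromere = FALSE) {
  dna <- if (is.character(seq)) Biostrings::DNAString(seq) else seq
  n_count <- Biostrings::countPattern("N", dna)
  has5 <- any(telomere_hits$contig_end == "five_prime")
  has3 <- any(telomere_hits$contig_end == "three_prime")
  has_cen <- !is.null(centromere_hits) && nrow(centromere_hits) > 0L
  reasons <- character()
  if (!has5) reasons <- c(reasons, "no 5' telomere")
  if (!has3) reasons <- c(reasons, "no 3' telomere")
  if (n_count > 0L) reasons <- c(reasons, "contains N")
  if (require_centromere && !has_cen) reasons <- c(reasons, "no centromere")
  list(is_t2t = length(reasons) == 0L, reasons = reasons,
       has_centromere = has_cen)
}
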