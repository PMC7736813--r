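## Selection, filtering and target-projection of assembly-to-assembly
## alignments, plus per-base mismatch extraction from difference strings.

#' Keep the primary alignment(s) per query contig
#'
#' Retains records flagged primary (PAF `tp:A:P`). When a query has no
#' flagged record, the single best alignment is kept instead: largest
#' `block_len`, ties broken by larger `n_matches`, then lowest
#' `target_start`.
#'
#' @param aln Alignment data.frame (see [read_paf()]).
#' @return Filtered alignment data.frame.
#' @export
select_primary <- function(aln) {
  if (nrow(aln) == 0L) return(aln)
  keep <- unlist(lapply(split(seq_len(nrow(aln)), aln$query_id), function(idx) {
    prim <- idx[aln$is_primary[idx]]
    if (length(prim)) return(prim)
    ord <- idx[order(-aln$block_len[idx], -aln$n_matches[idx],
                     aln$target_start[idx])]
    ord[1L]
  }), use.names = FALSE)
  out <- aln[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep reciprocal matches of at least a minimum span
#'
#' A record survives when its query span AND target span are each at least
#' `min_len_bp` (default 1 Mb, the reciprocal-match cutoff used to define
#' the comparable assembly backbone).
#'
#' @param aln Alignment data.frame.
#' @param min_len_bp Minimum span on both sequences.
#' @return Filtered alignment data.frame.
#' @export
filter_reciprocal_matches <- function(aln, min_len_bp = 1e6) {
  stopifnot(min_len_bp >= 0)
  keep <- (aln$query_end - aln$query_start) >= min_len_bp &
    (aln$target_end - aln$target_start) >= min_len_bp
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project retained alignments onto the target assembly
#'
#' Each query's alignments are mapped to merged target intervals (adjacent
#' or overlapping intervals from the same query are merged; `merge_gap_bp`
#' widens the tolerance). Identity per merged interval is
#' `sum(n_matches) / sum(block_len)` over the constituent records. Minus
#' strand alignments are projected in target coordinates; query orientation
#' never flips target intervals.
#'
#' @param aln Alignment data.frame; each query must hit a single target.
#' @param merge_gap_bp Maximum gap between same-query intervals to merge
#'   (default 0: strict adjacency).
#' @return data.frame `query_id`, `target_id`, `start`, `end` (0-based
#'   half-open target coords), `identity`.
#' @export
project_to_target <- function(aln, merge_gap_bp = 0L) {
  if (nrow(aln) == 0L)
    return(data.frame(query_id = character(), target_id = character(),
                      start = integer(), end = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(aln, aln$query_id), function(a) {
    if (length(unique(a$target_id)) > 1L)
      stop("query ", a$query_id[1], " maps to multiple targets in one group")
    ir <- IRanges::IRanges(start = a$target_start + 1L, end = a$target_end)
    merged <- IRanges::reduce(ir, min.gapwidth = merge_gap_bp + 1L)
    hits <- IRanges::findOverlaps(ir, merged)
    idn <- vapply(seq_along(merged), function(j) {
      src <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == j]
      sum(a$n_matches[src]) / sum(a$block_len[src])
    }, numeric(1))
    data.frame(query_id = a$query_id[1], target_id = a$target_id[1],
               start = IRanges::start(merged) - 1L, end = IRanges::end(merged),
               identity = idn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Projection depth over a target contig
#'
#' Integer count of projecting queries per target position, as stepwise
#' intervals.
#'
#' @param projections Projection data.frame from [project_to_target()].
#' @param target_id Target contig to profile.
#' @param target_len Its length in bp.
#' @return data.frame `start`, `end` (0-based half-open), `depth`.
#' @export
coverage_depth <- function(projections, target_id, target_len) {
  p <- projections[projections$target_id == target_id, , drop = FALSE]
  if (nrow(p) && any(p$end > target_len | p$start < 0))
    stop("projection interval outside [0, target_len)")
  ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)
  cov <- IRanges::coverage(ir, width = target_len)
  data.frame(start = cumsum(c(0L, S4Vectors::runLength(cov)))[seq_along(S4Vectors::runLength(cov))],
             end = cumsum(S4Vectors::runLength(cov)),
             depth = S4Vectors::runValue(cov))
}

#' Extract per-base mismatches from an alignment difference string
#'
#' Walks the cigar in target coordinates and emits every non-match run.
#' Substitutions require an extended difference string (`=`/`X` runs); when
#' the cigar uses plain `M` the result carries only insertions and
#' deletions, with attribute `substitutions_available = FALSE`.
#'
#' Kinds follow the query-vs-target convention: `insertion` means the query
#' carries bases absent from the target; `deletion` means target bases
#' absent from the query. A run longer than `local_threshold_bp` is
#' categorized `local`, otherwise `small_scale`.
#'
#' @param record One alignment row with a `cigar`.
#' @param local_threshold_bp Boundary between small-scale and local
#'   mismatches (default 85 bp).
#' @return data.frame `target_pos` (0-based), `kind`, `length`, `category`,
#'   with attribute `substitutions_available`.
#' @export
extract_mismatches <- function(record, local_threshold_bp = 85L) {
  stopifnot(nrow(record) == 1L, !is.na(record$cigar))
  p <- parse_cigar(record$cigar)
  cons <- cigar_consumed(record$cigar)
  if (cons[["query"]] != record$query_end - record$query_start ||
      cons[["target"]] != record$target_end - record$target_start)
    stop("inconsistent cigar for record")
  tpos <- record$target_start
  out <- list()
  for (i in seq_along(p$op)) {
    op <- p$op[i]; len <- p$len[i]
    if (op == "X") {
      out[[length(out) + 1L]] <- c(tpos, "substitution", len)
      tpos <- tpos + len
    } else if (op == "I") {
      out[[length(out) + 1L]] <- c(tpos, "insertion", len)
    } else if (op == "D") {
      out[[length(out) + 1L]] <- c(tpos, "deletion", len)
      tpos <- tpos + len
    } else if (op %in% c("M", "=")) {
      tpos <- tpos + len
    } else stop("unsupported cigar op: ", op)
  }
  res <- if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(target_pos = as.integer(m[, 1]), kind = m[, 2],
               length = as.integer(m[, 3]), stringsAsFactors = FALSE)
  } else data.frame(target_pos = integer(), kind = character(),
                    length = integer(), stringsAsFactors = FALSE)
  res$category <- ifelse(res$length > local_threshold_bp, "local", "small_scale")
  attr(res, "substitutions_available") <- !any(p$op == "M")
  res
}
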