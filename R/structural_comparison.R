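## Gap / overlap / redundancy / loss calling of a fragmented assembly (B)
## against a contiguous one (A), with repeat-context annotation and gene
## accounting.

new_call <- function(target_id, start, end, call_kind,
                     left_query = NA_character_, right_query = NA_character_,
                     similarity = NA_real_, depth_a = NA_real_,
                     depth_b = NA_real_, repeat_context = "unknown") {
  data.frame(target_id = target_id, start = start, end = end,
             call_kind = call_kind, left_query = left_query,
             right_query = right_query, similarity = similarity,
             depth_a = depth_a, depth_b = depth_b,
             repeat_context = repeat_context, stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(target_id = character(), start = integer(), end = integer(),
             call_kind = character(), left_query = character(),
             right_query = character(), similarity = numeric(),
             depth_a = numeric(), depth_b = numeric(),
             repeat_context = character(), stringsAsFactors = FALSE)
}

#' Redundancy classification criteria
#'
#' Defaults mirror the published decision rule: similarity of at least 97%
#' between the candidate copies, total read depth below 60 and each copy's
#' depth below 40 (appropriate for ~50x consensus coverage; exposed as
#' configuration).
#'
#' @param min_similarity Minimum alignment similarity between copies.
#' @param max_total_depth Combined depth must be strictly below this.
#' @param max_each_depth Each copy's depth must be strictly below this.
#' @return A list of class `redundancy_criteria`.
#' @export
redundancy_criteria <- function(min_similarity = 0.97, max_total_depth = 60,
                                max_each_depth = 40) {
  stopifnot(min_similarity > 0, min_similarity <= 1,
            max_total_depth > 0, max_each_depth > 0)
  structure(list(min_similarity = min_similarity,
                 max_total_depth = max_total_depth,
                 max_each_depth = max_each_depth),
            class = "redundancy_criteria")
}

#' Call uncovered gaps on the target assembly
#'
#' Maximal target intervals of length at least `min_gap_bp` covered by zero
#' projected intervals become `gap_uncovered` calls with flanking query ids.
#' Terminal uncovered ends get a one-sided flank.
#'
#' @param projections Projections from [project_to_target()].
#' @param target_id,target_len Target contig and its length.
#' @param min_gap_bp Minimum gap length to report (default 50; sub-50 bp
#'   boundary jitter is alignment noise, not structure).
#' @return StructuralCall data.frame.
#' @export
call_gaps <- function(projections, target_id, target_len, min_gap_bp = 50L) {
  p <- projections[projections$target_id == target_id, , drop = FALSE]
  ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)
  gaps <- IRanges::gaps(IRanges::reduce(ir), start = 1L, end = target_len)
  gaps <- gaps[IRanges::width(gaps) >= min_gap_bp]
  if (length(gaps) == 0L) return(empty_calls())
  gs <- IRanges::start(gaps) - 1L
  ge <- IRanges::end(gaps)
  left <- vapply(gs, function(s) {
    cand <- p[p$end <= s, , drop = FALSE]
    if (!nrow(cand)) NA_character_ else cand$query_id[which.max(cand$end)]
  }, character(1))
  right <- vapply(ge, function(e) {
    cand <- p[p$start >= e, , drop = FALSE]
    if (!nrow(cand)) NA_character_ else cand$query_id[which.min(cand$start)]
  }, character(1))
  new_call(target_id, gs, ge, "gap_uncovered", left, right)
}

#' Call pairwise overlaps between projections of distinct queries
#'
#' Emits one call per intersecting interval pair: the intersection interval
#' with the two query ids as flanks.
#'
#' @param projections Projections from [project_to_target()].
#' @return StructuralCall data.frame with `call_kind = "overlap"`.
#' @export
call_overlaps <- function(projections) {
  out <- list()
  for (tid in unique(projections$target_id)) {
    p <- projections[projections$target_id == tid, , drop = FALSE]
    qs <- unique(p$query_id)
    if (length(qs) < 2L) next
    for (i in seq_len(length(qs) - 1L)) for (j in seq(i + 1L, length(qs))) {
      a <- p[p$query_id == qs[i], , drop = FALSE]
      b <- p[p$query_id == qs[j], , drop = FALSE]
      ia <- IRanges::IRanges(a$start + 1L, a$end)
      ib <- IRanges::IRanges(b$start + 1L, b$end)
      ov <- IRanges::intersect(ia, ib)
      if (length(ov))
        out[[length(out) + 1L]] <-
          new_call(tid, IRanges::start(ov) - 1L, IRanges::end(ov),
                   "overlap", qs[i], qs[j])
    }
  }
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify an overlap as a redundancy
#'
#' Redundancy iff similarity >= `min_similarity` AND the two copies' depths
#' sum below `max_total_depth` AND each is below `max_each_depth`. Missing
#' depth yields `"unknown"`, never a silent redundancy call.
#'
#' @param similarity Alignment similarity between the two candidate copies.
#' @param depth_a,depth_b Mean read depth over each copy.
#' @param criteria A [redundancy_criteria()] object.
#' @return One of `"redundancy"`, `"not_redundancy"`, `"unknown"`.
#' @export
classify_redundancy <- function(similarity, depth_a, depth_b,
                                criteria = redundancy_criteria()) {
  if (is.na(depth_a) || is.na(depth_b) || is.na(similarity)) return("unknown")
  ok <- similarity >= criteria$min_similarity &&
    (depth_a + depth_b) < criteria$max_total_depth &&
    depth_a < criteria$max_each_depth && depth_b < criteria$max_each_depth
  if (ok) "redundancy" else "not_redundancy"
}

#' Classify gaps as losses or redundancies by projection coverage
#'
#' A gap interval left uncovered by the projections is a `loss`; one
#' covered at depth >= 2 over the majority of its bases is a `redundancy`;
#' single coverage yields no call (the defined dichotomy leaves it
#' uncalled).
#'
#' @param projections Projections evaluated over the gap intervals.
#' @param gaps StructuralCall data.frame of gap intervals.
#' @return StructuralCall data.frame of loss/redundancy calls.
#' @export
call_loss_and_double_cover <- function(projections, gaps) {
  if (nrow(gaps) == 0L) return(empty_calls())
  out <- list()
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    p <- projections[projections$target_id == g$target_id, , drop = FALSE]
    ir <- IRanges::IRanges(p$start + 1L, p$end)
    cov <- IRanges::coverage(ir, width = max(g$end, p$end, 1L))
    seg <- S4Vectors::window(cov, start = g$start + 1L, end = g$end)
    w <- g$end - g$start
    frac2 <- sum(S4Vectors::runLength(seg)[S4Vectors::runValue(seg) >= 2L]) / w
    all0 <- all(S4Vectors::runValue(seg) == 0L)
    kind <- if (all0) "loss" else if (frac2 > 0.5) "redundancy" else NA
    if (!is.na(kind))
      out[[length(out) + 1L]] <- new_call(g$target_id, g$start, g$end, kind,
                                          g$left_query, g$right_query)
  }
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out); rownames(res) <- NULL; res
}

#' Annotate a call's repeat context from assembly-A self-alignments
#'
#' `tandem` when a non-identity self-alignment pairs two same-contig copies
#' within `flank_dist_bp` of the call interval; `dispersed` when the
#' interval matches elsewhere at >= `min_dispersed_identity` on a different
#' contig or beyond `flank_dist_bp`; `none` otherwise; `unknown` when no
#' self-alignments are provided.
#'
#' @param calls StructuralCall data.frame.
#' @param self_aln Non-identity self-alignments of assembly A (PAF
#'   data.frame), or NULL.
#' @param flank_dist_bp Maximum distance for the tandem pairing (default
#'   100 kb).
#' @param min_dispersed_identity Identity floor for a dispersed match.
#' @return The calls with `repeat_context` filled in.
#' @export
annotate_repeat_context <- function(calls, self_aln, flank_dist_bp = 1e5,
                                    min_dispersed_identity = 0.95) {
  if (nrow(calls) == 0L) return(calls)
  if (is.null(self_aln)) { calls$repeat_context <- "unknown"; return(calls) }
  idn <- self_aln$n_matches / self_aln$block_len
  near <- function(s1, e1, s2, e2, d) (s1 - d) <= e2 & (s2 - d) <= e1
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    same <- self_aln$target_id == cl$target_id &
      self_aln$query_id == cl$target_id &
      !(self_aln$target_start == self_aln$query_start &
          self_aln$target_end == self_aln$query_end)
    ## the paired copies must flank (or contain) the call: both near it
    ## AND the call inside the span the pair covers
    span_lo <- pmin(self_aln$target_start, self_aln$query_start)
    span_hi <- pmax(self_aln$target_end, self_aln$query_end)
    tandem <- same &
      near(self_aln$target_start, self_aln$target_end, cl$start, cl$end,
           flank_dist_bp) &
      near(self_aln$query_start, self_aln$query_end, cl$start, cl$end,
           flank_dist_bp) &
      near(span_lo, span_hi, cl$start, cl$end, 0)
    if (any(tandem)) { calls$repeat_context[i] <- "tandem"; next }
    tgt_side <- self_aln$target_id == cl$target_id &
      near(self_aln$target_start, self_aln$target_end, cl$start, cl$end, 0)
    far_query <- self_aln$query_id != cl$target_id |
      !near(self_aln$query_start, self_aln$query_end, cl$start, cl$end,
            flank_dist_bp)
    dispersed <- tgt_side & far_query & idn >= min_dispersed_identity
    calls$repeat_context[i] <- if (any(dispersed)) "dispersed" else "none"
  }
  calls
}

#' Count genes gained (redundancy) and lost per structural call set
#'
#' A gene counts toward a call when at least 1 bp of its CDS overlaps the
#' call interval (configurable to whole-gene containment); each gene is
#' counted once per call kind.
#'
#' @param calls StructuralCall data.frame (kinds `redundancy` and `loss`
#'   are tallied).
#' @param genes CDS data.frame from [read_gff3()] on assembly-A coordinates.
#' @param containment Require the whole gene span inside the call interval.
#' @return list `redundancy_genes`, `loss_genes`, `per_call` breakdown.
#' @export
count_gene_gain_loss <- function(calls, genes, containment = FALSE) {
  tally <- function(kind) {
    k <- calls[calls$call_kind == kind, , drop = FALSE]
    if (!nrow(k) || !nrow(genes)) return(character())
    hits <- character()
    for (i in seq_len(nrow(k))) {
      g <- genes[genes$contig == k$target_id[i], , drop = FALSE]
      if (!nrow(g)) next
      if (containment) {
        span <- do.call(rbind, lapply(split(g, g$gene_id), function(x)
          data.frame(gene_id = x$gene_id[1], start = min(x$start),
                     end = max(x$end))))
        sel <- span$start >= k$start[i] & span$end <= k$end[i]
        hits <- c(hits, span$gene_id[sel])
      } else {
        sel <- g$start < k$end[i] & g$end > k$start[i]
        hits <- c(hits, g$gene_id[sel])
      }
    }
    unique(hits)
  }
  red <- tally("redundancy"); los <- tally("loss")
  per_call <- data.frame(call_kind = c("redundancy", "loss"),
                         n_genes = c(length(red), length(los)))
  list(redundancy_genes = length(red), loss_genes = length(los),
       redundancy_gene_ids = red, loss_gene_ids = los, per_call = per_call)
}
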