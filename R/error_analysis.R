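## Consensus-error definition from variant calls and its characterization:
## hard filters, homozygous selection, InDel lengths, spatial clustering
## versus a Poisson null, sliding-window enrichment, depth at error sites
## and GC/methylation association.

#' GATK-style hard-filter thresholds
#'
#' A variant FAILS when any condition of its class holds:
#' SNPs: QD < 2.0, MQ < 40.0, FS > 60.0, SOR > 3.0, MQRankSum < -12.5,
#' ReadPosRankSum < -8.0. InDels: QD < 2.0, FS > 200.0, SOR > 10.0,
#' MQRankSum < -12.5, ReadPosRankSum < -8.0.
#'
#' @return List of class `filter_thresholds` with `snp` and `indel` sets.
#' @export
filter_thresholds <- function() {
  structure(list(
    snp = list(min_QD = 2.0, min_MQ = 40.0, max_FS = 60.0, max_SOR = 3.0,
               min_MQRankSum = -12.5, min_ReadPosRankSum = -8.0),
    indel = list(min_QD = 2.0, max_FS = 200.0, max_SOR = 10.0,
                 min_MQRankSum = -12.5, min_ReadPosRankSum = -8.0)),
    class = "filter_thresholds")
}

#' Apply hard filters to variant records
#'
#' Records missing an annotation pass the condition that references it
#' (GATK convention: dropping them would silently bias the error set
#' toward well-annotated sites).
#'
#' @param variants Variant data.frame from [read_vcf()].
#' @param thresholds A [filter_thresholds()] object.
#' @return The passing records.
#' @export
apply_hard_filters <- function(variants, thresholds = filter_thresholds()) {
  if (nrow(variants) == 0L) return(variants)
  lt <- function(x, t) !is.na(x) & x < t
  gt <- function(x, t) !is.na(x) & x > t
  is_snp <- variants$variant_class == "substitution"
  th <- thresholds
  fail_snp <- lt(variants$QD, th$snp$min_QD) | lt(variants$MQ, th$snp$min_MQ) |
    gt(variants$FS, th$snp$max_FS) | gt(variants$SOR, th$snp$max_SOR) |
    lt(variants$MQRankSum, th$snp$min_MQRankSum) |
    lt(variants$ReadPosRankSum, th$snp$min_ReadPosRankSum)
  fail_indel <- lt(variants$QD, th$indel$min_QD) |
    gt(variants$FS, th$indel$max_FS) | gt(variants$SOR, th$indel$max_SOR) |
    lt(variants$MQRankSum, th$indel$min_MQRankSum) |
    lt(variants$ReadPosRankSum, th$indel$min_ReadPosRankSum)
  keep <- ifelse(is_snp, !fail_snp, !fail_indel)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select assembly errors from filtered variants
#'
#' Heterozygous calls represent residual heterozygosity of the sequenced
#' individual, not consensus errors; only homozygous derived alleles (1/1)
#' are kept as errors of the assembly. Positions are converted to 0-based.
#'
#' @param variants Passing variant records.
#' @return AssemblyError data.frame: `contig`, `pos` (0-based anchor),
#'   `error_kind`, `length` (1 for substitutions, allele length difference
#'   for InDels), `assembly_allele`, `evidence_allele`.
#' @export
select_assembly_errors <- function(variants) {
  v <- variants[variants$genotype == "1/1", , drop = FALSE]
  out <- data.frame(contig = v$contig, pos = v$pos - 1L,
                    error_kind = v$variant_class,
                    length = ifelse(v$variant_class == "substitution", 1L,
                                    abs(nchar(v$alt_allele) - nchar(v$ref_allele))),
                    assembly_allele = v$ref_allele,
                    evidence_allele = v$alt_allele,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' InDel length statistics
#'
#' Mean over insertion/deletion errors only; histogram capped with an
#' overflow bucket for lengths beyond `max_len`.
#'
#' @param errors AssemblyError data.frame.
#' @param max_len Histogram cap (default 20).
#' @return list `mean_bp` (NA when no InDels), `histogram` (named counts,
#'   last bucket `>max_len`), `n_indels`.
#' @export
indel_length_stats <- function(errors, max_len = 20L) {
  len <- errors$length[errors$error_kind %in% c("insertion", "deletion")]
  if (!length(len))
    return(list(mean_bp = NA_real_, histogram = integer(), n_indels = 0L))
  capped <- pmin(len, max_len + 1L)
  h <- tabulate(capped, nbins = max_len + 1L)
  names(h) <- c(as.character(seq_len(max_len)), paste0(">", max_len))
  list(mean_bp = mean(len), histogram = h, n_indels = length(len))
}

#' Distances between adjacent errors within each contig
#'
#' @param errors AssemblyError data.frame.
#' @return Integer vector of successive position differences (no
#'   cross-contig distances).
#' @export
adjacent_distances <- function(errors) {
  if (nrow(errors) == 0L) return(integer())
  unlist(lapply(split(errors$pos, errors$contig), function(p) diff(sort(p))),
         use.names = FALSE)
}

#' Simulate adjacent-error distances under random placement
#'
#' Errors are placed as a homogeneous Poisson process along the genome;
#' adjacent distances are then exponential with mean `1000 / rate_per_kb`
#' bp, which is what "randomly and evenly distributed" errors would show.
#'
#' @param rate_per_kb Error rate per kb (> 0).
#' @param genome_len_bp Sequence length to simulate over.
#' @param seed Optional seed for reproducibility.
#' @return list `distances`, `mean_bp`, `n_errors`.
#' @export
random_placement_null <- function(rate_per_kb, genome_len_bp, seed = NULL) {
  stopifnot(rate_per_kb > 0, genome_len_bp > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- stats::rpois(1L, rate_per_kb * genome_len_bp / 1000)
  pos <- sort(stats::runif(n, 0, genome_len_bp))
  d <- diff(pos)
  list(distances = d, mean_bp = if (length(d)) mean(d) else NA_real_,
       n_errors = n)
}

#' Test observed adjacent-error distances for clustering
#'
#' One-sample Kolmogorov-Smirnov test of the observed distances against the
#' exponential law with mean `1000 / rate_per_kb` bp. Verdict `"clustered"`
#' when the test rejects at `alpha` AND the observed median lies below the
#' exponential median (clustering shortens distances).
#'
#' @param distances Observed adjacent distances (bp).
#' @param rate_per_kb Genome-wide error rate per kb defining the null.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum number of distances (default 10); below it the
#'   verdict is `"undetermined"`.
#' @return list `ks_statistic`, `p_value`, `verdict`.
#' @export
clustering_test <- function(distances, rate_per_kb, alpha = 0.05, min_n = 10L) {
  if (length(distances) < min_n)
    return(list(ks_statistic = NA_real_, p_value = NA_real_,
                verdict = "undetermined"))
  rate <- rate_per_kb / 1000
  ks <- suppressWarnings(stats::ks.test(distances, "pexp", rate = rate))
  clustered <- ks$p.value < alpha &&
    stats::median(distances) < stats::qexp(0.5, rate)
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       verdict = if (clustered) "clustered" else "not_clustered")
}

#' Sliding-window error scan
#'
#' Tiles each contig with windows of `window_bp` advancing by `step_bp`
#' (the final short window is kept and flagged), counts errors per window
#' by half-open position membership, computes GC fraction from the
#' sequence and the mean methylated fraction of retained sites, and flags
#' windows with at least `min_count` errors as error-enriched.
#'
#' @param errors AssemblyError data.frame.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window_bp,step_bp Window width and step (defaults 1000/500).
#' @param min_count Enrichment threshold (default 5 errors).
#' @param genome Optional [Biostrings::DNAStringSet] for GC content.
#' @param methylation Optional methylation site data.frame (already
#'   support-filtered).
#' @return ErrorWindow data.frame: `contig`, `start`, `end`, `error_count`,
#'   `gc_fraction`, `methylation_level`, `enriched`, `short_window`.
#' @export
window_error_scan <- function(errors, contig_lengths, window_bp = 1000L,
                              step_bp = 500L, min_count = 5L, genome = NULL,
                              methylation = NULL) {
  stopifnot(window_bp >= step_bp, step_bp > 0)
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(0L, max(len - 1L, 0L), by = step_bp)
    ends <- pmin(starts + window_bp, len)
    win <- IRanges::IRanges(starts + 1L, ends)
    epos <- errors$pos[errors$contig == ctg]
    cnt <- IRanges::countOverlaps(win, IRanges::IRanges(epos + 1L, epos + 1L))
    gc <- rep(NA_real_, length(win))
    if (!is.null(genome) && ctg %in% names(genome)) {
      v <- Biostrings::Views(genome[[ctg]], start = starts + 1L, end = ends)
      fr <- Biostrings::letterFrequency(v, letters = c("G", "C"))
      gc <- rowSums(fr) / (ends - starts)
    }
    ml <- rep(NA_real_, length(win))
    if (!is.null(methylation)) {
      ms <- methylation[methylation$contig == ctg, , drop = FALSE]
      if (nrow(ms)) {
        hits <- IRanges::findOverlaps(win, IRanges::IRanges(ms$pos + 1L, ms$pos + 1L))
        if (length(hits)) {
          agg <- tapply(ms$methylated_fraction[S4Vectors::subjectHits(hits)],
                        S4Vectors::queryHits(hits), mean)
          ml[as.integer(names(agg))] <- as.numeric(agg)
        }
      }
    }
    data.frame(contig = ctg, start = starts, end = ends, error_count = cnt,
               gc_fraction = gc, methylation_level = ml,
               enriched = cnt >= min_count,
               short_window = (ends - starts) < window_bp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contrast GC and methylation between enriched and other windows
#'
#' Two-sided Mann-Whitney U tests comparing error-enriched windows against
#' the rest, for GC fraction and methylation level, with group medians for
#' effect direction. A test is skipped (with a reason) when either group
#' has fewer than two windows with data.
#'
#' @param windows ErrorWindow data.frame from [window_error_scan()].
#' @return list `gc_test`, `methylation_test`; each is either a list with
#'   `p_value`, `median_enriched`, `median_other`, `direction` or a list
#'   with `skipped` and `reason`.
#' @export
contrast_enriched_windows <- function(windows) {
  one <- function(values) {
    enr <- values[windows$enriched]; oth <- values[!windows$enriched]
    enr <- enr[!is.na(enr)]; oth <- oth[!is.na(oth)]
    if (length(enr) < 2L || length(oth) < 2L)
      return(list(skipped = TRUE,
                  reason = "fewer than 2 windows with data in a group"))
    w <- suppressWarnings(stats::wilcox.test(enr, oth, alternative = "two.sided"))
    me <- stats::median(enr); mo <- stats::median(oth)
    list(skipped = FALSE, p_value = w$p.value, statistic = unname(w$statistic),
         median_enriched = me, median_other = mo,
         direction = if (me > mo) "higher_in_enriched"
                     else if (me < mo) "lower_in_enriched" else "equal")
  }
  list(gc_test = one(windows$gc_fraction),
       methylation_test = one(windows$methylation_level))
}

#' Fraction of error sites at or below a depth cutoff
#'
#' @param errors AssemblyError data.frame.
#' @param depth_track Depth track data.frame (short-read depths).
#' @param cutoff Inclusive depth cutoff (default 5).
#' @return list `fraction_at_or_below`, `n_missing_depth`, `n_errors`.
#' @export
error_site_depth_summary <- function(errors, depth_track, cutoff = 5) {
  d <- depth_at(depth_track, errors$contig, errors$pos)
  known <- !is.na(d)
  list(fraction_at_or_below = if (any(known)) mean(d[known] <= cutoff) else NA_real_,
       n_missing_depth = sum(!known), n_errors = nrow(errors))
}

#' Genome-wide error rate per kb
#'
#' @param errors AssemblyError data.frame.
#' @param denominator_bp Length of the region the errors were called over
#'   (full assembly or the reciprocal-match backbone).
#' @return Errors per kb.
#' @export
error_rate_per_kb <- function(errors, denominator_bp) {
  stopifnot(denominator_bp > 0)
  nrow(errors) / denominator_bp * 1000
}
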