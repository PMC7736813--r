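## End-to-end orchestration: read every input, run the structural, error,
## coding and chromosome-feature analyses in dependency order, and emit a
## machine-readable report plus per-module tables.

#' Validate and assemble a run configuration
#'
#' All referenced files must exist at validation time. Optional inputs
#' (self-alignments, methylation, depth tracks, centromeric consensus) may
#' be NULL: the corresponding analyses are skipped and flagged, not failed.
#'
#' @param assembly_a,assembly_b FASTA paths.
#' @param paf B-onto-A alignment PAF path.
#' @param vcf Variant calls (reads vs. assembly A) VCF path.
#' @param gff3 Gene models on assembly A.
#' @param self_paf Optional assembly-A self-alignment PAF.
#' @param methylation Optional methylation TSV.
#' @param depth_shotgun,depth_consensus Optional depth TSVs.
#' @param centromere_consensus Optional FASTA with the centromeric repeat
#'   unit.
#' @param min_gap_bp,min_reciprocal_bp,local_threshold_bp Structural
#'   thresholds.
#' @param redundancy [redundancy_criteria()].
#' @param thresholds [filter_thresholds()].
#' @param window_bp,step_bp,min_window_errors Error-window parameters.
#' @param min_called_sites Methylation read-support threshold.
#' @param depth_cutoff Shotgun-depth cutoff for the error-site summary.
#' @return list of class `run_config`.
#' @export
run_config <- function(assembly_a, assembly_b, paf, vcf, gff3,
                       self_paf = NULL, methylation = NULL,
                       depth_shotgun = NULL, depth_consensus = NULL,
                       centromere_consensus = NULL,
                       min_gap_bp = 50L, min_reciprocal_bp = 0,
                       local_threshold_bp = 85L,
                       redundancy = redundancy_criteria(),
                       thresholds = filter_thresholds(),
                       window_bp = 1000L, step_bp = 500L,
                       min_window_errors = 5L, min_called_sites = 10L,
                       depth_cutoff = 5) {
  cfg <- as.list(environment())
  req <- c("assembly_a", "assembly_b", "paf", "vcf", "gff3")
  opt <- c("self_paf", "methylation", "depth_shotgun", "depth_consensus",
           "centromere_consensus")
  for (f in req)
    if (!file.exists(cfg[[f]])) stop("input file missing: ", f, " = ", cfg[[f]])
  for (f in opt)
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file missing: ", f, " = ", cfg[[f]])
  structure(cfg, class = "run_config")
}

mean_track_depth <- function(track, contig, start, end) {
  if (is.null(track)) return(NA_real_)
  tr <- track[track$contig == contig & track$end > start & track$start < end, ,
              drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  w <- pmin(tr$end, end) - pmax(tr$start, start)
  sum(tr$depth * w) / sum(w)
}

#' Run the full two-assembly comparison
#'
#' Executes the modules in dependency order: alignment selection and
#' projection, gap/overlap/redundancy/loss calling with repeat-context
#' annotation and gene accounting, hard-filtered error selection with
#' clustering, window-enrichment, depth and methylation analyses,
#' coding-impact classification, and telomere/centromere/T2T assessment.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, per-module TSVs,
#'   `report.json` and `report.txt` are written.
#' @return The comparison report (list).
#' @export
run_compare <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  genome_a <- read_assembly_fasta(config$assembly_a)
  genome_b <- read_assembly_fasta(config$assembly_b)
  aln <- read_paf(config$paf)
  self_aln <- if (!is.null(config$self_paf)) read_paf(config$self_paf) else NULL
  variants <- read_vcf(config$vcf)
  genes <- read_gff3(config$gff3)
  meth <- if (!is.null(config$methylation))
    read_methylation_table(config$methylation, config$min_called_sites) else NULL
  dep_sh <- if (!is.null(config$depth_shotgun))
    read_depth_track(config$depth_shotgun) else NULL
  dep_co <- if (!is.null(config$depth_consensus))
    read_depth_track(config$depth_consensus) else NULL
  cen_unit <- if (!is.null(config$centromere_consensus))
    as.character(read_assembly_fasta(config$centromere_consensus)[[1]]) else NULL

  lens_a <- stats::setNames(Biostrings::width(genome_a), names(genome_a))

  ## structural arm
  aln_p <- select_primary(aln)
  if (config$min_reciprocal_bp > 0)
    aln_p <- filter_reciprocal_matches(aln_p, config$min_reciprocal_bp)
  proj <- project_to_target(aln_p)
  calls <- list()
  for (tid in names(lens_a)) {
    gaps <- call_gaps(proj, tid, lens_a[[tid]], config$min_gap_bp)
    ovl <- call_overlaps(proj[proj$target_id == tid, , drop = FALSE])
    if (nrow(ovl)) for (i in seq_len(nrow(ovl))) {
      pr <- proj[proj$target_id == tid &
                   proj$query_id %in% c(ovl$left_query[i], ovl$right_query[i]), ,
                 drop = FALSE]
      hit <- pr$start < ovl$end[i] & pr$end > ovl$start[i]
      ovl$similarity[i] <- mean(pr$identity[hit])
      ## reads mapped to the redundant assembly split across the two
      ## copies: model per-copy depth as half the A-track depth
      d <- mean_track_depth(dep_co, tid, ovl$start[i], ovl$end[i])
      ovl$depth_a[i] <- d / 2; ovl$depth_b[i] <- d / 2
      verdict <- classify_redundancy(ovl$similarity[i], ovl$depth_a[i],
                                     ovl$depth_b[i], config$redundancy)
      if (verdict == "redundancy") ovl$call_kind[i] <- "redundancy"
    }
    losses <- call_loss_and_double_cover(proj, gaps)
    calls[[length(calls) + 1L]] <- rbind(gaps, ovl, losses)
  }
  calls <- do.call(rbind, calls)
  calls <- annotate_repeat_context(calls, self_aln)
  gene_counts <- count_gene_gain_loss(calls, genes)

  ## error arm
  passing <- apply_hard_filters(variants, config$thresholds)
  errors <- select_assembly_errors(passing)
  istats <- indel_length_stats(errors)
  dists <- adjacent_distances(errors)
  total_len <- sum(lens_a)
  backbone_len <- sum(proj$end - proj$start)
  rate_full <- error_rate_per_kb(errors, total_len)
  clust <- clustering_test(dists, rate_full)
  windows <- window_error_scan(errors, lens_a,
                               window_bp = config$window_bp,
                               step_bp = config$step_bp,
                               min_count = config$min_window_errors,
                               genome = genome_a, methylation = meth)
  contrasts <- if (!is.null(meth)) contrast_enriched_windows(windows) else
    list(gc_test = contrast_enriched_windows(windows)$gc_test,
         methylation_test = list(skipped = TRUE,
                                 reason = "no methylation table provided"))
  depth_summary <- if (!is.null(dep_sh))
    error_site_depth_summary(errors, dep_sh, config$depth_cutoff) else
      list(skipped = TRUE, reason = "no shotgun depth track provided")

  ## coding arm
  coding <- count_affected(errors, genes, genome_a)

  ## feature arm
  feature_rows <- list(); t2t <- list()
  for (nm in names(genome_a)) {
    tel <- find_telomere_arrays(genome_a[[nm]], contig = nm)
    cen <- find_centromere(genome_a[[nm]], cen_unit, contig = nm)
    feature_rows[[length(feature_rows) + 1L]] <- rbind(tel, cen)
    v <- assess_t2t(genome_a[[nm]], tel, cen)
    t2t[[length(t2t) + 1L]] <- data.frame(
      contig = nm, is_t2t = v$is_t2t, has_centromere = v$has_centromere,
      reasons = paste(v$reasons, collapse = "; "), stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feature_rows)
  t2t <- do.call(rbind, t2t)

  report <- list(
    structural = list(
      n_calls = nrow(calls),
      by_kind = as.list(table(calls$call_kind)),
      bp_by_kind = as.list(tapply(calls$end - calls$start, calls$call_kind, sum)),
      redundancy_genes = gene_counts$redundancy_genes,
      loss_genes = gene_counts$loss_genes),
    errors = list(
      n_errors = nrow(errors),
      by_kind = as.list(table(errors$error_kind)),
      mean_indel_bp = istats$mean_bp,
      rate_per_kb_full = rate_full,
      rate_per_kb_backbone = if (backbone_len > 0)
        error_rate_per_kb(errors, backbone_len) else NA_real_,
      clustering = clust,
      n_enriched_windows = sum(windows$enriched),
      contrasts = contrasts,
      depth_at_errors = depth_summary),
    coding = coding[c("affected_exons", "affected_genes",
                      "affected_exons_strict", "affected_genes_strict")],
    features = list(n_telomeres = sum(features$feature == "telomere"),
                    n_centromeres = sum(features$feature == "centromere"),
                    n_t2t = sum(t2t$is_t2t)),
    tables = list(calls = calls, errors = errors, windows = windows,
                  per_error_impact = coding$per_error, features = features,
                  t2t = t2t))
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tab <- report$tables
  wt <- function(df, f) utils::write.table(df, file.path(outdir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(tab$calls, "structural_calls.tsv")
  wt(tab$errors, "errors.tsv")
  wt(tab$windows, "windows.tsv")
  wt(tab$per_error_impact, "coding_impact.tsv")
  wt(tab$features, "features.tsv")
  wt(tab$t2t, "t2t.tsv")
  slim <- report[setdiff(names(report), "tables")]
  jsonlite::write_json(slim, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  txt <- c(
    sprintf("structural calls: %d (redundancy genes %d, loss genes %d)",
            report$structural$n_calls, report$structural$redundancy_genes,
            report$structural$loss_genes),
    sprintf("errors: %d (%.3f per kb); clustering: %s",
            report$errors$n_errors, report$errors$rate_per_kb_full,
            report$errors$clustering$verdict),
    sprintf("error-enriched windows: %d", report$errors$n_enriched_windows),
    sprintf("affected exons/genes: %d/%d (strict %d/%d)",
            report$coding$affected_exons, report$coding$affected_genes,
            report$coding$affected_exons_strict,
            report$coding$affected_genes_strict),
    sprintf("telomeres %d, centromeres %d, T2T contigs %d",
            report$features$n_telomeres, report$features$n_centromeres,
            report$features$n_t2t))
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(report)
}
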