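## Synthetic-truth generator: a truth genome with planted repeat structure,
## a fragmented but accurate assembly B, a contiguous but error-prone
## assembly A, companion tracks (variants, methylation, read depths) and a
## complete planted-event ledger. Everything is a pure function of
## (config, seed).

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: a
#' fragmented assembly broken at repeats of 14-48 kb (beyond the
#' consensus-read span proxy of 20 kb), a contiguous assembly carrying
#' 1.06 errors per kb with geometric InDel lengths of mean 1.39 bp, half
#' of the errors clustered inside high-methylation / low-short-read-depth
#' windows, heterozygous sites at 0.5 per kb and 5% spurious filter-failing
#' calls.
#'
#' @param seed Integer seed; every derived output is deterministic in it.
#' @param n_chromosomes,chromosome_len_bp Genome shape.
#' @param gc_target Background GC fraction.
#' @param gene_density Genes per Mb.
#' @param tandem_repeat_lengths Tandem repeat unit lengths (bp), cycled
#'   across chromosomes.
#' @param tandem_copies Copies per tandem array.
#' @param dispersed_dup_lengths Dispersed duplication lengths (bp), cycled;
#'   each plants two copies on different chromosomes at >= 97% identity.
#' @param telomere_units Motif copies per telomere array.
#' @param telomere_motif Telomere repeat unit.
#' @param centromere_unit_bp,centromere_units Centromeric repeat unit
#'   length and copies per array.
#' @param error_rate_per_kb Homozygous consensus-error rate on assembly A.
#' @param clustered_error_fraction Fraction of errors placed inside
#'   designated high-methylation windows.
#' @param cluster_window_bp Width of those windows.
#' @param errors_per_cluster Mean planted errors per cluster window.
#' @param het_site_rate_per_kb Heterozygous (0/1) site rate.
#' @param indel_mean_bp Mean InDel length (geometric law).
#' @param indel_fraction Fraction of errors that are InDels.
#' @param filter_fail_fraction Spurious 1/1 records with failing
#'   annotations, as a fraction of the error count.
#' @param read_len_proxy_bp Repeat length above which assembly B breaks.
#' @param gap_mode_weight Probability a break is an uncovered gap (vs. an
#'   overlap redundancy).
#' @param meth_site_spacing_bp Spacing of methylation sites.
#' @param shotgun_depth,consensus_depth Mean depths of the short-read and
#'   consensus long-read tracks.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 2L, chromosome_len_bp = 1e7,
                       gc_target = 0.435, gene_density = 40,
                       tandem_repeat_lengths = c(14000L, 23000L, 48000L),
                       tandem_copies = 2L,
                       dispersed_dup_lengths = c(48000L, 15000L),
                       telomere_units = 100L, telomere_motif = "AAACCCT",
                       centromere_unit_bp = 155L, centromere_units = 50L,
                       error_rate_per_kb = 1.06,
                       clustered_error_fraction = 0.5,
                       cluster_window_bp = 1000L, errors_per_cluster = 8,
                       het_site_rate_per_kb = 0.5, indel_mean_bp = 1.39,
                       indel_fraction = 0.5, filter_fail_fraction = 0.05,
                       read_len_proxy_bp = 20000L, gap_mode_weight = 0.5,
                       meth_site_spacing_bp = 200L, shotgun_depth = 30,
                       consensus_depth = 28) {
  cfg <- as.list(environment())
  stopifnot(cfg$error_rate_per_kb >= 0, cfg$het_site_rate_per_kb >= 0,
            cfg$clustered_error_fraction >= 0, cfg$clustered_error_fraction <= 1,
            cfg$indel_fraction >= 0, cfg$indel_fraction <= 1,
            cfg$filter_fail_fraction >= 0, cfg$gc_target > 0, cfg$gc_target < 1,
            all(cfg$tandem_repeat_lengths > 0),
            all(cfg$dispersed_dup_lengths > 0),
            cfg$chromosome_len_bp > 0, cfg$indel_mean_bp >= 1)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

## allocate a free slot of width w on [margin, L - margin), away from
## occupied intervals (given as a 2-column matrix of 0-based half-open)
alloc_slot <- function(occ, L, w, margin, pad = 1000L) {
  lo <- margin; hi <- L - margin - w
  if (hi <= lo) stop("requested features exceed chromosome length")
  for (try in 1:500) {
    s <- lo + sample.int(hi - lo, 1L)
    if (!nrow(occ) || all(s >= occ[, 2] + pad | (s + w) <= occ[, 1] - pad))
      return(s)
  }
  stop("requested features exceed chromosome length (no free slot)")
}

make_gene <- function(gid, contig, strand, gc) {
  n_exons <- sample(2:4, 1L)
  n_codons <- sample(60:200, 1L)
  codons <- c("ATG",
              sample(setdiff(mkAllTriplets(), c("TAA", "TAG", "TGA")),
                     n_codons - 2L, replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  cuts <- sort(sample(seq(30L, nchar(cds) - 30L), n_exons - 1L))
  bounds <- c(0L, cuts, nchar(cds))
  pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- vapply(seq_len(n_exons - 1L),
                    function(i) random_dna(sample(80:300, 1L), gc), character(1))
  g <- character(2L * n_exons - 1L)
  g[seq(1L, length(g), 2L)] <- pieces
  if (n_exons > 1L) g[seq(2L, length(g), 2L)] <- introns
  region <- paste(g, collapse = "")
  lens <- nchar(g)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  ex <- seq(1L, length(g), 2L)
  iv <- data.frame(start = starts[ex], end = starts[ex] + lens[ex])
  if (strand == "-") {
    Lg <- nchar(region)
    region <- revcomp_chr(region)
    iv <- data.frame(start = Lg - iv$end, end = Lg - iv$start)
    iv <- iv[order(iv$start), ]
  }
  list(region = region,
       cds = data.frame(gene_id = gid, contig = contig, strand = strand,
                        start = iv$start, end = iv$end,
                        exon_index = seq_len(nrow(iv)),
                        stringsAsFactors = FALSE))
}

mkAllTriplets <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Generate the truth genome with its planted-feature ledger
#'
#' Random background sequence at the target GC with telomere arrays at both
#' chromosome ends, one centromeric repeat array per chromosome, tandem
#' repeat arrays and cross-chromosome dispersed duplications (mutual
#' identity >= 97%), and non-overlapping multi-exon gene models.
#' Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return list `genome` (named character vector), `genes` (CDS
#'   data.frame), `repeats` (planted repeat/feature ledger),
#'   `centromere_consensus`, `config`.
#' @export
generate_truth_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_chromosomes; L <- as.integer(config$chromosome_len_bp)
  tel_len <- nchar(config$telomere_motif) * config$telomere_units
  cen_unit <- random_dna(config$centromere_unit_bp, 0.42)
  margin <- tel_len + 5000L

  feats <- vector("list", n)      # per chrom: list of (start, str, kind, ...)
  occ <- vector("list", n)
  repeat_genes <- list()
  chrom_names <- paste0("chr", seq_len(n))
  repeats <- list()
  add_feat <- function(ci, start, str, kind, unit_len = NA_integer_,
                       pair_id = NA_character_, copy = NA_integer_,
                       unit_count = NA_integer_) {
    feats[[ci]][[length(feats[[ci]]) + 1L]] <<- list(start = start, str = str)
    occ[[ci]] <<- rbind(occ[[ci]], c(start, start + nchar(str)))
    repeats[[length(repeats) + 1L]] <<- data.frame(
      contig = chrom_names[ci], start = start, end = start + nchar(str),
      kind = kind, unit_len = unit_len, pair_id = pair_id, copy = copy,
      unit_count = unit_count, stringsAsFactors = FALSE)
  }

  for (ci in seq_len(n)) {
    feats[[ci]] <- list(); occ[[ci]] <- matrix(numeric(0), ncol = 2)
    tel5 <- strrep(config$telomere_motif, config$telomere_units)
    tel3 <- strrep(revcomp_chr(config$telomere_motif), config$telomere_units)
    add_feat(ci, 0L, tel5, "telomere", nchar(config$telomere_motif),
             copy = 1L, unit_count = config$telomere_units)
    add_feat(ci, L - tel_len, tel3, "telomere", nchar(config$telomere_motif),
             copy = 2L, unit_count = config$telomere_units)
    cen <- paste(vapply(seq_len(config$centromere_units),
                        function(i) mutate_dna(cen_unit, 0.02), character(1)),
                 collapse = "")
    cen_start <- as.integer(L / 2 - nchar(cen) / 2)
    add_feat(ci, cen_start, cen, "centromere", config$centromere_unit_bp,
             unit_count = config$centromere_units)
    ulen <- config$tandem_repeat_lengths[((ci - 1L) %% length(config$tandem_repeat_lengths)) + 1L]
    unit <- random_dna(ulen, config$gc_target)
    ## each repeat unit hosts one gene (when genes are requested), so
    ## redundancies and losses carry annotated genes as in real
    ## long-repeat misassemblies
    off <- ulen %/% 3L
    gt <- NULL
    if (config$gene_density > 0) {
      gt <- make_gene("placeholder", chrom_names[ci], "+", config$gc_target)
      unit <- paste0(substr(unit, 1L, off), gt$region,
                     substr(unit, off + nchar(gt$region) + 1L, ulen))
    }
    arr <- strrep(unit, config$tandem_copies)
    s <- alloc_slot(occ[[ci]], L, nchar(arr), margin)
    add_feat(ci, s, arr, "tandem", ulen, pair_id = paste0("tand_", ci),
             unit_count = config$tandem_copies)
    if (!is.null(gt)) for (cp in seq_len(config$tandem_copies)) {
      cds <- gt$cds
      cds$gene_id <- sprintf("gr_t%d_c%d", ci, cp)
      cds$start <- cds$start + s + (cp - 1L) * ulen + off
      cds$end <- cds$end + s + (cp - 1L) * ulen + off
      repeat_genes[[length(repeat_genes) + 1L]] <- cds
    }
  }
  if (n >= 2L) {
    for (ci in seq_len(n)) {
      dlen <- config$dispersed_dup_lengths[((ci - 1L) %% length(config$dispersed_dup_lengths)) + 1L]
      seg <- random_dna(dlen, config$gc_target)
      doff <- dlen %/% 3L
      gd <- NULL
      if (config$gene_density > 0) {
        gd <- make_gene("placeholder", chrom_names[ci], "+", config$gc_target)
        seg <- paste0(substr(seg, 1L, doff), gd$region,
                      substr(seg, doff + nchar(gd$region) + 1L, dlen))
      }
      cj <- (ci %% n) + 1L
      s1 <- alloc_slot(occ[[ci]], L, dlen, margin)
      add_feat(ci, s1, seg, "dispersed", dlen, pair_id = paste0("disp_", ci),
               copy = 1L, unit_count = 1L)
      s2 <- alloc_slot(occ[[cj]], L, dlen, margin)
      add_feat(cj, s2, mutate_dna(seg, 0.01), "dispersed", dlen,
               pair_id = paste0("disp_", ci), copy = 2L, unit_count = 1L)
      if (!is.null(gd)) for (cp in 1:2) {
        cds <- gd$cds
        cds$gene_id <- sprintf("gr_d%d_c%d", ci, cp)
        cds$contig <- chrom_names[if (cp == 1L) ci else cj]
        cds$start <- cds$start + (if (cp == 1L) s1 else s2) + doff
        cds$end <- cds$end + (if (cp == 1L) s1 else s2) + doff
        repeat_genes[[length(repeat_genes) + 1L]] <- cds
      }
    }
  }
  genes <- repeat_genes
  for (ci in seq_len(n)) {
    n_genes <- round(config$gene_density * L / 1e6)
    for (gi in seq_len(n_genes)) {
      gid <- sprintf("g%02d_%04d", ci, gi)
      gene <- make_gene(gid, chrom_names[ci],
                        if (stats::runif(1) < 0.5) "+" else "-",
                        config$gc_target)
      s <- alloc_slot(occ[[ci]], L, nchar(gene$region), margin, pad = 200L)
      feats[[ci]][[length(feats[[ci]]) + 1L]] <- list(start = s, str = gene$region)
      occ[[ci]] <- rbind(occ[[ci]], c(s, s + nchar(gene$region)))
      gene$cds$start <- gene$cds$start + s
      gene$cds$end <- gene$cds$end + s
      genes[[length(genes) + 1L]] <- gene$cds
    }
  }
  genome <- character(n); names(genome) <- chrom_names
  for (ci in seq_len(n)) {
    bg <- random_dna(L, config$gc_target)
    fs <- feats[[ci]]
    ord <- order(vapply(fs, `[[`, numeric(1), "start"))
    parts <- character(0); cur <- 0L
    for (f in fs[ord]) {
      parts <- c(parts, substr(bg, cur + 1L, f$start), f$str)
      cur <- f$start + nchar(f$str)
    }
    parts <- c(parts, substr(bg, cur + 1L, L))
    genome[ci] <- paste(parts, collapse = "")
    stopifnot(nchar(genome[ci]) == L)
  }
  genes_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), contig = character(), strand = character(),
               start = integer(), end = integer(), exon_index = integer())
  list(genome = genome, genes = genes_df,
       repeats = do.call(rbind, repeats),
       centromere_consensus = cen_unit, config = config)
}

## interval membership helper: is position p inside any [s,e) row?
in_zone <- function(p, zones) {
  if (!nrow(zones)) return(rep(FALSE, length(p)))
  ir <- IRanges::IRanges(zones$start + 1L, zones$end)
  IRanges::countOverlaps(IRanges::IRanges(p + 1L, p + 1L), ir) > 0L
}

map_truth_to_a <- function(events, p) {
  ## A coordinate of truth position p given sorted edit events
  ## (t_anchor, delta); events strictly before p shift it
  if (!nrow(events)) return(p)
  cum <- c(0L, cumsum(events$delta))
  idx <- findInterval(p - 1L, events$t_anchor)
  p + cum[idx + 1L]
}

#' Derive the contiguous, error-prone assembly A
#'
#' A contiguous copy of each truth chromosome with homozygous substitution
#' and small-InDel errors planted at `error_rate_per_kb`; a
#' `clustered_error_fraction` of the errors sits inside designated
#' high-methylation windows which also receive short-read depth <= 5.
#' InDel lengths are geometric with the configured mean. Heterozygous
#' sites are planted separately and emitted as 0/1; all homozygous errors
#' are emitted as 1/1 with passing site annotations, plus spurious 1/1
#' records with failing annotations to exercise the hard filters.
#' Telomere and centromere arrays are excluded from error planting, and
#' InDel anchors keep clear of repeat and CDS boundaries, so planted
#' intervals remain unambiguous.
#'
#' @param truth Output of [generate_truth_genome()].
#' @param config The same [sim_config()].
#' @return list `assembly_a` (named character vector), `planted_errors`
#'   (AssemblyError ledger, A coordinates), `truth_vcf` (variant
#'   data.frame as from [read_vcf()]), `events` (truth->A edit table),
#'   `genes_a` (gene models lifted to A), `high_meth_windows`,
#'   `methylation_sites`, `depth_shotgun`, `depth_consensus`.
#' @export
derive_assembly_a <- function(truth, config) {
  set.seed(config$seed + 1000L)
  n <- length(truth$genome)
  out_seq <- character(n); names(out_seq) <- names(truth$genome)
  errors <- list(); vcf <- list(); events_all <- list(); hmw <- list()
  meth <- list(); dsh <- list(); dco <- list()
  bases <- c("A", "C", "G", "T")
  p_geom <- 1 / config$indel_mean_bp

  for (ci in seq_len(n)) {
    ctg <- names(truth$genome)[ci]
    seq_t <- truth$genome[[ci]]
    L <- nchar(seq_t)
    rep_c <- truth$repeats[truth$repeats$contig == ctg, , drop = FALSE]
    gen_c <- truth$genes[truth$genes$contig == ctg, , drop = FALSE]
    hard <- rep_c[rep_c$kind %in% c("telomere", "centromere"), c("start", "end")]
    hard$start <- hard$start - 50L; hard$end <- hard$end + 50L
    bnd <- c(rep_c$start[rep_c$kind %in% c("tandem", "dispersed")],
             rep_c$end[rep_c$kind %in% c("tandem", "dispersed")])
    indel_zone <- rbind(
      data.frame(start = bnd - 200L, end = bnd + 200L),
      data.frame(start = gen_c$start - 12L, end = gen_c$start + 12L),
      data.frame(start = gen_c$end - 12L, end = gen_c$end + 12L))

    n_err <- stats::rpois(1L, config$error_rate_per_kb * L / 1000)
    n_clu <- round(config$clustered_error_fraction * n_err)
    n_win <- max(if (n_clu > 0) 1L else 0L,
                 ceiling(n_clu / config$errors_per_cluster))
    win_occ <- rbind(as.matrix(hard),
                     as.matrix(indel_zone[, c("start", "end")]))
    win_starts <- integer(0)
    for (wi in seq_len(n_win)) {
      s <- alloc_slot(matrix(win_occ, ncol = 2), L, config$cluster_window_bp,
                      margin = nchar(config$telomere_motif) * config$telomere_units + 2000L,
                      pad = 500L)
      win_starts <- c(win_starts, s)
      win_occ <- rbind(win_occ, c(s, s + config$cluster_window_bp))
    }
    windows <- data.frame(start = win_starts,
                          end = win_starts + config$cluster_window_bp)

    draw_scatter <- function(k) {
      p <- integer(0)
      while (length(p) < k) {
        cand <- sample.int(L - 2L * 7500L, 2L * k) + 7500L
        ok <- !in_zone(cand, hard) & !in_zone(cand, windows)
        p <- c(p, cand[ok])
      }
      p[seq_len(k)]
    }
    draw_cluster <- function(k) {
      if (k == 0L) return(integer(0))
      wi <- sample.int(nrow(windows), k, replace = TRUE)
      windows$start[wi] + sample.int(config$cluster_window_bp - 20L, k,
                                     replace = TRUE) + 10L
    }
    pos <- c(draw_scatter(n_err - n_clu), draw_cluster(n_clu))
    clustered <- c(rep(FALSE, n_err - n_clu), rep(TRUE, n_clu))
    ## resample until anchors are >= 12 bp apart (edits must not overlap)
    for (it in 1:200) {
      ord <- order(pos)
      pos <- pos[ord]; clustered <- clustered[ord]
      bad <- which(diff(pos) < 12L) + 1L
      if (!length(bad)) break
      pos[bad] <- ifelse(clustered[bad], draw_cluster(length(bad)),
                         draw_scatter(length(bad)))
    }
    is_indel <- stats::runif(n_err) < config$indel_fraction
    is_indel <- is_indel & !in_zone(pos, indel_zone)
    ilen <- integer(n_err)
    ilen[is_indel] <- pmin(stats::rgeom(sum(is_indel), p_geom) + 1L, 8L)
    ## kind in VCF convention relative to assembly A:
    ## insertion = A lacks truth bases; deletion = A carries extra bases
    kind <- ifelse(!is_indel, "substitution",
                   ifelse(stats::runif(n_err) < 0.5, "insertion", "deletion"))
    tb <- if (n_err > 0L) substring(seq_t, pos + 1L, pos + 1L) else character(0)

    parts <- character(2L * n_err + 1L); np <- 0L; cur <- 0L
    put <- function(x) { np <<- np + 1L; parts[np] <<- x }
    delta <- integer(n_err); refs <- character(n_err); alts <- character(n_err)
    for (i in seq_len(n_err)) {
      t <- pos[i]
      if (kind[i] == "substitution") {
        mut <- sample(setdiff(bases, tb[i]), 1L)
        put(substr(seq_t, cur + 1L, t)); put(mut)
        cur <- t + 1L
        refs[i] <- mut; alts[i] <- tb[i]; delta[i] <- 0L
      } else if (kind[i] == "insertion") {
        k <- ilen[i]
        extra <- substr(seq_t, t + 2L, t + 1L + k)
        put(substr(seq_t, cur + 1L, t + 1L))
        cur <- t + 1L + k
        refs[i] <- tb[i]; alts[i] <- paste0(tb[i], extra); delta[i] <- -k
      } else {
        k <- ilen[i]
        extra <- random_dna(k, config$gc_target)
        put(substr(seq_t, cur + 1L, t + 1L)); put(extra)
        cur <- t + 1L
        refs[i] <- paste0(tb[i], extra); alts[i] <- tb[i]; delta[i] <- k
      }
    }
    put(substr(seq_t, cur + 1L, L))
    parts <- parts[seq_len(np)]
    seq_a <- paste(parts, collapse = "")
    out_seq[ci] <- seq_a
    La <- nchar(seq_a)
    apos <- pos + c(0L, cumsum(delta))[seq_len(n_err)]
    ev <- data.frame(contig = ctg, t_anchor = pos, delta = delta, apos = apos,
                     kind = kind, len = pmax(ilen, 1L), stringsAsFactors = FALSE)
    events_all[[ci]] <- ev
    errors[[ci]] <- if (n_err > 0L) data.frame(
      contig = ctg, pos = apos,
      error_kind = kind, length = pmax(ilen, 1L),
      assembly_allele = refs, evidence_allele = alts,
      clustered = clustered, stringsAsFactors = FALSE) else NULL

    pass_ann <- function(m) data.frame(
      QD = stats::runif(m, 5, 30), FS = stats::runif(m, 0, 10),
      SOR = stats::runif(m, 0.5, 2), MQ = stats::runif(m, 55, 60),
      MQRankSum = stats::runif(m, -2, 2),
      ReadPosRankSum = stats::runif(m, -2, 2))
    v_err <- if (n_err > 0L) cbind(
      data.frame(contig = ctg, pos = apos + 1L,
                 ref_allele = refs, alt_allele = alts,
                 genotype = "1/1", stringsAsFactors = FALSE),
      pass_ann(n_err)) else NULL

    n_het <- stats::rpois(1L, config$het_site_rate_per_kb * L / 1000)
    hp <- draw_scatter(n_het)
    hp <- hp[!vapply(hp, function(p) any(abs(p - pos) < 12L), logical(1))]
    hb <- if (length(hp)) substring(seq_t, hp + 1L, hp + 1L) else character(0)
    halt <- vapply(hb, function(b) sample(setdiff(bases, b), 1L), character(1))
    v_het <- if (length(hp)) cbind(
      data.frame(contig = ctg, pos = map_truth_to_a(ev, hp) + 1L,
                 ref_allele = hb, alt_allele = halt, genotype = "0/1",
                 stringsAsFactors = FALSE),
      pass_ann(length(hp))) else NULL

    n_ff <- stats::rpois(1L, config$filter_fail_fraction * n_err)
    fp <- draw_scatter(n_ff)
    fp <- fp[!vapply(fp, function(p) any(abs(p - pos) < 12L) ||
                       any(abs(p - hp) < 4L), logical(1))]
    fb <- if (length(fp)) substring(seq_t, fp + 1L, fp + 1L) else character(0)
    falt <- vapply(fb, function(b) sample(setdiff(bases, b), 1L), character(1))
    v_ff <- if (length(fp)) {
      ann <- pass_ann(length(fp))
      mode <- sample(c("QD", "FS", "SOR"), length(fp), replace = TRUE)
      ann$QD[mode == "QD"] <- stats::runif(sum(mode == "QD"), 0, 1.9)
      ann$FS[mode == "FS"] <- stats::runif(sum(mode == "FS"), 70, 300)
      ann$SOR[mode == "SOR"] <- stats::runif(sum(mode == "SOR"), 3.5, 6)
      cbind(data.frame(contig = ctg, pos = map_truth_to_a(ev, fp) + 1L,
                       ref_allele = fb, alt_allele = falt, genotype = "1/1",
                       stringsAsFactors = FALSE), ann)
    } else NULL
    vcf[[ci]] <- do.call(rbind, Filter(Negate(is.null),
                                       list(v_err, v_het, v_ff)))

    ## high-methylation windows in A coordinates
    wa <- if (nrow(windows)) data.frame(
      contig = ctg, start = map_truth_to_a(ev, windows$start),
      end = map_truth_to_a(ev, windows$end), stringsAsFactors = FALSE) else
        data.frame(contig = character(), start = integer(), end = integer())
    hmw[[ci]] <- wa
    mp <- seq(100L, La - 100L, by = config$meth_site_spacing_bp)
    in_w <- in_zone(mp, wa)
    meth[[ci]] <- data.frame(
      contig = ctg, pos = mp,
      called_sites = stats::rpois(length(mp), 15),
      methylated_fraction = ifelse(in_w, stats::rbeta(length(mp), 8, 2),
                                   stats::rbeta(length(mp), 2, 8)),
      stringsAsFactors = FALSE)
    bs <- seq(0L, La - 1L, by = 1000L)
    be <- pmin(bs + 1000L, La)
    bin_in_w <- in_zone(bs, wa) | in_zone(be - 1L, wa)
    dsh[[ci]] <- data.frame(
      contig = ctg, start = bs, end = be,
      depth = ifelse(bin_in_w, sample(0:5, length(bs), replace = TRUE),
                     stats::rpois(length(bs), config$shotgun_depth)))
    dco[[ci]] <- data.frame(contig = ctg, start = bs, end = be,
                            depth = stats::rpois(length(bs), config$consensus_depth))
  }
  events <- do.call(rbind, events_all)
  genes_a <- truth$genes
  if (nrow(genes_a)) {
    for (ctg in unique(genes_a$contig)) {
      ev <- events[events$contig == ctg, , drop = FALSE]
      sel <- genes_a$contig == ctg
      genes_a$start[sel] <- map_truth_to_a(ev, genes_a$start[sel])
      genes_a$end[sel] <- map_truth_to_a(ev, genes_a$end[sel])
    }
  }
  vcf_df <- do.call(rbind, Filter(Negate(is.null), vcf))
  if (is.null(vcf_df)) {
    vcf_df <- empty_variants()
  } else {
    vcf_df$variant_class <- variant_class(vcf_df$ref_allele, vcf_df$alt_allele)
    vcf_df <- vcf_df[order(vcf_df$contig, vcf_df$pos), ]
    rownames(vcf_df) <- NULL
  }
  err_df <- do.call(rbind, Filter(Negate(is.null), errors))
  if (is.null(err_df)) {
    err_df <- data.frame(contig = character(), pos = integer(),
                         error_kind = character(), length = integer(),
                         assembly_allele = character(),
                         evidence_allele = character(), clustered = logical(),
                         stringsAsFactors = FALSE)
  } else {
    err_df <- err_df[order(err_df$contig, err_df$pos), ]
    rownames(err_df) <- NULL
  }
  list(assembly_a = out_seq, planted_errors = err_df, truth_vcf = vcf_df,
       events = events, genes_a = genes_a,
       high_meth_windows = do.call(rbind, hmw),
       methylation_sites = do.call(rbind, meth),
       depth_shotgun = do.call(rbind, dsh),
       depth_consensus = do.call(rbind, dco))
}

build_cigar <- function(ev, s, e) {
  ## exact difference string for truth interval [s, e) of B against A
  toks <- character(0); cur <- s
  n_eq <- 0L; n_other <- 0L
  emit <- function(len, op) if (len > 0L) toks[length(toks) + 1L] <<- paste0(len, op)
  sel <- ev[ev$t_anchor >= s & ev$t_anchor < e, , drop = FALSE]
  if (nrow(sel)) for (i in seq_len(nrow(sel))) {
    t <- sel$t_anchor[i]; k <- sel$len[i]
    if (sel$kind[i] == "substitution") {
      emit(t - cur, "="); emit(1L, "X"); cur <- t + 1L
    } else if (sel$kind[i] == "insertion") {      # truth extra, absent in A
      emit(t - cur + 1L, "="); emit(k, "I"); cur <- t + 1L + k
    } else {                                       # A carries extra bases
      emit(t - cur + 1L, "="); emit(k, "D"); cur <- t + 1L
    }
  }
  emit(e - cur, "=")
  paste(toks, collapse = "")
}

#' Derive the fragmented assembly B with true alignments and the
#' structural ledger
#'
#' Chromosomes split at every planted tandem/dispersed repeat whose span
#' is at least the read-length proxy. Each split is either an uncovered
#' gap (the repeat is omitted from assembly B) or an overlap redundancy
#' (the repeat is carried by both flanking contigs), chosen by
#' `gap_mode_weight`. True alignments of B onto A carry exact difference
#' strings over the planted errors; self-alignments of A pairing the
#' planted repeat copies are emitted for repeat-context annotation.
#'
#' @param truth Output of [generate_truth_genome()].
#' @param asm_a Output of [derive_assembly_a()] (A coordinates are needed
#'   for the ledger and alignments).
#' @param config The same [sim_config()].
#' @return list `assembly_b` (named character vector), `true_alignments`
#'   (PAF-style data.frame with cigars), `planted_structural` (ledger with
#'   `call_kind` and `expected_redundant`), `self_alignments`.
#' @export
derive_assembly_b <- function(truth, asm_a, config) {
  set.seed(config$seed + 2000L)
  contigs <- character(0); aln <- list(); planted <- list(); self <- list()
  for (ci in seq_along(truth$genome)) {
    ctg <- names(truth$genome)[ci]
    seq_t <- truth$genome[[ci]]
    L <- nchar(seq_t)
    La <- nchar(asm_a$assembly_a[[ctg]])
    ev <- asm_a$events[asm_a$events$contig == ctg, , drop = FALSE]
    mapA <- function(p) map_truth_to_a(ev, p)
    rep_c <- truth$repeats[truth$repeats$contig == ctg &
                             truth$repeats$kind %in% c("tandem", "dispersed"), ,
                           drop = FALSE]
    brk <- rep_c[(rep_c$end - rep_c$start) >= config$read_len_proxy_bp, ,
                 drop = FALSE]
    brk <- brk[order(brk$start), , drop = FALSE]
    segs <- list(); cs <- 0L
    if (nrow(brk)) for (i in seq_len(nrow(brk))) {
      gap_mode <- stats::runif(1) < config$gap_mode_weight
      if (gap_mode) {
        segs[[length(segs) + 1L]] <- c(cs, brk$start[i])
        planted[[length(planted) + 1L]] <- data.frame(
          contig = ctg, start = mapA(brk$start[i]), end = mapA(brk$end[i]),
          call_kind = "gap_uncovered", expected_redundant = FALSE,
          repeat_kind = brk$kind[i], stringsAsFactors = FALSE)
        cs <- brk$end[i]
      } else {
        segs[[length(segs) + 1L]] <- c(cs, brk$end[i])
        planted[[length(planted) + 1L]] <- data.frame(
          contig = ctg, start = mapA(brk$start[i]), end = mapA(brk$end[i]),
          call_kind = "overlap", expected_redundant = TRUE,
          repeat_kind = brk$kind[i], stringsAsFactors = FALSE)
        cs <- brk$start[i]
      }
    }
    segs[[length(segs) + 1L]] <- c(cs, L)
    for (si in seq_along(segs)) {
      s <- segs[[si]][1]; e <- segs[[si]][2]
      qid <- sprintf("%s_b%02d", ctg, si)
      contigs[qid] <- substr(seq_t, s + 1L, e)
      cig <- build_cigar(ev, s, e)
      p <- parse_cigar(cig)
      aln[[length(aln) + 1L]] <- data.frame(
        query_id = qid, query_len = e - s, query_start = 0L,
        query_end = e - s, strand = "+", target_id = ctg, target_len = La,
        target_start = mapA(s), target_end = mapA(e),
        n_matches = sum(p$len[p$op == "="]), block_len = sum(p$len),
        mapq = 60L, is_primary = TRUE, cigar = cig, stringsAsFactors = FALSE)
    }
    ## self-alignments of A pairing tandem copies
    tand <- rep_c[rep_c$kind == "tandem", , drop = FALSE]
    if (nrow(tand)) for (i in seq_len(nrow(tand))) {
      u <- tand$unit_len[i]
      for (cp in seq_len(tand$unit_count[i] - 1L)) {
        a0 <- tand$start[i] + (cp - 1L) * u; a1 <- a0 + u
        b0 <- a1; b1 <- b0 + u
        blk <- mapA(b1) - mapA(b0)
        self[[length(self) + 1L]] <- data.frame(
          query_id = ctg, query_len = La, query_start = mapA(a0),
          query_end = mapA(a1), strand = "+", target_id = ctg,
          target_len = La, target_start = mapA(b0), target_end = mapA(b1),
          n_matches = round(0.99 * blk), block_len = blk, mapq = 60L,
          is_primary = TRUE, cigar = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  ## self-alignments pairing dispersed copies (both directions)
  disp <- truth$repeats[truth$repeats$kind == "dispersed", , drop = FALSE]
  for (pid in unique(disp$pair_id)) {
    pr <- disp[disp$pair_id == pid, , drop = FALSE]
    if (nrow(pr) != 2L) next
    coords <- lapply(1:2, function(k) {
      ev <- asm_a$events[asm_a$events$contig == pr$contig[k], , drop = FALSE]
      c(map_truth_to_a(ev, pr$start[k]), map_truth_to_a(ev, pr$end[k]))
    })
    lens <- vapply(pr$contig, function(c2) nchar(asm_a$assembly_a[[c2]]),
                   numeric(1))
    for (k in 1:2) {
      o <- 3L - k
      blk <- coords[[k]][2] - coords[[k]][1]
      self[[length(self) + 1L]] <- data.frame(
        query_id = pr$contig[o], query_len = lens[o],
        query_start = coords[[o]][1], query_end = coords[[o]][2],
        strand = "+", target_id = pr$contig[k], target_len = lens[k],
        target_start = coords[[k]][1], target_end = coords[[k]][2],
        n_matches = round(0.985 * blk), block_len = blk, mapq = 60L,
        is_primary = TRUE, cigar = NA_character_, stringsAsFactors = FALSE)
    }
  }
  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(contig = character(), start = integer(), end = integer(),
               call_kind = character(), expected_redundant = logical(),
               repeat_kind = character(), stringsAsFactors = FALSE)
  list(assembly_b = contigs,
       true_alignments = do.call(rbind, aln),
       planted_structural = planted_df,
       self_alignments = if (length(self)) do.call(rbind, self) else NULL)
}

#' Run the full simulation
#'
#' @param config A [sim_config()].
#' @return list combining the truth genome, assembly A and assembly B
#'   outputs (see the individual generators).
#' @export
simulate_assemblies <- function(config = sim_config()) {
  truth <- generate_truth_genome(config)
  a <- derive_assembly_a(truth, config)
  b <- derive_assembly_b(truth, a, config)
  c(list(truth = truth), a, b)
}

## --- fixture writing -------------------------------------------------------

write_fasta_chr <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(as.list(seqs))), path)
}

write_vcf_file <- function(v, contig_lengths, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(contig_lengths), ",length=",
                  contig_lengths, ">"),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"SymmetricOddsRatio\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MappingQuality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQRankSum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"ReadPosRankSum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample1")
  fmt <- function(x) formatC(x, format = "f", digits = 3)
  keys <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum")
  lines <- vapply(seq_len(nrow(v)), function(i) {
    vals <- unlist(v[i, keys])
    info <- paste(paste0(keys[!is.na(vals)], "=", fmt(vals[!is.na(vals)])),
                  collapse = ";")
    if (!nzchar(info)) info <- "."
    paste(v$contig[i], v$pos[i], ".", v$ref_allele[i], v$alt_allele[i],
          "100", "PASS", info, "GT", v$genotype[i], sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
}

write_gff3_file <- function(genes, path) {
  lines <- "##gff-version 3"
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    s <- min(g$start) + 1L; e <- max(g$end); st <- g$strand[1]
    lines <- c(lines,
               paste(g$contig[1], "sim", "gene", s, e, ".", st, ".",
                     paste0("ID=", gid, "_g"), sep = "\t"),
               paste(g$contig[1], "sim", "mRNA", s, e, ".", st, ".",
                     paste0("ID=", gid, ";Parent=", gid, "_g"), sep = "\t"),
               vapply(seq_len(nrow(g)), function(i)
                 paste(g$contig[i], "sim", "CDS", g$start[i] + 1L, g$end[i],
                       ".", st, "0", paste0("Parent=", gid), sep = "\t"),
                 character(1)))
  }
  writeLines(lines, path)
}

#' Write the complete synthetic dataset to a fixture directory
#'
#' Regenerates deterministically from the configuration: assemblies
#' (FASTA), B-onto-A and A-self alignments (PAF with cg tags), variant
#' calls (VCF), gene models on A (GFF3), methylation table, depth tracks,
#' centromeric consensus, and the planted-event ledgers (TSV).
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the simulation object with `$paths` added.
#' @export
make_fixtures <- function(config = sim_config(), outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sim <- simulate_assemblies(config)
  p <- function(f) file.path(outdir, f)
  write_fasta_chr(sim$truth$genome, p("truth.fasta"))
  write_fasta_chr(sim$assembly_a, p("assembly_a.fasta"))
  write_fasta_chr(sim$assembly_b, p("assembly_b.fasta"))
  writeLines(c(">cen_unit_synthetic", sim$truth$centromere_consensus),
             p("centromere_consensus.fasta"))
  write_paf(sim$true_alignments, p("b_vs_a.paf"))
  if (!is.null(sim$self_alignments))
    write_paf(sim$self_alignments, p("a_self.paf"))
  write_vcf_file(sim$truth_vcf, nchar(sim$assembly_a), p("calls.vcf"))
  write_gff3_file(sim$genes_a, p("genes_a.gff3"))
  mt <- sim$methylation_sites
  names(mt) <- c("chromosome", "start", "called_sites", "methylated_frequency")
  utils::write.table(mt, p("methylation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$depth_shotgun, p("depth_shotgun.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$depth_consensus, p("depth_consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$planted_structural, p("ledger_structural.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$planted_errors, p("ledger_errors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$repeats, p("ledger_repeats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sim$paths <- list(
    assembly_a = p("assembly_a.fasta"), assembly_b = p("assembly_b.fasta"),
    paf = p("b_vs_a.paf"), self_paf = p("a_self.paf"), vcf = p("calls.vcf"),
    gff3 = p("genes_a.gff3"), methylation = p("methylation.tsv"),
    depth_shotgun = p("depth_shotgun.tsv"),
    depth_consensus = p("depth_consensus.tsv"),
    centromere_consensus = p("centromere_consensus.fasta"), dir = outdir)
  invisible(sim)
}
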