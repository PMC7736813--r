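## File readers/writers for every external format the pipeline touches.
## Internal convention: 0-based half-open coordinates everywhere; 1-based
## closed only at the GFF3/VCF boundary.

#' Read a multi-record assembly FASTA
#'
#' Sequences are uppercased on read; characters outside \{A,C,G,T,N\} are
#' rejected. Record ids must be non-empty and unique.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_assembly_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  if (any(Biostrings::width(seqs) < 1L)) stop("zero-length sequence in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T", "N"))
  if (any(rowSums(freq) != Biostrings::width(seqs)))
    stop("sequence characters outside {A,C,G,T,N} in ", path)
  names(seqs) <- ids
  seqs
}

## --- CIGAR helpers (extended cg:Z strings; ops in M,=,X,I,D) ---------------

parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1L) stop("unparsable cigar: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("unparsable cigar: ", cigar)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op  = sub("^\\d+", "", toks))
}

cigar_consumed <- function(cig) {
  p <- parse_cigar(cig)
  c(query  = sum(p$len[p$op %in% c("M", "=", "X", "I")]),
    target = sum(p$len[p$op %in% c("M", "=", "X", "D")]))
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory columns plus the optional `cg:Z` difference string
#' and `tp:A` primary/secondary tag. Coordinates stay 0-based half-open as in
#' PAF. When a `cg` tag is present its consumed lengths are checked against
#' the query and target spans.
#'
#' @param path Path to a PAF file.
#' @return A data.frame with one row per alignment record: `query_id`,
#'   `query_len`, `query_start`, `query_end`, `strand`, `target_id`,
#'   `target_len`, `target_start`, `target_end`, `n_matches`, `block_len`,
#'   `mapq`, `is_primary`, `cigar` (NA when absent).
#' @export
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("PAF parse error at line ", i, ": fewer than 12 columns")
    tags <- if (length(f) > 12L) f[13:length(f)] else character()
    tp <- sub("^tp:A:", "", grep("^tp:A:", tags, value = TRUE))
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE))
    rows[[i]] <- data.frame(
      query_id = f[1], query_len = as.integer(f[2]),
      query_start = as.integer(f[3]), query_end = as.integer(f[4]),
      strand = f[5],
      target_id = f[6], target_len = as.integer(f[7]),
      target_start = as.integer(f[8]), target_end = as.integer(f[9]),
      n_matches = as.integer(f[10]), block_len = as.integer(f[11]),
      mapq = as.integer(f[12]),
      is_primary = if (length(tp)) identical(tp[1], "P") else TRUE,
      cigar = if (length(cg)) cg[1] else NA_character_,
      stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, rows)
  validate_paf(aln)
  aln
}

empty_paf <- function() {
  data.frame(query_id = character(), query_len = integer(),
             query_start = integer(), query_end = integer(),
             strand = character(), target_id = character(),
             target_len = integer(), target_start = integer(),
             target_end = integer(), n_matches = integer(),
             block_len = integer(), mapq = integer(),
             is_primary = logical(), cigar = character(),
             stringsAsFactors = FALSE)
}

validate_paf <- function(aln) {
  bad <- with(aln, query_start < 0 | query_start >= query_end |
                query_end > query_len |
                target_start < 0 | target_start >= target_end |
                target_end > target_len)
  if (any(bad))
    stop("PAF coordinate inversion/overflow at record(s): ",
         paste(which(bad), collapse = ", "))
  if (any(aln$n_matches > aln$block_len))
    stop("PAF n_matches > block_len at record(s): ",
         paste(which(aln$n_matches > aln$block_len), collapse = ", "))
  has_cg <- !is.na(aln$cigar)
  for (i in which(has_cg)) {
    cons <- cigar_consumed(aln$cigar[i])
    if (cons[["query"]] != aln$query_end[i] - aln$query_start[i] ||
        cons[["target"]] != aln$target_end[i] - aln$target_start[i])
      stop("cigar consumed lengths disagree with spans at record ", i)
  }
  invisible(aln)
}

#' Write alignment records as PAF
#'
#' Inverse of [read_paf()] on the mandatory fields plus `tp:A` and `cg:Z`.
#'
#' @param aln Alignment data.frame as returned by [read_paf()].
#' @param path Output path.
#' @export
write_paf <- function(aln, path) {
  lines <- vapply(seq_len(nrow(aln)), function(i) {
    r <- aln[i, ]
    f <- c(r$query_id, r$query_len, r$query_start, r$query_end, r$strand,
           r$target_id, r$target_len, r$target_start, r$target_end,
           r$n_matches, r$block_len, r$mapq,
           paste0("tp:A:", if (isTRUE(r$is_primary)) "P" else "S"))
    if (!is.na(r$cigar)) f <- c(f, paste0("cg:Z:", r$cigar))
    paste(f, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

## --- VCF -------------------------------------------------------------------

#' Read a single-sample VCF into variant records
#'
#' Multi-allelic lines are split into one record per alternate allele, each
#' inheriting the genotype re-expressed with respect to that allele (e.g. GT
#' `1/2` becomes `0/1` for each of the two alternates). Symbolic alternate
#' alleles (`<...>`) are dropped; the count of dropped records is attached as
#' attribute `n_symbolic_dropped`. Missing INFO annotations are stored as NA,
#' never as zero: downstream hard filters treat a missing annotation as
#' passing, mirroring GATK semantics.
#'
#' @param path Path to an uncompressed VCF v4.x file with one sample column.
#' @return A data.frame with columns `contig`, `pos` (1-based, as in the
#'   file), `ref_allele`, `alt_allele`, `genotype` (`0/0`, `0/1`, `1/1`,
#'   `missing`), the site annotations `QD`, `FS`, `SOR`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum` (NA when absent), and `variant_class`.
#' @export
read_vcf <- function(path) {
  stopifnot(file.exists(path))
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0L) {
    out <- empty_variants()
    attr(out, "n_symbolic_dropped") <- 0L
    return(out)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_keys <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum")
  info <- lapply(info_keys, function(k)
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = k))))
  names(info) <- info_keys
  gt_raw <- if (ncol(vcf@gt) >= 2L)
    vcfR::extract.gt(vcf, element = "GT")[, 1] else rep(NA_character_, n)

  base <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                     ref_allele = fix$REF, alt_allele = fix$ALT,
                     genotype = NA_character_, QD = info$QD, FS = info$FS,
                     SOR = info$SOR, MQ = info$MQ, MQRankSum = info$MQRankSum,
                     ReadPosRankSum = info$ReadPosRankSum,
                     stringsAsFactors = FALSE)
  ## fast path: biallelic, non-symbolic, plain diploid GT
  gt_norm <- gsub("|", "/", gt_raw, fixed = TRUE)
  simple_gt <- c("0/0" = "0/0", "0/1" = "0/1", "1/0" = "0/1", "1/1" = "1/1",
                 "./." = "missing", "." = "missing")
  simple <- !grepl(",", fix$ALT, fixed = TRUE) & !grepl("^<", fix$ALT) &
    (is.na(gt_norm) | gt_norm %in% names(simple_gt))
  fast <- base[simple, , drop = FALSE]
  fast$genotype <- ifelse(is.na(gt_norm[simple]), "missing",
                          unname(simple_gt[gt_norm[simple]]))
  n_symbolic <- 0L
  rows <- list()
  for (i in which(!simple)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    sym <- grepl("^<", alts)
    n_symbolic <- n_symbolic + sum(sym)
    keep <- which(!sym)
    if (!length(keep)) next
    gt_alleles <- parse_gt(gt_raw[i])
    sub <- base[rep(i, length(keep)), , drop = FALSE]
    sub$alt_allele <- alts[keep]
    sub$genotype <- vapply(keep, function(k) {
      if (is.null(gt_alleles)) "missing" else
        c("0/0", "0/1", "1/1")[sum(gt_alleles == k) + 1L]
    }, character(1))
    rows[[length(rows) + 1L]] <- sub
  }
  out <- do.call(rbind, c(list(fast), rows))
  out <- out[order(match(out$contig, unique(fix$CHROM)), out$pos), ]
  if (is.null(out) || nrow(out) == 0L) out <- empty_variants()
  bad <- !grepl("^[ACGT]+$", out$ref_allele) | !grepl("^[ACGT]+$", out$alt_allele)
  if (any(bad)) stop("VCF alleles outside {A,C,G,T} at record(s): ",
                     paste(which(bad), collapse = ", "))
  out$variant_class <- variant_class(out$ref_allele, out$alt_allele)
  rownames(out) <- NULL
  attr(out, "n_symbolic_dropped") <- n_symbolic
  out
}

parse_gt <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".")) return(NULL)
  as.integer(al)
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "substitution",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

empty_variants <- function() {
  data.frame(contig = character(), pos = integer(), ref_allele = character(),
             alt_allele = character(), genotype = character(),
             QD = numeric(), FS = numeric(), SOR = numeric(), MQ = numeric(),
             MQRankSum = numeric(), ReadPosRankSum = numeric(),
             variant_class = character(), stringsAsFactors = FALSE)
}

## --- GFF3 ------------------------------------------------------------------

#' Read gene models from a GFF3 file
#'
#' One gene model per mRNA; CDS intervals are converted from 1-based closed
#' to 0-based half-open and kept in ascending genomic order regardless of
#' strand. CDS features without a parent are skipped and counted in the
#' `n_orphan_cds` attribute.
#'
#' @param path Path to a GFF3 file with gene/mRNA/CDS features.
#' @return A data.frame of CDS intervals: `gene_id` (the mRNA id), `contig`,
#'   `strand`, `start`, `end` (0-based half-open), `exon_index` (ascending
#'   genomic order).
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0L) {
    out <- empty_genes(); attr(out, "n_orphan_cds") <- 0L; return(out)
  }
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) {
    out <- empty_genes(); attr(out, "n_orphan_cds") <- 0L; return(out)
  }
  parents <- cds$Parent
  orphan <- S4Vectors::elementNROWS(parents) == 0L
  n_orphan <- sum(orphan)
  if (n_orphan > 0L) {
    warning(n_orphan, " CDS feature(s) without parent skipped")
    cds <- cds[!orphan]
  }
  if (length(cds) == 0L) {
    out <- empty_genes(); attr(out, "n_orphan_cds") <- n_orphan; return(out)
  }
  out <- data.frame(
    gene_id = vapply(cds$Parent, `[`, character(1), 1L),
    contig = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$start), ]
  out$exon_index <- stats::ave(out$start, out$gene_id,
                               FUN = function(x) seq_along(x))
  rownames(out) <- NULL
  attr(out, "n_orphan_cds") <- n_orphan
  out
}

empty_genes <- function() {
  data.frame(gene_id = character(), contig = character(), strand = character(),
             start = integer(), end = integer(), exon_index = integer(),
             stringsAsFactors = FALSE)
}

#' CDS completeness per gene model
#'
#' Total CDS length divisible by 3 is recorded as a flag, never required.
#'
#' @param genes CDS data.frame from [read_gff3()].
#' @return data.frame with `gene_id`, `cds_len`, `complete` (length %% 3 == 0).
#' @export
gene_completeness <- function(genes) {
  if (nrow(genes) == 0L)
    return(data.frame(gene_id = character(), cds_len = integer(),
                      complete = logical()))
  len <- tapply(genes$end - genes$start, genes$gene_id, sum)
  data.frame(gene_id = names(len), cds_len = as.integer(len),
             complete = as.integer(len) %% 3L == 0L, row.names = NULL)
}

## --- Methylation and depth tracks -----------------------------------------

#' Read a per-site methylation table
#'
#' Nanopolish-style TSV with columns contig, position (0-based), number of
#' called reads, methylated frequency. Rows below the read-support threshold
#' are excluded (default `called_sites >= 10`).
#'
#' @param path Path to the TSV (header required).
#' @param min_called_sites Minimum read support to retain a site.
#' @return data.frame `contig`, `pos`, `called_sites`, `methylated_fraction`.
#' @export
read_methylation_table <- function(path, min_called_sites = 10L) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    return(data.frame(contig = character(), pos = integer(),
                      called_sites = integer(), methylated_fraction = numeric()))
  names(tab)[1:4] <- c("contig", "pos", "called_sites", "methylated_fraction")
  if (any(tab$methylated_fraction < 0 | tab$methylated_fraction > 1))
    stop("methylated fraction outside [0,1]")
  if (any(tab$called_sites < 0)) stop("negative called_sites")
  tab <- tab[tab$called_sites >= min_called_sites, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read a BED-like depth track
#'
#' @param path 4-column TSV: contig, start, end (0-based half-open), depth.
#' @return data.frame `contig`, `start`, `end`, `depth`.
#' @export
read_depth_track <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("contig", "start", "end", "depth"))
  if (nrow(tab) && any(tab$depth < 0)) stop("negative depth in ", path)
  tab
}

#' Depth at single positions
#'
#' Returns NA (an explicit missing marker) where the track has no interval.
#'
#' @param track Depth data.frame from [read_depth_track()].
#' @param contig,pos Vectors of positions (0-based) to query.
#' @return Numeric vector of depths, NA where uncovered.
#' @export
depth_at <- function(track, contig, pos) {
  out <- rep(NA_real_, length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    tr <- track[track$contig == ctg, , drop = FALSE]
    if (!nrow(tr)) next
    tr <- tr[order(tr$start), , drop = FALSE]
    idx <- findInterval(pos[sel], tr$start)
    hit <- idx >= 1L & pos[sel] < tr$end[pmax(idx, 1L)]
    out[sel][hit] <- tr$depth[idx[hit]]
  }
  out
}
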