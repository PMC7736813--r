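# Shared synthetic fixtures, generated once per test session.

small_sim_config <- function(seed = 42L) {
  sim_config(seed = seed, n_chromosomes = 2L, chromosome_len_bp = 4e5,
             gene_density = 30, tandem_repeat_lengths = 14000L,
             dispersed_dup_lengths = 25000L, telomere_units = 30L,
             centromere_units = 20L, read_len_proxy_bp = 20000L)
}

get_small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_assemblies(small_sim_config())
    cache
  }
})

get_small_fixture_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "duoasm_small_fx")
      make_fixtures(small_sim_config(), dir)
      cache <<- dir
    }
    cache
  }
})

# study-condition simulation used by the acceptance checks
# (2 chromosomes x 10 Mb, one tandem and one dispersed repeat pair per
# chromosome, errors at 1.06/kb with 0.5/kb heterozygous sites and 5%
# filter-failing records)
get_accept_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "duoasm_accept_fx")
      cache <<- make_fixtures(sim_config(seed = 20260922L), dir)
      cache$dir <- dir
    }
    cache
  }
})

# a random gene model plus a consistent random error on a small contig,
# for oracle-equivalence property tests
random_gene_case <- function() {
  L <- 4000L
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  g <- duoasm:::make_gene("g1", "ctg", sample(c("+", "-"), 1L), 0.45)
  s <- sample(200:(L - nchar(g$region) - 200L), 1L)
  seq <- paste0(substr(seq, 1, s), g$region,
                substr(seq, s + nchar(g$region) + 1L, L))
  gene <- g$cds
  gene$start <- gene$start + s
  gene$end <- gene$end + s
  span <- c(min(gene$start) - 30L, max(gene$end) + 30L)
  pos <- sample(span[1]:span[2], 1L)
  base <- substr(seq, pos + 1L, pos + 1L)
  type <- sample(c("sub", "ins", "del"), 1L, prob = c(0.5, 0.25, 0.25))
  if (type == "sub") {
    ref <- base; alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
  } else if (type == "del") {       # assembly carries extra bases
    k <- sample(1:4, 1L)
    ref <- substr(seq, pos + 1L, pos + 1L + k); alt <- base
  } else {                           # assembly misses bases
    k <- sample(1:4, 1L)
    ref <- base; alt <- paste0(base, paste(sample(c("A", "C", "G", "T"), k,
                                                  replace = TRUE), collapse = ""))
  }
  err <- data.frame(contig = "ctg", pos = pos,
                    error_kind = variantkind(ref, alt),
                    length = max(1L, abs(nchar(ref) - nchar(alt))),
                    assembly_allele = ref, evidence_allele = alt,
                    stringsAsFactors = FALSE)
  list(seq = seq, gene = gene, error = err)
}

variantkind <- function(ref, alt) {
  if (nchar(ref) == nchar(alt)) "substitution"
  else if (nchar(alt) > nchar(ref)) "insertion" else "deletion"
}
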