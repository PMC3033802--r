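# Toy builders shared across test files. All coordinates 0-based half-open.

tx <- function(id, exons, cds = NULL) {
  list(transcript_id = id,
       exons = data.frame(start = exons[, 1], end = exons[, 2]),
       cds = if (is.null(cds)) data.frame(start = integer(), end = integer())
             else data.frame(start = cds[, 1], end = cds[, 2]))
}

toy_gene <- function(id, chrom, strand, exons, cds = NULL) {
  gene_model(id, chrom, strand, min(exons[, 1]), max(exons[, 2]),
             list(tx(paste0(id, ".t1"), exons, cds)))
}

# a SNP table built directly in memory (bypasses the TSV readers)
toy_snps <- function(chrom, pos, freq_AFR, allele_a = "A", allele_b = "G",
                     multi_mapped = FALSE, on_Y = FALSE, in_dbsnp = TRUE,
                     resequenced = TRUE, biallelic_substitution = TRUE,
                     ids = NULL) {
  n <- length(pos)
  df <- data.frame(
    snp_id = if (is.null(ids)) sprintf("s%03d", seq_len(n)) else ids,
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    allele_a = rep_len(allele_a, n), allele_b = rep_len(allele_b, n),
    freq_AFR = freq_AFR,
    multi_mapped = rep_len(multi_mapped, n), on_Y = rep_len(on_Y, n),
    in_dbsnp = rep_len(in_dbsnp, n),
    resequenced = rep_len(resequenced, n),
    biallelic_substitution = rep_len(biallelic_substitution, n),
    stringsAsFactors = FALSE)
  attr(df, "populations") <- "AFR"
  class(df) <- c("snp_table", "data.frame")
  df
}

# small single-population study condition used by the faster simulation tests
small_sim_config <- function(seed, gamma_class = 0, n_class_snps = 300L,
                             n_background = 3000L, label = "test_class") {
  simulation_config(
    chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
    n_genes = 20L,
    gene_length_range = c(2000L, 8000L),
    region_specs = list(
      list(label = label, n_regions = 60L, length_range = c(1000L, 3000L),
           placement = "uniform", gamma = gamma_class,
           n_snps = n_class_snps)),
    n_background_snps = n_background,
    populations = "AFR",
    seed = seed)
}

# brute-force quadratic oracle: which SNP 1-bp intervals intersect a region set
brute_members <- function(snps, rs) {
  hit <- vapply(seq_len(nrow(snps)), function(i) {
    any(rs$chrom == snps$chrom[i] &
          rs$start <= snps$pos[i] & snps$pos[i] < rs$end)
  }, TRUE)
  sort(snps$snp_id[hit])
}

# brute-force per-base coverage of a region set on one chromosome
brute_coverage <- function(rs, chrom, upto) {
  cov <- logical(upto)
  sel <- rs$chrom == chrom
  for (i in which(sel)) {
    lo <- max(0L, rs$start[i]); hi <- min(upto, rs$end[i])
    if (hi > lo) cov[(lo + 1):hi] <- TRUE
  }
  cov
}

# full-enumeration Mann-Whitney oracle over all class/background splits
enum_mw_p <- function(x, y, alternative = "less") {
  pool <- c(x, y)
  r <- rank(pool)
  n1 <- length(x)
  splits <- combn(length(pool), n1)
  Us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  switch(alternative,
         less = mean(Us <= U_obs + eps),
         greater = mean(Us >= U_obs - eps),
         two.sided = min(1, 2 * min(mean(Us <= U_obs + eps),
                                    mean(Us >= U_obs - eps))))
}
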