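#' Relative site-frequency-spectrum density under selection
#'
#' Un-normalised density of the population derived-allele frequency `q` under
#' the classical diffusion stationary form
#' `f(q | gamma) = (1 - exp(-gamma (1 - q))) / (q (1 - q) (1 - exp(-gamma)))`,
#' where `gamma = 2 N s` is the scaled selection coefficient. `gamma = 0`
#' returns the neutral limit `1/q`. Negative `gamma` (deleterious derived
#' alleles) tilts mass toward low frequencies -- the excess of rare derived
#' alleles that a purifying-selection scan looks for.
#'
#' @param q frequencies, strictly inside (0, 1)
#' @param gamma scaled selection coefficient (finite; 0 = neutral)
#' @return relative density values (un-normalised)
#' @examples
#' sfs_density(0.5, 0)        # 2: neutral 1/q
#' sfs_density(0.1, -10) / sfs_density(0.9, -10)  # >> 9, the neutral ratio
#' @export
sfs_density <- function(q, gamma = 0) {
  if (any(q <= 0 | q >= 1)) stop("sfs_density: q must be in (0,1)")
  if (!is.finite(gamma)) stop("sfs_density: gamma must be finite")
  if (gamma == 0) return(1 / q)
  (-expm1(-gamma * (1 - q))) / (q * (1 - q) * (-expm1(-gamma)))
}

.daf_grid <- function(gamma, two_n, grid_points = 4096L) {
  lo <- 1 / (2 * two_n)
  q <- seq(lo, 1 - lo, length.out = grid_points)
  w <- sfs_density(q, gamma)
  list(q = q, p = w / sum(w))
}

#' Draw sample derived-allele frequencies
#'
#' Draws a population frequency `q` from the normalised [sfs_density()] on a
#' fine grid (inverse-CDF sampling), then binomially resamples `2n`
#' chromosomes: the returned values live on the sample-frequency grid
#' `{0, 1/2n, ..., 1}`. Monomorphic outcomes (0 or 1) are permitted.
#'
#' @param n number of draws
#' @param gamma scaled selection coefficient
#' @param two_n sample size in chromosomes (`>= 2`)
#' @param grid_points resolution of the frequency grid (default 4096, below
#'   one sample-frequency step for any realistic `2n`)
#' @return numeric vector of length `n`
#' @export
draw_sample_daf <- function(n, gamma = 0, two_n = 48L, grid_points = 4096L) {
  stopifnot(two_n >= 2)
  g <- .daf_grid(gamma, two_n, grid_points)
  qs <- sample(g$q, n, replace = TRUE, prob = g$p)
  stats::rbinom(n, two_n, qs) / two_n
}

#' Configuration for the synthetic-data generator
#'
#' Defaults define the demo study condition: three 10-Mb chromosomes, 100
#' non-overlapping protein-coding genes, a constrained-element-like class of
#' 200 elements under strong purifying selection (`gamma = -15`), a neutral
#' ancestral-repeat class, a neutral genome-wide SNP background, and three
#' populations of 48 chromosomes each genotyped at every SNP.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp)
#' @param n_genes number of genes, placed without overlap
#' @param gene_length_range min/max gene span (bp)
#' @param n_transcripts_per_gene transcripts per gene
#' @param region_specs list of specs, each a list with `label`, `n_regions`,
#'   `length_range`, `placement` (`"uniform"`, `"near_gene"`,
#'   `"far_from_gene"`), optional `min_bp` (for `far_from_gene`), `gamma`,
#'   and `n_snps` (SNPs placed inside the set)
#' @param n_background_snps neutral SNPs placed uniformly on the genome
#' @param background_gamma selection coefficient of background SNPs (0)
#' @param populations population codes
#' @param sample_size_chromosomes `2n` per population
#' @param p_chimp_fail probability the chimpanzee call misses or mismatches
#'   the true ancestral allele
#' @param p_macaque_rescue probability the macaque call reports the ancestral
#'   allele given the chimpanzee call failed
#' @param seed RNG seed; the bundle is a deterministic function of the config
#' @return a `simulation_config` list
#' @export
simulation_config <- function(
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
    n_genes = 100L,
    gene_length_range = c(2000L, 20000L),
    n_transcripts_per_gene = 1L,
    region_specs = list(
      list(label = "constrained_elements", n_regions = 200L,
           length_range = c(500L, 2000L), placement = "uniform",
           gamma = -15, n_snps = 600L),
      list(label = "ancestral_repeats", n_regions = 300L,
           length_range = c(500L, 2000L), placement = "uniform",
           gamma = 0, n_snps = 1500L)
    ),
    n_background_snps = 6000L,
    background_gamma = 0,
    populations = c("AFR", "EUR", "CHN"),
    sample_size_chromosomes = 48L,
    p_chimp_fail = 0.02,
    p_macaque_rescue = 0.8,
    seed = 1L) {
  stopifnot(all(chrom_lengths > 0), sample_size_chromosomes >= 2,
            p_chimp_fail >= 0, p_chimp_fail <= 1,
            p_macaque_rescue >= 0, p_macaque_rescue <= 1,
            is.finite(background_gamma))
  for (rs in region_specs) {
    stopifnot(!is.null(rs$label), rs$n_regions >= 0, is.finite(rs$gamma),
              length(rs$length_range) == 2)
    if (identical(rs$placement, "far_from_gene") && is.null(rs$min_bp))
      stop("simulation_config: far_from_gene placement needs min_bp (",
           rs$label, ")")
  }
  structure(list(chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 n_transcripts_per_gene = as.integer(n_transcripts_per_gene),
                 region_specs = region_specs,
                 n_background_snps = as.integer(n_background_snps),
                 background_gamma = background_gamma,
                 populations = populations,
                 sample_size_chromosomes = as.integer(sample_size_chromosomes),
                 p_chimp_fail = p_chimp_fail,
                 p_macaque_rescue = p_macaque_rescue,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

.place_genes <- function(config) {
  chroms <- names(config$chrom_lengths)
  placed <- list()
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)
  for (i in seq_len(config$n_genes)) {
    ok <- FALSE
    for (try in 1:1000) {
      chrom <- sample(chroms, 1, prob = config$chrom_lengths)
      len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
      maxs <- config$chrom_lengths[[chrom]] - len
      if (maxs < 1) next
      s <- sample.int(maxs, 1)
      occ <- occupied[[chrom]]
      clash <- !is.null(occ) &&
        any(s < occ[, 2] & (s + len) > occ[, 1])
      if (!clash) {
        occupied[[chrom]] <- rbind(occ, c(s, s + len))
        strand <- sample(c("+", "-"), 1)
        placed[[i]] <- .random_gene(sprintf("gene%04d", i), chrom, strand,
                                    s, s + len, config$n_transcripts_per_gene)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("generate_bundle: could not place gene ", i,
                  " without overlap")
  }
  .gene_models(placed)
}

.random_gene <- function(gid, chrom, strand, start, end, n_tx) {
  txs <- list()
  for (t in seq_len(max(1L, n_tx))) {
    n_ex <- sample(1:4, 1)
    len <- end - start
    if (n_ex == 1 || len < 40 * n_ex) {
      ex <- data.frame(start = start, end = end)
    } else {
      # 2*n_ex-1 alternating exon/intron blocks with >= 20 bp each
      cuts <- sort(sample(seq(start + 20L, end - 20L, by = 10L),
                          2L * n_ex - 2L))
      b <- c(start, cuts, end)
      ex <- data.frame(start = b[seq(1, length(b) - 1, by = 2)],
                       end = b[seq(2, length(b), by = 2)])
    }
    # CDS: trim UTR-like margins off the first and last exon
    cds <- ex
    trim <- min(15L, floor((cds$end[1] - cds$start[1]) / 3))
    cds$start[1] <- cds$start[1] + trim
    trim2 <- min(15L, floor((cds$end[nrow(cds)] - cds$start[nrow(cds)]) / 3))
    cds$end[nrow(cds)] <- cds$end[nrow(cds)] - trim2
    cds <- cds[cds$end > cds$start, , drop = FALSE]
    txs[[t]] <- list(transcript_id = sprintf("%s.t%d", gid, t),
                     exons = ex, cds = cds)
  }
  gene_model(gid, chrom, strand, start, end, txs)
}

.place_regions <- function(spec, config, genes, max_retries = 500L) {
  chroms <- names(config$chrom_lengths)
  spans <- gene_spans(genes)
  chrom <- character(spec$n_regions)
  start <- integer(spec$n_regions)
  end <- integer(spec$n_regions)
  for (i in seq_len(spec$n_regions)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      len <- sample(spec$length_range[1]:spec$length_range[2], 1)
      if (identical(spec$placement, "near_gene") && length(genes) > 0) {
        g <- genes[[sample.int(length(genes), 1)]]
        s <- g$start + sample.int(max(1L, g$end - g$start + len), 1) - len
        ch <- g$chrom
      } else {
        ch <- sample(chroms, 1, prob = config$chrom_lengths)
        maxs <- config$chrom_lengths[[ch]] - len
        if (maxs < 1) next
        s <- sample.int(maxs, 1)
      }
      if (s < 0 || s + len > config$chrom_lengths[[ch]]) next
      if (identical(spec$placement, "far_from_gene") && nrow(spans) > 0) {
        d <- distance_to_nearest_gene(region_set(ch, s, s + len), genes)
        if (is.finite(d) && d < spec$min_bp) next
      }
      chrom[i] <- ch; start[i] <- s; end[i] <- s + len
      ok <- TRUE
      break
    }
    if (!ok) stop("generate_bundle: infeasible placement for region spec '",
                  spec$label, "'")
  }
  region_set(chrom, start, end, label = spec$label)
}

#' Generate a complete synthetic input bundle
#'
#' Produces gene models, region sets, a multi-population SNP table, and
#' outgroup calls from a [simulation_config()]. Genes are placed without
#' overlap; regions follow their placement rule (`far_from_gene` guarantees
#' edge distance `>= min_bp` from every gene span); each region set's SNPs are
#' placed uniformly over the set's bases (regions weighted by length) and the
#' background SNPs uniformly over the genome. Every SNP draws one population
#' frequency `q` at its class's `gamma` and the configured populations then
#' draw independent binomial samples from that shared `q`. The chimpanzee
#' call reports the true ancestral allele with probability
#' `1 - p_chimp_fail`; otherwise the macaque call rescues it with probability
#' `p_macaque_rescue`, else both calls fail (a mismatching base, occasionally
#' a missing call), which downstream polarization discards.
#'
#' @param config a `simulation_config`
#' @return a `fixture_bundle`: list with `genes`, `region_sets` (named list),
#'   `snps` (a `snp_table`), `outgroup`, `truth` (named `gamma` per region
#'   label plus `background`), and `config`
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- .place_genes(config)
  region_sets <- list()
  for (spec in config$region_specs)
    region_sets[[spec$label]] <- .place_regions(spec, config, genes)

  # SNP positions: per-set placement inside regions, plus uniform background
  chrom <- character(); pos <- integer(); gam <- numeric(); origin <- character()
  for (spec in config$region_specs) {
    if (is.null(spec$n_snps) || spec$n_snps == 0) next
    rs <- region_sets[[spec$label]]
    lens <- rs$end - rs$start
    idx <- sample.int(nrow(rs), spec$n_snps, replace = TRUE, prob = lens)
    p <- rs$start[idx] + floor(stats::runif(spec$n_snps) * lens[idx])
    chrom <- c(chrom, rs$chrom[idx]); pos <- c(pos, as.integer(p))
    gam <- c(gam, rep(spec$gamma, spec$n_snps))
    origin <- c(origin, rep(spec$label, spec$n_snps))
  }
  if (config$n_background_snps > 0) {
    ch <- sample(names(config$chrom_lengths), config$n_background_snps,
                 replace = TRUE, prob = config$chrom_lengths)
    p <- floor(stats::runif(config$n_background_snps) *
                 config$chrom_lengths[ch])
    chrom <- c(chrom, ch); pos <- c(pos, as.integer(p))
    gam <- c(gam, rep(config$background_gamma, config$n_background_snps))
    origin <- c(origin, rep("background", config$n_background_snps))
  }
  n <- length(pos)
  if (n == 0) stop("generate_bundle: no SNPs configured")

  # shared-q independent-binomial frequencies per population
  two_n <- config$sample_size_chromosomes
  qs <- numeric(n)
  for (g in unique(gam)) {
    sel <- gam == g
    grid <- .daf_grid(g, two_n)
    qs[sel] <- sample(grid$q, sum(sel), replace = TRUE, prob = grid$p)
  }
  daf <- vapply(config$populations,
                function(p) stats::rbinom(n, two_n, qs) / two_n,
                numeric(n))
  if (n == 1) daf <- matrix(daf, nrow = 1,
                            dimnames = list(NULL, config$populations))

  anc <- sample(.BASES, n, replace = TRUE)
  der <- vapply(anc, function(a) sample(setdiff(.BASES, a), 1), "")
  b_is_derived <- stats::runif(n) < 0.5      # random a/b orientation
  allele_a <- ifelse(b_is_derived, anc, der)
  allele_b <- ifelse(b_is_derived, der, anc)

  snps <- data.frame(snp_id = sprintf("snp%06d", seq_len(n)),
                     chrom = chrom, pos = pos,
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  for (p in config$populations)
    snps[[paste0("freq_", p)]] <- ifelse(b_is_derived, daf[, p], 1 - daf[, p])
  snps$multi_mapped <- FALSE
  snps$on_Y <- FALSE
  snps$in_dbsnp <- TRUE
  snps$resequenced <- TRUE
  snps$biallelic_substitution <- TRUE
  snps$true_origin <- origin                  # generator ground truth

  chimp_ok <- stats::runif(n) >= config$p_chimp_fail
  mac_ok <- !chimp_ok & (stats::runif(n) < config$p_macaque_rescue)
  fail_base <- function(a, d) {
    out <- vapply(seq_along(a), function(i)
      sample(setdiff(.BASES, c(a[i], d[i])), 1), "")
    out[stats::runif(length(a)) < 0.2] <- NA   # some failures are missing calls
    out
  }
  chimp <- ifelse(chimp_ok, anc, fail_base(anc, der))
  macaque <- ifelse(chimp_ok | mac_ok, anc, fail_base(anc, der))
  outgroup <- data.frame(snp_id = snps$snp_id, chimp_allele = chimp,
                         macaque_allele = macaque, stringsAsFactors = FALSE)

  truth <- c(stats::setNames(vapply(config$region_specs, `[[`, 0, "gamma"),
                             vapply(config$region_specs, `[[`, "", "label")),
             background = config$background_gamma)
  structure(list(genes = genes, region_sets = region_sets,
                 snps = .as_snp_table(.validate_snps(snps)),
                 outgroup = outgroup, truth = truth, config = config),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d genes, %d region sets, %d SNPs, seed %d\n",
              length(x$genes), length(x$region_sets), nrow(x$snps),
              x$config$seed))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Writes `genes.gff3`, one `<label>.bed` per region set, `snps.tsv`,
#' `outgroup.tsv`, and `truth.json` under `dir`.
#'
#' @param bundle a `fixture_bundle`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genes(bundle$genes, file.path(dir, "genes.gff3"))
  for (nm in names(bundle$region_sets))
    write_region_set(bundle$region_sets[[nm]], file.path(dir,
                                                         paste0(nm, ".bed")))
  write_snp_table(bundle$snps, file.path(dir, "snps.tsv"))
  write_outgroup(bundle$outgroup, file.path(dir, "outgroup.tsv"))
  jsonlite::write_json(as.list(bundle$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
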