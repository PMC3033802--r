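#' Sample a random region matched in size and gene distance to a source region
#'
#' Draws a gene uniformly at random and a side (upstream/downstream of its
#' span) uniformly, and returns an interval of exactly the source's length
#' placed at exactly the source's edge distance `d` from the drawn gene's
#' span on the drawn side. The distance is matched to the *drawn* gene, not
#' re-measured against all genes (a sampled region may incidentally sit
#' nearer another gene). When `d = 0` (the source overlaps or abuts a gene)
#' the source's offset relative to its own nearest gene's start is
#' transplanted to the drawn gene. Placements that would overrun the
#' chromosome are re-drawn, up to `max_redraws` attempts.
#'
#' @param source one-row `region_set` (or data.frame with `chrom`, `start`,
#'   `end`)
#' @param genes a `gene_models` object with at least one gene
#' @param chrom_lengths named vector of chromosome lengths (bp), used to
#'   check the upper bound
#' @param max_redraws bound on re-draws (default 100)
#' @return one-row data.frame: `chrom`, `start`, `end`, `gene_id`, `side`,
#'   `source_distance`
#' @export
sample_matched_region <- function(source, genes, chrom_lengths,
                                  max_redraws = 100L) {
  if (length(genes) == 0) stop("sample_matched_region: no genes")
  src <- region_set(source$chrom[1], source$start[1], source$end[1])
  len <- src$end - src$start
  spans <- gene_spans(genes)
  dists <- .dist_to_gr(.rs_to_gr(src), .rs_to_gr(spans))
  d <- dists[1]
  if (!is.finite(d)) stop("sample_matched_region: no gene on any chromosome")
  for (try in seq_len(max_redraws)) {
    gi <- sample.int(length(genes), 1)
    g <- genes[[gi]]
    side <- sample(c("upstream", "downstream"), 1)
    if (d > 0) {
      if (side == "downstream") {
        s <- g$end + d
      } else {
        s <- g$start - d - len
      }
    } else {
      sd <- .source_gene_offset(src, genes)
      s <- g$start + sd
      side <- "offset"
    }
    e <- s + len
    lim <- chrom_lengths[[g$chrom]]
    if (is.null(lim)) stop("sample_matched_region: unknown chromosome ",
                           g$chrom, " in chrom_lengths")
    if (s >= 0 && e <= lim)
      return(data.frame(chrom = g$chrom, start = as.integer(s),
                        end = as.integer(e), gene_id = g$gene_id,
                        side = side, source_distance = d,
                        stringsAsFactors = FALSE))
  }
  stop("sample_matched_region: no feasible placement after ", max_redraws,
       " re-draws for region ", src$chrom, ":", src$start, "-", src$end)
}

## offset of the source start relative to the start of its nearest gene span
.source_gene_offset <- function(src, genes) {
  spans <- gene_spans(genes)
  per_gene <- vapply(seq_len(nrow(spans)), function(i) {
    if (spans$chrom[i] != src$chrom) return(Inf)
    max(0, spans$start[i] - src$end, src$start - spans$end[i])
  }, 0)
  i <- which.min(per_gene)
  src$start - spans$start[i]
}

#' Matched-region permutation test for hitchhiking / background selection
#'
#' Controls for the possibility that a class's low DAF spectrum reflects
#' linkage to nearby selected sites rather than selection on the class
#' itself. Per iteration, every attribute region is replaced by a random
#' region of identical size and gene distance ([sample_matched_region()]),
#' overlapping sampled regions are merged, the SNPs inside them are pooled,
#' and one Mann-Whitney p-value against the background is computed under the
#' same overlap-removal policy as the real scan. The real p-value, computed
#' identically on the true regions, is then compared against the `n_iter`
#' generated p-values.
#'
#' @param attribute_regions a `region_set` (e.g. H3K79me3 regions)
#' @param polarized a `polarized_snps` table
#' @param genes a `gene_models` object
#' @param chrom_lengths named vector of chromosome lengths
#' @param population population code (default `"AFR"`, the most diverse
#'   sample and the default spectrum for this control)
#' @param background `"genome"` or `"ancestral_repeats"`
#' @param background_ids SNP ids of the background class (required for
#'   `"ancestral_repeats"`; ignored for `"genome"`, which uses all polarized
#'   SNPs)
#' @param n_iter number of permutation iterations (default 100)
#' @param seed RNG seed for the permutations
#' @param m declared number of tests for the FDR-adjusted real p (default 44)
#' @param other_pvalues optional p-values of the other real tests; when
#'   given, the adjusted real p is its BH-adjusted value within that set,
#'   otherwise rank 1 is assumed (`adjusted = min(1, m * real_p)`)
#' @param alternative,method passed to [mann_whitney()]
#' @return a `matched_null_result` list: `real_p`, `real_adjusted_p`,
#'   `generated_p` (length `n_iter`), `n_generated_le_real`, `n_iter`,
#'   `seed`, `population`, `background`
#' @export
matched_null_test <- function(attribute_regions, polarized, genes,
                              chrom_lengths, population = "AFR",
                              background = c("genome", "ancestral_repeats"),
                              background_ids = NULL, n_iter = 100L,
                              seed = NULL, m = 44L, other_pvalues = NULL,
                              alternative = "less", method = "auto") {
  background <- match.arg(background)
  stopifnot(n_iter >= 1)
  daf_col <- paste0("daf_", population)
  if (!(daf_col %in% names(polarized)))
    stop("matched_null_test: unknown population ", population)
  daf <- stats::setNames(polarized[[daf_col]], polarized$snp_id)
  if (background == "genome") {
    bg_ids <- polarized$snp_id
    policy <- "genome_background"
  } else {
    if (is.null(background_ids))
      stop("matched_null_test: background_ids required for ancestral_repeats")
    bg_ids <- intersect(background_ids, polarized$snp_id)
    policy <- "ancestral_repeat_background"
  }

  snp_gr <- GenomicRanges::GRanges(polarized$chrom,
                                   IRanges::IRanges(polarized$pos + 1L,
                                                    width = 1L))
  pool_p <- function(chroms, starts, ends) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      chroms, IRanges::IRanges(starts + 1L, ends)))
    lev <- union(GenomeInfoDb::seqlevels(snp_gr),
                 GenomeInfoDb::seqlevels(gr))
    sg <- snp_gr; GenomeInfoDb::seqlevels(sg) <- lev
    GenomeInfoDb::seqlevels(gr) <- lev
    hit <- GenomicRanges::findOverlaps(sg, gr, ignore.strand = TRUE)
    ids <- unique(polarized$snp_id[S4Vectors::queryHits(hit)])
    if (length(ids) == 0) return(NULL)
    sets <- remove_overlap(ids, bg_ids, policy)
    mann_whitney(daf[sets$class_ids], daf[sets$background_ids],
                 alternative = alternative, method = method)$p_raw
  }

  real_p <- pool_p(attribute_regions$chrom, attribute_regions$start,
                   attribute_regions$end)
  if (is.null(real_p))
    stop("matched_null_test: no SNPs in the attribute regions")

  # precompute matching inputs once; per-iteration sampling is arithmetic only
  spans <- gene_spans(genes)
  if (nrow(spans) == 0) stop("matched_null_test: no genes")
  src_len <- attribute_regions$end - attribute_regions$start
  src_d <- distance_to_nearest_gene(attribute_regions, genes)
  src_off <- rep(NA_integer_, nrow(attribute_regions))
  for (i in which(src_d == 0))
    src_off[i] <- .source_gene_offset(attribute_regions[i, , drop = FALSE],
                                      genes)

  if (!is.null(seed)) set.seed(seed)
  draw_iteration <- function() {
    n <- length(src_len)
    ch <- character(n); s <- integer(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:100) {
        gi <- sample.int(nrow(spans), 1)
        if (src_d[i] > 0) {
          si <- if (stats::runif(1) < 0.5) spans$end[gi] + src_d[i]
                else spans$start[gi] - src_d[i] - src_len[i]
        } else {
          si <- spans$start[gi] + src_off[i]
        }
        if (si >= 0 && si + src_len[i] <= chrom_lengths[[spans$chrom[gi]]]) {
          ch[i] <- spans$chrom[gi]; s[i] <- si
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("matched_null_test: no feasible placement for region ",
                    i, " after 100 re-draws")
    }
    list(chrom = ch, start = s, end = s + src_len)
  }
  generated <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    it_regions <- draw_iteration()
    p <- pool_p(it_regions$chrom, it_regions$start, it_regions$end)
    if (is.null(p)) {
      it_regions <- draw_iteration()                # one re-draw
      p <- pool_p(it_regions$chrom, it_regions$start, it_regions$end)
    }
    if (is.null(p)) {
      warning("matched_null_test: iteration ", it,
              " pooled zero SNPs twice; recording p = 1")
      p <- 1
    }
    generated[it] <- p
  }

  real_adj <- if (is.null(other_pvalues)) {
    min(1, m * real_p)
  } else {
    all_p <- c(real = real_p, other_pvalues)
    rep <- bh_report(pmax(pmin(all_p, 1), .P_FLOOR * 1e-4), m = max(m, length(all_p)))
    rep$adjusted_p[rep$class == "real"]
  }
  structure(list(real_p = real_p, real_adjusted_p = real_adj,
                 generated_p = generated,
                 n_generated_le_real = sum(generated <= real_p),
                 n_iter = n_iter, seed = seed, population = population,
                 background = background),
            class = "matched_null_result")
}

#' @export
print.matched_null_result <- function(x, ...) {
  cat(sprintf(
    "<matched_null_result> %s vs %s: real p = %.3g (adjusted %.3g); %d of %d generated p <= real\n",
    x$population, x$background, x$real_p, x$real_adjusted_p,
    x$n_generated_le_real, x$n_iter))
  invisible(x)
}
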