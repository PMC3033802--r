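#' Configuration for an end-to-end scan run
#'
#' Collects input paths (or in-memory objects), populations, backgrounds,
#' and testing parameters for [run_pipeline()]. Either `bundle` (an
#' in-memory `fixture_bundle`) or the path arguments must be given.
#'
#' @param out_dir output directory
#' @param bundle optional `fixture_bundle`; when given, `genes_path`,
#'   `region_beds`, `snps_path`, `outgroup_path` are ignored
#' @param genes_path GFF3/GTF file
#' @param region_beds named list of BED paths (labels = class names)
#' @param snps_path SNP TSV
#' @param outgroup_path outgroup TSV
#' @param populations population codes to scan
#' @param backgrounds subset of `c("genome", "ancestral_repeats")`
#' @param alpha FDR level
#' @param m_genome,m_repeats declared numbers of tests per background
#'   (`NULL` = number of classes actually tested)
#' @param alternative,exact_threshold,method Mann-Whitney settings
#' @param require_resequenced passed to [filter_snps()]
#' @param matched_null_classes labels to put through [matched_null_test()]
#' @param n_iter matched-null iterations
#' @param seed seed for all randomness in the run
#' @return a `run_config` list
#' @export
run_config <- function(out_dir, bundle = NULL, genes_path = NULL,
                       region_beds = list(), snps_path = NULL,
                       outgroup_path = NULL,
                       populations = c("AFR", "EUR", "CHN"),
                       backgrounds = c("genome", "ancestral_repeats"),
                       alpha = 0.05, m_genome = NULL, m_repeats = NULL,
                       alternative = "less", method = "auto",
                       exact_threshold = 50L, require_resequenced = TRUE,
                       matched_null_classes = character(), n_iter = 100L,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  backgrounds <- match.arg(backgrounds, several.ok = TRUE)
  if (is.null(bundle) &&
      (is.null(genes_path) || is.null(snps_path) || is.null(outgroup_path)))
    stop("run_config: give either a bundle or genes/snps/outgroup paths")
  structure(list(out_dir = out_dir, bundle = bundle, genes_path = genes_path,
                 region_beds = region_beds, snps_path = snps_path,
                 outgroup_path = outgroup_path, populations = populations,
                 backgrounds = backgrounds, alpha = alpha,
                 m_genome = m_genome, m_repeats = m_repeats,
                 alternative = alternative, method = method,
                 exact_threshold = as.integer(exact_threshold),
                 require_resequenced = require_resequenced,
                 matched_null_classes = matched_null_classes,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full negative-selection scan pipeline
#'
#' Stages: read inputs, filter SNPs, polarize against the outgroups, build
#' the class catalog and SNP membership, report per-class densities and
#' class intersections, scan every class against the configured backgrounds
#' and populations (Mann-Whitney + BH FDR), and optionally run the
#' matched-region permutation control for selected classes. All tables are
#' written as TSV, summaries as JSON, plus a provenance record sufficient to
#' reproduce the run.
#'
#' @param config a `run_config`
#' @return invisibly, a list with the in-memory stage outputs (`polarized`,
#'   `catalog`, `membership`, `density`, `scans`, `matched_null`, `paths`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (!is.null(config$bundle)) {
    b <- config$bundle
    genes <- b$genes; snps <- b$snps; outgroup <- b$outgroup
    supplied <- b$region_sets
    chrom_lengths <- b$config$chrom_lengths
  } else {
    genes <- read_genes(config$genes_path)
    snps <- read_snps(config$snps_path)
    outgroup <- read_outgroup(config$outgroup_path)
    supplied <- lapply(config$region_beds, read_region_set)
    names(supplied) <- names(config$region_beds)
    chrom_lengths <- NULL
  }
  bad_pop <- setdiff(config$populations, populations(snps))
  if (length(bad_pop) > 0)
    stop("run_pipeline: unknown population(s): ",
         paste(bad_pop, collapse = ", "))

  filt <- filter_snps(snps, config$require_resequenced)
  pol <- polarize_snps(filt$kept, outgroup)
  polarized <- pol$polarized
  write_polarized(polarized, file.path(config$out_dir, "polarized.tsv"))
  utils::write.table(
    data.frame(stage = c(names(filt$drop_counts), names(pol$counts)),
               count = c(unname(filt$drop_counts), unname(pol$counts))),
    file.path(config$out_dir, "filter_log.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  catalog <- build_class_catalog(genes, supplied)
  membership <- assign_snps_to_classes(polarized, catalog)
  density <- class_density_report(membership, catalog)
  utils::write.table(density, file.path(config$out_dir, "density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  venn_labels <- intersect(c("promoter", "coding", "splice_site"),
                           names(membership))
  if (length(venn_labels) >= 2) {
    ic <- intersection_counts(membership, venn_labels)
    jsonlite::write_json(ic, file.path(config$out_dir, "intersections.json"))
  }

  scans <- list()
  for (bg in config$backgrounds) {
    m_decl <- if (bg == "genome") config$m_genome else config$m_repeats
    for (pop in config$populations) {
      key <- paste(bg, pop, sep = "_")
      sc <- run_scan(polarized, membership, pop, background = bg,
                     alpha = config$alpha, m = m_decl,
                     alternative = config$alternative,
                     method = config$method,
                     exact_threshold = config$exact_threshold)
      scans[[key]] <- sc
      tab <- merge(sc$results, as.data.frame(sc$fdr)[, c("class", "rank",
                   "critical_value", "adjusted_p", "significant")],
                   by = "class")
      tab <- tab[order(tab$rank), ]
      utils::write.table(tab,
        file.path(config$out_dir, sprintf("scan_%s.tsv", key)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      hists <- do.call(rbind, lapply(names(sc$summaries), function(cl)
        cbind(class = cl, sc$summaries[[cl]]$histogram)))
      utils::write.table(hists,
        file.path(config$out_dir, sprintf("daf_hist_%s.tsv", key)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  mn <- list()
  if (length(config$matched_null_classes) > 0) {
    if (is.null(chrom_lengths))
      stop("run_pipeline: matched-null control needs chromosome lengths ",
           "(available when running from a bundle)")
    for (cl in config$matched_null_classes) {
      rs <- catalog$region_sets[[cl]]
      if (is.null(rs)) stop("run_pipeline: unknown matched-null class ", cl)
      for (bg in config$backgrounds) {
        key <- paste(cl, bg, sep = "_")
        mn[[key]] <- matched_null_test(
          rs, polarized, genes, chrom_lengths,
          population = config$populations[1], background = bg,
          background_ids = membership[["ancestral_repeats"]],
          n_iter = config$n_iter, seed = config$seed + 1000L,
          alternative = config$alternative)
      }
    }
    jsonlite::write_json(
      lapply(mn, function(x) x[c("real_p", "real_adjusted_p",
                                 "n_generated_le_real", "n_iter")]),
      file.path(config$out_dir, "matched_null.json"), auto_unbox = TRUE,
      digits = NA)
  }

  prov <- list(
    package = "dafscan",
    version = as.character(utils::packageVersion("dafscan")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "bundle")],
    timestamp_free = TRUE   # outputs are a pure function of config + inputs
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)

  invisible(list(polarized = polarized, catalog = catalog,
                 membership = membership, density = density, scans = scans,
                 matched_null = mn,
                 paths = list.files(config$out_dir, full.names = TRUE)))
}
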