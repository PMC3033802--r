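#' Promoter regions derived from gene models
#'
#' One strand-aware window per transcript covering the 1000 bases upstream of
#' the transcription start site, the TSS base itself, and the 200 bases
#' downstream: 1201 bp per transcript before clipping at the chromosome start
#' and merging across transcripts.
#'
#' @param genes a `gene_models` object (all genes must be stranded)
#' @return a merged `region_set` labelled `"promoter"`
#' @export
promoter_regions <- function(genes) {
  rows <- list()
  for (g in genes) {
    if (!(g$strand %in% c("+", "-")))
      stop("promoter_regions: promoter undefined for unstranded gene ",
           g$gene_id)
    for (tx in g$transcripts) {
      ex <- tx$exons
      if (g$strand == "+") {
        tss <- min(ex$start)                 # first transcribed base
        w <- c(tss - 1000L, tss + 201L)
      } else {
        tss <- max(ex$end) - 1L              # last physical base
        w <- c(tss - 200L, tss + 1001L)
      }
      rows[[length(rows) + 1L]] <- c(w[1], w[2])
      names(rows)[length(rows)] <- g$chrom
    }
  }
  if (length(rows) == 0) return(.empty_rs("promoter"))
  m <- do.call(rbind, rows)
  m[, 1] <- pmax(m[, 1], 0L)                 # clip at chromosome start
  merge_regions(region_set(names(rows), m[, 1], m[, 2], label = "promoter"))
}

#' Splice control regions derived from gene models
#'
#' For every intron of every multi-exon transcript two strand-aware windows
#' are emitted, in transcript orientation:
#' * acceptor (intron/exon interface): 50 intronic bases upstream of the
#'   interface plus 2 exonic bases downstream (52 bp), covering the
#'   polypyrimidine tract;
#' * donor (exon/intron interface): 3 exonic bases upstream plus 6 intronic
#'   bases downstream (9 bp).
#'
#' Windows are clipped to the extent of the intron/exon that carries them when
#' those are shorter than the nominal window, then merged across transcripts.
#' Single-exon transcripts contribute nothing.
#'
#' @param genes a `gene_models` object
#' @return a merged `region_set` labelled `"splice_site"`
#' @export
splice_control_regions <- function(genes) {
  chroms <- character(); starts <- integer(); ends <- integer()
  add <- function(chrom, s, e) {
    if (e > s) {
      chroms <<- c(chroms, chrom); starts <<- c(starts, s); ends <<- c(ends, e)
    }
  }
  for (g in genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
      if (nrow(ex) < 2) next
      for (i in seq_len(nrow(ex) - 1L)) {
        s <- ex$end[i]; e <- ex$start[i + 1L]   # intron [s, e)
        ls <- ex$start[i]; re <- ex$end[i + 1L] # flanking exon extents
        if (g$strand == "+") {
          # donor at left boundary, acceptor at right boundary
          add(g$chrom, max(ls, s - 3L), s)            # donor exonic
          add(g$chrom, s, min(e, s + 6L))             # donor intronic
          add(g$chrom, max(s, e - 50L), e)            # acceptor intronic
          add(g$chrom, e, min(re, e + 2L))            # acceptor exonic
        } else {
          # transcription right-to-left: donor at right boundary
          add(g$chrom, e, min(re, e + 3L))            # donor exonic
          add(g$chrom, max(s, e - 6L), e)             # donor intronic
          add(g$chrom, s, min(e, s + 50L))            # acceptor intronic
          add(g$chrom, max(ls, s - 2L), s)            # acceptor exonic
        }
      }
    }
  }
  if (length(chroms) == 0) return(.empty_rs("splice_site"))
  merge_regions(region_set(chroms, starts, ends, label = "splice_site"))
}

#' Coding regions: union of all CDS intervals
#'
#' @param genes a `gene_models` object
#' @return a merged `region_set` labelled `"coding"` (empty, with a message,
#'   when no transcript carries a CDS)
#' @export
coding_regions <- function(genes) {
  chroms <- character(); starts <- integer(); ends <- integer()
  for (g in genes) for (tx in g$transcripts) {
    if (!is.null(tx$cds) && nrow(tx$cds) > 0) {
      chroms <- c(chroms, rep(g$chrom, nrow(tx$cds)))
      starts <- c(starts, tx$cds$start)
      ends <- c(ends, tx$cds$end)
    }
  }
  if (length(chroms) == 0) {
    message("coding_regions: no CDS in any gene; returning empty set")
    return(.empty_rs("coding"))
  }
  merge_regions(region_set(chroms, starts, ends, label = "coding"))
}

#' Subset a constrained-element (or any) region set relative to genes
#'
#' Rules:
#' * `"minus_coding"` / `"minus_genes"`: base-wise subtraction of the coding
#'   union / merged gene spans (elements may be truncated or split);
#' * `"min_distance"`: keep whole elements whose edge distance to the nearest
#'   gene span is at least `min_bp` (elements are kept or dropped atomically,
#'   never truncated).
#'
#' @param constrained a `region_set`
#' @param genes a `gene_models` object
#' @param rule one of `"minus_coding"`, `"minus_genes"`, `"min_distance"`
#' @param min_bp distance threshold in bp (required for `"min_distance"`)
#' @param label label for the result
#' @return a `region_set`
#' @export
subset_constrained <- function(constrained, genes,
                               rule = c("minus_coding", "minus_genes",
                                        "min_distance"),
                               min_bp = NULL, label = NULL) {
  rule <- match.arg(rule)
  base <- region_label(constrained)
  if (rule == "minus_coding") {
    out <- subtract_regions(constrained, coding_regions(genes),
                            label = label %||% paste0(base, "_minus_coding"))
  } else if (rule == "minus_genes") {
    out <- subtract_regions(constrained, gene_span_regions(genes),
                            label = label %||% paste0(base, "_minus_genes"))
  } else {
    if (is.null(min_bp)) stop("subset_constrained: min_distance needs min_bp")
    d <- distance_to_nearest_gene(constrained, genes)
    out <- constrained[d >= min_bp, , drop = FALSE]
    attr(out, "label") <- label %||% sprintf("%s_%s_from_genes", base,
                                             .bp_label(min_bp))
    class(out) <- c("region_set", "data.frame")
  }
  out
}

.bp_label <- function(bp) {
  if (bp %% 1000 == 0) paste0(bp / 1000, "kb") else paste0(bp, "bp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the catalog of annotation classes
#'
#' Derives gene-structure classes (promoter, splice control, coding) from the
#' gene models, adds the supplied region sets verbatim, and, when a
#' constrained-element set is among them, derives the four standard
#' constrained subsets (minus coding, minus genes, at least 1 kb from genes,
#' at least 100 kb from genes).
#'
#' @param genes a `gene_models` object
#' @param supplied named list of `region_set` objects (names override each
#'   set's own label), e.g. constrained elements, histone-mark regions,
#'   ancestral repeats
#' @param constrained_label which supplied set to treat as constrained
#'   elements (`NULL` to skip subset derivation)
#' @param derive_gene_classes derive promoter/splice/coding classes?
#' @return a `class_catalog`: list with `region_sets` (named list) and
#'   `provenance` (named list of character descriptions)
#' @export
build_class_catalog <- function(genes, supplied = list(),
                                constrained_label = "constrained_elements",
                                derive_gene_classes = TRUE) {
  sets <- list()
  prov <- list()
  if (derive_gene_classes && length(genes) > 0) {
    sets$promoter <- promoter_regions(genes)
    sets$splice_site <- splice_control_regions(genes)
    sets$coding <- coding_regions(genes)
    prov[c("promoter", "splice_site", "coding")] <- "derived_from_genes"
  }
  for (nm in names(supplied)) {
    if (nm %in% names(sets)) stop("build_class_catalog: duplicate label ", nm)
    s <- supplied[[nm]]
    attr(s, "label") <- nm
    sets[[nm]] <- s
    prov[[nm]] <- "supplied"
  }
  if (!is.null(constrained_label) && constrained_label %in% names(sets)) {
    ce <- sets[[constrained_label]]
    der <- list(
      subset_constrained(ce, genes, "minus_coding"),
      subset_constrained(ce, genes, "minus_genes"),
      subset_constrained(ce, genes, "min_distance", min_bp = 1000L),
      subset_constrained(ce, genes, "min_distance", min_bp = 100000L)
    )
    rules <- c("minus_coding", "minus_genes", "min_distance(1kb)",
               "min_distance(100kb)")
    for (i in seq_along(der)) {
      lbl <- region_label(der[[i]])
      if (lbl %in% names(sets))
        stop("build_class_catalog: duplicate label ", lbl)
      sets[[lbl]] <- der[[i]]
      prov[[lbl]] <- sprintf("derived_by_subset(%s, %s)",
                             constrained_label, rules[i])
    }
  }
  structure(list(region_sets = sets, provenance = prov),
            class = "class_catalog")
}

#' @export
print.class_catalog <- function(x, ...) {
  cat(sprintf("<class_catalog> %d classes\n", length(x$region_sets)))
  for (nm in names(x$region_sets))
    cat(sprintf("  %-38s %8d intervals %12d bp  [%s]\n", nm,
                nrow(x$region_sets[[nm]]),
                region_length(x$region_sets[[nm]]), x$provenance[[nm]]))
  invisible(x)
}

#' Assign SNPs to annotation classes
#'
#' A SNP occupies the 1-bp interval `[pos, pos+1)` and belongs to a class iff
#' that interval intersects any interval of the class's region set (so a SNP
#' at `pos = end` of a half-open interval is outside it). Classes are not
#' mutually exclusive. Implemented with a sorted overlap sweep
#' (`GenomicRanges::findOverlaps`).
#'
#' @param snps a SNP table (data.frame with `snp_id`, `chrom`, `pos`) --
#'   filtered/polarized tables work directly
#' @param catalog a `class_catalog`, or a named list of `region_set`s
#' @return a `class_membership`: named list mapping class label to the sorted
#'   character vector of member `snp_id`s
#' @export
assign_snps_to_classes <- function(snps, catalog) {
  sets <- if (inherits(catalog, "class_catalog")) catalog$region_sets else catalog
  sg <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos + 1L, width = 1L))
  out <- lapply(sets, function(rs) {
    if (nrow(rs) == 0) return(character())
    gr <- .rs_to_gr(rs)
    lev <- union(GenomeInfoDb::seqlevels(sg), GenomeInfoDb::seqlevels(gr))
    s2 <- sg; GenomeInfoDb::seqlevels(s2) <- lev
    GenomeInfoDb::seqlevels(gr) <- lev
    hit <- GenomicRanges::findOverlaps(s2, gr, ignore.strand = TRUE)
    sort(unique(snps$snp_id[S4Vectors::queryHits(hit)]))
  })
  structure(out, class = "class_membership")
}

#' @export
print.class_membership <- function(x, ...) {
  cat("<class_membership>\n")
  for (nm in names(x)) cat(sprintf("  %-38s %8d SNPs\n", nm, length(x[[nm]])))
  invisible(x)
}

#' SNP density in SNPs per kilobase
#'
#' @param n_snps number of SNPs in the class
#' @param size_kb merged class size in kilobases
#' @param digits decimal places in the reported density
#' @return `n_snps / size_kb` rounded, or `NA` for zero-size classes
#' @export
snp_density <- function(n_snps, size_kb, digits = 2) {
  ifelse(size_kb > 0, round(n_snps / size_kb, digits), NA_real_)
}

#' Per-class SNP count, size, and density report
#'
#' Class sizes are the merged interval lengths; the unmerged (raw summed)
#' length is reported alongside since supplied sets may contain overlapping
#' intervals.
#'
#' @param membership a `class_membership`
#' @param catalog a `class_catalog` (or named list of `region_set`s) covering
#'   the membership labels
#' @return data.frame with `class`, `n_snps`, `size_kb`, `size_kb_raw`,
#'   `snps_per_kb` (2 decimals; `NA` for zero-size classes)
#' @export
class_density_report <- function(membership, catalog) {
  sets <- if (inherits(catalog, "class_catalog")) catalog$region_sets else catalog
  labs <- names(membership)
  n <- vapply(membership, length, 0L)
  bp <- vapply(labs, function(l) region_length(sets[[l]]), 0)
  raw <- vapply(labs, function(l) {
    rs <- sets[[l]]
    if (nrow(rs) == 0) 0 else sum(rs$end - rs$start)
  }, 0)
  data.frame(class = labs, n_snps = unname(n),
             size_kb = unname(round(bp / 1000, 3)),
             size_kb_raw = unname(round(raw / 1000, 3)),
             snps_per_kb = unname(snp_density(n, bp / 1000)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Counts of every region of the Venn partition of 2-4 classes
#'
#' @param membership a `class_membership`
#' @param labels 2 to 4 class labels
#' @return data.frame with one logical column per label plus `count`; the
#'   all-`FALSE` pattern is omitted, so counts sum to the size of the union
#' @export
intersection_counts <- function(membership, labels) {
  if (length(labels) < 2 || length(labels) > 4)
    stop("intersection_counts: between 2 and 4 labels supported")
  missing <- setdiff(labels, names(membership))
  if (length(missing) > 0)
    stop("intersection_counts: unknown class ", missing[1])
  ids <- sort(unique(unlist(membership[labels], use.names = FALSE)))
  inset <- vapply(labels, function(l) ids %in% membership[[l]],
                  logical(length(ids)))
  if (length(ids) == 1) inset <- matrix(inset, nrow = 1,
                                        dimnames = list(NULL, labels))
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), length(labels)))[-1, , drop = FALSE]
  names(pat) <- labels
  pat$count <- apply(pat, 1, function(p) {
    if (length(ids) == 0) return(0L)
    sum(apply(inset == matrix(as.logical(p), nrow(inset), length(labels),
                              byrow = TRUE), 1, all))
  })
  rownames(pat) <- NULL
  pat
}
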