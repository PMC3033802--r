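#' Construct a region set
#'
#' A region set is a named collection of genomic intervals, the basic unit in
#' which annotation classes (constrained elements, histone-mark regions,
#' promoters, ...) are represented. All coordinates in this package are
#' 0-based half-open (`[start, end)`), i.e. native BED convention; GFF3/GTF
#' input is converted on read.
#'
#' @param chrom character vector of chromosome names (taken verbatim; no
#'   `chr`-prefix normalisation is ever applied).
#' @param start,end integer vectors; `0 <= start < end` required.
#' @param strand one of `"+"`, `"-"`, `"*"`, recycled.
#' @param label class name of the set (e.g. `"constrained_elements"`).
#' @return a `region_set`: a data.frame with columns `chrom`, `start`, `end`,
#'   `strand` and a `"label"` attribute.
#' @examples
#' region_set("chr1", c(100, 500), c(200, 900), label = "demo")
#' @export
region_set <- function(chrom, start, end, strand = "*", label = "regions") {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom)),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0) {
    if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
      stop("region_set: chrom must be non-empty")
    if (any(df$start < 0)) stop("region_set: start must be >= 0")
    if (any(df$end <= df$start))
      stop("region_set: end must be > start (rows: ",
           paste(which(df$end <= df$start), collapse = ", "), ")")
    if (!all(df$strand %in% c("+", "-", "*")))
      stop("region_set: strand must be one of +, -, *")
  }
  attr(df, "label") <- label
  class(df) <- c("region_set", "data.frame")
  df
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s'> %d intervals, %d merged bp\n",
              region_label(x), nrow(x), region_length(x)))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Label of a region set
#' @param x a `region_set`
#' @return the label string
#' @export
region_label <- function(x) {
  lbl <- attr(x, "label", exact = TRUE)
  if (is.null(lbl)) "regions" else lbl
}

## 0-based half-open data.frame -> GRanges (1-based closed) and back.
.rs_to_gr <- function(rs) {
  if (nrow(rs) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = rs$chrom,
    ranges = IRanges::IRanges(start = rs$start + 1L, end = rs$end),
    strand = if ("strand" %in% names(rs)) rs$strand else "*"
  )
}

.gr_to_rs <- function(gr, label = "regions") {
  region_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    label = label
  )
}

## zero-width anchors at SNP base positions; distance() then measures from the
## base itself, so a SNP at pos p is 1000 bp from a gene starting at p + 1000.
.snp_points_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 0L))
}

.empty_rs <- function(label) {
  region_set(character(), integer(), integer(), character(), label = label)
}

#' Merge overlapping and adjacent intervals of a region set
#'
#' @param rs a `region_set`
#' @return a `region_set` with the same label whose intervals are disjoint,
#'   sorted, and strand-blind (strand set to `*`).
#' @export
merge_regions <- function(rs) {
  if (nrow(rs) == 0) return(rs)
  gr <- GenomicRanges::reduce(.rs_to_gr(rs), ignore.strand = TRUE)
  .gr_to_rs(gr, label = region_label(rs))
}

#' Total merged length of a region set in base pairs
#'
#' Overlapping intervals are counted once: this is the "size of region" a
#' per-kilobase SNP density refers to.
#'
#' @param rs a `region_set`
#' @return integer, total merged bp
#' @export
region_length <- function(rs) {
  if (nrow(rs) == 0) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(.rs_to_gr(rs),
                                                 ignore.strand = TRUE)))
}

#' Base-wise subtraction of one region set from another
#'
#' Returns the bases of `x` not covered by `y`; intervals of `x` may be
#' truncated or split. Used to build classes such as "constrained elements
#' minus coding".
#'
#' @param x,y `region_set` objects
#' @param label label of the result (default `"<x> minus <y>"`)
#' @return a merged `region_set`
#' @export
subtract_regions <- function(x, y,
                             label = paste(region_label(x), "minus",
                                           region_label(y))) {
  if (nrow(x) == 0) return(.empty_rs(label))
  if (nrow(y) == 0) {
    out <- merge_regions(x)
    attr(out, "label") <- label
    return(out)
  }
  gx <- .rs_to_gr(x)
  gy <- .rs_to_gr(y)
  lev <- union(GenomeInfoDb::seqlevels(gx), GenomeInfoDb::seqlevels(gy))
  GenomeInfoDb::seqlevels(gx) <- lev
  GenomeInfoDb::seqlevels(gy) <- lev
  gd <- GenomicRanges::setdiff(gx, gy, ignore.strand = TRUE)
  if (length(gd) == 0) return(.empty_rs(label))
  .gr_to_rs(gd, label = label)
}

#' Distance from intervals or SNPs to the nearest gene
#'
#' For a `region_set` query the distance is the edge-to-edge gap between the
#' interval and the nearest gene span (0 when they intersect). For a SNP table
#' the distance is measured from the SNP base position itself, so a SNP at
#' position 5000 is 1000 bp from a gene span starting at 6000. Queries on
#' chromosomes carrying no gene get `Inf`.
#'
#' @param x a `region_set`, or a data.frame with `chrom` and `pos` columns
#'   (SNP table), or a `polarized_snps` table
#' @param genes a `gene_models` object (see [read_genes()])
#' @return numeric vector of distances, one per row of `x`
#' @export
distance_to_nearest_gene <- function(x, genes) {
  spans <- gene_spans(genes)
  if (inherits(x, "region_set")) {
    q <- .rs_to_gr(x)
  } else if (is.data.frame(x) && all(c("chrom", "pos") %in% names(x))) {
    q <- .snp_points_gr(x$chrom, x$pos)
  } else {
    stop("distance_to_nearest_gene: x must be a region_set or a table with chrom/pos")
  }
  .dist_to_gr(q, .rs_to_gr(spans))
}

.dist_to_gr <- function(q, subject) {
  out <- rep(Inf, length(q))
  if (length(subject) == 0 || length(q) == 0) return(out)
  lev <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(q) <- lev
  GenomeInfoDb::seqlevels(subject) <- lev
  hits <- GenomicRanges::distanceToNearest(q, subject, ignore.strand = TRUE)
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Read a BED file into a region set
#'
#' BED is 0-based half-open natively, so intervals are loaded verbatim.
#' Overlapping intervals are permitted on load; merging is an explicit
#' downstream choice ([merge_regions()]).
#'
#' @param path BED3+ file (plain or gzip)
#' @param label class name to attach
#' @return a `region_set`
#' @export
read_region_set <- function(path, label = sub("\\.bed(\\.gz)?$", "", basename(path))) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) return(.empty_rs(label))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("read_region_set: fewer than 3 fields at line ", which(nf < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end)))
    stop("read_region_set: non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop("read_region_set: end <= start at line ", bad[1])
  strand <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*"
  }, "")
  region_set(chrom, start, end, strand, label = label)
}

#' Write a region set to BED
#'
#' @param rs a `region_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_region_set <- function(rs, path) {
  df <- data.frame(rs$chrom, rs$start, rs$end,
                   name = region_label(rs), score = 0L, strand = rs$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
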