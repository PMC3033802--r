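#' Construct a gene model
#'
#' @param gene_id gene identifier
#' @param chrom chromosome name
#' @param strand `"+"` or `"-"`
#' @param start,end 0-based half-open gene span
#' @param transcripts list of transcripts, each a list with `transcript_id`,
#'   `exons` (data.frame with 0-based `start`/`end`, sorted, non-overlapping)
#'   and `cds` (data.frame, possibly empty; must be covered by the exons)
#' @return a `gene_model` list
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, transcripts) {
  stopifnot(strand %in% c("+", "-"), end > start, start >= 0)
  for (tx in transcripts) {
    ex <- tx$exons
    if (nrow(ex) == 0) stop("gene_model: transcript without exons in ", gene_id)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("gene_model: overlapping exons in transcript ", tx$transcript_id)
    if (!is.null(tx$cds) && nrow(tx$cds) > 0) {
      exr <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      cdr <- IRanges::reduce(IRanges::IRanges(tx$cds$start + 1L, tx$cds$end))
      if (sum(IRanges::width(IRanges::setdiff(cdr, exr))) > 0)
        stop("gene_model: CDS outside exons in transcript ", tx$transcript_id)
    }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 transcripts = transcripts),
            class = "gene_model")
}

.gene_models <- function(genes) {
  structure(genes, class = "gene_models")
}

#' Bundle gene models into a `gene_models` collection
#' @param ... `gene_model` objects (or a single list of them)
#' @return a `gene_models` object
#' @export
gene_models <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && !inherits(gs[[1]], "gene_model")) gs <- gs[[1]]
  stopifnot(all(vapply(gs, inherits, TRUE, "gene_model")))
  .gene_models(gs)
}

#' @export
print.gene_models <- function(x, ...) {
  ntx <- sum(vapply(x, function(g) length(g$transcripts), 0L))
  cat(sprintf("<gene_models> %d genes, %d transcripts on %d chromosome(s)\n",
              length(x), ntx, length(unique(vapply(x, `[[`, "", "chrom")))))
  invisible(x)
}

#' @export
`[.gene_models` <- function(x, i) .gene_models(unclass(x)[i])

#' Gene spans as a region set
#'
#' One interval per gene (union of its transcripts), with a `gene_id` column.
#'
#' @param genes a `gene_models` object
#' @return a `region_set` labelled `"genes"` with an extra `gene_id` column
#' @export
gene_spans <- function(genes) {
  if (length(genes) == 0) return(.empty_rs("genes"))
  rs <- region_set(
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0L, "start"),
    end = vapply(genes, `[[`, 0L, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    label = "genes"
  )
  rs$gene_id <- vapply(genes, `[[`, "", "gene_id")
  rs
}

#' Merged gene spans as a strand-blind region set
#' @param genes a `gene_models` object
#' @return a merged `region_set` labelled `"genes"`
#' @export
gene_span_regions <- function(genes) merge_regions(gene_spans(genes))

#' Read gene models from GFF3 or GTF
#'
#' Uses `rtracklayer` for parsing; 1-based inclusive file coordinates are
#' converted to the package's 0-based half-open convention. GFF3 files are
#' expected to carry a gene > mRNA/transcript > exon/CDS hierarchy via
#' `ID`/`Parent` attributes; GTF files are grouped by `gene_id` and
#' `transcript_id`. Unstranded gene records are rejected with a warning.
#' Malformed hierarchies (exon or CDS pointing at an unknown transcript, CDS
#' outside any exon) raise an error naming the offending feature.
#'
#' @param path GFF3/GFF or GTF file (gzip transparent)
#' @return a `gene_models` object
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_gtf <- grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE) ||
    (!("ID" %in% names(md)) && "gene_id" %in% names(md))
  if (is_gtf) .genes_from_gtf(gr) else .genes_from_gff3(gr)
}

.feat_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

.genes_from_gff3 <- function(gr) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  pos <- .feat_df(gr)
  ids <- as.character(md$ID)
  parent <- md$Parent
  first_parent <- vapply(seq_along(gr), function(i) {
    p <- parent[[i]]
    if (length(p) == 0) NA_character_ else p[[1]]
  }, "")

  gi <- which(type == "gene")
  ti <- which(type %in% c("mRNA", "transcript"))
  fi <- which(type %in% c("exon", "CDS"))
  tx_by_gene <- split(ti, first_parent[ti])
  feat_by_tx <- split(fi, first_parent[fi])

  bad_tx <- setdiff(names(tx_by_gene), ids[gi])
  if (length(bad_tx) > 0)
    stop("read_genes: transcript parent '", bad_tx[1], "' is not a gene feature")
  bad_ft <- setdiff(names(feat_by_tx), ids[ti])
  if (length(bad_ft) > 0)
    stop("read_genes: exon/CDS parent '", bad_ft[1],
         "' is not a transcript feature")

  out <- list()
  for (g in gi) {
    gid <- ids[g]
    if (!(pos$strand[g] %in% c("+", "-"))) {
      warning("read_genes: rejecting unstranded gene ", gid)
      next
    }
    txs <- list()
    for (t in tx_by_gene[[gid]]) {
      tid <- ids[t]
      feats <- feat_by_tx[[tid]]
      exi <- feats[type[feats] == "exon"]
      cdi <- feats[type[feats] == "CDS"]
      if (length(exi) == 0)
        stop("read_genes: transcript ", tid, " has no exons")
      ex <- pos[exi, c("start", "end"), drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- pos[cdi, c("start", "end"), drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      txs[[tid]] <- list(transcript_id = tid, exons = ex, cds = cds)
    }
    if (length(txs) == 0)   # gene with no annotated transcript: single-exon span
      txs <- list(list(transcript_id = paste0(gid, ".t1"),
                       exons = pos[g, c("start", "end"), drop = FALSE],
                       cds = pos[0, c("start", "end"), drop = FALSE]))
    out[[gid]] <- gene_model(gid, pos$chrom[g], pos$strand[g],
                             pos$start[g], pos$end[g], txs)
  }
  .gene_models(unname(out))
}

.genes_from_gtf <- function(gr) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  pos <- .feat_df(gr)
  keep <- type %in% c("exon", "CDS")
  pos <- pos[keep, , drop = FALSE]
  type <- type[keep]
  gid <- as.character(md$gene_id)[keep]
  tid <- as.character(md$transcript_id)[keep]
  out <- list()
  for (g in unique(gid)) {
    sel <- gid == g
    strand <- unique(pos$strand[sel])
    if (length(strand) != 1 || !(strand %in% c("+", "-"))) {
      warning("read_genes: rejecting unstranded or mixed-strand gene ", g)
      next
    }
    txs <- list()
    for (t in unique(tid[sel])) {
      tsel <- sel & tid == t
      ex <- pos[tsel & type == "exon", c("start", "end"), drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- pos[tsel & type == "CDS", c("start", "end"), drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      if (nrow(ex) == 0) stop("read_genes: transcript ", t, " has no exons")
      txs[[t]] <- list(transcript_id = t, exons = ex, cds = cds)
    }
    allex <- do.call(rbind, lapply(txs, `[[`, "exons"))
    out[[g]] <- gene_model(g, unique(pos$chrom[sel]), strand,
                           min(allex$start), max(allex$end), txs)
  }
  .gene_models(unname(out))
}

#' Write gene models to GFF3
#'
#' @param genes a `gene_models` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, src, type, s0, e0, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, s0 + 1L, e0, strand, attrs)
  for (g in genes) {
    writeLines(fmt(g$chrom, "dafscan", "gene", g$start, g$end, g$strand,
                   paste0("ID=", g$gene_id)), con)
    for (tx in g$transcripts) {
      ex <- tx$exons
      writeLines(fmt(g$chrom, "dafscan", "mRNA", min(ex$start), max(ex$end),
                     g$strand, paste0("ID=", tx$transcript_id,
                                      ";Parent=", g$gene_id)), con)
      for (i in seq_len(nrow(ex)))
        writeLines(fmt(g$chrom, "dafscan", "exon", ex$start[i], ex$end[i],
                       g$strand, paste0("Parent=", tx$transcript_id)), con)
      if (!is.null(tx$cds)) for (i in seq_len(nrow(tx$cds)))
        writeLines(fmt(g$chrom, "dafscan", "CDS", tx$cds$start[i],
                       tx$cds$end[i], g$strand,
                       paste0("Parent=", tx$transcript_id)), con)
    }
  }
  invisible(path)
}
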