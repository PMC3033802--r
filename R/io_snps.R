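.FLAG_COLS <- c("multi_mapped", "on_Y", "in_dbsnp", "resequenced",
                "biallelic_substitution")
.FLAG_DEFAULTS <- c(multi_mapped = FALSE, on_Y = NA, in_dbsnp = TRUE,
                    resequenced = TRUE, biallelic_substitution = TRUE)

.as_snp_table <- function(df) {
  pops <- sub("^freq_", "", grep("^freq_", names(df), value = TRUE))
  attr(df, "populations") <- pops
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Populations carried by a SNP or polarized-SNP table
#' @param x a `snp_table` or `polarized_snps` object
#' @return character vector of population codes
#' @export
populations <- function(x) attr(x, "populations", exact = TRUE)

.validate_snps <- function(df) {
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id: ", df$snp_id[duplicated(df$snp_id)][1])
  freq_cols <- grep("^freq_", names(df), value = TRUE)
  if (length(freq_cols) == 0) stop("no freq_<POP> columns found")
  for (fc in freq_cols) {
    bad <- which(!is.na(df[[fc]]) & (df[[fc]] < 0 | df[[fc]] > 1))
    if (length(bad) > 0)
      stop("frequency outside [0,1] in ", fc, " (snp ", df$snp_id[bad[1]], ")")
  }
  if (any(df$pos < 0)) stop("negative SNP position")
  same <- which(df$allele_a == df$allele_b)
  if (length(same) > 0)
    stop("allele_a == allele_b for snp ", df$snp_id[same[1]])
  df
}

#' Read a SNP table from TSV
#'
#' Expected header: `snp_id chrom pos allele_a allele_b freq_<POP>...` plus
#' optional flag columns `multi_mapped on_Y in_dbsnp resequenced
#' biallelic_substitution` (logical or 0/1). `pos` is 0-based. Missing flag
#' columns default to permissive values (a message reports which); `on_Y`
#' defaults to `chrom` being `Y`/`chrY`. `freq_<POP>` is the frequency of
#' `allele_b` in that population.
#'
#' @param path TSV file (gzip transparent)
#' @return a `snp_table` data.frame; population codes in
#'   `populations(x)`
#' @export
read_snps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(snp_id = "character",
                                         chrom = "character",
                                         allele_a = "character",
                                         allele_b = "character"))
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("read_snps: missing column(s) ",
                             paste(miss, collapse = ", "))
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  defaulted <- character()
  for (fl in .FLAG_COLS) {
    if (!(fl %in% names(df))) {
      df[[fl]] <- if (fl == "on_Y") df$chrom %in% c("Y", "chrY")
                  else unname(.FLAG_DEFAULTS[fl])
      defaulted <- c(defaulted, fl)
    } else {
      df[[fl]] <- as.logical(df[[fl]])
    }
  }
  if (length(defaulted) > 0)
    message("read_snps: defaulting absent flag column(s): ",
            paste(defaulted, collapse = ", "))
  .as_snp_table(.validate_snps(df))
}

#' Write a SNP table to TSV
#' @param snps a `snp_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(.full_precision(as.data.frame(snps)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## serialise doubles with enough digits that a write/read round trip is exact
## (rank ties in DAF columns must survive the trip)
.full_precision <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Read outgroup (chimpanzee / macaque) allele calls
#'
#' TSV with header `snp_id chimp_allele macaque_allele`; alleles are single
#' bases A/C/G/T or `.`/`NA`/empty for missing.
#'
#' @param path TSV file
#' @return data.frame with `snp_id`, `chimp_allele`, `macaque_allele`
#'   (missing as `NA`)
#' @export
read_outgroup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ".", ""),
                          colClasses = "character")
  need <- c("snp_id", "chimp_allele", "macaque_allele")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("read_outgroup: missing column(s) ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stop("read_outgroup: duplicate snp_id ",
         df$snp_id[duplicated(df$snp_id)][1])
  ok <- function(x) is.na(x) | x %in% c("A", "C", "G", "T")
  if (!all(ok(df$chimp_allele)) || !all(ok(df$macaque_allele)))
    stop("read_outgroup: alleles must be single bases A/C/G/T or missing")
  df$snp_id <- as.character(df$snp_id)
  df
}

#' Write an outgroup-call table to TSV
#' @param outgroup data.frame as returned by [read_outgroup()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_outgroup <- function(outgroup, path) {
  utils::write.table(outgroup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read SNPs and outgroup calls from a VCF file
#'
#' A VCF route for callers whose upstream tooling emits VCF (parsed with
#' `VariantAnnotation`): biallelic SNV records become `snp_table` rows (REF as
#' `allele_a`, ALT as `allele_b`); records with symbolic, multiple, or
#' multi-base alleles are kept but flagged `biallelic_substitution = FALSE`
#' (the polarization filter drops them). Per-population frequencies are taken
#' from `AF_<POP>` INFO keys (frequency of the ALT allele) and outgroup
#' alleles from `AA_CHIMP` / `AA_MACAQUE` INFO keys.
#'
#' @param path VCF file (uncompressed or bgzip)
#' @return list with `snps` (a `snp_table`) and `outgroup` (data.frame)
#' @export
read_snps_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(seq_along(altl),
                 function(i) paste(as.character(altl[[i]]), collapse = ","), "")
  bases <- c("A", "C", "G", "T")
  biallelic <- lengths(altl) == 1 & ref %in% bases & alt1 %in% bases
  info <- VariantAnnotation::info(vcf)
  af_cols <- grep("^AF_", names(info), value = TRUE)
  if (length(af_cols) == 0)
    stop("read_snps_vcf: no AF_<POP> INFO fields declared")
  scalar <- function(x) {          # Number=1 gives a vector, Number=A a List
    if (is.list(x) || methods::is(x, "List"))
      vapply(x, function(v) if (length(v) == 0) NA else v[[1]], x[[1]][1])
    else x
  }
  df <- data.frame(
    snp_id = names(rr), chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    allele_a = ref,
    allele_b = ifelse(biallelic, alt1,
                      vapply(ref, function(r) setdiff(bases, r)[1], "")),
    stringsAsFactors = FALSE
  )
  for (ac in af_cols)
    df[[sub("^AF_", "freq_", ac)]] <- as.numeric(scalar(info[[ac]]))
  df$multi_mapped <- FALSE
  df$on_Y <- df$chrom %in% c("Y", "chrY")
  df$in_dbsnp <- TRUE
  df$resequenced <- TRUE
  df$biallelic_substitution <- biallelic
  clean_base <- function(x) {
    x <- as.character(scalar(x))
    x[!x %in% bases] <- NA
    x
  }
  og <- data.frame(
    snp_id = df$snp_id,
    chimp_allele = if ("AA_CHIMP" %in% names(info))
      clean_base(info$AA_CHIMP) else NA_character_,
    macaque_allele = if ("AA_MACAQUE" %in% names(info))
      clean_base(info$AA_MACAQUE) else NA_character_,
    stringsAsFactors = FALSE
  )
  list(snps = .as_snp_table(.validate_snps(df)), outgroup = og)
}
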