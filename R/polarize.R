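#' Apply the standard SNP quality filters
#'
#' Keeps SNPs with `multi_mapped = FALSE`, `on_Y = FALSE`, `in_dbsnp = TRUE`,
#' `biallelic_substitution = TRUE`, and (optionally) `resequenced = TRUE`.
#' Dropped SNPs are partitioned by the *first* failing rule in that fixed
#' order, so drop-reason accounting is deterministic.
#'
#' @param snps a `snp_table`
#' @param require_resequenced restrict to resequenced SNPs (minimises
#'   ascertainment bias between genic and non-genic regions)?
#' @return list with `kept` (a `snp_table`), `drop_counts` (named integer
#'   vector over the rules), and `dropped` (data.frame of `snp_id`, `reason`)
#' @export
filter_snps <- function(snps, require_resequenced = TRUE) {
  rules <- list(
    multi_mapped = snps$multi_mapped,
    on_Y = snps$on_Y,
    not_in_dbsnp = !snps$in_dbsnp,
    not_biallelic_substitution = !snps$biallelic_substitution
  )
  if (require_resequenced)
    rules$not_resequenced <- !snps$resequenced
  reason <- rep(NA_character_, nrow(snps))
  for (nm in names(rules)) {
    fail <- is.na(reason) & !is.na(rules[[nm]]) & rules[[nm]]
    reason[fail] <- nm
  }
  kept <- snps[is.na(reason), , drop = FALSE]
  attr(kept, "populations") <- populations(snps)
  class(kept) <- class(snps)
  drop_counts <- vapply(names(rules),
                        function(nm) sum(reason == nm, na.rm = TRUE), 0L)
  list(kept = kept,
       drop_counts = drop_counts,
       dropped = data.frame(snp_id = snps$snp_id[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

#' Polarize SNPs against chimpanzee and macaque outgroup calls
#'
#' The ancestral allele is the chimpanzee call when it matches one of the two
#' human alleles; otherwise the macaque call is consulted; when neither
#' matches (missing calls count as non-matching) the SNP is discarded. The
#' derived allele is the other human allele, and the per-population derived
#' allele frequency (DAF) is computed from the stored `allele_b` frequencies.
#'
#' @param snps a filtered `snp_table`
#' @param outgroup outgroup-call table ([read_outgroup()] format); SNPs
#'   without an outgroup row are discarded with reason `"no_outgroup"` and a
#'   warning
#' @return list with `polarized` (a `polarized_snps` data.frame: `snp_id`,
#'   `chrom`, `pos`, `ancestral`, `derived`, `source`, `daf_<POP>...`),
#'   `discarded` (data.frame of `snp_id`, `reason`), and `counts` (named:
#'   `chimp`, `macaque`, `discarded`)
#' @export
polarize_snps <- function(snps, outgroup) {
  idx <- match(snps$snp_id, outgroup$snp_id)
  if (anyNA(idx))
    warning("polarize_snps: ", sum(is.na(idx)),
            " SNP(s) without an outgroup call; discarded")
  chimp <- outgroup$chimp_allele[idx]
  mac <- outgroup$macaque_allele[idx]
  chimp_match <- !is.na(chimp) &
    (chimp == snps$allele_a | chimp == snps$allele_b)
  mac_match <- !is.na(mac) & (mac == snps$allele_a | mac == snps$allele_b)

  source <- ifelse(chimp_match, "chimp",
                   ifelse(mac_match, "macaque", NA_character_))
  ancestral <- ifelse(chimp_match, chimp, ifelse(mac_match, mac, NA))
  keep <- !is.na(source)
  derived <- ifelse(ancestral == snps$allele_a, snps$allele_b, snps$allele_a)

  pol <- data.frame(snp_id = snps$snp_id[keep], chrom = snps$chrom[keep],
                    pos = snps$pos[keep], ancestral = ancestral[keep],
                    derived = derived[keep], source = source[keep],
                    stringsAsFactors = FALSE)
  pops <- populations(snps)
  for (p in pops) {
    fb <- snps[[paste0("freq_", p)]][keep]
    pol[[paste0("daf_", p)]] <-
      ifelse(pol$derived == snps$allele_b[keep], fb, 1 - fb)
  }
  attr(pol, "populations") <- pops
  class(pol) <- c("polarized_snps", "data.frame")

  disc_reason <- ifelse(is.na(idx), "no_outgroup", "outgroup_mismatch")
  discarded <- data.frame(snp_id = snps$snp_id[!keep],
                          reason = disc_reason[!keep],
                          stringsAsFactors = FALSE)
  list(polarized = pol, discarded = discarded,
       counts = c(chimp = sum(source == "chimp", na.rm = TRUE),
                  macaque = sum(source == "macaque", na.rm = TRUE),
                  discarded = sum(!keep)))
}

#' Write / read a polarized-SNP table
#'
#' TSV with header `snp_id chrom pos ancestral derived source daf_<POP>...`.
#'
#' @param polarized a `polarized_snps` data.frame
#' @param path file path
#' @return `path` (write) / a `polarized_snps` data.frame (read)
#' @export
write_polarized <- function(polarized, path) {
  utils::write.table(.full_precision(as.data.frame(polarized)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polarized
#' @export
read_polarized <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ancestral", "derived", "source")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("read_polarized: missing column(s) ",
                             paste(miss, collapse = ", "))
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  attr(df, "populations") <- sub("^daf_", "", grep("^daf_", names(df),
                                                   value = TRUE))
  class(df) <- c("polarized_snps", "data.frame")
  df
}
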