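#' Remove SNPs overlapping both sides of a class/background comparison
#'
#' Mirrors the two overlap policies of the scan: against the genome-wide
#' background the overlapping SNPs are removed from the *background only*
#' (the class is never changed); against the ancestral-repeat background they
#' are removed from *both* sides, leaving disjoint sets.
#'
#' @param class_ids,background_ids character vectors of SNP ids
#' @param policy `"genome_background"` or `"ancestral_repeat_background"`
#' @return list with `class_ids` and `background_ids`
#' @export
remove_overlap <- function(class_ids, background_ids,
                           policy = c("genome_background",
                                      "ancestral_repeat_background")) {
  policy <- match.arg(policy)
  if (policy == "genome_background") {
    out <- list(class_ids = class_ids,
                background_ids = setdiff(background_ids, class_ids))
  } else {
    out <- list(class_ids = setdiff(class_ids, background_ids),
                background_ids = setdiff(background_ids, class_ids))
  }
  if (length(out$class_ids) == 0 || length(out$background_ids) == 0)
    stop("remove_overlap: degenerate comparison (empty class or background ",
         "after overlap removal)")
  out
}

.P_FLOOR <- 1e-8

#' Mann-Whitney U test of two DAF samples
#'
#' Rank-sum test with midranks for ties. The default one-sided alternative
#' (`"less"`: class stochastically smaller than background) targets the
#' signature of purifying selection, an excess of low-frequency derived
#' alleles. Methods:
#' * `exact`, tie-free data: the exact null distribution of U
#'   (`stats::pwilcox`); refused for genome-scale backgrounds
#'   (`n_background > 10000`), where it falls back with a message;
#' * `exact`, tied data: full enumeration over all splits of the pooled
#'   midranks, feasible only for combined `n <= 25` (falls back otherwise);
#' * `normal_approx`: normal approximation with tie-corrected variance and
#'   continuity correction (`stats::wilcox.test` machinery);
#' * `auto`: exact when `min(n) <= exact_threshold` and the exact route is
#'   feasible as above, else the normal approximation.
#'
#' Reported `p_value` is floored at `1e-8` (`p_raw` keeps full precision).
#'
#' @param class_dafs,background_dafs numeric vectors in `[0, 1]`
#' @param alternative `"less"` (default), `"greater"`, or `"two.sided"`
#' @param method `"auto"`, `"exact"`, or `"normal_approx"`
#' @param exact_threshold largest `min(n)` for which `auto` attempts the
#'   exact method (default 50)
#' @return an `mw_result` list: `U`, `p_value`, `p_raw`, `method`,
#'   `alternative`, `n_class`, `n_background`, `median_class`,
#'   `median_background`
#' @examples
#' mann_whitney(c(0.1, 0.2), c(0.3, 0.4, 0.5))$p_value  # exact 0.1
#' @export
mann_whitney <- function(class_dafs, background_dafs,
                         alternative = c("less", "greater", "two.sided"),
                         method = c("auto", "exact", "normal_approx"),
                         exact_threshold = 50L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(class_dafs); y <- as.numeric(background_dafs)
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney: empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  res <- function(p, used) {
    structure(list(U = U, p_value = max(min(p, 1), .P_FLOOR), p_raw = p,
                   method = used, alternative = alternative,
                   n_class = n1, n_background = n2,
                   median_class = stats::median(x),
                   median_background = stats::median(y)),
              class = "mw_result")
  }

  if (length(unique(c(x, y))) == 1) {
    warning("mann_whitney: all values identical in both samples; p = 1")
    return(res(1, "degenerate"))
  }

  want_exact <- method == "exact" ||
    (method == "auto" && min(n1, n2) <= exact_threshold)
  if (want_exact && !ties && max(n1, n2) <= 10000) {
    p <- switch(alternative,
      less = stats::pwilcox(U, n1, n2),
      greater = stats::pwilcox(n1 * n2 - U, n1, n2),
      two.sided = min(1, 2 * min(stats::pwilcox(U, n1, n2),
                                 stats::pwilcox(n1 * n2 - U, n1, n2))))
    return(res(p, "exact"))
  }
  if (want_exact && ties && N <= 25) {
    return(res(.mw_exact_ties(r, n1, U, alternative), "exact"))
  }
  if (method == "exact")
    message("mann_whitney: exact method infeasible here (",
            if (ties) "tied data with large n" else "genome-scale background",
            "); using normal approximation")
  # tie-corrected normal approximation with continuity correction
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) {
    warning("mann_whitney: zero variance; p = 1")
    return(res(1, "degenerate"))
  }
  sd <- sqrt(sigma2)
  p <- switch(alternative,
    less = stats::pnorm((U - mu + 0.5) / sd),
    greater = stats::pnorm((U - mu - 0.5) / sd, lower.tail = FALSE),
    two.sided = {
      z <- (U - mu - sign(U - mu) * 0.5) / sd
      min(1, 2 * stats::pnorm(-abs(z)))
    })
  res(p, "normal_approx")
}

## exact p by complete enumeration of class-label assignments on the pooled
## midranks; O(choose(N, n1)), used only for small combined n
.mw_exact_ties <- function(r, n1, U_obs, alternative) {
  N <- length(r)
  splits <- utils::combn(N, n1)
  offset <- n1 * (n1 + 1) / 2
  Us <- colSums(matrix(r[splits], nrow = n1)) - offset
  eps <- 1e-9
  p_less <- mean(Us <= U_obs + eps)
  p_greater <- mean(Us >= U_obs - eps)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney (%s, %s): U = %.1f, p = %.3g; n = %d vs %d, medians %.3f vs %.3f\n",
    x$alternative, x$method, x$U, x$p_value, x$n_class, x$n_background,
    x$median_class, x$median_background))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR report
#'
#' Ranks the supplied p-values, attaches the step-up critical values
#' `c_i = i * alpha / m`, the BH-adjusted p-values
#' `min_(j >= i) (m * p_j / j)` capped at 1 (`stats::p.adjust` with `n = m`),
#' and marks ranks `1..k` significant where `k` is the largest rank with
#' `p_k <= c_k`. `m` may exceed the number of supplied p-values when tests
#' were declared but not computed.
#'
#' @param pvalues named numeric vector of p-values in `(0, 1]` (names =
#'   class labels)
#' @param alpha FDR level (default 0.05)
#' @param m declared number of tests (default `length(pvalues)`)
#' @return an `fdr_report` data.frame: `rank`, `class`, `p_value`,
#'   `critical_value`, `adjusted_p`, `significant`, with `alpha` and `m`
#'   attributes
#' @examples
#' bh_report(c(a = 1e-4, b = 0.03, c = 0.2), alpha = 0.05, m = 44)
#' @export
bh_report <- function(pvalues, alpha = 0.05, m = length(pvalues)) {
  if (any(pvalues <= 0 | pvalues > 1))
    stop("bh_report: p-values must be in (0, 1]")
  if (m < length(pvalues))
    stop("bh_report: m (", m, ") smaller than the number of p-values (",
         length(pvalues), ")")
  if (alpha <= 0 || alpha >= 1) stop("bh_report: alpha must be in (0, 1)")
  ord <- order(pvalues)
  p <- unname(pvalues[ord])
  labs <- if (is.null(names(pvalues))) as.character(ord) else
    names(pvalues)[ord]
  i <- seq_along(p)
  crit <- i * alpha / m
  adj <- stats::p.adjust(p, method = "BH", n = m)
  k <- suppressWarnings(max(which(p <= crit)))
  signif <- if (is.finite(k)) i <= k else rep(FALSE, length(p))
  out <- data.frame(rank = i, class = labs, p_value = p,
                    critical_value = crit, adjusted_p = adj,
                    significant = signif, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("fdr_report", "data.frame")
  out
}

#' Histogram of DAF values on fixed 0.05-wide bins
#'
#' Bins are right-open on `[0, 1)` with the last bin `[0.95, 1]` closed.
#'
#' @param dafs numeric vector in `[0, 1]`
#' @return data.frame with `bin_start`, `bin_end`, `count`
#' @export
daf_histogram <- function(dafs) {
  br <- seq(0, 1, by = 0.05)
  h <- graphics::hist(dafs, breaks = br, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  data.frame(bin_start = br[-length(br)], bin_end = br[-1], count = h$counts)
}

#' Scan annotation classes for purifying selection
#'
#' For every class, applies the background's overlap-removal policy, runs the
#' Mann-Whitney test of the class DAF spectrum against the background
#' spectrum in the chosen population, and assembles a BH step-up FDR report.
#' The `"genome"` background is the set of all polarized SNPs; the
#' `"ancestral_repeats"` background is that class's membership.
#'
#' @param polarized a `polarized_snps` table
#' @param membership a `class_membership` (from [assign_snps_to_classes()])
#' @param population population code (e.g. `"AFR"`)
#' @param background `"genome"` or `"ancestral_repeats"`
#' @param classes class labels to test (default: all membership labels except
#'   the background class); classes absent from the membership, or degenerate
#'   after overlap removal, are skipped with a warning and excluded from the
#'   ranking
#' @param alpha FDR level
#' @param m declared number of tests (default: number of classes actually
#'   tested)
#' @param alternative,method,exact_threshold passed to [mann_whitney()]
#' @return a `scan_result` list: `results` (one row per tested class),
#'   `fdr` (an `fdr_report`), `summaries` (per-class median and DAF histogram
#'   including the background), `population`, `background`
#' @export
run_scan <- function(polarized, membership, population,
                     background = c("genome", "ancestral_repeats"),
                     classes = NULL, alpha = 0.05, m = NULL,
                     alternative = "less", method = "auto",
                     exact_threshold = 50L) {
  background <- match.arg(background)
  daf_col <- paste0("daf_", population)
  if (!(daf_col %in% names(polarized)))
    stop("run_scan: unknown population ", population)
  daf <- stats::setNames(polarized[[daf_col]], polarized$snp_id)

  if (background == "genome") {
    bg_ids <- polarized$snp_id
    policy <- "genome_background"
  } else {
    if (!("ancestral_repeats" %in% names(membership)))
      stop("run_scan: membership lacks an 'ancestral_repeats' class")
    bg_ids <- membership[["ancestral_repeats"]]
    policy <- "ancestral_repeat_background"
  }
  if (is.null(classes))
    classes <- setdiff(names(membership), c("ancestral_repeats", "genome"))

  rows <- list(); summaries <- list()
  for (cl in classes) {
    ids <- intersect(membership[[cl]], polarized$snp_id)
    if (is.null(membership[[cl]]) || length(ids) == 0) {
      warning("run_scan: class ", cl, " absent or empty; skipped")
      next
    }
    sets <- tryCatch(remove_overlap(ids, intersect(bg_ids, polarized$snp_id),
                                    policy),
                     error = function(e) {
                       warning("run_scan: class ", cl, ": ",
                               conditionMessage(e), "; skipped")
                       NULL
                     })
    if (is.null(sets)) next
    mw <- mann_whitney(daf[sets$class_ids], daf[sets$background_ids],
                       alternative = alternative, method = method,
                       exact_threshold = exact_threshold)
    rows[[cl]] <- data.frame(
      class = cl, background = background, population = population,
      n_class = mw$n_class, n_background = mw$n_background, U = mw$U,
      p_value = mw$p_value, p_raw = mw$p_raw, method = mw$method,
      median_class = mw$median_class,
      median_background = mw$median_background, stringsAsFactors = FALSE)
    summaries[[cl]] <- list(median = mw$median_class,
                            histogram = daf_histogram(daf[sets$class_ids]))
  }
  if (length(rows) == 0) stop("run_scan: no testable class")
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # rank on full-precision p so classes below the reporting floor still order
  pv <- stats::setNames(results$p_value, results$class)
  fdr <- bh_report(pv, alpha = alpha, m = if (is.null(m)) length(pv) else m)
  ord <- order(results$p_raw)
  fdr$class <- results$class[ord]
  fdr$p_value <- results$p_value[ord]
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  bg_daf <- daf[intersect(bg_ids, polarized$snp_id)]
  summaries[[background]] <- list(median = stats::median(bg_daf),
                                  histogram = daf_histogram(bg_daf))
  structure(list(results = results, fdr = fdr, summaries = summaries,
                 population = population, background = background),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s vs %s background (%d classes)\n",
              x$population, x$background, nrow(x$results)))
  df <- merge(x$results[, c("class", "n_class", "U", "p_value",
                            "median_class")],
              as.data.frame(x$fdr)[, c("class", "rank", "critical_value",
                                       "adjusted_p", "significant")],
              by = "class")
  df <- df[order(df$rank), ]
  rownames(df) <- NULL
  print(df, digits = 3)
  invisible(x)
}
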