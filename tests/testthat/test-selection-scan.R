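test_that("overlap removal follows the background-specific policies", {
  cl <- c("a", "b", "c")
  genome <- c("a", "b", "c", "d", "e")
  got <- remove_overlap(cl, genome, "genome_background")
  expect_equal(got$class_ids, cl)                   # class never changes
  expect_equal(got$background_ids, c("d", "e"))
  reps <- c("b", "c", "d")
  got2 <- remove_overlap(cl, reps, "ancestral_repeat_background")
  expect_equal(got2$class_ids, "a")
  expect_equal(got2$background_ids, "d")
  expect_equal(length(intersect(got2$class_ids, got2$background_ids)), 0)
  # disjoint sets pass through unchanged under either policy
  got3 <- remove_overlap(c("x", "y"), c("u", "v"),
                         "ancestral_repeat_background")
  expect_equal(got3$class_ids, c("x", "y"))
  expect_equal(got3$background_ids, c("u", "v"))
  expect_error(remove_overlap(c("a"), c("a"), "ancestral_repeat_background"),
               "degenerate")
})

test_that("Mann-Whitney exact p-values match hand enumeration", {
  # class {0.1, 0.2} vs background {0.3, 0.4, 0.5}: 1 of C(5,2)=10 splits as
  # extreme
  mw <- mann_whitney(c(0.1, 0.2), c(0.3, 0.4, 0.5), alternative = "less")
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  # identical multisets: two-sided p = 1
  mw2 <- mann_whitney(c(0.1, 0.4, 0.7), c(0.1, 0.4, 0.7),
                      alternative = "two.sided")
  expect_equal(mw2$p_value, 1)
  # all values identical -> degenerate with warning
  expect_warning(mw3 <- mann_whitney(rep(0.5, 3), rep(0.5, 4)),
                 "identical")
  expect_equal(mw3$p_value, 1)
  expect_error(mann_whitney(numeric(), c(0.1)), "empty")
})

test_that("exact method equals the full-enumeration oracle, ties included", {
  set.seed(61)
  for (i in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    tied <- i %% 2 == 0
    pool <- if (tied) sample(seq(0, 1, by = 0.25), n1 + n2, replace = TRUE)
            else runif(n1 + n2)
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    if (length(unique(pool)) == 1) next
    for (alt in c("less", "greater", "two.sided")) {
      mw <- mann_whitney(x, y, alternative = alt, method = "exact")
      expect_equal(mw$p_raw, enum_mw_p(x, y, alt), tolerance = 1e-12,
                   info = sprintf("i=%d alt=%s", i, alt))
    }
  }
})

test_that("normal approximation matches R's wilcox.test and the exact tail", {
  set.seed(62)
  for (i in 1:10) {
    x <- runif(10); y <- runif(200)
    mwe <- mann_whitney(x, y, alternative = "less", method = "exact")
    mwn <- mann_whitney(x, y, alternative = "less", method = "normal_approx")
    expect_equal(mwe$method, "exact")
    expect_lt(abs(mwe$p_raw - mwn$p_raw), 0.01)
    ref <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                               exact = FALSE, correct = TRUE))
    expect_equal(mwn$p_raw, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(mwn$U, unname(ref$statistic))
  }
  # tie-corrected variance agrees with wilcox.test on tied data too
  x <- sample(seq(0, 1, 0.05), 40, TRUE); y <- sample(seq(0, 1, 0.05), 60, TRUE)
  mwn <- mann_whitney(x, y, alternative = "less", method = "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                             exact = FALSE, correct = TRUE))
  expect_equal(mwn$p_raw, unname(ref$p.value), tolerance = 1e-10)
})

test_that("auto method prefers normal approximation for tied, larger samples", {
  set.seed(63)
  x <- sample(seq(0, 1, 0.05), 30, TRUE)
  y <- sample(seq(0, 1, 0.05), 100, TRUE)
  expect_equal(mann_whitney(x, y)$method, "normal_approx")
  # genome-scale background refuses the exact path even tie-free
  expect_message(
    mwg <- mann_whitney(runif(5), runif(10001), method = "exact"),
    "infeasible")
  expect_equal(mwg$method, "normal_approx")
  # reporting floor
  mwf <- mann_whitney(runif(500, 0, 0.2), runif(2000, 0.3, 1))
  expect_equal(mwf$p_value, 1e-8)
  expect_lt(mwf$p_raw, 1e-8)
})

test_that("BH report reproduces step-up critical values and adjusted p", {
  p <- c(a = 1e-6, b = 0.004, c = 0.02, d = 0.3)
  rep <- bh_report(p, alpha = 0.05, m = 4)
  expect_equal(rep$critical_value, (1:4) * 0.05 / 4)
  expect_equal(rep$adjusted_p, unname(stats::p.adjust(sort(p), "BH")))
  expect_equal(rep$significant, c(TRUE, TRUE, TRUE, FALSE))
  # critical values increase and end at alpha when m = number of tests
  expect_equal(rep$critical_value[4], 0.05)
  # m larger than supplied p-values scales both columns
  rep44 <- bh_report(p, alpha = 0.05, m = 44)
  expect_equal(rep44$critical_value, (1:4) * 0.05 / 44)
  expect_equal(rep44$adjusted_p,
               unname(stats::p.adjust(sort(p), "BH", n = 44)))
  # single test at the boundary is significant
  rep1 <- bh_report(c(only = 0.05), alpha = 0.05, m = 1)
  expect_true(rep1$significant)
  expect_equal(rep1$adjusted_p, 0.05)
  expect_error(bh_report(c(0.1, 0)), "in \\(0, 1\\]")
  expect_error(bh_report(p, m = 2), "smaller than")
  # significant set is always a prefix of the ranking
  set.seed(64)
  for (i in 1:20) {
    pv <- runif(12)^sample(1:4, 1)
    r <- bh_report(stats::setNames(pv, paste0("c", 1:12)), m = 15)
    expect_true(all(diff(r$significant) <= 0))
    expect_true(all(diff(r$adjusted_p) >= -1e-15))
  }
})

test_that("run_scan detects a selected class and respects both backgrounds", {
  cfg <- simulation_config(
    chrom_lengths = c(chr1 = 4e6, chr2 = 4e6), n_genes = 30L,
    gene_length_range = c(2000L, 8000L),
    region_specs = list(
      list(label = "selected", n_regions = 60L, length_range = c(800L, 2500L),
           placement = "uniform", gamma = -15, n_snps = 500L),
      list(label = "ancestral_repeats", n_regions = 80L,
           length_range = c(800L, 2500L), placement = "uniform", gamma = 0,
           n_snps = 800L)),
    n_background_snps = 4000L, populations = "AFR", seed = 71)
  b <- generate_bundle(cfg)
  pol <- polarize_snps(filter_snps(b$snps)$kept, b$outgroup)$polarized
  cat <- build_class_catalog(b$genes, b$region_sets,
                             constrained_label = NULL)
  memb <- assign_snps_to_classes(pol, cat)
  for (bg in c("genome", "ancestral_repeats")) {
    sc <- run_scan(pol, memb, "AFR", background = bg)
    expect_equal(sc$fdr$class[1], "selected")
    expect_true(sc$fdr$significant[1])
    expect_lt(sc$results$median_class[sc$results$class == "selected"],
              sc$results$median_background[sc$results$class == "selected"])
    # histograms cover [0,1] in 20 bins and count every class SNP
    h <- sc$summaries$selected$histogram
    expect_equal(nrow(h), 20)
    expect_equal(sum(h$count),
                 sc$results$n_class[sc$results$class == "selected"])
  }
  expect_error(run_scan(pol, memb, "nope"), "unknown population")
})

test_that("a class that copies the background is never significant", {
  set.seed(72)
  pol <- data.frame(snp_id = sprintf("s%04d", 1:800), chrom = "chr1",
                    pos = 1:800, daf_AFR = sample(seq(0, 1, 1/48), 800, TRUE),
                    stringsAsFactors = FALSE)
  attr(pol, "populations") <- "AFR"
  class(pol) <- c("polarized_snps", "data.frame")
  memb <- structure(list(copy = pol$snp_id[1:400],
                         ancestral_repeats = pol$snp_id[1:400]),
                    class = "class_membership")
  sc <- run_scan(pol, memb, "AFR", background = "genome",
                 classes = "copy")
  expect_gt(sc$results$p_value[1], 0.05)
  expect_false(sc$fdr$significant[1])
})

test_that("MW p-values rank monotonically with selection strength", {
  # gamma in {0, -5, -15}: stronger selection gives smaller p in the majority
  # of seeded replicates
  wins <- 0L
  for (seed in 1:5) {
    cfg <- simulation_config(
      chrom_lengths = c(chr1 = 4e6), n_genes = 10L,
      gene_length_range = c(2000L, 5000L),
      region_specs = list(
        list(label = "g0", n_regions = 40L, length_range = c(500L, 1500L),
             placement = "uniform", gamma = 0, n_snps = 250L),
        list(label = "g5", n_regions = 40L, length_range = c(500L, 1500L),
             placement = "uniform", gamma = -5, n_snps = 250L),
        list(label = "g15", n_regions = 40L, length_range = c(500L, 1500L),
             placement = "uniform", gamma = -15, n_snps = 250L)),
      n_background_snps = 3000L, populations = "AFR", seed = 700 + seed)
    b <- generate_bundle(cfg)
    pol <- polarize_snps(filter_snps(b$snps)$kept, b$outgroup)$polarized
    memb <- assign_snps_to_classes(pol, b$region_sets)
    sc <- run_scan(pol, memb, "AFR", background = "genome",
                   classes = c("g0", "g5", "g15"))
    p <- stats::setNames(sc$results$p_raw, sc$results$class)
    if (p["g15"] <= p["g5"] && p["g5"] <= p["g0"]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
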