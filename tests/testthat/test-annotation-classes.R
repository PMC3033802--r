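test_that("promoter windows are strand-aware 1201-bp TSS windows", {
  gplus <- toy_gene("gp", "chr1", "+", rbind(c(10000, 12000)))
  gminus <- toy_gene("gm", "chr1", "-", rbind(c(8000, 10001)))  # TSS base 10000
  expect_equal(as.data.frame(promoter_regions(gene_models(gplus)))[, 1:3],
               data.frame(chrom = "chr1", start = 9000, end = 10201),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(promoter_regions(gene_models(gminus)))[, 1:3],
               data.frame(chrom = "chr1", start = 9800, end = 11001),
               ignore_attr = TRUE)
  # clipped at the chromosome start
  gclip <- toy_gene("gc", "chr1", "+", rbind(c(500, 2000)))
  expect_equal(as.data.frame(promoter_regions(gene_models(gclip)))[, 1:3],
               data.frame(chrom = "chr1", start = 0, end = 701),
               ignore_attr = TRUE)
  expect_equal(region_length(promoter_regions(gene_models(gplus))), 1201)
})

test_that("splice control windows are 52 bp at acceptors and 9 bp at donors", {
  # + strand: exon [800,1000), intron [1000,1200), exon [1200,1300)
  gp <- toy_gene("gp", "chr1", "+", rbind(c(800, 1000), c(1200, 1300)))
  sp <- splice_control_regions(gene_models(gp))
  expect_equal(sp$start, c(997, 1150))
  expect_equal(sp$end, c(1006, 1202))   # donor [997,1006), acceptor [1150,1202)
  expect_equal(region_length(sp), 9 + 52)

  # - strand with the same physical exons, windows hand-enumerated:
  # donor at the right intron boundary: exonic [1200,1203) + intronic [1194,1200)
  # acceptor at the left boundary: intronic [1000,1050) + exonic [998,1000)
  gm <- toy_gene("gm", "chr1", "-", rbind(c(800, 1000), c(1200, 1300)))
  sm <- splice_control_regions(gene_models(gm))
  expect_equal(sm$start, c(998, 1194))
  expect_equal(sm$end, c(1050, 1203))
  expect_equal(region_length(sm), 52 + 9)

  # single-exon transcripts contribute nothing
  g1 <- toy_gene("g1", "chr1", "+", rbind(c(500, 900)))
  expect_equal(nrow(splice_control_regions(gene_models(g1))), 0)

  # short introns/exons clip the windows; the 4-bp intron is shared by the
  # donor and acceptor windows, so the merged union is [998, 1006)
  gshort <- toy_gene("gs", "chr1", "+", rbind(c(998, 1000), c(1004, 1006)))
  ss <- splice_control_regions(gene_models(gshort))   # 2-bp exons, 4-bp intron
  expect_equal(as.data.frame(ss)[, 1:3],
               data.frame(chrom = "chr1", start = 998, end = 1006),
               ignore_attr = TRUE)
})

test_that("strand symmetry: reverse-complementing the genome maps windows exactly", {
  L <- 50000L
  g <- toy_gene("g", "chr1", "+", rbind(c(20000, 21000), c(22000, 23000)),
                cds = rbind(c(20100, 21000), c(22000, 22500)))
  flip <- function(iv) rbind(L - rev(iv[, 2:1, drop = FALSE])[, 2:1])
  # mirrored gene: coordinates x -> L - x, strand flipped, exon order reversed
  ex_f <- apply(rbind(c(20000, 21000), c(22000, 23000)), 2, function(z) L - z)
  gf <- toy_gene("gf", "chr1", "-",
                 cbind(rev(ex_f[, 2]), rev(ex_f[, 1])),
                 cds = cbind(rev(apply(rbind(c(20100, 21000), c(22000, 22500)),
                                       2, function(z) L - z)[, 2]),
                             rev(apply(rbind(c(20100, 21000), c(22000, 22500)),
                                       2, function(z) L - z)[, 1])))
  mirror_rs <- function(rs) {
    out <- region_set(rs$chrom, L - rs$end, L - rs$start)
    out[order(out$start), c("start", "end")]
  }
  for (fn in list(promoter_regions, splice_control_regions, coding_regions)) {
    a <- fn(gene_models(g))
    b <- fn(gene_models(gf))
    expect_equal(mirror_rs(b), a[, c("start", "end")], ignore_attr = TRUE)
  }
})

test_that("coding regions take the union of CDS across transcripts", {
  g <- gene_model("g", "chr1", "+", 100, 500, list(
    tx("t1", rbind(c(100, 250)), cds = rbind(c(100, 200))),
    tx("t2", rbind(c(150, 300)), cds = rbind(c(150, 250)))))
  cr <- coding_regions(gene_models(g))
  expect_equal(as.data.frame(cr)[, 1:3],
               data.frame(chrom = "chr1", start = 100, end = 250),
               ignore_attr = TRUE)
  g2 <- toy_gene("g2", "chr1", "+", rbind(c(100, 200)))
  expect_message(cr2 <- coding_regions(gene_models(g2)), "no CDS")
  expect_equal(nrow(cr2), 0)
})

test_that("distance to nearest gene follows gap semantics, points for SNPs", {
  genes <- gene_models(toy_gene("g1", "chr1", "+", rbind(c(6000, 9000))),
                       toy_gene("g2", "chr1", "+", rbind(c(15000, 16000))),
                       toy_gene("g3", "chr2", "+", rbind(c(100, 200))))
  snps <- toy_snps("chr1", c(5000, 7000, 12000), freq_AFR = rep(0.5, 3))
  d <- distance_to_nearest_gene(snps, genes)
  expect_equal(d[1], 1000)   # measured from the base position
  expect_equal(d[2], 0)      # inside g1
  expect_equal(d[3], 3000)   # min(12000-9000, 15000-12000)
  # interval queries: plain edge-to-edge gap
  rs <- region_set("chr1", c(9500, 6500), c(9800, 6600))
  expect_equal(distance_to_nearest_gene(rs, genes), c(500, 0))
  # no gene on that chromosome -> Inf
  rs3 <- region_set("chr9", 100, 200)
  expect_equal(distance_to_nearest_gene(rs3, genes), Inf)
  # brute-force cross-check on a random toy instance
  set.seed(15)
  qs <- region_set("chr1", s <- sort(sample(1:40000, 20)), s + 50)
  dd <- distance_to_nearest_gene(qs, genes)
  spans <- gene_spans(genes)
  for (i in seq_len(nrow(qs))) {
    per_gene <- vapply(which(spans$chrom == "chr1"), function(j)
      max(0, spans$start[j] - qs$end[i], qs$start[i] - spans$end[j]), 0)
    expect_equal(dd[i], min(per_gene))
  }
})

test_that("constrained subsets: subtraction truncates, distance filters whole elements", {
  genes <- gene_models(
    toy_gene("g1", "chr1", "+", rbind(c(200, 400)), cds = rbind(c(250, 350))),
    toy_gene("g2", "chr1", "-", rbind(c(2000, 3000)), cds = rbind(c(2100, 2900))))
  ce <- region_set("chr1", c(100, 300, 1500, 4100, 150000),
                   c(300, 500, 1600, 4200, 150100),
                   label = "constrained_elements")
  minus_genes <- subset_constrained(ce, genes, "minus_genes")
  # element [100,300) -> [100,200); [300,500) -> [400,500); others untouched
  expect_equal(minus_genes$start, c(100, 400, 1500, 4100, 150000))
  expect_equal(minus_genes$end, c(200, 500, 1600, 4200, 150100))
  minus_coding <- subset_constrained(ce, genes, "minus_coding")
  # only CDS [250,350) bites: [100,300)->[100,250); [300,500)->[350,500)
  expect_equal(region_length(minus_coding),
               region_length(ce) - 100)
  d1kb <- subset_constrained(ce, genes, "min_distance", min_bp = 1000)
  expect_equal(d1kb$start, c(4100, 150000))   # whole elements, never truncated
  d100kb <- subset_constrained(ce, genes, "min_distance", min_bp = 100000)
  expect_equal(d100kb$start, 150000)
  expect_error(subset_constrained(ce, genes, "min_distance"), "min_bp")

  # brute-force per-base verification of both subtractions
  for (rs in list(minus_genes, minus_coding)) {
    other <- if (identical(rs, minus_genes)) gene_span_regions(genes)
             else coding_regions(genes)
    expect_equal(brute_coverage(rs, "chr1", 200000),
                 brute_coverage(ce, "chr1", 200000) &
                   !brute_coverage(other, "chr1", 200000))
  }
})

test_that("subtraction conserves length and distance subsets nest monotonically", {
  set.seed(33)
  x <- region_set("chr1", s <- sample(1:100000, 40), s + sample(50:500, 40, TRUE))
  y <- region_set("chr1", s2 <- sample(1:100000, 30), s2 + sample(50:500, 30, TRUE))
  lx <- region_length(x)
  diff_len <- region_length(subtract_regions(x, y))
  inter <- subtract_regions(x, subtract_regions(x, y))  # x minus (x \ y) = x ∩ y
  expect_equal(diff_len + region_length(inter), lx)

  cfg <- small_sim_config(seed = 44)
  b <- generate_bundle(cfg)
  ce <- b$region_sets$test_class
  attr(ce, "label") <- "constrained_elements"
  near <- subset_constrained(ce, b$genes, "min_distance", min_bp = 1000)
  far <- subset_constrained(ce, b$genes, "min_distance", min_bp = 100000)
  key <- function(rs) paste(rs$chrom, rs$start, rs$end)
  expect_true(all(key(far) %in% key(near)))
  # every min-distance survivor lies wholly outside the merged gene spans
  expect_equal(region_length(subtract_regions(near, gene_span_regions(b$genes))),
               region_length(near))
})

test_that("SNP-class assignment matches the quadratic oracle and boundary rules", {
  rs <- region_set("chr1", 100, 200, label = "c")
  snps <- toy_snps("chr1", c(150, 199, 200, 99, 100), freq_AFR = rep(0.5, 5))
  memb <- assign_snps_to_classes(snps, list(c = rs))
  expect_equal(memb$c, sort(snps$snp_id[c(1, 2, 5)]))  # 200 excluded (half-open)
  set.seed(8)
  snps2 <- toy_snps(sample(c("chr1", "chr2"), 200, TRUE),
                    sample(1:5000, 200), freq_AFR = runif(200))
  sets <- list(
    a = region_set(sample(c("chr1", "chr2"), 20, TRUE),
                   s <- sample(1:4500, 20), s + sample(10:400, 20, TRUE)),
    b = region_set(sample(c("chr1", "chr2"), 10, TRUE),
                   s2 <- sample(1:4500, 10), s2 + sample(10:400, 10, TRUE)))
  memb2 <- assign_snps_to_classes(snps2, sets)
  expect_equal(memb2$a, brute_members(snps2, sets$a))
  expect_equal(memb2$b, brute_members(snps2, sets$b))
})

test_that("density report reproduces count/(kb) on merged sets", {
  rs <- region_set("chr1", c(0, 500, 500), c(1000, 1500, 1200), label = "c")
  snps <- toy_snps("chr1", seq(0, 1490, by = 10), freq_AFR = 0.5)
  memb <- assign_snps_to_classes(snps, list(c = rs))
  rep <- class_density_report(memb, list(c = rs))
  expect_equal(rep$size_kb, 1.5)          # merged [0,1500)
  expect_equal(rep$size_kb_raw, 2.7)      # unmerged sum 1000+1000+700
  expect_equal(rep$n_snps, 150)
  expect_equal(rep$snps_per_kb, 100.00)
  empty <- list(e = region_set(character(), integer(), integer()))
  memb0 <- assign_snps_to_classes(snps, empty)
  rep0 <- class_density_report(memb0, empty)
  expect_true(is.na(rep0$snps_per_kb))    # undefined, not an error
})

test_that("Venn partition counts agree with brute-force set algebra", {
  memb <- structure(list(A = c("s1", "s2", "s3"), B = c("s4", "s5", "s6", "s7")),
                    class = "class_membership")
  ic <- intersection_counts(memb, c("A", "B"))
  expect_equal(ic$count[ic$A & !ic$B], 3)
  expect_equal(ic$count[!ic$A & ic$B], 4)
  expect_equal(ic$count[ic$A & ic$B], 0)
  memb2 <- structure(list(A = c("s1", "s2"), B = c("s1", "s2", "s3")),
                     class = "class_membership")
  ic2 <- intersection_counts(memb2, c("A", "B"))
  expect_equal(ic2$count[ic2$A & !ic2$B], 0)   # A is a subset of B
  set.seed(19)
  univ <- sprintf("s%02d", 1:40)
  memb3 <- structure(lapply(1:3, function(i) sort(sample(univ, 15))),
                     class = "class_membership")
  names(memb3) <- c("X", "Y", "Z")
  ic3 <- intersection_counts(memb3, c("X", "Y", "Z"))
  for (r in seq_len(nrow(ic3))) {
    want <- univ
    for (lbl in c("X", "Y", "Z")) {
      want <- if (ic3[[lbl]][r]) intersect(want, memb3[[lbl]])
              else setdiff(want, memb3[[lbl]])
    }
    expect_equal(ic3$count[r], length(want))
  }
  expect_equal(sum(ic3$count), length(Reduce(union, memb3)))
  expect_error(intersection_counts(memb3, "X"), "between 2 and 4")
  expect_error(intersection_counts(memb3, c("X", "nope")), "unknown class")
})

test_that("catalog provenance records how each class arose", {
  cfg <- small_sim_config(seed = 50, n_class_snps = 20L, n_background = 50L)
  b <- generate_bundle(cfg)
  supplied <- b$region_sets
  names(supplied)[1] <- "constrained_elements"
  cat <- build_class_catalog(b$genes, supplied)
  expect_true(all(c("promoter", "splice_site", "coding",
                    "constrained_elements",
                    "constrained_elements_minus_coding",
                    "constrained_elements_minus_genes",
                    "constrained_elements_1kb_from_genes",
                    "constrained_elements_100kb_from_genes") %in%
                    names(cat$region_sets)))
  expect_equal(cat$provenance$promoter, "derived_from_genes")
  expect_equal(cat$provenance$constrained_elements, "supplied")
  expect_match(cat$provenance$constrained_elements_minus_genes,
               "derived_by_subset")
  expect_error(build_class_catalog(b$genes, c(supplied, supplied[1])),
               "duplicate label")
})
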