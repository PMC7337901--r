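iv <- function(start, end, strand = "+", chrom = "S", ...) {
  genomic_intervals(chrom, start, end, strand, ...)
}

mk_model <- function(gene_id, strand, exons, cds, chrom = "S",
                     tx = paste0(gene_id, ".t1")) {
  list(transcript_id = tx, gene_id = gene_id, chrom = chrom, strand = strand,
       exons = data.frame(start = exons[, 1], end = exons[, 2]),
       cds = data.frame(start = cds[, 1], end = cds[, 2]),
       tags = character(0))
}

test_that("the feature partition of a three-exon gene is exact", {
  # plus-strand gene: exons 1000-1200, 1500-1800, 2100-2400;
  # CDS 1100-1200, 1500-1800, 2100-2300
  m <- mk_model("gA", "+",
                exons = cbind(c(1000, 1500, 2100), c(1200, 1800, 2400)),
                cds = cbind(c(1100, 1500, 2100), c(1200, 1800, 2300)))
  part <- build_partition(list(m), contig_lengths = c(S = 100000),
                          flank = 500)
  get <- function(feat) part[part$feature == feat, c("start", "end", "strand")]
  expect_equal(get("five_prime_utr"),
               data.frame(start = 1000, end = 1100, strand = "+"),
               ignore_attr = TRUE)
  expect_equal(get("three_prime_utr"),
               data.frame(start = 2300, end = 2400, strand = "+"),
               ignore_attr = TRUE)
  expect_equal(get("cds")$start, c(1100, 1500, 2100))
  expect_equal(get("cds")$end, c(1200, 1800, 2300))
  expect_equal(get("intron")$start, c(1200, 1800))
  expect_equal(get("intron")$end, c(1500, 2100))
  expect_equal(get("three_prime_utr_ext"),
               data.frame(start = 2400, end = 2900, strand = "+"),
               ignore_attr = TRUE)
  # promoter flank carries the antisense strand
  expect_equal(get("promoter_antisense"),
               data.frame(start = 500, end = 1000, strand = "-"),
               ignore_attr = TRUE)
})

test_that("partition flanks respect strand and contig bounds", {
  m <- mk_model("gB", "-", exons = cbind(c(200, 700), c(400, 900)),
                cds = cbind(c(250, 700), c(400, 850)))
  part <- build_partition(list(m), contig_lengths = c(S = 1100), flank = 500)
  ext <- part[part$feature == "three_prime_utr_ext", ]
  prom <- part[part$feature == "promoter_antisense", ]
  # minus strand: 3' extension runs left of the gene, clamped at zero
  expect_equal(c(ext$start, ext$end), c(0, 200))
  expect_equal(ext$strand, "-")
  # promoter is right of the gene, clamped at the contig length, antisense
  expect_equal(c(prom$start, prom$end), c(900, 1100))
  expect_equal(prom$strand, "+")
  # minus strand flips the UTR sides relative to coordinates
  expect_equal(part$start[part$feature == "five_prime_utr"], 850)
  expect_equal(part$end[part$feature == "three_prime_utr"], 250)
  no_cds <- mk_model("gC", "+", exons = cbind(100, 200), cds = cbind(100, 200))
  no_cds$cds <- NULL
  expect_warning(build_partition(list(mk_model("gB", "-",
                                               cbind(c(200, 700), c(400, 900)),
                                               cbind(c(250, 700), c(400, 850))),
                                      no_cds)),
                 "gC")
})

test_that("polyA sites override positional UTR assignment", {
  m <- mk_model("gA", "+", exons = cbind(c(1000, 1500), c(1200, 1800)),
                cds = cbind(1100, 1700))
  pa <- iv(1050, 1060)
  part <- build_partition(list(m), polya = pa)
  # the left UTR overlaps the polyA site and is forced to the 3' side
  left <- part[part$start == 1000 & part$end == 1100, ]
  expect_equal(left$feature, "three_prime_utr")
})

test_that("null matching enforces its bounds on randomized inputs", {
  set.seed(111)
  for (i in 1:5) {
    n <- 200
    ids <- sprintf("g%d", seq_len(n))
    pa <- data.frame(gene_id = ids, p = runif(n), stringsAsFactors = FALSE)
    pb <- data.frame(gene_id = ids, p = runif(n), stringsAsFactors = FALSE)
    lengths <- stats::setNames(stats::rlnorm(n, 7, 1), ids)
    expr <- stats::setNames(stats::rlnorm(n, 4, 1), ids)
    test_ids <- sample(ids, 30)
    got <- tryCatch(
      suppressWarnings(match_null(test_ids, pa, pb, lengths, expr)),
      error = function(e) character(0))
    lb <- stats::quantile(lengths[test_ids], c(0.25, 0.75))
    eb <- stats::quantile(expr[test_ids], c(0.25, 0.75))
    for (g in got) {
      expect_false(g %in% test_ids)
      expect_gt(pa$p[pa$gene_id == g], 0.05)
      expect_gt(pb$p[pb$gene_id == g], 0.05)
      expect_true(lengths[g] >= lb[1] && lengths[g] <= lb[2])
      expect_true(expr[g] >= eb[1] && expr[g] <= eb[2])
    }
  }
})

test_that("null matching bounds are closed and failures are informative", {
  ids <- c("t1", "t2", "t3", "t4", "n1", "n2")
  pa <- data.frame(gene_id = ids, p = c(0.5, 0.5, 0.5, 0.5, 0.9, 0.01))
  pb <- data.frame(gene_id = ids, p = rep(0.9, 6))
  lengths <- stats::setNames(c(100, 200, 300, 400, 200, 200), ids)
  expr <- stats::setNames(c(10, 20, 30, 40, 20, 20), ids)
  # n1 sits exactly on the quartile bounds and must be kept (closed bounds);
  # n2 fails the p threshold in model a
  expect_warning(
    got <- match_null(c("t1", "t2", "t3", "t4"), pa, pb, lengths, expr),
    "smaller")
  expect_identical(got, "n1")
  lengths["n1"] <- 1e6
  expect_error(match_null(c("t1", "t2", "t3", "t4"), pa, pb, lengths, expr),
               "relax")
})

test_that("the two-proportion chi-squared test matches its closed form", {
  # score test without continuity correction:
  # chi2 = (p1-p2)^2 / (p(1-p)(1/n1+1/n2)) with pooled p
  x1 <- 30; n1 <- 100; x2 <- 10; n2 <- 100
  pool <- (x1 + x2) / (n1 + n2)
  chi2 <- (x1 / n1 - x2 / n2)^2 / (pool * (1 - pool) * (1 / n1 + 1 / n2))
  got <- jointlof:::two_prop_chisq(x1, n1, x2, n2)
  expect_equal(got$chi2, chi2, tolerance = 1e-12)
  expect_equal(got$p, stats::pchisq(chi2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("overlap testing is strand-specific and counts any-base overlap", {
  test_r <- iv(c(100, 300, 500), c(200, 400, 600),
               c("+", "+", "-"))
  null_r <- iv(c(1000, 1200), c(1100, 1300), "+")
  clusters <- iv(c(199, 350, 550), c(250, 360, 560), c("+", "-", "-"))
  got <- overlap_test(test_r, null_r, clusters)
  # region 1 overlaps by one base same strand; region 2's cluster is
  # antisense; region 3 matches on the minus strand
  expect_equal(got$prop_test, 2 / 3)
  expect_equal(got$prop_null, 0)
  expect_equal(got$n_test, 3)
  expect_error(overlap_test(test_r[0, ], null_r, clusters), "empty")
})

test_that("weighted median handles point masses, ties and splits", {
  expect_equal(jointlof:::weighted_median(5, 10), 5)
  expect_equal(jointlof:::weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  # equal halves straddle the midpoint
  expect_equal(jointlof:::weighted_median(c(0, 1), c(5, 5)), 0.5)
  expect_equal(jointlof:::weighted_median(c(0, 1), c(6, 4)), 0)
  expect_true(is.na(jointlof:::weighted_median(numeric(0), numeric(0))))
  # splitting one interval into two equal-weight pieces changes nothing
  set.seed(121)
  v <- rnorm(20); w <- runif(20) + 0.5
  a <- jointlof:::weighted_median(v, w)
  b <- jointlof:::weighted_median(c(v, v), c(w / 2, w / 2))
  expect_equal(a, b)
})

test_that("median conservation weights scores by covered bases", {
  scores <- genomic_intervals("S", c(0, 100, 200), c(100, 200, 300), ".",
                              score = c(0.1, 0.9, 0.5))
  # region 50-250 covers 50 bases of 0.1, 100 of 0.9 and 50 of 0.5;
  # cumulative weight reaches half exactly at 0.5, so the weighted median
  # interpolates to (0.5 + 0.9) / 2 = 0.7
  r2 <- iv(c(50, 400), c(250, 500), ".")
  m <- median_conservation(r2, scores)
  expect_equal(m[1], 0.7)
  expect_true(is.na(m[2]))  # no scored bases
  # full symmetric coverage: median at the middle score
  expect_equal(median_conservation(iv(0, 300, "."), scores)[1], 0.5)
})

test_that("conservation testing applies a strict threshold", {
  scores <- genomic_intervals("S", c(0, 100), c(100, 200), ".",
                              score = c(0.5, 0.8))
  test_r <- iv(c(0, 100), c(100, 200), ".")
  null_r <- iv(c(0, 0), c(100, 100), ".")
  got <- conservation_test(test_r, null_r, scores)
  # a median of exactly 0.5 does not pass the strict > 0.5 cutoff
  expect_equal(got$prop_test, 0.5)
  expect_equal(got$prop_null, 0)
  expect_error(conservation_test(iv(5000, 5100, "."), null_r, scores), "NA")
})

test_that("proximity flags distinguish overlap, nearby and none", {
  regions <- iv(c(1000, 3000, 9000), c(1100, 3100, 9100))
  clusters <- iv(c(1050, 3600, 20000), c(1060, 3700, 20100))
  got <- proximity_flag(regions, clusters, distance = 1000)
  expect_identical(got, c("overlapping", "within_distance", "none"))
  # shrinking the window demotes the nearby case
  expect_identical(proximity_flag(regions, clusters, distance = 100)[2],
                   "none")
  # antisense clusters do not count
  anti <- clusters
  anti$strand <- "-"
  expect_identical(proximity_flag(regions, anti, 1000),
                   c("none", "none", "none"))
})

test_that("the feature profile applies Bonferroni over the tests run", {
  m1 <- mk_model("gU", "+", exons = cbind(c(1000, 2000), c(1500, 2500)),
                 cds = cbind(c(1100, 2000), c(1500, 2400)))
  m2 <- mk_model("gD", "+", exons = cbind(c(5000, 6000), c(5500, 6500)),
                 cds = cbind(c(5100, 6000), c(5500, 6400)))
  m3 <- mk_model("gN", "+", exons = cbind(c(9000, 9900), c(9500, 10400)),
                 cds = cbind(c(9100, 9900), c(9500, 10300)))
  part <- build_partition(list(m1, m2, m3), contig_lengths = c(S = 50000))
  clusters <- iv(1600, 1700)  # inside gU's intron only
  prof <- feature_profile("gU", "gD", "gN", part, clusters)
  expect_true(all(c("feature", "direction", "p_bonferroni") %in% names(prof)))
  expect_equal(prof$p_bonferroni, pmin(1, prof$p * nrow(prof)))
  up_intron <- prof[prof$feature == "intron" & prof$direction == "up", ]
  expect_equal(up_intron$prop_test, 1)
  expect_equal(up_intron$prop_null, 0)
  down <- prof[prof$direction == "down", ]
  expect_true(all(down$prop_test == 0))
})

test_that("chi-squared enrichment agrees with a permutation test", {
  # fixed 2x2 layout: 35/100 vs 15/100; permutation null from shuffling
  # the membership labels
  x <- c(rep(1, 35), rep(0, 65), rep(1, 15), rep(0, 85))
  grp <- rep(c(1, 0), each = 100)
  obs <- jointlof:::two_prop_chisq(35, 100, 15, 100)
  set.seed(131)
  perm <- replicate(10000, {
    g <- sample(grp)
    abs(mean(x[g == 1]) - mean(x[g == 0]))
  })
  p_perm <- mean(perm >= abs(35 / 100 - 15 / 100) - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.01)
})
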