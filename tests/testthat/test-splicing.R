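event_tab <- function(inc, exc, types = NULL, strand = "+") {
  ne <- nrow(inc)
  if (is.null(types)) types <- rep("retained_intron", ne)
  ev <- data.frame(
    event_id = sprintf("e%03d", seq_len(ne)),
    gene_id = sprintf("g%03d", seq_len(ne)),
    chrom = "S", start = 1000 * seq_len(ne), end = 1000 * seq_len(ne) + 500,
    strand = strand, stringsAsFactors = FALSE)
  ev$descriptor <- vapply(seq_len(ne), function(i) {
    make_descriptor(types[i], ev$start[i], ev$end[i], strand)
  }, "")
  rownames(inc) <- rownames(exc) <- ev$event_id
  splice_event_table(ev, inc, exc)
}

usage_sheet <- function(n_wt, n_mut, dataset = "ds1") {
  data.frame(sample_id = sprintf("%s_s%d", dataset, seq_len(n_wt + n_mut)),
             dataset = dataset,
             genotype = c(rep("WT", n_wt), rep("HOM", n_mut)),
             arm = "KO", stringsAsFactors = FALSE)
}

test_that("PSI is inclusion over total with a low-coverage flag", {
  inc <- matrix(c(8L, 2L, 0L, 30L), 2, 2)
  exc <- matrix(c(2L, 2L, 0L, 10L), 2, 2)
  colnames(inc) <- colnames(exc) <- c("a", "b")
  tab <- event_tab(inc, exc)
  psi <- compute_psi(tab, min_total = 10)
  expect_equal(psi$psi[psi$event_id == "e001" & psi$sample_id == "a"], 0.8)
  expect_equal(psi$psi[psi$event_id == "e002" & psi$sample_id == "b"], 0.75)
  expect_equal(psi$psi[psi$event_id == "e002" & psi$sample_id == "a"], 0.5)
  # zero total: PSI undefined, flagged low coverage
  expect_true(is.na(psi$psi[psi$event_id == "e001" & psi$sample_id == "b"]))
  expect_identical(psi$low_coverage[psi$event_id == "e001"], c(FALSE, TRUE))
  expect_identical(psi$low_coverage[psi$event_id == "e002" &
                                      psi$sample_id == "a"], TRUE)
})

test_that("swapping inclusion and exclusion reflects PSI about one half", {
  set.seed(41)
  inc <- matrix(rpois(40, 30), 10, 4)
  exc <- matrix(rpois(40, 20), 10, 4)
  colnames(inc) <- colnames(exc) <- paste0("s", 1:4)
  storage.mode(inc) <- storage.mode(exc) <- "integer"
  a <- compute_psi(event_tab(inc, exc))
  b <- compute_psi(event_tab(exc, inc))
  expect_equal(a$psi + b$psi, rep(1, length(a$psi)))
  expect_identical(a$total, b$total)
})

test_that("event classification matches each definitional case", {
  d <- function(...) {
    jsonlite::toJSON(list(...), auto_unbox = TRUE)
  }
  j <- function(s, e) list(s, e)
  expect_equal(classify_event(d(strand = "+", inclusion = list(),
                                exclusion = list(j(100, 200)))),
               "retained_intron")
  expect_equal(classify_event(d(strand = "+",
                                inclusion = list(j(100, 130), j(170, 200)),
                                exclusion = list(j(100, 200)))),
               "cassette_exon")
  # shared acceptor (end, plus strand), alternative donor => alt5
  expect_equal(classify_event(d(strand = "+", inclusion = list(j(100, 200)),
                                exclusion = list(j(120, 200)))), "alt5")
  # same junctions on the minus strand: the shared end is now the donor
  expect_equal(classify_event(d(strand = "-", inclusion = list(j(100, 200)),
                                exclusion = list(j(120, 200)))), "alt3")
  expect_equal(classify_event(d(strand = "+", inclusion = list(j(100, 200)),
                                exclusion = list(j(100, 180)))), "alt3")
  expect_equal(classify_event(d(strand = "-", inclusion = list(j(100, 200)),
                                exclusion = list(j(100, 180)))), "alt5")
  # identical single junctions are degenerate
  expect_equal(classify_event(d(strand = "+", inclusion = list(j(100, 200)),
                                exclusion = list(j(100, 200)))), "other")
  # flanking junctions not matching the skip junction ends
  expect_equal(classify_event(d(strand = "+",
                                inclusion = list(j(100, 130), j(170, 210)),
                                exclusion = list(j(100, 200)))), "complex")
  expect_equal(classify_event(d(strand = "+",
                                inclusion = list(j(100, 140)),
                                exclusion = list(j(150, 200)))), "complex")
  expect_error(classify_event(d(strand = "+", inclusion = list(),
                                exclusion = list())), "empty")
})

test_that("every generated descriptor type classifies to itself", {
  set.seed(51)
  for (i in 1:30) {
    type <- sample(c("retained_intron", "cassette_exon", "alt5", "alt3",
                     "complex"), 1)
    strand <- sample(c("+", "-"), 1)
    s <- sample.int(50000, 1)
    e <- s + sample(60:3000, 1)
    expect_equal(classify_event(make_descriptor(type, s, e, strand)), type)
  }
})

test_that("classification is total on random well-formed descriptors", {
  set.seed(61)
  labels <- c("retained_intron", "cassette_exon", "alt5", "alt3",
              "complex", "other")
  for (i in 1:40) {
    nI <- sample(0:3, 1); nE <- sample(0:3, 1)
    if (nI + nE == 0) nE <- 1
    mk <- function(n) {
      lapply(seq_len(n), function(k) {
        s <- sample.int(1000, 1)
        list(s, s + sample.int(500, 1))
      })
    }
    desc <- jsonlite::toJSON(list(strand = sample(c("+", "-"), 1),
                                  inclusion = mk(nI), exclusion = mk(nE)),
                             auto_unbox = TRUE)
    expect_true(classify_event(desc) %in% labels)
  }
})

test_that("identical groups yield a null usage fit", {
  set.seed(71)
  sheet <- usage_sheet(4, 4)
  inc <- matrix(50L, 5, 8)
  exc <- matrix(50L, 5, 8)
  colnames(inc) <- colnames(exc) <- sheet$sample_id
  res <- fit_usage(event_tab(inc, exc), sheet)
  expect_equal(res$log2_usage_fc, rep(0, 5), tolerance = 1e-6)
  expect_equal(res$delta_psi, rep(0, 5))
  expect_true(all(res$p > 0.5))
})

test_that("the usage test recovers a strong simulated shift", {
  set.seed(81)
  sheet <- usage_sheet(4, 4)
  n <- 40
  shift <- rep(c(0, -2), c(30, 10))
  base <- stats::qlogis(0.7)
  inc <- exc <- matrix(0L, n, 8)
  colnames(inc) <- colnames(exc) <- sheet$sample_id
  for (i in seq_len(n)) {
    for (s in 1:8) {
      tot <- rpois(1, 120)
      p <- stats::plogis(base + shift[i] * (sheet$genotype[s] != "WT"))
      inc[i, s] <- rbinom(1, tot, p)
      exc[i, s] <- tot - inc[i, s]
    }
  }
  res <- fit_usage(event_tab(inc, exc), sheet)
  expect_true(all(res$fdr[31:40] < 0.05))
  expect_lt(mean(res$p[1:30] < 0.05), 0.2)
  # the logit coefficient is reported in log2 units
  expect_equal(mean(res$log2_usage_fc[31:40]), -2 / log(2), tolerance = 0.15)
  expect_true(all(res$delta_psi[31:40] < -0.2))
})

test_that("all-low-coverage events are NA and the joint flag is honoured", {
  sheet <- rbind(usage_sheet(2, 2, "ds1"), usage_sheet(2, 2, "ds2"))
  inc <- matrix(c(rep(30L, 8), rep(2L, 8)), 2, 8, byrow = TRUE)
  exc <- matrix(c(rep(10L, 8), rep(1L, 8)), 2, 8, byrow = TRUE)
  colnames(inc) <- colnames(exc) <- sheet$sample_id
  res <- fit_usage(event_tab(inc, exc), sheet, joint = TRUE)
  expect_true(is.na(res$p[2]))
  expect_false(is.na(res$p[1]))
  expect_identical(unique(res$model), "joint")
  single <- fit_usage(event_tab(inc[, 1:4], exc[, 1:4]), sheet[1:4, ],
                      joint = TRUE)
  expect_identical(unique(single$model), "per-dataset")
})

test_that("usage fitting flags regulated events on the shared simulation", {
  sim <- shared_sim
  ko <- arm_events(sim, "KO")
  keep <- ko$sheet$genotype %in% c("WT", "HOM")
  tab <- splice_event_table(ko$tab$events,
                            ko$tab$inclusion[, ko$sheet$sample_id[keep]],
                            ko$tab$exclusion[, ko$sheet$sample_id[keep]])
  res <- fit_usage(tab, ko$sheet[keep, ], joint = TRUE)
  te <- sim$ev$truth_events
  reg <- te$regulated[match(res$event_id, te$event_id)]
  expect_gt(mean(res$fdr[reg] < 0.05, na.rm = TRUE), 0.8)
  expect_lt(mean(res$fdr[!reg] < 0.05, na.rm = TRUE), 0.1)
  expect_true(all(res$type[reg] == "retained_intron"))
  # negative psi_shift must come out as negative delta PSI
  expect_lt(median(res$delta_psi[reg], na.rm = TRUE), -0.1)
})

test_that("delta PSI subtracts the WT group mean per event", {
  sheet <- usage_sheet(2, 2)
  inc <- matrix(c(8L, 8L, 2L, 2L), 1, 4)
  exc <- matrix(c(2L, 2L, 8L, 8L), 1, 4)
  colnames(inc) <- colnames(exc) <- sheet$sample_id
  psi <- compute_psi(event_tab(inc, exc), min_total = 1)
  d <- delta_psi(psi, sheet)
  expect_equal(unname(d["e001"]), -0.6)
  expect_error(delta_psi(psi, sheet[sheet$genotype == "WT", ]), "mutant")
})

test_that("cryptic and skiptic exons are labelled from WT and mutant PSI", {
  sheet <- usage_sheet(2, 2)
  # e1 cryptic (0 -> 0.5), e2 skiptic (1 -> 0.6), e3 neither (0.5 -> 0.55)
  inc <- matrix(c(0L, 0L, 50L, 50L,
                  100L, 100L, 60L, 60L,
                  50L, 50L, 55L, 55L), 3, 4, byrow = TRUE)
  exc <- matrix(c(100L, 100L, 50L, 50L,
                  0L, 0L, 40L, 40L,
                  50L, 50L, 45L, 45L), 3, 4, byrow = TRUE)
  colnames(inc) <- colnames(exc) <- sheet$sample_id
  tab <- event_tab(inc, exc, types = rep("cassette_exon", 3))
  res <- fit_usage(tab, sheet)
  psi <- compute_psi(tab)
  lab <- classify_cryptic_skiptic(res, psi, sheet)
  expect_identical(lab$label, c("cryptic", "skiptic", "neither"))
  # a sub-threshold gain is neither
  strict <- classify_cryptic_skiptic(res, psi, sheet, min_gain = 0.6)
  expect_identical(strict$label, c("neither", "neither", "neither"))
  res_ri <- res
  res_ri$type <- "retained_intron"
  expect_error(classify_cryptic_skiptic(res_ri, psi, sheet), "cassette")
})

test_that("event tables round-trip through their TSV serialization", {
  sim <- shared_sim
  tab <- sim$ev$events$ds2
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(tab, f)
  back <- read_events(f)
  expect_identical(back$inclusion, tab$inclusion)
  expect_identical(back$exclusion, tab$exclusion)
  expect_equal(back$events, tab$events, ignore_attr = TRUE)
})
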