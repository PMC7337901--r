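#' Simulation configuration
#'
#' Defines the generative model for a multi-dataset knockout (KO) and
#' NLS-mutant (NLS) study: three independent datasets, each with KO-vs-WT and
#' NLS-vs-WT arms sharing true effects, where the NLS effect is an attenuated
#' multiple of the KO effect (the loss-of-function structure), plus splice
#' events whose genotype-dependent PSI shifts are concentrated in retained
#' introns, CLIP clusters enriched over regulated introns, and an elevated
#' conservation track over the same introns.
#'
#' @param n_genes number of genes.
#' @param n_datasets number of independent datasets.
#' @param samples_per_group samples per genotype group within a dataset arm.
#' @param baseline_mean_log c(meanlog, sdlog) of the log-normal gene baseline
#'   mean counts.
#' @param dispersion NB dispersion alpha, Var = mu + alpha mu^2.
#' @param frac_shared_de fraction of genes differentially expressed in both
#'   arms (NLS effect = attenuation x KO effect).
#' @param frac_ko_specific,frac_nls_specific fractions DE in one arm only.
#' @param attenuation true ratio of NLS to KO log2 effect, in (0, 1].
#' @param effect_sd sd of true KO log2 effects.
#' @param dataset_effect_sd sd of per-gene, per-dataset baseline log2 shifts;
#'   this is what the dataset covariate in the joint model absorbs.
#' @param n_events number of splice events.
#' @param frac_ir_regulated fraction of events with a true genotype effect;
#'   regulated events are retained introns.
#' @param psi_shift true KO-arm shift for regulated events, on the logit(PSI)
#'   scale (negative = loss of retention); the NLS shift is
#'   attenuation x psi_shift.
#' @param event_depth mean total reads per event per unit size factor.
#' @param type_props named proportions over unregulated event types.
#' @param clip_enrichment odds multiplier for cluster placement over regulated
#'   introns relative to background.
#' @param clip_background_prob background probability that an intron carries a
#'   cluster.
#' @param conservation_shift mean phyloP increment over regulated introns.
#' @param conservation_sd per-bin phyloP sd around the mean.
#' @param conservation_bin bin width (bases) at which the conservation track
#'   is drawn.
#' @param include_het also simulate heterozygote samples (half the homozygote
#'   log2 / logit effect) in every dataset arm.
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return a validated config list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000,
                       n_datasets = 3,
                       samples_per_group = 4,
                       baseline_mean_log = c(5, 1.5),
                       dispersion = 0.05,
                       frac_shared_de = 0.15,
                       frac_ko_specific = 0.05,
                       frac_nls_specific = 0.01,
                       attenuation = 0.76,
                       effect_sd = 1,
                       dataset_effect_sd = 0.5,
                       n_events = 1000,
                       frac_ir_regulated = 0.10,
                       psi_shift = -1.5,
                       event_depth = 100,
                       type_props = c(retained_intron = 0.35, cassette_exon = 0.2,
                                      alt5 = 0.1, alt3 = 0.1, complex = 0.25),
                       clip_enrichment = 5,
                       clip_background_prob = 0.15,
                       conservation_shift = 2,
                       conservation_sd = 0.5,
                       conservation_bin = 25,
                       include_het = TRUE,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_datasets = n_datasets,
              samples_per_group = samples_per_group,
              baseline_mean_log = baseline_mean_log, dispersion = dispersion,
              frac_shared_de = frac_shared_de,
              frac_ko_specific = frac_ko_specific,
              frac_nls_specific = frac_nls_specific,
              attenuation = attenuation, effect_sd = effect_sd,
              dataset_effect_sd = dataset_effect_sd,
              n_events = n_events, frac_ir_regulated = frac_ir_regulated,
              psi_shift = psi_shift, event_depth = event_depth,
              type_props = type_props, clip_enrichment = clip_enrichment,
              clip_background_prob = clip_background_prob,
              conservation_shift = conservation_shift,
              conservation_sd = conservation_sd,
              conservation_bin = conservation_bin,
              include_het = include_het, seed = as.integer(seed))
  fracs <- c(frac_shared_de, frac_ko_specific, frac_nls_specific,
             frac_ir_regulated, clip_background_prob)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (frac_shared_de + frac_ko_specific + frac_nls_specific > 1) {
    stop("DE fractions sum to more than 1")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (attenuation <= 0 || attenuation > 1) stop("attenuation must be in (0, 1]")
  if (samples_per_group < 2) {
    stop("samples_per_group must be >= 2; smaller groups make the models unfittable")
  }
  if (abs(sum(type_props) - 1) > 1e-8) stop("type_props must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

dataset_names <- function(cfg) paste0("ds", seq_len(cfg$n_datasets))

#' Simulate per-dataset count matrices with known ground truth
#'
#' Counts for sample j of gene g are NB(mu, alpha) with
#' mu = sf_j x baseline_g x 2^(dataset shift) x 2^(effect x dose), where dose
#' is 1 for HOM, 0.5 for HET and 0 for WT, and per-sample size factors sf are
#' drawn log-uniform in [0.5, 2]. Shared genes satisfy
#' NLS effect = attenuation x KO effect exactly.
#'
#' @param config a [sim_config()].
#' @return list with \code{datasets} (per dataset: \code{counts} matrix and
#'   \code{sheet}) and \code{truth} (per-gene effects, per-sample size
#'   factors, per-gene/dataset mean matrices).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ng <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))
  n_sh <- round(ng * config$frac_shared_de)
  n_ko <- round(ng * config$frac_ko_specific)
  n_nls <- round(ng * config$frac_nls_specific)
  cls <- rep("null", ng)
  cls[seq_len(n_sh)] <- "shared"
  if (n_ko > 0) cls[n_sh + seq_len(n_ko)] <- "ko_specific"
  if (n_nls > 0) cls[n_sh + n_ko + seq_len(n_nls)] <- "nls_specific"
  ko_lfc <- nls_lfc <- rep(0, ng)
  draw <- stats::rnorm(ng, 0, config$effect_sd)
  ko_lfc[cls == "shared"] <- draw[cls == "shared"]
  nls_lfc[cls == "shared"] <- config$attenuation * ko_lfc[cls == "shared"]
  ko_lfc[cls == "ko_specific"] <- draw[cls == "ko_specific"]
  nls_lfc[cls == "nls_specific"] <- draw[cls == "nls_specific"]
  baseline <- stats::rlnorm(ng, config$baseline_mean_log[1],
                            config$baseline_mean_log[2])
  genotypes <- if (config$include_het) c("WT", "HET", "HOM") else c("WT", "HOM")
  dose <- c(WT = 0, HET = 0.5, HOM = 1)
  datasets <- list()
  sf_all <- list()
  means <- list()
  for (d in dataset_names(config)) {
    ds_shift <- matrix(stats::rnorm(ng * 2, 0, config$dataset_effect_sd),
                       nrow = ng)[, 1]
    sheet <- expand.grid(rep = seq_len(config$samples_per_group),
                         genotype = genotypes, arm = c("KO", "NLS"),
                         stringsAsFactors = FALSE)
    sheet$dataset <- d
    sheet$sample_id <- sprintf("%s_%s_%s_%d", d, sheet$arm, sheet$genotype,
                               sheet$rep)
    sheet <- sheet[, c("sample_id", "dataset", "genotype", "arm")]
    ns <- nrow(sheet)
    sf <- exp(stats::runif(ns, log(0.5), log(2)))
    names(sf) <- sheet$sample_id
    eff <- ifelse(sheet$arm == "KO", 1, 0)
    mu <- matrix(0, ng, ns, dimnames = list(gene_ids, sheet$sample_id))
    for (j in seq_len(ns)) {
      lfc <- if (sheet$arm[j] == "KO") ko_lfc else nls_lfc
      mu[, j] <- sf[j] * baseline * 2^(ds_shift + lfc * dose[sheet$genotype[j]])
    }
    counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                    size = 1 / config$dispersion),
                     ng, ns, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"
    datasets[[d]] <- list(counts = counts, sheet = sheet)
    sf_all[[d]] <- sf
    means[[d]] <- mu
  }
  truth <- list(
    genes = data.frame(gene_id = gene_ids, class = cls, ko_lfc = ko_lfc,
                       nls_lfc = nls_lfc, baseline = baseline,
                       stringsAsFactors = FALSE),
    size_factors = sf_all,
    means = means
  )
  list(datasets = datasets, truth = truth)
}

#' Simulate a compact single-chromosome annotation
#'
#' Genes are tiled without overlap on one synthetic chromosome, alternating
#' strand, each with at least three exons, a CDS confined to the internal
#' exons, and terminal UTR exons, so the genomic feature partition
#' (5' UTR / CDS / intron / extended 3' UTR / promoter-antisense) is
#' non-degenerate for every gene.
#'
#' @param config a [sim_config()].
#' @return list with \code{models} (transcript models, one per gene),
#'   \code{introns} (interval data.frame with gene_id and intron index) and
#'   \code{contig_lengths} (named numeric).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ng <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))
  pos <- 10000
  models <- vector("list", ng)
  intron_rows <- vector("list", ng)
  for (i in seq_len(ng)) {
    n_ex <- sample(3:5, 1)
    ex_w <- sample(150:300, n_ex, replace = TRUE)
    in_w <- sample(200:800, n_ex - 1, replace = TRUE)
    starts <- pos + cumsum(c(0, ex_w[-n_ex] + in_w))
    ends <- starts + ex_w
    strand <- if (i %% 2 == 1) "+" else "-"
    exons <- data.frame(start = starts, end = ends)
    # CDS spans from inside the first exon to inside the last exon, leaving
    # terminal UTR stubs on both ends
    cds <- exons
    cds$start[1] <- exons$start[1] + round(ex_w[1] / 2)
    cds$end[n_ex] <- exons$end[n_ex] - round(ex_w[n_ex] / 2)
    models[[i]] <- list(transcript_id = paste0(gene_ids[i], ".t1"),
                        gene_id = gene_ids[i], chrom = "S", strand = strand,
                        exons = exons, cds = cds, tags = character())
    intron_rows[[i]] <- data.frame(chrom = "S", start = ends[-n_ex],
                                   end = starts[-1], strand = strand,
                                   gene_id = gene_ids[i],
                                   intron_index = seq_len(n_ex - 1),
                                   stringsAsFactors = FALSE)
    pos <- ends[n_ex] + 2000
  }
  introns <- do.call(rbind, intron_rows)
  validate_intervals(introns)
  list(models = models, introns = introns,
       contig_lengths = c(S = pos + 10000))
}

#' Simulate splice-event inclusion/exclusion tables
#'
#' Each event occupies one intron of the synthetic annotation. Per sample,
#' total reads ~ Poisson(event_depth x size factor) and inclusion reads ~
#' Binomial(total, psi) with psi = logistic(logit(base_psi) + shift x dose).
#' Regulated events are retained introns with KO shift = psi_shift and NLS
#' shift = attenuation x psi_shift on the logit scale; heterozygotes receive
#' half the homozygote shift.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_counts()] (supplies per-sample
#'   size factors and the sample layout).
#' @param annotation annotation from [simulate_annotation()]; generated when
#'   NULL.
#' @param datasets the \code{datasets} element from [simulate_counts()].
#' @return list with \code{events} (per dataset: a splice event table, see
#'   [splice_event_table()]) and \code{truth_events} (per-event data.frame).
#' @export
simulate_events <- function(config, truth, datasets, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_events == 0) stop("n_events must be positive")
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  set.seed(config$seed + 2L)
  ne <- config$n_events
  introns <- annotation$introns
  if (nrow(introns) < ne) stop("not enough introns to host events")
  pick <- sort(sample.int(nrow(introns), ne))
  ev_introns <- introns[pick, , drop = FALSE]
  event_ids <- sprintf("e%04d", seq_len(ne))
  n_reg <- round(ne * config$frac_ir_regulated)
  regulated <- c(rep(TRUE, n_reg), rep(FALSE, ne - n_reg))
  types <- character(ne)
  types[regulated] <- "retained_intron"
  if (any(!regulated)) {
    types[!regulated] <- sample(names(config$type_props), sum(!regulated),
                                replace = TRUE, prob = config$type_props)
  }
  base_psi <- stats::runif(ne, 0.1, 0.9)
  ko_shift <- ifelse(regulated, config$psi_shift, 0)
  nls_shift <- config$attenuation * ko_shift
  descriptors <- vapply(seq_len(ne), function(i) {
    make_descriptor(types[i], ev_introns$start[i], ev_introns$end[i],
                    ev_introns$strand[i])
  }, "")
  truth_events <- data.frame(
    event_id = event_ids, gene_id = ev_introns$gene_id, type = types,
    regulated = regulated, base_psi = base_psi,
    ko_shift = ko_shift, nls_shift = nls_shift,
    chrom = ev_introns$chrom, start = ev_introns$start, end = ev_introns$end,
    strand = ev_introns$strand, stringsAsFactors = FALSE)
  dose <- c(WT = 0, HET = 0.5, HOM = 1)
  events <- list()
  for (d in names(datasets)) {
    sheet <- datasets[[d]]$sheet
    sf <- truth$size_factors[[d]]
    ns <- nrow(sheet)
    incl <- excl <- matrix(0L, ne, ns,
                           dimnames = list(event_ids, sheet$sample_id))
    for (j in seq_len(ns)) {
      shift <- if (sheet$arm[j] == "KO") ko_shift else nls_shift
      psi <- stats::plogis(stats::qlogis(base_psi) +
                             shift * dose[sheet$genotype[j]])
      tot <- stats::rpois(ne, config$event_depth * sf[sheet$sample_id[j]])
      inc <- stats::rbinom(ne, tot, psi)
      incl[, j] <- inc
      excl[, j] <- tot - inc
    }
    events[[d]] <- splice_event_table(
      events = data.frame(event_id = event_ids, gene_id = ev_introns$gene_id,
                          descriptor = descriptors, chrom = ev_introns$chrom,
                          start = ev_introns$start, end = ev_introns$end,
                          strand = ev_introns$strand, stringsAsFactors = FALSE),
      inclusion = incl, exclusion = excl)
  }
  list(events = events, truth_events = truth_events)
}

#' Build a JSON splicing descriptor for a canonical event type
#'
#' The descriptor records the variant junctions (start, end in 0-based
#' half-open genomic coordinates) of the inclusion and exclusion forms, plus
#' the strand; [classify_event()] inverts this construction.
#'
#' @param type one of retained_intron, cassette_exon, alt5, alt3, complex.
#' @param start,end encompassing intron coordinates.
#' @param strand "+" or "-".
#' @return a JSON string.
#' @export
make_descriptor <- function(type, start, end, strand) {
  third <- round((end - start) / 3)
  j <- function(...) list(...)
  junc <- switch(type,
    retained_intron = list(inclusion = list(), exclusion = list(j(start, end))),
    cassette_exon = list(
      inclusion = list(j(start, start + third), j(end - third, end)),
      exclusion = list(j(start, end))),
    alt5 = if (strand == "+") {
      list(inclusion = list(j(start, end)),
           exclusion = list(j(start + third, end)))
    } else {
      list(inclusion = list(j(start, end)),
           exclusion = list(j(start, end - third)))
    },
    alt3 = if (strand == "+") {
      list(inclusion = list(j(start, end)),
           exclusion = list(j(start, end - third)))
    } else {
      list(inclusion = list(j(start, end)),
           exclusion = list(j(start + third, end)))
    },
    complex = list(
      inclusion = list(j(start, start + third), j(end - third, end)),
      exclusion = list(j(start, end),
                       j(start, start + 2 * third), j(end - third, end))),
    stop("unknown event type: ", type))
  jsonlite::toJSON(c(list(strand = strand), junc), auto_unbox = TRUE)
}

#' Simulate CLIP-cluster and conservation tracks
#'
#' Each intron carries a cluster with background probability
#' \code{clip_background_prob}; over introns hosting regulated events the
#' placement odds are multiplied by \code{clip_enrichment}. Clusters lie
#' inside their intron on the host gene strand, with at least two supporting
#' reads. The conservation track covers every event intron at
#' \code{conservation_bin} resolution, drawn Normal(0, conservation_sd) with
#' mean raised by \code{conservation_shift} over regulated introns.
#'
#' @param config a [sim_config()].
#' @param truth_events per-event truth from [simulate_events()].
#' @param annotation annotation from [simulate_annotation()].
#' @return list with \code{clusters} (BED-style interval data.frame),
#'   \code{conservation} (scored interval data.frame) and
#'   \code{cluster_truth} (per-intron placement flags).
#' @export
simulate_tracks <- function(config, truth_events, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  introns <- annotation$introns
  key <- paste(introns$start, introns$end)
  reg_key <- paste(truth_events$start, truth_events$end)[truth_events$regulated]
  regulated <- key %in% reg_key
  p0 <- config$clip_background_prob
  odds <- p0 / (1 - p0)
  p1 <- odds * config$clip_enrichment / (1 + odds * config$clip_enrichment)
  prob <- ifelse(regulated, p1, p0)
  has_cluster <- stats::runif(nrow(introns)) < prob
  idx <- which(has_cluster)
  width <- pmin(30, introns$end[idx] - introns$start[idx])
  offset <- floor(stats::runif(length(idx)) *
                    (introns$end[idx] - introns$start[idx] - width + 1))
  clusters <- genomic_intervals(
    chrom = introns$chrom[idx], start = introns$start[idx] + offset,
    end = introns$start[idx] + offset + width, strand = introns$strand[idx],
    name = sprintf("c%04d", seq_along(idx)),
    score = 2 + stats::rpois(length(idx), 3))
  # conservation over event introns only, binned
  ev <- truth_events[order(truth_events$start), , drop = FALSE]
  bin <- config$conservation_bin
  nb <- pmax(1, ceiling((ev$end - ev$start) / bin))
  idx <- rep(seq_len(nrow(ev)), nb)
  off <- sequence(nb) - 1
  bstart <- ev$start[idx] + off * bin
  bend <- pmin(bstart + bin, ev$end[idx])
  mu <- ifelse(ev$regulated[idx], config$conservation_shift, 0)
  conservation <- data.frame(
    chrom = ev$chrom[idx], start = bstart, end = bend, strand = ".",
    score = stats::rnorm(length(bstart), mu, config$conservation_sd),
    stringsAsFactors = FALSE)
  cluster_truth <- data.frame(introns, regulated = regulated,
                              has_cluster = has_cluster,
                              stringsAsFactors = FALSE)
  list(clusters = clusters, conservation = conservation,
       cluster_truth = cluster_truth)
}

#' Write a complete fixture bundle to disk
#'
#' Generates annotation, counts, events and tracks for one configuration and
#' writes them in the package's external formats (TSV, GTF, BED, bedGraph)
#' together with the ground truth tables and a JSON manifest recording the
#' config, the seed and the md5 checksum of every file. With the seed fixed
#' the whole bundle is byte-reproducible.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the manifest, invisibly.
#' @export
write_fixture_bundle <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config)
  cnt <- simulate_counts(config)
  ev <- simulate_events(config, cnt$truth, cnt$datasets, ann)
  trk <- simulate_tracks(config, ev$truth_events, ann)
  files <- character()
  for (d in names(cnt$datasets)) {
    f1 <- file.path(out_dir, paste0("counts_", d, ".tsv"))
    f2 <- file.path(out_dir, paste0("samples_", d, ".tsv"))
    f3 <- file.path(out_dir, paste0("events_", d, ".tsv"))
    write_counts(cnt$datasets[[d]]$counts, f1)
    utils::write.table(cnt$datasets[[d]]$sheet, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_events(ev$events[[d]], f3)
    files <- c(files, f1, f2, f3)
  }
  fg <- file.path(out_dir, "annotation.gtf")
  fb <- file.path(out_dir, "clusters.bed")
  fc <- file.path(out_dir, "conservation.bedgraph")
  ft1 <- file.path(out_dir, "truth_genes.tsv")
  ft2 <- file.path(out_dir, "truth_events.tsv")
  write_gtf(ann$models, fg)
  write_bed(trk$clusters, fb)
  write_bedgraph(trk$conservation, fc)
  write_results(cnt$truth$genes, ft1)
  write_results(ev$truth_events, ft2)
  files <- c(files, fg, fb, fc, ft1, ft2)
  manifest <- list(config = unclass(config),
                   datasets = dataset_names(config),
                   arms = c("KO", "NLS"),
                   files = stats::setNames(as.list(unname(tools::md5sum(files))),
                                           basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate paired effect sizes for attenuation-recovery designs
#'
#' Draws n reference (KO or homozygote) log2 effects from N(0, 1) and sets the
#' paired (NLS or heterozygote) effect to ratio x reference plus Gaussian
#' noise. The noise sd is either given directly or derived from a target
#' coefficient of determination: with x ~ N(0,1) the signal variance is
#' ratio^2, so sd = |ratio| sqrt((1 - R2)/R2).
#'
#' @param n number of paired effects.
#' @param ratio true attenuation slope.
#' @param r_squared target R^2 (used when \code{noise_sd} is NULL).
#' @param noise_sd noise standard deviation (overrides \code{r_squared}).
#' @return data.frame with columns \code{ref} and \code{att}.
#' @export
simulate_paired_effects <- function(n, ratio, r_squared = NULL,
                                    noise_sd = NULL) {
  if (is.null(noise_sd)) {
    stopifnot(!is.null(r_squared), r_squared > 0, r_squared < 1)
    noise_sd <- abs(ratio) * sqrt((1 - r_squared) / r_squared)
  }
  ref <- stats::rnorm(n)
  att <- ratio * ref + stats::rnorm(n, 0, noise_sd)
  data.frame(ref = ref, att = att)
}
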