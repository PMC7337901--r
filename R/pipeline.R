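#' Pipeline run configuration
#'
#' Bundles the simulation configuration with analysis settings so a run is
#' fully described by one object; all defaults are echoed into the run
#' manifest.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param out_dir output directory; fixtures under \code{fixtures/}, result
#'   tables under \code{results/}.
#' @param alpha significance level for overlap classification.
#' @param min_total coverage filter for the usage test.
#' @param min_cluster_reads cluster support filter.
#' @param conservation_threshold median-score cutoff.
#' @param proximity_distance window for the proximity flag (bases).
#' @param force overwrite an existing fixture directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sim = sim_config(), out_dir = "jointlof_run",
                       alpha = 0.05, min_total = 10, min_cluster_reads = 2,
                       conservation_threshold = 0.5,
                       proximity_distance = 1000, force = FALSE) {
  stopifnot(inherits(sim, "sim_config"), alpha > 0, alpha < 1)
  structure(list(sim = sim, out_dir = out_dir, alpha = alpha,
                 min_total = min_total, min_cluster_reads = min_cluster_reads,
                 conservation_threshold = conservation_threshold,
                 proximity_distance = proximity_distance, force = force),
            class = "run_config")
}

merge_datasets <- function(datasets) {
  counts <- do.call(cbind, lapply(datasets, `[[`, "counts"))
  sheet <- do.call(rbind, c(lapply(datasets, `[[`, "sheet"),
                            make.row.names = FALSE))
  list(counts = counts, sheet = sheet)
}

merge_event_tables <- function(tabs) {
  splice_event_table(tabs[[1]]$events,
                     do.call(cbind, lapply(tabs, `[[`, "inclusion")),
                     do.call(cbind, lapply(tabs, `[[`, "exclusion")))
}

subset_arm <- function(counts, sheet, arm) {
  keep <- sheet$arm == arm
  list(counts = counts[, sheet$sample_id[keep], drop = FALSE],
       sheet = sheet[keep, , drop = FALSE])
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in order: simulate (fixture bundle), de (joint NB models for the
#' KO and NLS arms, homozygote and, when simulated, heterozygote
#' comparisons), splice (joint usage models), overlap (strict/relaxed
#' classification, direction concordance, attenuation and dosage
#' regressions, DE x DS Fisher intersections) and enrich (event-type cluster
#' enrichment, conservation enrichment, proximity flags and the per-feature
#' gene binding profile against matched nulls). Each stage writes its tables
#' under \code{results/} and is recorded in a JSON manifest; with a fixed
#' seed the whole run is byte-reproducible.
#'
#' @param config a [run_config()].
#' @return the manifest list, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fx_dir <- file.path(config$out_dir, "fixtures")
  rs_dir <- file.path(config$out_dir, "results")
  dir.create(rs_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = list(sim = unclass(config$sim),
                                 alpha = config$alpha,
                                 min_total = config$min_total,
                                 min_cluster_reads = config$min_cluster_reads,
                                 conservation_threshold =
                                   config$conservation_threshold,
                                 proximity_distance =
                                   config$proximity_distance),
                   seed = config$sim$seed, stages = list())
  mark <- function(stage, files) {
    manifest$stages[[stage]] <<- list(status = "completed",
                                      outputs = basename(files))
  }
  # -- simulate ---------------------------------------------------------------
  write_fixture_bundle(config$sim, fx_dir, force = config$force)
  ann <- simulate_annotation(config$sim)
  cnt <- simulate_counts(config$sim)
  ev <- simulate_events(config$sim, cnt$truth, cnt$datasets, ann)
  trk <- simulate_tracks(config$sim, ev$truth_events, ann)
  mark("simulate", list.files(fx_dir))
  merged <- merge_datasets(cnt$datasets)
  ev_merged <- merge_event_tables(ev$events)
  genotypes <- if (config$sim$include_het) c("HOM", "HET") else "HOM"
  # -- de ---------------------------------------------------------------------
  de <- list()
  de_files <- character()
  for (arm in c("KO", "NLS")) {
    sub <- subset_arm(merged$counts, merged$sheet, arm)
    for (gt in genotypes) {
      key <- paste(arm, gt, sep = "_")
      de[[key]] <- fit_de(sub$counts, sub$sheet, joint = TRUE, genotype = gt)
      f <- file.path(rs_dir, sprintf("de_joint_%s.tsv", key))
      write_results(de[[key]], f)
      de_files <- c(de_files, f)
    }
  }
  mark("de", de_files)
  # -- splice -----------------------------------------------------------------
  ds <- list()
  ds_files <- character()
  for (arm in c("KO", "NLS")) {
    keep <- merged$sheet$arm == arm
    sheet_arm <- merged$sheet[keep, , drop = FALSE]
    tab_arm <- splice_event_table(
      ev_merged$events,
      ev_merged$inclusion[, sheet_arm$sample_id, drop = FALSE],
      ev_merged$exclusion[, sheet_arm$sample_id, drop = FALSE])
    for (gt in genotypes) {
      key <- paste(arm, gt, sep = "_")
      ds[[key]] <- fit_usage(tab_arm, sheet_arm, joint = TRUE, genotype = gt,
                             min_total = config$min_total)
      f <- file.path(rs_dir, sprintf("splice_joint_%s.tsv", key))
      write_results(ds[[key]], f)
      ds_files <- c(ds_files, f)
    }
  }
  mark("splice", ds_files)
  # -- overlap ----------------------------------------------------------------
  ov_files <- character()
  ov_de <- classify_overlap(de$KO_HOM, de$NLS_HOM, alpha = config$alpha)
  ov_ds <- classify_overlap(ds$KO_HOM, ds$NLS_HOM, alpha = config$alpha)
  f <- file.path(rs_dir, "overlap_de.tsv"); write_results(ov_de, f)
  ov_files <- c(ov_files, f)
  f <- file.path(rs_dir, "overlap_splice.tsv"); write_results(ov_ds, f)
  ov_files <- c(ov_files, f)
  conc_de <- direction_concordance(ov_de)
  conc_ds <- direction_concordance(ov_ds)
  shared_de <- ov_de[ov_de$label %in% c("shared_strict", "shared_relaxed_only"), ]
  shared_ds <- ov_ds[ov_ds$label %in% c("shared_strict", "shared_relaxed_only"), ]
  fits <- list()
  if (nrow(shared_de) >= 3 && stats::var(shared_de$ko_lfc, na.rm = TRUE) > 0) {
    fits$attenuation_expression <- fit_attenuation(shared_de$ko_lfc,
                                                   shared_de$nls_lfc)
  }
  if (nrow(shared_ds) >= 3 && stats::var(shared_ds$ko_lfc, na.rm = TRUE) > 0) {
    fits$attenuation_splicing <- fit_attenuation(shared_ds$ko_lfc,
                                                 shared_ds$nls_lfc)
  }
  if (config$sim$include_het) {
    for (arm in c("KO", "NLS")) {
      ovh <- classify_overlap(ds[[paste0(arm, "_HOM")]],
                              ds[[paste0(arm, "_HET")]], alpha = config$alpha)
      sh <- ovh[ovh$label %in% c("shared_strict", "shared_relaxed_only"), ]
      if (nrow(sh) >= 3 && stats::var(sh$ko_lfc, na.rm = TRUE) > 0) {
        # ko_lfc column holds the first (HOM) model here
        fits[[paste0("dosage_splicing_", arm)]] <-
          fit_dosage(het_lfc = sh$nls_lfc, hom_lfc = sh$ko_lfc)
      }
    }
  }
  if (length(fits)) {
    fit_tab <- do.call(rbind, lapply(names(fits), function(nm) {
      data.frame(fit = nm, slope = fits[[nm]]$slope,
                 intercept = fits[[nm]]$intercept,
                 slope_origin = fits[[nm]]$slope_origin,
                 r_squared = fits[[nm]]$r_squared, f_p = fits[[nm]]$f_p,
                 n = fits[[nm]]$n, stringsAsFactors = FALSE)
    }))
    f <- file.path(rs_dir, "regression_fits.tsv"); write_results(fit_tab, f)
    ov_files <- c(ov_files, f)
  }
  de_set <- shared_de$feature_id
  universe <- ov_de$feature_id
  inter <- list()
  for (ty in c("complex", "retained_intron")) {
    genes_ty <- unique(ds$KO_HOM$gene_id[ds$KO_HOM$type == ty])
    genes_ty <- intersect(genes_ty, universe)
    if (length(genes_ty) > 0 && length(de_set) > 0) {
      it <- intersect_sets(genes_ty, de_set, universe)
      inter[[ty]] <- data.frame(event_type = ty, overlap = it$overlap,
                                n_events_genes = it$n_a, n_de = it$n_b,
                                n_universe = it$n_universe,
                                odds_ratio = it$odds_ratio, p = it$p,
                                stringsAsFactors = FALSE)
    }
  }
  if (length(inter)) {
    f <- file.path(rs_dir, "de_ds_intersection.tsv")
    write_results(do.call(rbind, inter), f)
    ov_files <- c(ov_files, f)
  }
  conc_tab <- data.frame(
    set = c("expression", "splicing"),
    n_concordant = c(conc_de$n_concordant, conc_ds$n_concordant),
    n_discordant = c(conc_de$n_discordant, conc_ds$n_discordant),
    stringsAsFactors = FALSE)
  f <- file.path(rs_dir, "concordance.tsv"); write_results(conc_tab, f)
  ov_files <- c(ov_files, f)
  count_labels <- function(set, labels) {
    tb <- table(labels)
    data.frame(set = set, label = names(tb), n = as.integer(tb),
               stringsAsFactors = FALSE)
  }
  label_counts <- rbind(count_labels("expression", ov_de$label),
                        count_labels("splicing", ov_ds$label))
  f <- file.path(rs_dir, "label_counts.tsv"); write_results(label_counts, f)
  ov_files <- c(ov_files, f)
  mark("overlap", ov_files)
  # -- enrich -----------------------------------------------------------------
  en_files <- character()
  clusters <- trk$clusters[trk$clusters$score >= config$min_cluster_reads, ,
                           drop = FALSE]
  ev_meta <- ev_merged$events
  ev_regions <- ev_meta[, c("chrom", "start", "end", "strand")]
  ev_len <- stats::setNames(ev_meta$end - ev_meta$start, ev_meta$event_id)
  wt_ids <- merged$sheet$sample_id[merged$sheet$genotype == "WT"]
  tot <- ev_merged$inclusion + ev_merged$exclusion
  ev_expr <- stats::setNames(
    rowMeans(tot[, wt_ids, drop = FALSE]), ev_meta$event_id)
  sig_events <- ov_ds$feature_id[ov_ds$label %in%
                                   c("shared_strict", "shared_relaxed_only")]
  type_map <- stats::setNames(ds$KO_HOM$type, ds$KO_HOM$event_id)
  en_rows <- list()
  cons_rows <- list()
  null_ev <- tryCatch(
    match_null(sig_events, ds$KO_HOM, ds$NLS_HOM, ev_len, ev_expr),
    error = function(e) character())
  for (ty in unique(type_map[sig_events])) {
    t_ids <- sig_events[type_map[sig_events] == ty]
    n_ids <- null_ev[type_map[null_ev] == ty]
    if (length(t_ids) < 2 || length(n_ids) < 2) next
    t_r <- ev_regions[match(t_ids, ev_meta$event_id), , drop = FALSE]
    n_r <- ev_regions[match(n_ids, ev_meta$event_id), , drop = FALSE]
    en_rows[[ty]] <- overlap_test(t_r, n_r, clusters, test_name = ty)
    cons_rows[[ty]] <- tryCatch(
      conservation_test(t_r, n_r, trk$conservation,
                        threshold = config$conservation_threshold,
                        test_name = ty),
      error = function(e) NULL)
  }
  if (length(en_rows)) {
    en <- do.call(rbind, en_rows)
    en$p_bonferroni <- pmin(1, en$p * nrow(en))
    f <- file.path(rs_dir, "clip_enrichment.tsv"); write_results(en, f)
    en_files <- c(en_files, f)
  }
  cons_rows <- Filter(Negate(is.null), cons_rows)
  if (length(cons_rows)) {
    cn <- do.call(rbind, cons_rows)
    cn$p_bonferroni <- pmin(1, cn$p * nrow(cn))
    f <- file.path(rs_dir, "conservation_enrichment.tsv")
    write_results(cn, f)
    en_files <- c(en_files, f)
  }
  if (length(sig_events)) {
    t_r <- ev_regions[match(sig_events, ev_meta$event_id), , drop = FALSE]
    prox <- data.frame(event_id = sig_events,
                       flag = proximity_flag(t_r, clusters,
                                             config$proximity_distance),
                       stringsAsFactors = FALSE)
    f <- file.path(rs_dir, "proximity_flags.tsv"); write_results(prox, f)
    en_files <- c(en_files, f)
  }
  # gene-level binding profile
  part <- build_partition(ann$models, contig_lengths = ann$contig_lengths)
  up <- shared_de$feature_id[shared_de$ko_lfc > 0]
  down <- shared_de$feature_id[shared_de$ko_lfc < 0]
  gene_len <- tapply(part$end[part$feature == "intron"] -
                       part$start[part$feature == "intron"],
                     part$gene_id[part$feature == "intron"], sum)
  sf_m <- size_factors(merged$counts)
  gene_expr <- rowMeans(sweep(merged$counts[, wt_ids, drop = FALSE], 2,
                              sf_m[wt_ids], "/"))
  null_genes <- tryCatch(
    match_null(shared_de$feature_id, de$KO_HOM, de$NLS_HOM,
               gene_len[rownames(merged$counts)], gene_expr),
    error = function(e) character())
  if (length(up) && length(down) && length(null_genes)) {
    prof <- feature_profile(up, down, null_genes, part, clusters)
    f <- file.path(rs_dir, "binding_profile.tsv"); write_results(prof, f)
    en_files <- c(en_files, f)
  }
  mark("enrich", en_files)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable run summary
#'
#' Summarises a completed run: overlap label counts, regression slopes,
#' discordant counts and the enrichment tables.
#'
#' @param out_dir the run directory written by [run_all()].
#' @return character vector of report lines (also printed).
#' @export
report <- function(out_dir) {
  rs <- file.path(out_dir, "results")
  lines <- c("jointlof run summary", "====================")
  grab <- function(f) {
    p <- file.path(rs, f)
    if (file.exists(p)) read_results(p) else NULL
  }
  lc <- grab("label_counts.tsv")
  if (!is.null(lc)) {
    lines <- c(lines, "", "Overlap label counts:",
               utils::capture.output(print(lc, row.names = FALSE)))
  }
  cc <- grab("concordance.tsv")
  if (!is.null(cc)) {
    lines <- c(lines, "", "Direction concordance:",
               utils::capture.output(print(cc, row.names = FALSE)))
  }
  ft <- grab("regression_fits.tsv")
  if (!is.null(ft)) {
    lines <- c(lines, "", "Attenuation / dosage regressions:",
               utils::capture.output(print(ft, row.names = FALSE)))
  } else {
    lines <- c(lines, "", "Regressions skipped (no shared features).")
  }
  for (f in c("clip_enrichment.tsv", "conservation_enrichment.tsv",
              "de_ds_intersection.tsv")) {
    tb <- grab(f)
    if (!is.null(tb)) {
      lines <- c(lines, "", paste0(sub(".tsv", "", f), ":"),
                 utils::capture.output(print(tb, row.names = FALSE)))
    }
  }
  if (!file.exists(file.path(out_dir, "manifest.json"))) {
    lines <- c(lines, "", "WARNING: manifest missing; run may be incomplete.")
  }
  lines
}
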