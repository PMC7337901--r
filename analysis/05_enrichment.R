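# Stage 5: cluster-overlap and conservation enrichment of the shared
# splicing events against a length- and expression-matched null, plus
# proximity flags.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

res <- function(f) read_results(file.path(results_dir, f))
ds_ko <- res("splice_joint_KO_HOM.tsv")
ds_nls <- res("splice_joint_NLS_HOM.tsv")
ov_ds <- res("overlap_splice.tsv")

clusters <- read_bed(file.path(fixture_dir, "clusters.bed"), min_score = 2)
scores <- read_bedgraph(file.path(fixture_dir, "conservation.bedgraph"))
tab <- merge_fixture_events()
merged <- merge_fixture_counts()

meta <- tab$events
regions <- meta[, c("chrom", "start", "end", "strand")]
lens <- stats::setNames(meta$end - meta$start, meta$event_id)
wt <- merged$sheet$sample_id[merged$sheet$genotype == "WT"]
tot <- tab$inclusion + tab$exclusion
expr <- stats::setNames(rowMeans(tot[, wt, drop = FALSE]), meta$event_id)

sig <- ov_ds$feature_id[ov_ds$label %in%
                          c("shared_strict", "shared_relaxed_only")]
type_map <- stats::setNames(ds_ko$type, ds_ko$event_id)
null_ids <- match_null(sig, ds_ko, ds_nls, lens, expr)

en <- cons <- list()
for (ty in unique(type_map[sig])) {
  t_ids <- sig[type_map[sig] == ty]
  n_ids <- null_ids[type_map[null_ids] == ty]
  if (length(t_ids) < 2 || length(n_ids) < 2) next
  t_r <- regions[match(t_ids, meta$event_id), ]
  n_r <- regions[match(n_ids, meta$event_id), ]
  en[[ty]] <- overlap_test(t_r, n_r, clusters, test_name = ty)
  cons[[ty]] <- conservation_test(t_r, n_r, scores, test_name = ty)
}
bonf <- function(rows) {
  tb <- do.call(rbind, rows)
  tb$p_bonferroni <- pmin(1, tb$p * nrow(tb))
  tb
}
if (length(en)) {
  write_results(bonf(en), file.path(results_dir, "clip_enrichment.tsv"))
}
if (length(cons)) {
  write_results(bonf(cons),
                file.path(results_dir, "conservation_enrichment.tsv"))
}
if (length(sig)) {
  t_r <- regions[match(sig, meta$event_id), ]
  write_results(data.frame(event_id = sig,
                           flag = proximity_flag(t_r, clusters)),
                file.path(results_dir, "proximity_flags.tsv"))
}
if (length(en)) print(bonf(en), row.names = FALSE)

# record the script-driven run so report() sees a completed provenance trail
jsonlite::write_json(
  list(driver = "analysis scripts", seed = seed,
       results = list.files(results_dir)),
  file.path(run_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
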