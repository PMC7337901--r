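# Stage 3: joint beta-binomial differential splicing usage per arm and
# genotype from the fixture event tables.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

merged <- merge_fixture_counts()
tab <- merge_fixture_events()
genotypes <- if (study$include_het) c("HOM", "HET") else "HOM"
for (arm in c("KO", "NLS")) {
  keep <- merged$sheet$arm == arm
  sheet <- merged$sheet[keep, , drop = FALSE]
  tab_arm <- splice_event_table(
    tab$events,
    tab$inclusion[, sheet$sample_id, drop = FALSE],
    tab$exclusion[, sheet$sample_id, drop = FALSE])
  for (gt in genotypes) {
    res <- fit_usage(tab_arm, sheet, joint = TRUE, genotype = gt)
    out <- file.path(results_dir, sprintf("splice_joint_%s_%s.tsv", arm, gt))
    write_results(res, out)
    cat(sprintf("%s: %d events, %d at FDR < %.2f\n", basename(out),
                nrow(res), sum(res$fdr < alpha, na.rm = TRUE), alpha))
  }
}
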