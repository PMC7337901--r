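# Stage 2: joint negative-binomial differential expression per arm and
# genotype, reading the fixture counts back through the I/O layer.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

merged <- merge_fixture_counts()
genotypes <- if (study$include_het) c("HOM", "HET") else "HOM"
for (arm in c("KO", "NLS")) {
  keep <- merged$sheet$arm == arm
  counts <- merged$counts[, merged$sheet$sample_id[keep], drop = FALSE]
  sheet <- merged$sheet[keep, , drop = FALSE]
  for (gt in genotypes) {
    res <- fit_de(counts, sheet, joint = TRUE, genotype = gt)
    out <- file.path(results_dir, sprintf("de_joint_%s_%s.tsv", arm, gt))
    write_results(res, out)
    cat(sprintf("%s: %d genes, %d at FDR < %.2f\n", basename(out), nrow(res),
                sum(res$fdr < alpha, na.rm = TRUE), alpha))
  }
}
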