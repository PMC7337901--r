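# Stage 4: strict/relaxed overlap classification between the KO and NLS
# joint models, direction concordance, attenuation and dosage regressions,
# and the event-type x DE Fisher intersections.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

res <- function(f) read_results(file.path(results_dir, f))
de_ko <- res("de_joint_KO_HOM.tsv"); de_nls <- res("de_joint_NLS_HOM.tsv")
ds_ko <- res("splice_joint_KO_HOM.tsv")
ds_nls <- res("splice_joint_NLS_HOM.tsv")

ov_de <- classify_overlap(de_ko, de_nls, alpha = alpha)
ov_ds <- classify_overlap(ds_ko, ds_nls, alpha = alpha)
write_results(ov_de, file.path(results_dir, "overlap_de.tsv"))
write_results(ov_ds, file.path(results_dir, "overlap_splice.tsv"))

shared <- function(ov) {
  ov[ov$label %in% c("shared_strict", "shared_relaxed_only"), ]
}
sh_de <- shared(ov_de); sh_ds <- shared(ov_ds)

fits <- list()
if (nrow(sh_de) >= 3) {
  fits$attenuation_expression <- fit_attenuation(sh_de$ko_lfc, sh_de$nls_lfc)
}
if (nrow(sh_ds) >= 3) {
  fits$attenuation_splicing <- fit_attenuation(sh_ds$ko_lfc, sh_ds$nls_lfc)
}
if (study$include_het) {
  for (arm in c("KO", "NLS")) {
    hom <- res(sprintf("splice_joint_%s_HOM.tsv", arm))
    het <- res(sprintf("splice_joint_%s_HET.tsv", arm))
    sh <- shared(classify_overlap(hom, het, alpha = alpha))
    if (nrow(sh) >= 3) {
      fits[[paste0("dosage_splicing_", arm)]] <-
        fit_dosage(het_lfc = sh$nls_lfc, hom_lfc = sh$ko_lfc)
    }
  }
}
fit_tab <- do.call(rbind, lapply(names(fits), function(nm) {
  data.frame(fit = nm, slope = fits[[nm]]$slope,
             intercept = fits[[nm]]$intercept,
             r_squared = fits[[nm]]$r_squared, n = fits[[nm]]$n)
}))
write_results(fit_tab, file.path(results_dir, "regression_fits.tsv"))

cc_de <- direction_concordance(ov_de)
cc_ds <- direction_concordance(ov_ds)
write_results(data.frame(
  set = c("expression", "splicing"),
  n_concordant = c(cc_de$n_concordant, cc_ds$n_concordant),
  n_discordant = c(cc_de$n_discordant, cc_ds$n_discordant)),
  file.path(results_dir, "concordance.tsv"))

count_labels <- function(set, labels) {
  tb <- table(labels)
  data.frame(set = set, label = names(tb), n = as.integer(tb))
}
write_results(rbind(count_labels("expression", ov_de$label),
                    count_labels("splicing", ov_ds$label)),
              file.path(results_dir, "label_counts.tsv"))

universe <- ov_de$feature_id
inter <- list()
for (ty in c("complex", "retained_intron")) {
  genes_ty <- intersect(unique(ds_ko$gene_id[ds_ko$type == ty]), universe)
  if (length(genes_ty) && nrow(sh_de)) {
    it <- intersect_sets(genes_ty, sh_de$feature_id, universe)
    inter[[ty]] <- data.frame(event_type = ty, overlap = it$overlap,
                              odds_ratio = it$odds_ratio, p = it$p)
  }
}
if (length(inter)) {
  write_results(do.call(rbind, inter),
                file.path(results_dir, "de_ds_intersection.tsv"))
}
print(fit_tab, row.names = FALSE)
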