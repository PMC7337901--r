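# Small shared study simulated once per test run: 3 datasets, both arms,
# moderate gene/event counts so recovery checks are meaningful but fast.
shared_sim <- local({
  cfg <- sim_config(n_genes = 300, n_events = 200, seed = 101)
  cnt <- simulate_counts(cfg)
  ann <- simulate_annotation(cfg)
  ev <- simulate_events(cfg, cnt$truth, cnt$datasets, ann)
  merged <- jointlof:::merge_datasets(cnt$datasets)
  list(cfg = cfg, cnt = cnt, ann = ann, ev = ev, merged = merged)
})

arm_subset <- function(merged, arm) {
  keep <- merged$sheet$arm == arm
  list(counts = merged$counts[, merged$sheet$sample_id[keep], drop = FALSE],
       sheet = merged$sheet[keep, , drop = FALSE])
}

arm_events <- function(sim, arm) {
  m <- jointlof:::merge_event_tables(sim$ev$events)
  keep <- sim$merged$sheet$arm == arm
  sheet <- sim$merged$sheet[keep, , drop = FALSE]
  list(tab = splice_event_table(m$events,
                                m$inclusion[, sheet$sample_id, drop = FALSE],
                                m$exclusion[, sheet$sample_id, drop = FALSE]),
       sheet = sheet)
}
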