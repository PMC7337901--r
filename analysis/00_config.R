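# Shared configuration for the numbered analysis scripts. Each script can be
# run on its own (earlier outputs must exist) or in sequence:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_differential_expression.R
#   ...
# Override the run directory with JOINTLOF_RUN_DIR and the seed with
# JOINTLOF_SEED.

suppressMessages(library(jointlof))

run_dir <- Sys.getenv("JOINTLOF_RUN_DIR", "results/run")
fixture_dir <- file.path(run_dir, "fixtures")
results_dir <- file.path(run_dir, "results")
seed <- as.integer(Sys.getenv("JOINTLOF_SEED", "1"))
alpha <- 0.05

# the generator defaults are the study conditions; only the size is set here
# so a laptop run finishes in about a minute
study <- sim_config(n_genes = 600, n_events = 400, seed = seed)

datasets <- paste0("ds", seq_len(study$n_datasets))

read_fixture_counts <- function(ds) {
  read_counts(file.path(fixture_dir, sprintf("counts_%s.tsv", ds)),
              file.path(fixture_dir, sprintf("samples_%s.tsv", ds)))
}

read_fixture_events <- function(ds) {
  read_events(file.path(fixture_dir, sprintf("events_%s.tsv", ds)))
}

merge_fixture_counts <- function() {
  parts <- lapply(datasets, read_fixture_counts)
  list(counts = do.call(cbind, lapply(parts, `[[`, "counts")),
       sheet = do.call(rbind, c(lapply(parts, `[[`, "sheet"),
                                make.row.names = FALSE)))
}

merge_fixture_events <- function() {
  tabs <- lapply(datasets, read_fixture_events)
  splice_event_table(tabs[[1]]$events,
                     do.call(cbind, lapply(tabs, `[[`, "inclusion")),
                     do.call(cbind, lapply(tabs, `[[`, "exclusion")))
}

dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
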