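# Stage 6: print a human-readable summary of the run.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

writeLines(report(run_dir))
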