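# Stage 1: simulate the synthetic multi-dataset study and write the fixture
# bundle (counts, sample sheets, splicing event tables, GTF annotation,
# iCLIP-style clusters, conservation track, ground truth).

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

manifest <- write_fixture_bundle(study, fixture_dir, force = TRUE)
cat("wrote", length(manifest$files), "fixture files to", fixture_dir, "\n")
for (f in names(manifest$files)) cat("  ", f, "\n")
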