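#!/usr/bin/env Rscript
# Generate the synthetic two-condition 4C experiment used throughout the
# analysis: a 20 Mb chromosome, one viewpoint at 2 Mb, three planted
# fold-4 interaction peaks plus one inside the deleted interval, and a
# 1.5 Mb hemizygous deletion (8.0-9.5 Mb) in the case condition.
# Emits fragment map, truth intervals, per-replicate count tracks and a
# reproducibility manifest under results/.

library(fourcbricks)

out <- "results/dataset"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  deletion = c(8e6, 9.5e6),
  peaks = data.frame(start = c(2.9e6, 4.0e6, 1.40e7, 8.5e6),
                     end   = c(2.98e6, 4.08e6, 1.408e7, 8.58e6),
                     fold  = 4),
  seed = 20260928
)
ex <- simulate_experiment(cfg)

write_manifest(cfg, file.path(out, "manifest.yaml"))
write_fragment_map(ex$fmap, file.path(out, "fragments.bed"))
write_bed(data.frame(chrom = ex$fmap$chrom, start = cfg$peaks$start,
                     end = cfg$peaks$end,
                     name = paste0("peak_fold", cfg$peaks$fold)),
          file.path(out, "truth_peaks.bed"))
write_bed(data.frame(chrom = ex$fmap$chrom, start = cfg$deletion[1],
                     end = cfg$deletion[2], name = "deletion"),
          file.path(out, "truth_deletion.bed"))
for (cond in c("control", "case")) {
  for (tr in ex[[cond]])
    write_count_table(tr, file.path(out, sprintf("counts_%s_%s.bedgraph",
                                                 cond, tr$replicate)))
}

message(sprintf("simulated %d fragments over %s bp; libraries: %s",
                n_fragments(ex$fmap),
                format(chrom_size(ex$fmap), big.mark = ",", scientific = FALSE),
                paste(sapply(c(ex$control, ex$case), `[[`, "library_size"),
                      collapse = ", ")))
message("wrote ", out)
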