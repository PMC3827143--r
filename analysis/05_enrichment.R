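#!/usr/bin/env Rscript
# Feature enrichment of the control interacting regions: simulate a gene set
# partially concentrated in the planted peaks, test overlap enrichment by
# region shuffling (10,000 permutations), and report gene density and the
# coverage/overlap matrix between the two conditions' Brick sets.

library(fourcbricks)

ds <- "results/dataset"
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifest <- yaml::read_yaml(file.path(ds, "manifest.yaml"))
fm_bed <- read_bed(file.path(ds, "fragments.bed"))
fmap <- fragment_map(fm_bed$chrom[1], fm_bed$start, fm_bed$end)
L <- chrom_size(fmap)
regions <- read_bed("results/bricks/control_regions.bed")
truth <- list(peaks = data.frame(start = manifest$peaks$start,
                                 end = manifest$peaks$end,
                                 fold = manifest$peaks$fold))

# genes enriched in planted peaks (enrich_prob 0.3) vs an independent set
genes_enr <- simulate_features(fmap, truth, n_genes = 120, enrich_prob = 0.3,
                               feature_length = 2e4, seed = 11)
genes_null <- simulate_features(fmap, truth, n_genes = 120, enrich_prob = 0,
                                feature_length = 2e4, seed = 12)
write_bed(genes_enr, file.path(out, "genes_enriched.bed"))

for (nm in c("enriched", "independent")) {
  genes <- if (nm == "enriched") genes_enr else genes_null
  res <- permutation_enrichment(regions, genes, L, N = 10000,
                                mode = "region_hits", seed = 13)
  message(sprintf("%s gene set: observed %d region hits, p = %.4g (N = %d)",
                  nm, res$observed, res$p_empirical, res$N))
  write.table(
    data.frame(set = nm, observed = res$observed, p = res$p_empirical,
               N = res$N, mode = res$mode, seed = 13),
    file.path(out, paste0("enrichment_", nm, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

dens <- gene_density(regions, genes_enr)
message(sprintf("gene density over interacting regions: %.4g genes/kb", dens))

case_regions <- read_bed("results/bricks/case_regions.bed")
cm <- coverage_matrix(list(control = regions, case = case_regions), L)
write.table(round(cm, 3), file.path(out, "coverage_matrix.tsv"),
            sep = "\t", quote = FALSE)
message("coverage (%): ", paste(capture.output(print(round(cm, 2)))[-1],
                                collapse = " | "))
message("wrote ", out)
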