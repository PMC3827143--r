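#!/usr/bin/env Rscript
# Differential interactions between case (deletion) and control: log2 ratio
# of the smoothed profile-corrected signals, signed ratio-Brick calling with
# the cross-set/gap/anchoring filters, read-count validation of the selected
# regions by rank-sum test, and the median interaction change inside the
# deleted interval with a bootstrap confidence interval.

library(fourcbricks)

ds <- "results/dataset"
out <- "results/differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifest <- yaml::read_yaml(file.path(ds, "manifest.yaml"))
fm_bed <- read_bed(file.path(ds, "fragments.bed"))
fmap <- fragment_map(fm_bed$chrom[1], fm_bed$start, fm_bed$end)
vp <- viewpoint_spec(manifest$viewpoint_name, fmap$chrom,
                     manifest$viewpoint_pos, manifest$exclusion_k)
srw <- short_range_window(fmap$chrom, max(0, vp$position - 2.5e6),
                          vp$position + 2.5e6)
fit_range <- c(1e3, 1e5)
deletion <- as.numeric(manifest$deletion)

read_cond <- function(cond) {
  paths <- Sys.glob(file.path(ds, sprintf("counts_%s_rep*.bedgraph", cond)))
  lapply(paths, function(p) read_count_table(p, vp, fmap = fmap, condition = cond))
}
ctrl_tracks <- read_cond("control")
case_tracks <- read_cond("case")

# per-condition Bricks (unsmoothed calling branch) anchor the ratio Bricks
cb_ctrl <- call_viewpoint_bricks(
  viewpoint_profile(ctrl_tracks, w = 1, fit_range = fit_range)$corrected,
  srw = srw)
cb_case <- call_viewpoint_bricks(
  viewpoint_profile(case_tracks, w = 1, fit_range = fit_range)$corrected,
  srw = srw)

# ratio branch on the 19-fragment smoothed corrected signals
rt <- log2_ratio(
  viewpoint_profile(case_tracks, w = 19, fit_range = fit_range)$corrected,
  viewpoint_profile(ctrl_tracks, w = 19, fit_range = fit_range)$corrected)
write_bedgraph(rt, file.path(out, "log2_ratio.bedgraph"))

nogaps <- data.frame(start = numeric(0), end = numeric(0))  # no assembly gaps
rb <- ratio_bricks(rt, cb_ctrl$bricks, cb_case$bricks, gaps = nogaps, srw = srw)
write_bricks_bed(rb$positive, file.path(out, "ratio_bricks_positive.bed"))
write_bricks_bed(rb$negative, file.path(out, "ratio_bricks_negative.bed"))
message(sprintf("ratio Bricks: %d positive, %d negative (candidates %d/%d)",
                nrow(rb$positive), nrow(rb$negative),
                rb$provenance$candidates["positive"],
                rb$provenance$candidates["negative"]))

regions <- rbind(rb$positive[, c("start", "end")], rb$negative[, c("start", "end")])
rct <- region_count_test(ctrl_tracks[[1]], case_tracks[[1]], regions,
                         rbind(cb_ctrl$bricks, cb_case$bricks))
ics <- interval_change_summary(rt, deletion, n_boot = 1000, seed = 1)
message(sprintf("deletion interval: median log2 ratio %.3f [%.3f, %.3f] over %d fragments",
                ics$median, ics$ci_low, ics$ci_high, ics$n_fragments))
message(sprintf("region read-count validation: W = %s, p = %.3g (%d regions vs %d Bricks)",
                format(rct$statistic), rct$p_value, rct$n_regions,
                rct$n_outside_bricks))
res <- data.frame(
  metric = c("deletion_median_log2", "deletion_ci_low", "deletion_ci_high",
             "region_test_p", "n_positive", "n_negative"),
  value = c(ics$median, ics$ci_low, ics$ci_high, rct$p_value,
            nrow(rb$positive), nrow(rb$negative)))
write.table(res, file.path(out, "summary.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote ", out)
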