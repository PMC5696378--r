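#!/usr/bin/env Rscript
# Downstream contact analytics on the processed synthetic library.
#
# Peak calling on tag depth, PET-peak enrichment, fold-change grouping
# against a depth-matched control, PET clustering into loops with
# ground-truth comparison, CTCF-motif orientation, a contact matrix with
# depth normalisation, and a virtual-4C profile from a loop-anchor
# viewpoint. Writes tables under results/.

suppressMessages(library(bridgepet))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1)
lib <- simulate_library(cfg)
res <- process_library(lib$reads$reads1, lib$reads$reads2, lib$genome,
                       linkers = linker_set(cfg$linker_mode))
pets <- res$pets
sizes <- attr(lib$genome, "chrom_sizes")
truth <- lib$truth

# --- peaks and enrichment ---------------------------------------------------
tags <- data.frame(chrom = c(pets$chrom1, pets$chrom2),
                   pos = c(pets$pos1, pets$pos2))
peaks <- call_peaks_simple(tags, sizes, extension = 500, threshold = 5)
cat(sprintf("called %d peaks from %d tags\n", nrow(peaks), nrow(tags)))

site_regions <- data.frame(chrom = truth$sites$chrom,
                           start = truth$sites$start - 500,
                           end = truth$sites$end + 500)
frac <- pet_overlap_fraction(pets, site_regions)
cat(sprintf("%.1f%% of PET tags fall within 500 bp of a planted site\n",
            100 * frac))

# depth-matched control: noise-only library at the same depth
cfg_ctrl <- sim_config(pairs_signal = 0, pairs_noise = 50000, n_loops = 0,
                       n_sites = cfg$n_sites, seed = 99)
lib_ctrl <- simulate_library(cfg_ctrl)
res_ctrl <- process_library(lib_ctrl$reads$reads1, lib_ctrl$reads$reads2,
                            lib_ctrl$genome,
                            linkers = linker_set(cfg_ctrl$linker_mode))
classes <- split(site_regions, truth$sites$class)
enr <- tf_enrichment_table(pets, res_ctrl$pets, classes)
write.table(enr, "results/enrichment_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(enr, row.names = FALSE)

# fold-change grouping of peaks between the two libraries
count_tags <- function(p, pk) {
  gr_t <- GenomicRanges::GRanges(
    c(p$chrom1, p$chrom2),
    IRanges::IRanges(c(p$pos1, p$pos2) + 1L, width = 1L))
  gr_p <- GenomicRanges::GRanges(
    pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
  GenomicRanges::countOverlaps(gr_p, gr_t)
}
grp <- group_peaks_by_fc(count_tags(pets, peaks),
                         count_tags(res_ctrl$pets, peaks),
                         total_A = 2 * nrow(pets),
                         total_B = 2 * nrow(res_ctrl$pets))
cat("peak fold-change groups vs noise control:\n")
print(table(grp$group))
write.table(cbind(peaks, grp[, c("log2_fc", "group")]),
            "results/peak_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# --- loops, motif orientation ----------------------------------------------
loops <- cluster_pets(pets, anchor_extension = 2500, min_count = 5)
truth_loops <- truth_loop_table(truth, half_width = cfg$site_width)
cl <- classify_loops(loops, truth_loops, slack = 2500)
cat(sprintf("%d loops called; %.0f%% common with truth; %d truth loops missed\n",
            nrow(loops), 100 * mean(cl$label_A == "common"),
            sum(cl$label_B != "common")))
write.table(cbind(loops, label = cl$label_A), "results/loops.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

motifs <- data.frame(chrom = truth$sites$chrom, start = truth$sites$start,
                     end = truth$sites$end, strand = truth$sites$strand)
mo <- motif_orientation(loops, motifs)
cat(sprintf("motif orientation over %d loops: convergent %.2f, divergent %.2f, identical %.2f\n",
            mo$n_classified, mo$proportions["convergent"],
            mo$proportions["divergent"], mo$proportions["identical"]))
jsonlite::write_json(mo, "results/motif_orientation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

# --- contact matrix and virtual 4C -----------------------------------------
m <- bin_contacts(pets, resolution = 1e4, chrom = "chr1",
                  chrom_size = sizes[["chr1"]])
mn <- normalize_per_million(m, total_pets = nrow(pets))
dense <- as.matrix(mn$counts)
write.table(dense, "results/contact_matrix_chr1_10kb.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat(sprintf("chr1 contact matrix at 10 kb: %d bins, %.0f counts per million total\n",
            nrow(dense), sum(dense)))

vp_anchor <- truth$loops[1, ]
vp <- list(chrom = vp_anchor$chrom, start = vp_anchor$anchor1_pos - 2500,
           end = vp_anchor$anchor1_pos + 2500)
v4c <- visual_4c(pets, vp, merge_gap = 5000, min_count = 5)
cat(sprintf("virtual 4C from loop-1 anchor: %d PETs selected, %d clusters\n",
            v4c$n_selected, nrow(v4c$clusters)))
write.table(v4c$clusters, "results/visual4c_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
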