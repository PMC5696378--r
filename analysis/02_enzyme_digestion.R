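#!/usr/bin/env Rscript
# In-silico digestion: spacing laws and enzyme targeting of binding sites.
#
# Digests a 10 Mb uniform random genome with HaeIII, MboI and HindIII to
# check the 4^k spacing law, then contrasts proximity profiles around
# planted binding sites for a genome whose cut sites are enriched near
# sites (site_cut_bias > 1) versus an unbiased genome. Writes
# results/digestion_spacing.tsv and results/proximity_profiles.tsv.

suppressMessages(library(bridgepet))
dir.create("results", showWarnings = FALSE)

g10 <- make_genome(sim_config(genome_length = 1e7, n_chroms = 1, seed = 42))
spacing <- do.call(rbind, lapply(builtin_enzymes(), function(enz) {
  s <- digest_genome(g10, enz)$summary
  data.frame(enzyme = enz$name, recognition = enz$recognition,
             n_sites = s$n_sites, mean_spacing = s$mean_spacing,
             mean_fragment = s$mean_length, median_fragment = s$median_length)
}))
write.table(spacing, "results/digestion_spacing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(spacing, row.names = FALSE)
cat("4-cutters land every ~256 bp on uniform sequence, the 6-cutter every\n")
cat("~4096 bp; a frequent cutter yields fragments short enough to resolve\n")
cat("individual protein-binding regions.\n\n")
rm(g10)

profile_for <- function(bias) {
  cfg <- sim_config(genome_length = 3e5, n_chroms = 1, n_sites = 50,
                    n_loops = 5, loop_dist_range = c(5000, 50000),
                    site_cut_bias = bias, seed = 31)
  truth <- plant_sites_and_loops(cfg)
  g <- make_genome(cfg, truth)
  dig <- digest_genome(g, cfg$enzyme)
  signal <- data.frame(chrom = dig$cut_sites$chrom,
                       start = dig$cut_sites$pos,
                       end = dig$cut_sites$pos + 1, depth = 1)
  prof <- proximity_profile(signal, truth$sites[, c("chrom", "start", "end")],
                            window = 2000, bin_size = 200, total_reads = 1e6)
  cbind(site_cut_bias = bias, prof)
}
profiles <- rbind(profile_for(5), profile_for(1))
write.table(profiles, "results/proximity_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (b in c(5, 1)) {
  pr <- profiles[profiles$site_cut_bias == b, ]
  central <- abs(pr$bin_mid) <= 400
  cat(sprintf(
    "bias %g: central/background depth ratio %.2f\n", b,
    mean(pr$depth[central]) / mean(pr$depth[!central])))
}
cat("A cutter enriched near binding sites produces a peaked profile; an\n")
cat("unbiased cutter is flat, mirroring the enzyme-targeting contrast.\n")
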