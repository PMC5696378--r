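mk_pets <- function(chrom1, pos1, chrom2, pos2,
                    strand1 = "+", strand2 = "-") {
  data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             category = ifelse(chrom1 == chrom2, "cis", "trans"),
             stringsAsFactors = FALSE)
}

test_that("PET tag overlap fractions count tags and ends correctly", {
  pets <- mk_pets(c("chr1", "chr1"), c(100, 5000),
                  c("chr1", "chr1"), c(900, 9000))
  regions <- data.frame(chrom = "chr1", start = c(0, 800, 4900),
                        end = c(200, 1000, 5100))
  # 3 of 4 tags fall in regions
  expect_equal(pet_overlap_fraction(pets, regions), 0.75)
  # both PETs have at least one end covered
  expect_equal(pet_overlap_fraction(pets, regions, mode = "either-end"), 1)
  whole <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  expect_equal(pet_overlap_fraction(pets, whole), 1)
  expect_error(pet_overlap_fraction(pets[0, ], regions), "empty")
})

test_that("overlap counting agrees with a naive interval scan", {
  set.seed(23)
  for (i in 1:50) {
    q <- data.frame(chrom = sample(c("c1", "c2"), 30, TRUE),
                    start = sample(0:500, 30, TRUE))
    q$end <- q$start + sample(1:50, 30, TRUE)
    s <- data.frame(chrom = sample(c("c1", "c2"), 10, TRUE),
                    start = sample(0:500, 10, TRUE))
    s$end <- s$start + sample(1:80, 10, TRUE)
    got <- IRanges::overlapsAny(
      bridgepet:::as_granges(q), bridgepet:::as_granges(s))
    expect_identical(got, naive_overlaps_any(q, s))
  }
})

test_that("enrichment ratios are depth-normalisation invariant", {
  set.seed(3)
  pets <- mk_pets(rep("chr1", 200), sample(0:99000, 200),
                  rep("chr1", 200), sample(0:99000, 200) + 500)
  sites <- list(
    TF1 = data.frame(chrom = "chr1", start = seq(0, 90000, 10000),
                     end = seq(0, 90000, 10000) + 2000),
    TF2 = data.frame(chrom = "chr1", start = 50000, end = 80000))
  tab_same <- tf_enrichment_table(pets, pets, sites)
  expect_true(all(tab_same$ratio == 1))
  # doubling every PET of A leaves the normalised ratio at 1
  tab_dup <- tf_enrichment_table(rbind(pets, pets), pets, sites)
  expect_true(all(abs(tab_dup$ratio - 1) < 1e-12))
  expect_equal(tab_dup$pct_A, tab_same$pct_A)
})

test_that("fold-change grouping follows the printed thresholds", {
  # normalised ratio 4 -> log2 FC 2 -> high; equal depths -> normal;
  # ratio exactly 2 -> log2 FC 1 -> normal (closed boundary)
  g <- group_peaks_by_fc(depth_A = c(7, 5, 3, 0),
                         depth_B = c(1, 5, 1, 7),
                         total_A = 1000, total_B = 1000)
  expect_equal(g$log2_fc, log2(c(8, 6, 4, 1) / c(2, 6, 2, 8)))
  expect_equal(g$group, c("high", "normal", "normal", "low"))
  # depth doubling of one library shifts nothing after normalisation
  g2 <- group_peaks_by_fc(depth_A = 2 * c(7, 5, 3, 0) + 1,
                          depth_B = c(1, 5, 1, 7),
                          total_A = 2000, total_B = 1000)
  expect_equal(g2$group, g$group)
  expect_error(group_peaks_by_fc(-1, 1, 10, 10), "negative")
})

test_that("feature annotation applies precedence and length backgrounds", {
  features <- list(
    promoter = data.frame(chrom = "chr1", start = 0, end = 10000),
    exon = data.frame(chrom = "chr1", start = c(5000, 20000),
                      end = c(15000, 30000)))
  peaks <- data.frame(chrom = "chr1",
                      start = c(2000, 7000, 25000, 60000),
                      end = c(2100, 7100, 25100, 60100))
  ann <- annotate_peak_groups(peaks, rep("g", 4), features,
                              genome_size = 1e5)
  # promoter wins over exon in the overlap region
  expect_equal(ann$n[ann$feature == "promoter"], 2L)
  expect_equal(ann$n[ann$feature == "exon"], 1L)
  expect_equal(ann$n[ann$feature == "intergenic"], 1L)
  # promoters are 10% of the genome and hold 50% of the peaks
  prom <- ann[ann$feature == "promoter", ]
  expect_equal(prom$background, 0.1)
  expect_equal(prom$enrichment, 0.5 / 0.1)
  # uniformly placed peaks have enrichment about 1 everywhere
  set.seed(8)
  upos <- sample(0:(1e5 - 100), 4000)
  upeaks <- data.frame(chrom = "chr1", start = upos, end = upos + 100)
  uann <- annotate_peak_groups(upeaks, rep("u", 4000), features,
                               genome_size = 1e5)
  expect_true(all(abs(uann$enrichment - 1) < 0.15))
  expect_error(annotate_peak_groups(peaks, rep("g", 4), list(), 1e5),
               "non-empty")
})

test_that("contact matrices bin, normalise and difference correctly", {
  pets <- mk_pets("chr1", 1500, "chr1", 25500)
  m <- bin_contacts(pets, resolution = 1e4, chrom = "chr1",
                    chrom_size = 1e5)
  expect_equal(dim(m$counts), c(10L, 10L))
  expect_equal(m$counts[1, 3], 1)
  expect_equal(m$counts[3, 1], 1)
  expect_equal(sum(m$counts), 2)
  # normalisation and self-difference
  mn <- normalize_per_million(m, total_pets = 500)
  expect_equal(mn$counts[1, 3], 2000)
  d <- diff_matrix(mn, mn)
  expect_equal(sum(abs(d$counts)), 0)
  expect_error(diff_matrix(m, bin_contacts(pets, 1e3, "chr1", 1e5)),
               "resolution")
  # marginals: row sums equal per-bin tag counts (diagonal counted once)
  set.seed(4)
  p2 <- mk_pets(rep("chr1", 300), sample(0:99999, 300),
                rep("chr1", 300), sample(0:99999, 300))
  m2 <- bin_contacts(p2, 1e4, "chr1", 1e5)
  bins1 <- floor(p2$pos1 / 1e4) + 1
  bins2 <- floor(p2$pos2 / 1e4) + 1
  marg <- tabulate(c(bins1, bins2), nbins = 10)
  diag_pets <- bins1 == bins2
  expect_equal(as.numeric(Matrix::rowSums(m2$counts)) +
                 tabulate(bins1[diag_pets], nbins = 10),
               marg)
})

test_that("PET clustering merges mutually overlapping pairs into loops", {
  # 5 PETs with both ends within the extension: one loop of count 5
  pets <- mk_pets(rep("chr1", 5), c(10000, 10400, 10800, 9600, 10200),
                  rep("chr1", 5), c(50000, 50500, 49500, 50100, 50300))
  loops <- cluster_pets(pets, anchor_extension = 2500, min_count = 5)
  expect_equal(nrow(loops), 1L)
  expect_equal(loops$pet_count, 5L)
  expect_true(loops$start1 <= 9600 - 2500 + 1 & loops$end1 >= 10800)
  # 4 PETs fall below the count threshold
  loops4 <- cluster_pets(pets[1:4, ], anchor_extension = 2500,
                         min_count = 5)
  expect_equal(nrow(loops4), 0L)
  expect_equal(attr(loops4, "n_dropped_pets"), 4L)
  # far-apart anchor pairs stay separate
  pets_far <- rbind(pets,
                    mk_pets(rep("chr1", 5), c(200000, 200100, 200050,
                                              199900, 200020),
                            rep("chr1", 5), rep(400000, 5) + (0:4) * 100))
  loops2 <- cluster_pets(pets_far, anchor_extension = 2500, min_count = 5)
  expect_equal(nrow(loops2), 2L)
  # conservation: counted + dropped = input
  set.seed(12)
  rnd <- mk_pets(rep("chr1", 120), sample(0:5e5, 120),
                 rep("chr1", 120), sample(5e5:1e6, 120))
  cl <- cluster_pets(rnd, anchor_extension = 2000, min_count = 2)
  expect_equal(sum(cl$pet_count) + attr(cl, "n_dropped_pets"), 120L)
})

test_that("loop classification implements both-anchor overlap semantics", {
  A <- data.frame(chrom1 = "chr1", start1 = 100, end1 = 200,
                  chrom2 = "chr1", start2 = 500, end2 = 600)
  B_common <- data.frame(chrom1 = "chr1", start1 = 150, end1 = 250,
                         chrom2 = "chr1", start2 = 550, end2 = 650)
  cl <- classify_loops(A, B_common)
  expect_equal(cl$label_A, "common")
  expect_equal(cl$label_B, "common")
  # swapped anchor order in the second file still matches
  B_swapped <- data.frame(chrom1 = "chr1", start1 = 550, end1 = 650,
                          chrom2 = "chr1", start2 = 150, end2 = 250)
  expect_equal(classify_loops(A, B_swapped)$label_A, "common")
  # a single overlapping anchor is not enough
  B_half <- data.frame(chrom1 = "chr1", start1 = 150, end1 = 250,
                       chrom2 = "chr1", start2 = 5000, end2 = 6000)
  expect_equal(classify_loops(A, B_half)$label_A, "A-specific")
  expect_equal(classify_loops(A, B_half)$label_B, "B-specific")
  # slack rescues near-misses
  B_near <- data.frame(chrom1 = "chr1", start1 = 210, end1 = 300,
                       chrom2 = "chr1", start2 = 610, end2 = 700)
  expect_equal(classify_loops(A, B_near)$label_A, "A-specific")
  expect_equal(classify_loops(A, B_near, slack = 20)$label_A, "common")
  # symmetry of the common relation
  set.seed(77)
  mk_loops <- function(n) {
    s1 <- sample(0:5e4, n)
    s2 <- sample(6e4:2e5, n)
    data.frame(chrom1 = "chr1", start1 = s1, end1 = s1 + 2000,
               chrom2 = "chr1", start2 = s2, end2 = s2 + 2000)
  }
  la <- mk_loops(40)
  lb <- mk_loops(40)
  ab <- classify_loops(la, lb)
  ba <- classify_loops(lb, la)
  expect_equal(sum(ab$label_A == "common"), sum(ba$label_B == "common"))
  expect_equal(sum(ab$label_B == "common"), sum(ba$label_A == "common"))
  # reference-overlap wrapper
  expect_equal(loop_reference_overlap(A, B_common), 1)
  B_other_chrom <- data.frame(chrom1 = "chr2", start1 = 100, end1 = 200,
                              chrom2 = "chr2", start2 = 500, end2 = 600)
  expect_equal(loop_reference_overlap(A, B_other_chrom), 0)
})

test_that("motif orientation classes follow anchor strand pairs", {
  loops <- data.frame(chrom1 = rep("chr1", 4),
                      start1 = c(100, 2100, 4100, 6100),
                      end1 = c(600, 2600, 4600, 6600),
                      chrom2 = rep("chr1", 4),
                      start2 = c(50100, 52100, 54100, 56100),
                      end2 = c(50600, 52600, 54600, 56600))
  motifs <- data.frame(
    chrom = "chr1",
    start = c(300, 50300, 2300, 52300, 4300, 54300, 6300, 6400, 56300),
    end = c(320, 50320, 2320, 52320, 4320, 54320, 6320, 6420, 56320),
    strand = c("+", "-",  "-", "+",  "+", "+",  "+", "-", "-"))
  mo <- motif_orientation(loops, motifs)
  # the fourth loop has two motifs in anchor1 and is excluded
  expect_equal(mo$n_classified, 3L)
  expect_equal(unname(mo$proportions),
               c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(sum(mo$proportions), 1)
  none <- motif_orientation(loops, motifs[0, ])
  expect_equal(none$n_classified, 0L)
})

test_that("virtual 4C accumulates distal ends into counted clusters", {
  vp <- list(chrom = "chr1", start = 10000, end = 12000)
  pets <- mk_pets(rep("chr1", 10), rep(11000, 10) + 0:9,
                  rep("chr1", 10), rep(80000, 10) + 0:9)
  prof <- visual_4c(pets, vp, merge_gap = 5000, min_count = 5)
  expect_equal(nrow(prof$clusters), 1L)
  expect_equal(prof$clusters$pet_count, 10L)
  expect_equal(prof$n_selected, 10L)
  # self-interactions (both ends inside the viewpoint) are excluded
  self_pet <- mk_pets("chr1", 10500, "chr1", 11500)
  prof2 <- visual_4c(rbind(pets, self_pet), vp, merge_gap = 5000,
                     min_count = 5)
  expect_equal(prof2$n_selected, 10L)
  # counts never exceed the selected PETs; equality at permissive settings
  set.seed(41)
  rnd <- mk_pets(rep("chr1", 60), sample(10000:11999, 60, TRUE),
                 sample(c("chr1", "chr2"), 60, TRUE),
                 sample(2e5:4e5, 60, TRUE))
  prof3 <- visual_4c(rnd, vp, merge_gap = 1e6, min_count = 1)
  expect_equal(sum(prof3$clusters$pet_count), prof3$n_selected)
  prof4 <- visual_4c(rnd, vp, merge_gap = 2000, min_count = 3)
  expect_lte(sum(prof4$clusters$pet_count), prof4$n_selected)
  # no PETs at the viewpoint: empty profile
  empty <- visual_4c(pets, list(chrom = "chr2", start = 0, end = 1000),
                     merge_gap = 5000, min_count = 5)
  expect_equal(nrow(empty$clusters), 0L)
})
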