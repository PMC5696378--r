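two_step <- linker_set("two-step")
one_step <- linker_set("one-step")

test_that("bitap finds leftmost hits with bounded mismatches", {
  expect_equal(bitap_search("TTACGTTT", "ACGT", 0),
               list(position = 2L, mismatches = 0L))
  expect_equal(bitap_search("TTACCTTT", "ACGT", 1),
               list(position = 2L, mismatches = 1L))
  expect_null(bitap_search("TTACCTTT", "ACGT", 0))
  expect_null(bitap_search("AAAA", "ACGTACGT", 1))   # pattern longer than text
  # leftmost wins even when a later position has fewer mismatches
  expect_equal(bitap_search("ACGAACGT", "ACGT", 1)$position, 0L)
  expect_error(bitap_search("ACGT", strrep("A", 65), 1), "64")
})

test_that("bitap agrees with the brute-force Hamming scan", {
  set.seed(99)
  for (i in 1:1000) {
    text <- random_dna(sample(15:60, 1))
    pattern <- random_dna(sample(3:10, 1))
    k <- sample(0:2, 1)
    got <- bitap_search(text, pattern, k)
    want <- naive_hamming_search(text, pattern, k)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(c(got$position, got$mismatches), want)
    }
  }
})

test_that("linker trimming keeps the genomic prefix and flags hits", {
  genomic <- random_dna(30)
  read1 <- paste0(genomic, two_step$half_A, random_dna(10))
  read2 <- paste0(random_dna(40), two_step$half_B, random_dna(5))
  tt <- detect_and_trim(read1, read2, two_step)
  expect_identical(tt$tags1$tag, genomic)
  expect_true(tt$tags1$linker_found)
  expect_equal(tt$tags1$linker_pos, 30L)
  expect_equal(tt$tags2$linker_pos, 40L)
  expect_equal(tt$summary$both_mates_linker, 1L)
  # no linker: whole read kept, flagged not-found
  plain <- random_dna(50)
  tt2 <- detect_and_trim(plain, plain, two_step)
  expect_identical(tt2$tags1$tag, plain)
  expect_false(tt2$tags1$linker_found)
  # reverse-complement patterns are searched too
  rc_read <- paste0(random_dna(25), revcomp(two_step$half_B), random_dna(8))
  tt3 <- detect_and_trim(rc_read, plain, two_step)
  expect_true(tt3$tags1$linker_found)
  expect_equal(tt3$tags1$linker_pos, 25L)
  # one mismatch tolerated
  mut <- two_step$half_A
  substr(mut, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 8, 8))[1]
  tt4 <- detect_and_trim(paste0(genomic, mut), plain, two_step)
  expect_true(tt4$tags1$linker_found)
  expect_equal(tt4$tags1$mismatches, 1L)
  # short tags are unusable
  short <- paste0(random_dna(10), two_step$half_A, random_dna(20))
  tt5 <- detect_and_trim(short, plain, two_step)
  expect_false(tt5$tags1$usable)
  # one-step mode searches the full 20-mer
  os_read <- paste0(genomic, one_step$full, random_dna(6))
  tt6 <- detect_and_trim(os_read, plain, one_step)
  expect_equal(tt6$tags1$linker_pos, 30L)
})

test_that("read-end suffix overlaps with a linker prefix are trimmed", {
  genomic <- random_dna(60)
  read <- paste0(genomic, substr(two_step$half_A, 1, 10))
  tt <- detect_and_trim(read, read, two_step)
  expect_true(tt$tags1$linker_found)
  expect_true(tt$tags1$suffix_hit)
  expect_equal(tt$tags1$linker_pos, 60L)
  expect_identical(tt$tags1$tag, genomic)
  # 7-base overlap is below the threshold
  read7 <- paste0(genomic, substr(two_step$half_A, 1, 7))
  tt7 <- detect_and_trim(read7, read7, two_step)
  expect_false(tt7$tags1$suffix_hit)
})

test_that("trimming is idempotent", {
  set.seed(31)
  for (i in 1:20) {
    read <- paste0(random_dna(sample(20:60, 1)), two_step$half_B,
                   random_dna(10))
    t1 <- detect_and_trim(read, read, two_step)
    t2 <- detect_and_trim(t1$tags1$tag, t1$tags1$tag, two_step)
    expect_false(t2$tags1$linker_found)
    expect_identical(t2$tags1$tag, t1$tags1$tag)
  }
})

test_that("exact-match alignment reports locus, strand and multiplicity", {
  set.seed(17)
  g <- c(chrA = random_dna(20000), chrB = random_dna(20000))
  tag <- substr(g[["chrB"]], 501, 560)
  aln <- align_tags(c(tag, revcomp(tag), random_dna(40), random_dna(10)), g)
  expect_equal(aln$status, c("unique", "unique", "unmapped", "unmapped"))
  expect_equal(aln$chrom[1:2], c("chrB", "chrB"))
  expect_equal(aln$pos[1], 500)           # 5' end on +
  expect_equal(aln$pos[2], 559)           # 5' end on - is the right edge
  expect_equal(aln$strand[1:2], c("+", "-"))
  # a tag planted twice is multi-mapping
  dup <- random_dna(30)
  g2 <- c(chrA = paste0(random_dna(500), dup, random_dna(500), dup,
                        random_dna(100)))
  expect_equal(align_tags(dup, g2)$status, "multi")
})

test_that("PET formation canonicalises, deduplicates and partitions", {
  mk <- function(chrom, pos, strand,
                 status = rep("unique", length(chrom))) {
    data.frame(chrom = chrom, pos = pos, strand = strand, status = status,
               stringsAsFactors = FALSE)
  }
  # 6 cis + 1 trans pairs, no duplicates
  a1 <- mk(rep("chr1", 7), c(1e4 * (1:6), 5e4), rep("+", 7))
  a2 <- mk(c(rep("chr1", 6), "chr2"), c(1e4 * (1:6) + 5e4, 100), rep("-", 7))
  fp <- form_pets(a1, a2)
  expect_equal(fp$stats$cis_trans_ratio, 6)
  expect_equal(fp$stats$unique_pets, 7L)
  # two identical pairs: one PET, duplicate rate 1/2
  b1 <- mk(c("chr1", "chr1"), c(100, 100), c("+", "+"))
  b2 <- mk(c("chr1", "chr1"), c(9000, 9000), c("-", "-"))
  fp2 <- form_pets(b1, b2)
  expect_equal(fp2$stats$unique_pets, 1L)
  expect_equal(fp2$stats$duplicate_rate, 0.5)
  # invariance to swapping mate order
  fp_swap <- form_pets(a2, a1)
  expect_equal(fp_swap$pets, fp$pets)
  # self-ligation: close cis pair excluded
  c1 <- mk("chr1", 1000, "+")
  c2 <- mk("chr1", 1500, "-")
  fp3 <- form_pets(c1, c2, self_ligation_cutoff = 1000)
  expect_equal(fp3$stats$self_ligation, 1L)
  expect_equal(fp3$stats$unique_pets, 0L)
  # counting identity on a mixed input
  d1 <- mk(c("chr1", "chr1", "chr1", "chr1", "chr1"),
           c(100, 100, NA, 5000, 70000),
           c("+", "+", NA, "+", "+"),
           c("unique", "unique", "unmapped", "unique", "unique"))
  d2 <- mk(c("chr1", "chr1", "chr2", "chr1", "chr1"),
           c(20000, 20000, 10, NA, 70100),
           c("-", "-", "+", NA, "-"),
           c("unique", "unique", "unique", "multi", "unique"))
  fp4 <- form_pets(d1, d2, usable1 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                   usable2 = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  st <- fp4$stats
  expect_equal(st$linker_unusable + st$not_both_unique + st$self_ligation +
                 st$duplicates + st$unique_pets, st$total_read_pairs)
  expect_equal(st$unique_pets, st$cis_unique + st$trans_unique)
})

test_that("depth-threshold peak calling finds summits", {
  tags <- data.frame(chrom = rep("chr1", 10), pos = rep(5000L, 10))
  pk <- call_peaks_simple(tags, c(chr1 = 10000L), extension = 100,
                          threshold = 5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$summit, 5000L)
  expect_equal(pk$max_depth, 10)
  # threshold above max depth: nothing called
  pk0 <- call_peaks_simple(tags, c(chr1 = 10000L), extension = 100,
                           threshold = 11)
  expect_equal(nrow(pk0), 0L)
  sparse <- data.frame(chrom = "chr1", pos = seq(100L, 9000L, by = 500L))
  pk1 <- call_peaks_simple(sparse, c(chr1 = 10000L), extension = 100,
                           threshold = 2)
  expect_equal(nrow(pk1), 0L)
  expect_error(call_peaks_simple(tags, c(chr1 = 1e4), extension = 0), ">")
})

test_that("externally aligned tag tables import into the PET path", {
  tab <- data.frame(
    read_id = rep(sprintf("r%02d", 1:6), each = 2),
    mate = rep(1:2, 6),
    chrom = c("chr1", "chr1",  "chr1", "chr2",  "chr1", "chr1",
              "chr1", "chr1",  "chr3", "chr3",  "chr1", "chr1"),
    pos = c(100, 60100,  200, 300,  100, 60100,
            400, 90400,  500, 40500,  600, 600),
    strand = rep(c("+", "-"), 6),
    mapq = c(60, 60,  60, 60,  60, 60,  60, 10,  60, 60,  60, 60)
  )
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  imp <- read_tag_table(path)
  fp <- form_pets(imp$aln1, imp$aln2)
  # r1 and r3 are coordinate duplicates; r4 fails mapq; r6 is self-ligation
  expect_equal(fp$stats$unique_pets, 3L)
  expect_equal(fp$stats$duplicates, 1L)
  expect_equal(fp$stats$not_both_unique, 1L)
  expect_equal(fp$stats$self_ligation, 1L)
  expect_equal(fp$stats$cis_unique, 2L)
  expect_equal(fp$stats$trans_unique, 1L)
})
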