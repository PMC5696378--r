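#' Process a paired-end library into PETs
#'
#' The standard processing chain: linker detection and trimming
#' ([detect_and_trim()]), exact-match alignment ([align_tags()]), and PET
#' formation with duplicate removal ([form_pets()]).
#'
#' @param reads1,reads2 mate sequences.
#' @param genome named character vector of chromosome sequences.
#' @param linkers a [linker_set()].
#' @param self_ligation_cutoff cis distance excluded as self-ligation, bp.
#' @param seed_k aligner seed length.
#' @return list with `pets`, `stats`, `trim` (the [detect_and_trim()]
#'   result) and `aln1`/`aln2`.
#' @examples
#' \donttest{
#' lib <- simulate_library(sim_config(genome_length = 5e4, n_chroms = 1,
#'   n_sites = 10, n_loops = 2, pairs_signal = 200, pairs_noise = 20,
#'   trans_fraction = 0, seed = 3))
#' res <- process_library(lib$reads$reads1, lib$reads$reads2, lib$genome)
#' res$stats$unique_pets
#' }
#' @export
process_library <- function(reads1, reads2, genome,
                            linkers = linker_set(),
                            self_ligation_cutoff = 1000L, seed_k = 16L) {
  trim <- detect_and_trim(reads1, reads2, linkers)
  aln1 <- align_tags(trim$tags1$tag, genome, k = seed_k)
  aln2 <- align_tags(trim$tags2$tag, genome, k = seed_k)
  fp <- form_pets(aln1, aln2, trim$tags1$usable, trim$tags2$usable,
                  self_ligation_cutoff = self_ligation_cutoff)
  list(pets = fp$pets, stats = fp$stats, trim = trim, aln1 = aln1,
       aln2 = aln2)
}

#' Ground-truth loop anchors as a loop table
#'
#' Converts the generator's loop table into the anchor-interval layout
#' used by [classify_loops()], with anchors of half-width `half_width`
#' around the planted anchor centers.
#'
#' @param truth a `sim_truth` (or `sim_library$truth`).
#' @param half_width anchor half-width, bp.
#' @return loop data.frame `chrom1, start1, end1, chrom2, start2, end2,
#'   loop_id`.
#' @export
truth_loop_table <- function(truth, half_width = 200L) {
  tl <- truth$loops
  data.frame(
    chrom1 = tl$chrom, start1 = tl$anchor1_pos - half_width,
    end1 = tl$anchor1_pos + half_width,
    chrom2 = tl$chrom, start2 = tl$anchor2_pos - half_width,
    end2 = tl$anchor2_pos + half_width,
    loop_id = tl$loop_id, stringsAsFactors = FALSE
  )
}
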