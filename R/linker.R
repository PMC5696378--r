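#' Bridge-linker search pattern set
#'
#' In two-step proximity ligation the 20-bp bridge linker is read as two
#' 15-mer halves (one per mate, either orientation), so the search set is
#' `{A, B, revcomp(A), revcomp(B)}`. In one-step ligation the junction
#' carries the full linker, searched as `{full, revcomp(full)}`. The
#' leftmost hit across patterns wins; position ties are broken by pattern
#' order.
#'
#' @param mode `"two-step"` or `"one-step"`.
#' @param half_A,half_B half-linker sequences (two-step).
#' @param full full linker sequence (one-step).
#' @param max_mismatch maximum substitutions allowed in a hit.
#' @param min_tag_len minimum usable tag length after trimming, bp.
#' @return an object of class `linker_set` with a `patterns` element.
#' @examples
#' linker_set()$patterns
#' @export
linker_set <- function(mode = c("two-step", "one-step"),
                       half_A = "ACGCGATATCTTATC",
                       half_B = "AGTCAGATAAGATAT",
                       full = "AGCTGAGGGATCCCTCAGCT",
                       max_mismatch = 1L, min_tag_len = 15L) {
  mode <- match.arg(mode)
  patterns <- if (mode == "two-step") {
    unique(c(half_A, half_B, revcomp(half_A), revcomp(half_B)))
  } else {
    unique(c(full, revcomp(full)))
  }
  if (any(nchar(patterns) > 64)) stop("linker patterns longer than 64 bases")
  structure(list(mode = mode, half_A = half_A, half_B = half_B, full = full,
                 patterns = patterns, max_mismatch = as.integer(max_mismatch),
                 min_tag_len = as.integer(min_tag_len)),
            class = "linker_set")
}

#' Bitap fuzzy search for a single pattern
#'
#' Bit-parallel shift-and search with substitution-only (Hamming) mismatch
#' counting, reporting the leftmost occurrence with at most `max_mismatch`
#' mismatches (and the smallest mismatch count at that position).
#'
#' @param text DNA string to search.
#' @param pattern DNA pattern, at most 64 bases.
#' @param max_mismatch maximum substitutions (0-3 are typical).
#' @return `NULL` if no hit, else a list with `position` (0-based) and
#'   `mismatches`.
#' @examples
#' bitap_search("TTACGTTT", "ACGT", 0)   # position 2
#' bitap_search("TTACCTTT", "ACGT", 1)   # position 2, 1 mismatch
#' @export
bitap_search <- function(text, pattern, max_mismatch = 1L) {
  res <- .bitap_search_cpp(as.character(text), as.character(pattern),
                           as.integer(max_mismatch))
  if (res[1] < 0) return(NULL)
  list(position = res[1], mismatches = res[2])
}

#' Detect bridge linkers and trim reads to genomic tags
#'
#' For each mate the full pattern set is searched with [bitap_search()]
#' semantics; the tag is the read prefix before the leftmost hit. Reads
#' with no internal hit are additionally checked for a read-end suffix
#' overlapping a pattern prefix (at least `suffix_min` bases, at most one
#' mismatch), so junctions falling near the read end are still trimmed.
#' Mates without any hit keep the full read with `linker_found = FALSE`.
#' Tags shorter than `min_tag_len` are marked unusable.
#'
#' @param reads1,reads2 character vectors of mate-1 / mate-2 sequences.
#' @param linkers a [linker_set()].
#' @param suffix_min minimum read-end overlap with a pattern prefix.
#' @return list with `tags1` and `tags2` (data.frames `tag, linker_found,
#'   linker_pos, pattern, mismatches, usable`) and `summary` (per-pair
#'   linker counts).
#' @export
detect_and_trim <- function(reads1, reads2, linkers, suffix_min = 8L) {
  stopifnot(inherits(linkers, "linker_set"))
  trim_one <- function(reads) {
    reads <- toupper(as.character(reads))
    hit <- .linker_scan_cpp(reads, linkers$patterns, linkers$max_mismatch,
                            as.integer(suffix_min), 1L)
    pos <- hit[, 1]
    found <- pos >= 0
    tag <- ifelse(found, substr(reads, 1L, pmax(pos, 0L)), reads)
    pat_idx <- hit[, 3]
    suffix_mode <- found & pat_idx > 1000L
    pat_idx <- ifelse(pat_idx > 1000L, pat_idx - 1000L, pat_idx)
    data.frame(
      tag = tag,
      linker_found = found,
      linker_pos = ifelse(found, pos, NA_integer_),
      pattern = ifelse(found, linkers$patterns[pmax(pat_idx, 1L)],
                       NA_character_),
      suffix_hit = suffix_mode,
      mismatches = ifelse(found, hit[, 2], NA_integer_),
      usable = nchar(tag) >= linkers$min_tag_len,
      stringsAsFactors = FALSE
    )
  }
  if (length(reads1) != length(reads2)) {
    stop("mate vectors must have equal length")
  }
  t1 <- trim_one(reads1)
  t2 <- trim_one(reads2)
  list(
    tags1 = t1,
    tags2 = t2,
    summary = list(
      n_pairs = length(reads1),
      pairs_with_linker = sum(t1$linker_found | t2$linker_found),
      both_mates_linker = sum(t1$linker_found & t2$linker_found),
      usable_pairs = sum(t1$usable & t2$usable)
    )
  )
}

#' Align tags to a genome by exact matching
#'
#' Exact-match alignment for synthetic genomes: a k-mer seed index over
#' the genome, full-length verification of the tag and its reverse
#' complement. A single exact locus gives status `unique`; several give
#' `multi`; none (or a tag shorter than `k`) gives `unmapped`. `pos` is
#' the 5'-most genomic coordinate of the tag: its leftmost base on `+`,
#' its rightmost base on `-` (0-based).
#'
#' @param tags character vector of tag sequences.
#' @param genome named character vector of chromosome sequences.
#' @param k seed length (default 16).
#' @return data.frame `chrom, pos, strand, status` with one row per tag.
#' @export
align_tags <- function(tags, genome, k = 16L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  m <- .align_tags_cpp(unname(genome), as.character(tags), as.integer(k))
  status <- c("unique", "multi", "unmapped")[m[, 4]]
  strand <- ifelse(m[, 3] == 1L, "+", "-")
  left <- m[, 2]
  len <- nchar(tags)
  pos <- ifelse(strand == "+", left, left + len - 1L)
  data.frame(
    chrom = ifelse(is.na(m[, 1]), NA_character_, names(genome)[m[, 1]]),
    pos = ifelse(m[, 4] == 1L, pos, NA_integer_),
    strand = ifelse(m[, 4] == 1L, strand, NA_character_),
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Form paired-end tags (PETs) from aligned mates
#'
#' Pairs where both mates aligned uniquely become PETs with anchors in
#' canonical order (`(chrom1, pos1) <= (chrom2, pos2)`). Cis PETs closer
#' than `self_ligation_cutoff` are flagged self-ligation and excluded from
#' unique PETs. Duplicates (identical coordinates and strands of both
#' ends after canonical ordering) are collapsed to their first occurrence
#' when `dedup = TRUE`. The returned statistics partition the input pairs
#' exactly: `total = linker_unusable + not_both_unique + self_ligation +
#' duplicates + unique_pets`.
#'
#' @param aln1,aln2 alignment data.frames from [align_tags()] (one row per
#'   pair; mate order is irrelevant).
#' @param usable1,usable2 logical vectors marking usable tags (default all
#'   usable); unusable pairs are counted separately and never aligned into
#'   PETs.
#' @param dedup collapse coordinate duplicates.
#' @param self_ligation_cutoff cis distance below which a PET is treated
#'   as self-ligation, bp.
#' @return list with `pets` (data.frame `chrom1, pos1, strand1, chrom2,
#'   pos2, strand2, category`) and `stats` (library statistics list).
#' @export
form_pets <- function(aln1, aln2, usable1 = NULL, usable2 = NULL,
                      dedup = TRUE, self_ligation_cutoff = 1000L) {
  n <- nrow(aln1)
  stopifnot(nrow(aln2) == n)
  if (is.null(usable1)) usable1 <- rep(TRUE, n)
  if (is.null(usable2)) usable2 <- rep(TRUE, n)
  usable <- usable1 & usable2
  both_unique <- usable & aln1$status == "unique" & aln2$status == "unique"

  # canonical anchor ordering
  swap <- both_unique &
    (aln1$chrom > aln2$chrom |
       (aln1$chrom == aln2$chrom & aln1$pos > aln2$pos))
  swap[is.na(swap)] <- FALSE
  c1 <- ifelse(swap, aln2$chrom, aln1$chrom)
  p1 <- ifelse(swap, aln2$pos, aln1$pos)
  s1 <- ifelse(swap, aln2$strand, aln1$strand)
  c2 <- ifelse(swap, aln1$chrom, aln2$chrom)
  p2 <- ifelse(swap, aln1$pos, aln2$pos)
  s2 <- ifelse(swap, aln1$strand, aln2$strand)

  idx <- which(both_unique)
  pets <- data.frame(
    chrom1 = c1[idx], pos1 = p1[idx], strand1 = s1[idx],
    chrom2 = c2[idx], pos2 = p2[idx], strand2 = s2[idx],
    stringsAsFactors = FALSE
  )
  pets$category <- ifelse(pets$chrom1 == pets$chrom2, "cis", "trans")
  self_lig <- pets$category == "cis" &
    abs(pets$pos2 - pets$pos1) < self_ligation_cutoff
  n_self <- sum(self_lig)
  pets <- pets[!self_lig, , drop = FALSE]

  n_dup <- 0L
  if (dedup && nrow(pets) > 0) {
    key <- paste(pets$chrom1, pets$pos1, pets$strand1,
                 pets$chrom2, pets$pos2, pets$strand2)
    keep <- !duplicated(key)
    n_dup <- sum(!keep)
    pets <- pets[keep, , drop = FALSE]
  }
  rownames(pets) <- NULL

  cis <- sum(pets$category == "cis")
  trans <- sum(pets$category == "trans")
  stats <- list(
    total_read_pairs = n,
    linker_unusable = sum(!usable),
    not_both_unique = sum(usable & !both_unique),
    self_ligation = n_self,
    duplicates = n_dup,
    duplicate_rate = if (n_dup + nrow(pets) > 0) {
      n_dup / (n_dup + nrow(pets))
    } else 0,
    unique_pets = nrow(pets),
    cis_unique = cis,
    trans_unique = trans,
    cis_trans_ratio = if (trans > 0) cis / trans else NA_real_,
    unique_pet_fraction = nrow(pets) / n
  )
  list(pets = pets, stats = stats)
}

#' Simple depth-threshold peak caller
#'
#' Extends each tag 5' position to a fixed-width interval, computes
#' per-base depth, and reports maximal runs with depth at or above
#' `threshold` as peaks, with the summit at the depth argmax (leftmost on
#' ties). Peaks are ranked by their maximum depth, a stand-in for a
#' q-value ranking.
#'
#' @param tags data.frame `chrom, pos` of aligned tag 5' positions
#'   (0-based).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param extension width of the extended tag interval, bp (> 0).
#' @param threshold minimum depth for a base to be inside a peak.
#' @return data.frame `chrom, start, end, summit, max_depth, rank`
#'   (0-based half-open), ranked by decreasing `max_depth`.
#' @export
call_peaks_simple <- function(tags, chrom_sizes, extension = 150L,
                              threshold = 5L) {
  if (extension <= 0) stop("extension must be > 0")
  out <- list()
  for (chrom in names(chrom_sizes)) {
    pos <- tags$pos[tags$chrom == chrom]
    if (!length(pos)) next
    L <- chrom_sizes[[chrom]]
    ir <- IRanges::IRanges(start = pmax(pos + 1L, 1L),
                           width = as.integer(extension))
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(L))
    cov <- IRanges::coverage(ir, width = as.integer(L))
    runs <- IRanges::slice(cov, lower = threshold, rangesOnly = TRUE)
    if (!length(runs)) next
    views <- IRanges::Views(cov, runs)
    summit1 <- IRanges::viewWhichMaxs(views)  # leftmost max, 1-based
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = BiocGenerics::start(runs) - 1L,
      end = BiocGenerics::end(runs),
      summit = summit1 - 1L,
      max_depth = as.numeric(IRanges::viewMaxs(views)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      max_depth = numeric(0), rank = integer(0)))
  }
  peaks <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  peaks$rank <- rank(-peaks$max_depth, ties.method = "first")
  peaks
}

#' Import externally aligned tags
#'
#' Interop path for real libraries processed with a published aligner:
#' reads a TSV with columns `read_id, mate, chrom, pos, strand, mapq` and
#' returns per-mate alignment frames suitable for [form_pets()]. Records
#' with `mapq` below `min_mapq` are downgraded to status `multi`.
#'
#' @param path TSV file path (with header).
#' @param min_mapq minimum mapping quality for a unique alignment.
#' @return list with `aln1` and `aln2` data.frames, ordered by `read_id`.
#' @export
read_tag_table <- function(path, min_mapq = 30) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("read_id", "mate", "chrom", "pos", "strand", "mapq")
  if (!all(need %in% names(tab))) {
    stop("tag table must have columns: ", paste(need, collapse = ", "))
  }
  one_mate <- function(m) {
    sub <- tab[tab$mate == m, , drop = FALSE]
    sub <- sub[order(sub$read_id), , drop = FALSE]
    status <- ifelse(is.na(sub$pos), "unmapped",
                     ifelse(sub$mapq >= min_mapq, "unique", "multi"))
    data.frame(read_id = sub$read_id, chrom = sub$chrom, pos = sub$pos,
               strand = sub$strand, status = status,
               stringsAsFactors = FALSE)
  }
  a1 <- one_mate(1L)
  a2 <- one_mate(2L)
  if (!identical(a1$read_id, a2$read_id)) {
    stop("mate 1 and mate 2 read_id sets differ")
  }
  list(aln1 = a1, aln2 = a2)
}
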