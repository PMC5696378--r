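#' Restriction enzyme specification
#'
#' Recognition/cut model for in-silico digestion. Cut positions are
#' between-base (0-based) coordinates: an occurrence of the recognition
#' sequence starting at position `s` cuts at `s + cut_offset`. Only
#' palindromic recognition sites over plain ACGT are supported, so a
#' single-strand scan finds every site.
#'
#' @param name enzyme name.
#' @param recognition recognition sequence, uppercase ACGT.
#' @param cut_offset top-strand cut offset within the site,
#'   `0 <= cut_offset <= nchar(recognition)`.
#' @param palindromic whether the site equals its reverse complement.
#' @return an object of class `enzyme_spec`.
#' @seealso [builtin_enzymes()]
#' @export
enzyme_spec <- function(name, recognition, cut_offset, palindromic = TRUE) {
  if (!is.character(recognition) || length(recognition) != 1L ||
      nchar(recognition) == 0L || grepl("[^ACGT]", recognition)) {
    stop("recognition must be a non-empty uppercase ACGT string")
  }
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within the recognition site")
  }
  if (palindromic && recognition != revcomp(recognition)) {
    stop("recognition sequence is not palindromic")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset),
                 palindromic = isTRUE(palindromic)),
            class = "enzyme_spec")
}

#' Built-in restriction enzymes
#'
#' HaeIII (GGCC, blunt cut in the middle), MboI (GATC, cuts before the
#' site, 5' overhang) and HindIII (AAGCTT, cuts after the first base, 5'
#' overhang). All three are palindromic.
#'
#' @return named list of [enzyme_spec()] objects.
#' @examples
#' builtin_enzymes()$HaeIII
#' @export
builtin_enzymes <- function() {
  list(
    HaeIII  = enzyme_spec("HaeIII",  "GGCC",   2L),
    MboI    = enzyme_spec("MboI",    "GATC",   0L),
    HindIII = enzyme_spec("HindIII", "AAGCTT", 1L)
  )
}

#' @exportS3Method base::print
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("enzyme_spec: %s %s cut_offset=%d\n", x$name, x$recognition,
              x$cut_offset))
  invisible(x)
}

#' Scan a sequence for restriction cut sites
#'
#' Finds every occurrence of the recognition sequence (overlapping
#' occurrences included) and reports cut coordinates `start + cut_offset`
#' in 0-based between-base coordinates, sorted ascending. Ambiguous bases
#' (N) never match, so recognition sites cannot span masked sequence.
#'
#' @param sequence a single DNA string (character or
#'   [Biostrings::DNAString]); lowercase is uppercased.
#' @param enzyme an [enzyme_spec()].
#' @return integer vector of cut positions.
#' @examples
#' scan_sites("AAGGCCTT", builtin_enzymes()$HaeIII)  # 4
#' @export
scan_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (!enzyme$palindromic) {
    stop("both-strand scanning unsupported: enzyme is not palindromic")
  }
  subject <- if (methods::is(sequence, "DNAString")) {
    sequence
  } else {
    Biostrings::DNAString(toupper(as.character(sequence)))
  }
  # fixed = TRUE: N in the subject matches nothing in an ACGT pattern
  hits <- Biostrings::matchPattern(enzyme$recognition, subject, fixed = TRUE)
  sort(BiocGenerics::start(hits) - 1L + enzyme$cut_offset)
}

#' In-silico digestion of a genome
#'
#' Cuts every sequence at all recognition-site positions and returns the
#' resulting fragments, which tile each sequence exactly (between
#' consecutive cuts plus the two terminal pieces). The summary reports
#' the mean cut spacing as non-N length divided by site count, the
#' sequence statistic behind genome-average cutting frequencies.
#'
#' @param genome named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param enzyme an [enzyme_spec()].
#' @return list with `fragments` (data.frame `chrom, start, end, length`),
#'   `cut_sites` (data.frame `chrom, pos`) and `summary` (list with
#'   `n_fragments`, `n_sites`, `mean_length`, `median_length`,
#'   `mean_spacing`, `non_n_length`).
#' @examples
#' digest_genome(c(chrA = "AAGGCCTT"), builtin_enzymes()$HaeIII)$fragments
#' @export
digest_genome <- function(genome, enzyme) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (length(genome) == 0L) stop("genome is empty")
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  frag_list <- list()
  site_list <- list()
  n_sites <- 0L
  non_n <- 0
  for (chrom in names(genome)) {
    seqstr <- toupper(genome[[chrom]])
    L <- nchar(seqstr)
    if (L == 0L) {
      warning(sprintf("skipping empty sequence '%s'", chrom))
      next
    }
    cuts <- scan_sites(seqstr, enzyme)
    cuts <- cuts[cuts > 0L & cuts < L]  # terminal cuts produce no new fragment
    bounds <- c(0L, cuts, L)
    frag_list[[chrom]] <- data.frame(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      stringsAsFactors = FALSE
    )
    if (length(cuts)) {
      site_list[[chrom]] <- data.frame(chrom = chrom, pos = cuts,
                                       stringsAsFactors = FALSE)
    }
    n_sites <- n_sites + length(cuts)
    non_n <- non_n + nchar(gsub("N", "", seqstr, fixed = TRUE))
  }
  fragments <- do.call(rbind, c(frag_list, list(make.row.names = FALSE)))
  fragments$length <- fragments$end - fragments$start
  cut_sites <- if (length(site_list)) {
    do.call(rbind, c(site_list, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom = character(0), pos = integer(0))
  }
  list(
    fragments = fragments,
    cut_sites = cut_sites,
    summary = list(
      n_fragments = nrow(fragments),
      n_sites = n_sites,
      mean_length = mean(fragments$length),
      median_length = stats::median(fragments$length),
      mean_spacing = if (n_sites > 0) non_n / n_sites else NA_real_,
      non_n_length = non_n
    )
  )
}

#' Average signal depth around reference peak centers
#'
#' Bins the signed distance from each reference-peak center to the centers
#' of nearby signal intervals and averages the signal depth per bin over
#' all reference peaks (peaks with no nearby signal contribute zeros),
#' scaled to counts per million sequenced reads. A peak's center is its
#' `summit` when present, else the interval midpoint.
#'
#' @param signal data.frame `chrom, start, end, depth` (0-based half-open).
#' @param peaks data.frame `chrom, start, end` with optional `summit`
#'   (absolute genomic coordinate).
#' @param window half-width of the profile in bp.
#' @param bin_size bin width in bp; must divide `window`.
#' @param total_reads library size used for per-million scaling.
#' @return data.frame `bin_start, bin_mid, bin_end, depth` with
#'   `2 * window / bin_size` rows.
#' @export
proximity_profile <- function(signal, peaks, window, bin_size, total_reads) {
  if (window %% bin_size != 0) {
    stop("window must be divisible by bin_size")
  }
  if (total_reads <= 0) stop("total_reads must be > 0")
  n_bins <- as.integer(2 * window / bin_size)
  edges <- seq(-window, window, by = bin_size)
  acc <- numeric(n_bins)
  peak_center <- if ("summit" %in% names(peaks)) {
    ifelse(is.na(peaks$summit), (peaks$start + peaks$end) / 2, peaks$summit)
  } else {
    (peaks$start + peaks$end) / 2
  }
  sig_center <- (signal$start + signal$end) / 2
  for (chrom in unique(peaks$chrom)) {
    pc <- peak_center[peaks$chrom == chrom]
    sel <- signal$chrom == chrom
    sc <- sig_center[sel]
    dep <- signal$depth[sel]
    if (!length(pc) || !length(sc)) next
    # pair every signal center with every reference center within the window
    ir_p <- IRanges::IRanges(start = round(pc - window), width = 2 * window)
    ir_s <- IRanges::IRanges(start = round(sc), width = 1L)
    ov <- IRanges::findOverlaps(ir_s, ir_p)
    if (!length(ov)) next
    d <- sc[queryHits(ov)] - pc[subjectHits(ov)]
    bin <- findInterval(d, edges, rightmost.closed = TRUE,
                        left.open = FALSE)
    ok <- bin >= 1 & bin <= n_bins
    acc <- acc + vapply(seq_len(n_bins), function(b) {
      sum(dep[queryHits(ov)][ok & bin == b])
    }, numeric(1))
  }
  depth <- acc / nrow(peaks) * 1e6 / total_reads
  data.frame(
    bin_start = edges[-length(edges)],
    bin_mid = edges[-length(edges)] + bin_size / 2,
    bin_end = edges[-1],
    depth = depth
  )
}

#' Uniform random down-sampling
#'
#' Subsamples rows (data.frame) or elements (vector/list) without
#' replacement, reproducibly under `seed`, preserving the original order
#' of the retained items. Used to equalise library depths before
#' comparisons.
#'
#' @param x data.frame, vector or list.
#' @param target number of items to keep; must not exceed the input size.
#' @param seed integer seed.
#' @return object of the same type as `x`, with `target` items.
#' @export
downsample <- function(x, target, seed) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (target > n) stop("target exceeds input size")
  idx <- with_seed(seed, sort(sample.int(n, target)))
  if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}
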