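pets_to_tag_granges <- function(pets) {
  GenomicRanges::GRanges(
    seqnames = c(pets$chrom1, pets$chrom2),
    ranges = IRanges::IRanges(start = c(pets$pos1, pets$pos2) + 1L,
                              width = 1L)
  )
}

#' Fraction of PET tags overlapping a region set
#'
#' Each PET contributes two 1-bp tags (its anchor positions); the
#' fraction of tags with at least 1 bp overlap with any region is
#' returned. With `mode = "either-end"` the unit is the whole PET instead
#' (a PET counts if either end overlaps).
#'
#' @param pets PET data.frame (`chrom1, pos1, chrom2, pos2`).
#' @param regions data.frame `chrom, start, end` (0-based half-open);
#'   overlapping regions are merged first.
#' @param mode `"tag"` (default) or `"either-end"`.
#' @return fraction in \[0, 1\].
#' @export
pet_overlap_fraction <- function(pets, regions, mode = c("tag", "either-end")) {
  mode <- match.arg(mode)
  if (nrow(pets) == 0) stop("empty PET list")
  gr_regions <- GenomicRanges::reduce(as_granges(regions))
  tags <- pets_to_tag_granges(pets)
  hit <- IRanges::overlapsAny(tags, gr_regions)
  if (mode == "tag") {
    mean(hit)
  } else {
    n <- nrow(pets)
    mean(hit[seq_len(n)] | hit[seq_len(n) + n])
  }
}

#' Per-site-set tag enrichment of one library over another
#'
#' For each named region set, reports the percentage of library A's tags
#' overlapping the set and the depth-normalised tag-count ratio
#' `(count_A / total_A) / (count_B / total_B)`. The ratio is reported as
#' `NA` when B has no overlapping tags.
#'
#' @param pets_A,pets_B PET data.frames.
#' @param site_sets named list of region data.frames.
#' @param total_A,total_B normalising tag totals (default: the libraries'
#'   own tag counts).
#' @return data.frame `site_set, count_A, count_B, pct_A, ratio`.
#' @export
tf_enrichment_table <- function(pets_A, pets_B, site_sets,
                                total_A = 2 * nrow(pets_A),
                                total_B = 2 * nrow(pets_B)) {
  if (total_A <= 0 || total_B <= 0) stop("totals must be > 0")
  tags_A <- pets_to_tag_granges(pets_A)
  tags_B <- pets_to_tag_granges(pets_B)
  rows <- lapply(names(site_sets), function(nm) {
    gr <- GenomicRanges::reduce(as_granges(site_sets[[nm]]))
    ca <- sum(IRanges::overlapsAny(tags_A, gr))
    cb <- sum(IRanges::overlapsAny(tags_B, gr))
    data.frame(
      site_set = nm, count_A = ca, count_B = cb,
      pct_A = 100 * ca / total_A,
      ratio = if (cb > 0) (ca / total_A) / (cb / total_B) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group peaks by depth fold change between two libraries
#'
#' Classifies each peak by the log2 fold change of depth-normalised tag
#' counts, `log2((depth_A + c) / total_A) - log2((depth_B + c) / total_B)`
#' with pseudocount `c = 1`: `high` for fold changes > 1, `low` for
#' < -1, and `normal` in between (boundary values of exactly +/-1 are
#' `normal`).
#'
#' @param depth_A,depth_B per-peak tag counts in libraries A and B.
#' @param total_A,total_B library tag totals.
#' @param pseudocount added to both depths before taking logs.
#' @return data.frame `depth_A, depth_B, log2_fc, group`.
#' @export
group_peaks_by_fc <- function(depth_A, depth_B, total_A, total_B,
                              pseudocount = 1) {
  if (total_A <= 0 || total_B <= 0) stop("totals must be > 0")
  if (any(depth_A < 0) || any(depth_B < 0)) stop("negative depths")
  lfc <- log2((depth_A + pseudocount) / total_A) -
    log2((depth_B + pseudocount) / total_B)
  group <- ifelse(lfc > 1, "high", ifelse(lfc < -1, "low", "normal"))
  data.frame(depth_A = depth_A, depth_B = depth_B, log2_fc = lfc,
             group = group, stringsAsFactors = FALSE)
}

#' Annotate grouped peaks with genomic features
#'
#' Assigns each peak (by its center) to the first feature class in
#' `precedence` that contains it, or `"intergenic"`, and reports per group
#' and feature the observed fraction, the genomic background fraction
#' (merged feature length share), and their ratio as fold enrichment.
#'
#' @param peaks data.frame `chrom, start, end` with optional `summit`.
#' @param groups character vector of group labels, one per peak.
#' @param features named list of feature data.frames (`chrom, start,
#'   end`); the list order is the assignment precedence.
#' @param genome_size total genome length used for background fractions.
#' @return data.frame `group, feature, n, observed, background,
#'   enrichment`.
#' @export
annotate_peak_groups <- function(peaks, groups, features, genome_size) {
  if (!length(features)) stop("features must be a non-empty named list")
  stopifnot(length(groups) == nrow(peaks))
  center <- if ("summit" %in% names(peaks)) {
    ifelse(is.na(peaks$summit), floor((peaks$start + peaks$end) / 2),
           peaks$summit)
  } else {
    floor((peaks$start + peaks$end) / 2)
  }
  gr_center <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = center + 1L, width = 1L))
  assigned <- rep("intergenic", nrow(peaks))
  feat_len <- numeric(0)
  covered <- NULL
  for (nm in names(features)) {
    gr <- GenomicRanges::reduce(as_granges(features[[nm]]))
    # precedence: length share counted net of higher-precedence features
    net <- if (is.null(covered)) gr else GenomicRanges::setdiff(gr, covered)
    feat_len[nm] <- sum(BiocGenerics::width(net))
    covered <- if (is.null(covered)) gr else GenomicRanges::union(covered, gr)
    hit <- IRanges::overlapsAny(gr_center, gr)
    assigned[hit & assigned == "intergenic"] <- nm
  }
  feat_len["intergenic"] <- max(genome_size - sum(feat_len), 0)
  classes <- c(names(features), "intergenic")
  rows <- list()
  for (g in unique(groups)) {
    in_g <- groups == g
    for (cl in classes) {
      obs <- sum(assigned[in_g] == cl) / sum(in_g)
      bg <- feat_len[[cl]] / genome_size
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, feature = cl, n = sum(assigned[in_g] == cl),
        observed = obs, background = bg,
        enrichment = if (bg > 0) obs / bg else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Bin intra-chromosomal PETs into a contact matrix
#'
#' Bin index is `floor(pos / resolution)`; each cis PET of the requested
#' chromosome adds one symmetric count to its bin pair.
#'
#' @param pets PET data.frame.
#' @param resolution bin size, bp.
#' @param chrom chromosome to bin.
#' @param chrom_size chromosome length, bp (fixes the bin count).
#' @return object of class `contact_matrix`: list with `counts` (sparse
#'   symmetric [Matrix::sparseMatrix]), `resolution`, `chrom`,
#'   `normalized` flag and `scale`.
#' @export
bin_contacts <- function(pets, resolution, chrom, chrom_size) {
  sel <- pets$chrom1 == chrom & pets$chrom2 == chrom
  n_bins <- as.integer(ceiling(chrom_size / resolution))
  b1 <- pmin(floor(pets$pos1[sel] / resolution), n_bins - 1L) + 1L
  b2 <- pmin(floor(pets$pos2[sel] / resolution), n_bins - 1L) + 1L
  lo <- pmin(b1, b2)
  hi <- pmax(b1, b2)
  m <- Matrix::sparseMatrix(i = lo, j = hi, x = 1, dims = c(n_bins, n_bins))
  m <- m + Matrix::t(m)
  diag_idx <- lo == hi
  if (any(diag_idx)) {
    # diagonal was double-counted by the symmetrisation
    m <- m - Matrix::sparseMatrix(i = lo[diag_idx], j = hi[diag_idx], x = 1,
                                  dims = c(n_bins, n_bins))
  }
  structure(list(counts = m, resolution = resolution, chrom = chrom,
                 normalized = FALSE, scale = 1),
            class = "contact_matrix")
}

#' Depth-normalise a contact matrix to counts per million PETs
#'
#' @param m a `contact_matrix`.
#' @param total_pets sequencing depth (total PETs) of the library.
#' @return the normalised `contact_matrix`.
#' @export
normalize_per_million <- function(m, total_pets) {
  stopifnot(inherits(m, "contact_matrix"))
  if (total_pets <= 0) stop("total_pets must be > 0")
  m$counts <- m$counts * (1e6 / total_pets)
  m$normalized <- TRUE
  m$scale <- 1e6 / total_pets
  m
}

#' Differential contact matrix
#'
#' Signed difference `A - B` of two contact matrices on the same
#' chromosome and resolution (normalise both first for a depth-fair
#' comparison).
#'
#' @param a,b `contact_matrix` objects.
#' @return a `contact_matrix` whose counts may be negative.
#' @export
diff_matrix <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (a$resolution != b$resolution || a$chrom != b$chrom ||
      !identical(dim(a$counts), dim(b$counts))) {
    stop("matrices must share chromosome, resolution and dimensions")
  }
  structure(list(counts = a$counts - b$counts, resolution = a$resolution,
                 chrom = a$chrom, normalized = a$normalized && b$normalized,
                 scale = NA_real_),
            class = "contact_matrix")
}

#' @exportS3Method base::print
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s @ %g bp, %d bins, %s\n", x$chrom,
              x$resolution, nrow(x$counts),
              if (x$normalized) "normalized (per million)" else "raw counts"))
  invisible(x)
}

#' Cluster PETs into loops
#'
#' Each PET end is extended by `anchor_extension` on both sides; two PETs
#' are linked when their extended first ends overlap AND their extended
#' second ends overlap (anchors are in canonical order, so the pairing is
#' well defined). Links are closed transitively (single linkage) and each
#' connected component becomes a loop whose anchors are the union spans of
#' the member ends and whose `pet_count` is the component size. Loops
#' with fewer than `min_count` PETs are dropped.
#'
#' @param pets PET data.frame with canonical anchor order.
#' @param anchor_extension half-width added to each end, bp.
#' @param min_count minimum PETs per reported loop.
#' @return data.frame `chrom1, start1, end1, chrom2, start2, end2,
#'   pet_count` sorted by anchors, plus attribute `n_dropped_pets` (PETs
#'   in components below `min_count`).
#' @export
cluster_pets <- function(pets, anchor_extension = 2500L, min_count = 5L) {
  n <- nrow(pets)
  if (n == 0) {
    out <- data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      pet_count = integer(0))
    attr(out, "n_dropped_pets") <- 0L
    return(out)
  }
  ord <- order(pets$chrom1, pets$pos1, pets$chrom2, pets$pos2)
  pets <- pets[ord, , drop = FALSE]
  ext <- as.integer(anchor_extension)
  gr1 <- GenomicRanges::GRanges(
    pets$chrom1,
    IRanges::IRanges(start = pets$pos1 - ext + 1L, end = pets$pos1 + ext + 1L))
  gr2 <- GenomicRanges::GRanges(
    pets$chrom2,
    IRanges::IRanges(start = pets$pos2 - ext + 1L, end = pets$pos2 + ext + 1L))
  h1 <- GenomicRanges::findOverlaps(gr1, drop.self = TRUE,
                                    drop.redundant = TRUE)
  h2 <- GenomicRanges::findOverlaps(gr2, drop.self = TRUE,
                                    drop.redundant = TRUE)
  # an edge links PETs i, j when both end pairs overlap
  k1 <- paste(queryHits(h1), subjectHits(h1))
  k2 <- paste(queryHits(h2), subjectHits(h2))
  shared <- intersect(k1, k2)
  edge_idx <- if (length(shared)) {
    m <- do.call(rbind, strsplit(shared, " "))
    as.integer(t(m))
  } else {
    integer(0)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edge_idx)) g <- igraph::add_edges(g, edge_idx)
  membership <- igraph::components(g)$membership
  sizes <- table(membership)
  keep_ids <- as.integer(names(sizes)[sizes >= min_count])
  dropped <- n - sum(sizes[sizes >= min_count])
  rows <- lapply(keep_ids, function(id) {
    sel <- membership == id
    data.frame(
      chrom1 = pets$chrom1[sel][1],
      start1 = min(pets$pos1[sel]) - ext,
      end1 = max(pets$pos1[sel]) + ext + 1L,
      chrom2 = pets$chrom2[sel][1],
      start2 = min(pets$pos2[sel]) - ext,
      end2 = max(pets$pos2[sel]) + ext + 1L,
      pet_count = sum(sel),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
               chrom2 = character(0), start2 = integer(0), end2 = integer(0),
               pet_count = integer(0))
  }
  out <- out[order(out$chrom1, out$start1, out$chrom2, out$start2), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_pets") <- as.integer(dropped)
  out
}

loop_anchor_granges <- function(loops, slack = 0L) {
  list(
    a1 = GenomicRanges::GRanges(
      loops$chrom1,
      IRanges::IRanges(start = loops$start1 + 1L - slack,
                       end = loops$end1 + slack)),
    a2 = GenomicRanges::GRanges(
      loops$chrom2,
      IRanges::IRanges(start = loops$start2 + 1L - slack,
                       end = loops$end2 + slack))
  )
}

#' Classify loops of two sets as common or set-specific
#'
#' A loop pair is common when anchor1 overlaps anchor1' AND anchor2
#' overlaps anchor2' (each within `slack`), testing both the direct and
#' the swapped anchor pairing ("pairtopair -type both" semantics: one
#' overlapping anchor is not enough). The classification partitions both
#' input sets.
#'
#' @param loops_A,loops_B loop data.frames (`chrom1, start1, end1, chrom2,
#'   start2, end2`).
#' @param slack extra bp allowed around each anchor when testing overlap.
#' @return list with `label_A`, `label_B` (factors `common` /
#'   `A-specific` resp. `B-specific`) and `pairs` (data.frame of common
#'   index pairs).
#' @export
classify_loops <- function(loops_A, loops_B, slack = 0L) {
  slack <- as.integer(slack)
  ga <- loop_anchor_granges(loops_A, slack)
  gb <- loop_anchor_granges(loops_B)
  pair_hits <- function(qa1, qa2, sb1, sb2) {
    # disjoint seqlevel sets are a legitimate "nothing in common" case,
    # not worth a GenomicRanges warning per comparison
    h1 <- suppressWarnings(GenomicRanges::findOverlaps(qa1, sb1))
    h2 <- suppressWarnings(GenomicRanges::findOverlaps(qa2, sb2))
    intersect(paste(queryHits(h1), subjectHits(h1)),
              paste(queryHits(h2), subjectHits(h2)))
  }
  direct <- pair_hits(ga$a1, ga$a2, gb$a1, gb$a2)
  swapped <- pair_hits(ga$a1, ga$a2, gb$a2, gb$a1)
  common <- union(direct, swapped)
  pairs <- if (length(common)) {
    m <- do.call(rbind, strsplit(common, " "))
    data.frame(idx_A = as.integer(m[, 1]), idx_B = as.integer(m[, 2]))
  } else {
    data.frame(idx_A = integer(0), idx_B = integer(0))
  }
  label_A <- rep("A-specific", nrow(loops_A))
  label_A[unique(pairs$idx_A)] <- "common"
  label_B <- rep("B-specific", nrow(loops_B))
  label_B[unique(pairs$idx_B)] <- "common"
  list(label_A = label_A, label_B = label_B, pairs = pairs)
}

#' Fraction of loops shared with a reference loop set
#'
#' Wraps [classify_loops()] and returns the fraction of `loops` classified
#' common with `reference_loops`.
#'
#' @inheritParams classify_loops
#' @param loops query loop data.frame (must be non-empty).
#' @param reference_loops reference loop data.frame.
#' @return fraction in \[0, 1\].
#' @export
loop_reference_overlap <- function(loops, reference_loops, slack = 0L) {
  if (nrow(loops) == 0) stop("empty loop list")
  cl <- classify_loops(loops, reference_loops, slack = slack)
  mean(cl$label_A == "common")
}

#' Motif orientation proportions over loop anchors
#'
#' Restricts to loops whose anchors each contain exactly one stranded
#' motif hit; with anchors in genomic order, strand pair `(+,-)` is
#' convergent, `(-,+)` divergent and `(+,+)` / `(-,-)` identical.
#'
#' @param loops loop data.frame.
#' @param motifs data.frame `chrom, start, end, strand`.
#' @return list with `n_classified` and `proportions` (named numeric:
#'   convergent, divergent, identical; sums to 1 when `n_classified > 0`).
#' @export
motif_orientation <- function(loops, motifs) {
  gm <- as_granges(motifs, strand_col = "strand")
  ga <- loop_anchor_granges(loops)
  hits1 <- GenomicRanges::findOverlaps(ga$a1, gm, ignore.strand = TRUE)
  hits2 <- GenomicRanges::findOverlaps(ga$a2, gm, ignore.strand = TRUE)
  cnt1 <- tabulate(queryHits(hits1), nbins = nrow(loops))
  cnt2 <- tabulate(queryHits(hits2), nbins = nrow(loops))
  usable <- cnt1 == 1L & cnt2 == 1L
  if (!any(usable)) {
    return(list(n_classified = 0L,
                proportions = c(convergent = NA_real_, divergent = NA_real_,
                                identical = NA_real_)))
  }
  strand_chr <- as.character(GenomicRanges::strand(gm))
  s1 <- strand_chr[subjectHits(hits1)[match(which(usable), queryHits(hits1))]]
  s2 <- strand_chr[subjectHits(hits2)[match(which(usable), queryHits(hits2))]]
  class <- ifelse(s1 == "+" & s2 == "-", "convergent",
                  ifelse(s1 == "-" & s2 == "+", "divergent", "identical"))
  prop <- c(convergent = mean(class == "convergent"),
            divergent = mean(class == "divergent"),
            identical = mean(class == "identical"))
  list(n_classified = sum(usable), proportions = prop)
}

#' Virtual 4C profile around a viewpoint
#'
#' Selects PETs with at least one end inside the viewpoint (PETs with
#' both ends inside are self-interactions and excluded), projects the
#' distal ends onto the genome, merges ends within `merge_gap` into
#' clusters, and reports clusters with at least `min_count` PETs as arcs.
#'
#' @param pets PET data.frame.
#' @param viewpoint list or one-row data.frame with `chrom, start, end`
#'   (0-based half-open).
#' @param merge_gap maximum gap between distal ends merged into one
#'   cluster, bp.
#' @param min_count minimum PET count per reported cluster.
#' @return list with `viewpoint`, `n_selected` (PETs with exactly one end
#'   in the viewpoint) and `clusters` (data.frame `chrom, start, end,
#'   pet_count`).
#' @export
visual_4c <- function(pets, viewpoint, merge_gap = 5000L, min_count = 5L) {
  vp_chrom <- viewpoint$chrom
  in_vp <- function(chrom, pos) {
    chrom == vp_chrom & pos >= viewpoint$start & pos < viewpoint$end
  }
  end1_in <- in_vp(pets$chrom1, pets$pos1)
  end2_in <- in_vp(pets$chrom2, pets$pos2)
  sel <- xor(end1_in, end2_in)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), pet_count = integer(0))
  if (!any(sel)) {
    return(list(viewpoint = viewpoint, n_selected = 0L, clusters = empty))
  }
  distal_chrom <- ifelse(end1_in[sel], pets$chrom2[sel], pets$chrom1[sel])
  distal_pos <- ifelse(end1_in[sel], pets$pos2[sel], pets$pos1[sel])
  gr <- GenomicRanges::GRanges(
    distal_chrom, IRanges::IRanges(start = distal_pos + 1L, width = 1L))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap)
  cnt <- GenomicRanges::countOverlaps(merged, gr)
  keep <- cnt >= min_count
  clusters <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged))[keep],
    start = BiocGenerics::start(merged)[keep] - 1L,
    end = BiocGenerics::end(merged)[keep],
    pet_count = as.integer(cnt[keep]),
    stringsAsFactors = FALSE
  )
  list(viewpoint = viewpoint, n_selected = sum(sel), clusters = clusters)
}
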