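#' Simulation configuration for a synthetic proximity-ligation library
#'
#' Defines the ground-truth study conditions: a random genome with
#' restriction sites, planted stranded protein-binding sites, planted
#' loops between same-chromosome sites, two-step (or one-step) ligation
#' junction molecules carrying the bridge linker, sonication arms, paired
#' reads with substitution errors, and cis/trans noise pairs.
#'
#' Defaults describe the reference library used throughout the package:
#' a 1 Mb genome on 2 chromosomes, 200 binding sites of which 100 anchor
#' 50 loops, 50 000 read pairs at 1% per-base substitution error with
#' 150-bp reads (HiSeq X Ten era lengths), 10% noise pairs of which 85%
#' are trans (random inter-chromosomal collisions dominate the noise
#' channel), sonication arms uniform in \[50, 500\] bp, 5% molecule
#' duplication, HaeIII digestion and the two-step bridge linker. The
#' convergent-motif fraction of loops defaults to 0.9, the canonical
#' convergence rate of CTCF-anchored loops.
#'
#' @param genome_length total genome length, bp (>= 10 kb).
#' @param n_chroms number of chromosomes (equal sizes).
#' @param gc_content GC fraction of the random genome.
#' @param n_sites number of planted binding sites (>= 2 * n_loops).
#' @param site_width width of each planted site, bp.
#' @param site_cut_bias target enrichment of enzyme recognition sites
#'   within `site_window` of planted sites (1 = no biasing).
#' @param site_window half-width of the biased window around sites, bp.
#' @param n_loops number of planted loops.
#' @param loop_dist_range log-uniform range of anchor distances, bp.
#' @param convergent_fraction fraction of loops with convergent (+,-)
#'   anchor motifs; the remainder splits equally between divergent and
#'   identical.
#' @param pairs_signal number of signal ligation events.
#' @param pairs_noise number of noise ligation events.
#' @param trans_fraction fraction of noise events joining different
#'   chromosomes.
#' @param arm_range sonication arm length range, bp (uniform).
#' @param read_length read length, bp.
#' @param error_rate per-base substitution probability.
#' @param linker_mode `"two-step"` or `"one-step"`.
#' @param duplicate_rate fraction of extra duplicate molecules injected.
#' @param enzyme an [enzyme_spec()]; default HaeIII.
#' @param seed master seed; every random stream is derived from it by
#'   labelled sub-seeds.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, n_chroms = 2, gc_content = 0.5,
                       n_sites = 200, site_width = 200, site_cut_bias = 1,
                       site_window = 500, n_loops = 50,
                       loop_dist_range = c(1e4, 2e5),
                       convergent_fraction = 0.9,
                       pairs_signal = 45000, pairs_noise = 5000,
                       trans_fraction = 0.85, arm_range = c(50, 500),
                       read_length = 150, error_rate = 0.01,
                       linker_mode = c("two-step", "one-step"),
                       duplicate_rate = 0.05,
                       enzyme = builtin_enzymes()$HaeIII, seed = 1L) {
  linker_mode <- match.arg(linker_mode)
  if (genome_length < 1e4) stop("genome_length must be >= 10 kb")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  for (fr in c(trans_fraction, error_rate, duplicate_rate,
               convergent_fraction)) {
    if (fr < 0 || fr > 1) stop("fractions must be in [0, 1]")
  }
  if (n_sites < 2 * n_loops) stop("n_sites must be >= 2 * n_loops")
  if (n_chroms < 1) stop("n_chroms must be >= 1")
  structure(list(
    genome_length = genome_length, n_chroms = as.integer(n_chroms),
    gc_content = gc_content, n_sites = as.integer(n_sites),
    site_width = as.integer(site_width), site_cut_bias = site_cut_bias,
    site_window = as.integer(site_window), n_loops = as.integer(n_loops),
    loop_dist_range = loop_dist_range,
    convergent_fraction = convergent_fraction,
    pairs_signal = as.integer(pairs_signal),
    pairs_noise = as.integer(pairs_noise),
    trans_fraction = trans_fraction, arm_range = as.integer(arm_range),
    read_length = as.integer(read_length), error_rate = error_rate,
    linker_mode = linker_mode, duplicate_rate = duplicate_rate,
    enzyme = enzyme, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Event mix from the kinetics model
#'
#' Convenience: signal/noise event counts proportional to the two-step
#' closed-form `y(t*) / z(t*)`, for tying the generator's event mix to
#' the kinetic model.
#'
#' @param params a [kinetics_params()].
#' @param t_star evaluation time.
#' @param n_pairs total event count to split.
#' @param model which closed form to use.
#' @return list with `pairs_signal` and `pairs_noise`.
#' @export
event_mix_from_kinetics <- function(params, t_star, n_pairs,
                                    model = c("two-step", "one-step")) {
  model <- match.arg(model)
  st <- if (model == "two-step") {
    two_step_closed_form(params, t_star)
  } else {
    one_step_closed_form(params, t_star)
  }
  frac_signal <- st$y / (st$y + st$z)
  ns <- as.integer(round(n_pairs * frac_signal))
  list(pairs_signal = ns, pairs_noise = as.integer(n_pairs) - ns)
}

#' Generate a random genome
#'
#' I.i.d. bases at the configured GC content, split into equal
#' chromosomes. When `truth` (from [plant_sites_and_loops()]) is given
#' and `site_cut_bias > 1`, extra enzyme recognition occurrences are
#' written within `site_window` of each planted site so that the local
#' recognition-site density is about `site_cut_bias` times the genomic
#' background, emulating a cutter that lands preferentially near active
#' protein-bound regions.
#'
#' @param config a [sim_config()].
#' @param truth optional ground truth with a `sites` table.
#' @return named character vector of chromosome sequences, with
#'   `chrom_sizes` attribute.
#' @export
make_genome <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- as.integer(config$genome_length / config$n_chroms)
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  genome <- with_seed(sub_seed(config$seed, "genome"), {
    vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  if (!is.null(truth) && config$site_cut_bias > 1) {
    genome <- with_seed(sub_seed(config$seed, "cut_bias"), {
      plant_recognition_sites(genome, truth$sites, config)
    })
  }
  attr(genome, "chrom_sizes") <- setNames(rep(L, config$n_chroms),
                                          names(genome))
  genome
}

# Overwrite bases with the enzyme recognition sequence at random positions
# inside +/- site_window of each site center, until the windowed density is
# about site_cut_bias times the background rate 4^-k.
plant_recognition_sites <- function(genome, sites, config) {
  rec <- config$enzyme$recognition
  k <- nchar(rec)
  bg_rate <- 0.25^k
  win <- config$site_window
  # extra occurrences needed per window of length 2*win
  n_extra <- max(0, round((config$site_cut_bias - 1) * bg_rate * 2 * win))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    center <- floor((sites$start[i] + sites$end[i]) / 2)
    L <- nchar(genome[[chrom]])
    lo <- max(0, center - win)
    hi <- min(L - k, center + win - k)
    if (hi <= lo || n_extra == 0) next
    at <- sample(seq(lo, hi), n_extra, replace = FALSE)
    for (a in at) {
      substr(genome[[chrom]], a + 1, a + k) <- rec
    }
  }
  genome
}

#' Plant binding sites and loops
#'
#' Places `n_sites` non-overlapping stranded sites on the genome;
#' `2 * n_loops` of them are placed as same-chromosome anchor pairs with
#' log-uniform distances in `loop_dist_range`, and the remainder
#' uniformly. Loop anchor strand pairs are convergent with probability
#' `convergent_fraction`, else divergent or identical with equal
#' probability.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_truth` with `sites` (data.frame `site_id,
#'   chrom, start, end, strand, class, in_loop`) and `loops` (data.frame
#'   `loop_id, chrom, site1, site2, anchor1_pos, anchor2_pos,
#'   orientation`).
#' @export
plant_sites_and_loops <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- as.integer(config$genome_length / config$n_chroms)
  w <- config$site_width
  margin <- 1000L  # keep sites away from chromosome ends
  if (L < 2 * margin + 10 * w) stop("genome too small to place sites")
  with_seed(sub_seed(config$seed, "sites"), {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    occupied <- setNames(
      lapply(chroms, function(x) IRanges::IRanges()), chroms)
    place <- function(chrom, center) {
      start <- as.integer(center - w / 2)
      ir <- IRanges::IRanges(start = start + 1L, width = w)
      if (start < margin || start + w > L - margin) return(NULL)
      if (length(IRanges::findOverlaps(ir, occupied[[chrom]]))) return(NULL)
      occupied[[chrom]] <<- c(occupied[[chrom]], ir)
      start
    }
    sites <- list()
    loops <- list()
    # loop anchor pairs first
    ld <- log(config$loop_dist_range)
    for (l in seq_len(config$n_loops)) {
      repeat {
        chrom <- sample(chroms, 1L)
        d <- round(exp(runif(1, ld[1], ld[2])))
        if (L - margin - w - d <= margin + w) next  # distance does not fit
        c1 <- round(runif(1, margin + w, L - margin - w - d))
        s1 <- place(chrom, c1)
        if (is.null(s1)) next
        s2 <- place(chrom, c1 + d)
        if (is.null(s2)) {
          # release the first anchor and retry
          occupied[[chrom]] <- occupied[[chrom]][-length(occupied[[chrom]])]
          next
        }
        u <- runif(1)
        ori <- if (u < config$convergent_fraction) {
          "convergent"
        } else if (u < config$convergent_fraction +
                   (1 - config$convergent_fraction) / 2) {
          "divergent"
        } else {
          "identical"
        }
        strands <- switch(ori,
          convergent = c("+", "-"),
          divergent = c("-", "+"),
          identical = if (runif(1) < 0.5) c("+", "+") else c("-", "-"))
        id1 <- length(sites) + 1L
        id2 <- length(sites) + 2L
        sites[[id1]] <- data.frame(
          site_id = id1, chrom = chrom, start = s1, end = s1 + w,
          strand = strands[1], class = "CTCF", in_loop = TRUE,
          stringsAsFactors = FALSE)
        sites[[id2]] <- data.frame(
          site_id = id2, chrom = chrom, start = s2, end = s2 + w,
          strand = strands[2], class = "CTCF", in_loop = TRUE,
          stringsAsFactors = FALSE)
        loops[[l]] <- data.frame(
          loop_id = l, chrom = chrom, site1 = id1, site2 = id2,
          anchor1_pos = s1 + as.integer(w / 2),
          anchor2_pos = s2 + as.integer(w / 2),
          orientation = ori, stringsAsFactors = FALSE)
        break
      }
    }
    # remaining sites uniform, alternating class labels
    n_free <- config$n_sites - 2L * config$n_loops
    placed <- 0L
    while (placed < n_free) {
      chrom <- sample(chroms, 1L)
      center <- round(runif(1, margin + w, L - margin - w))
      s <- place(chrom, center)
      if (is.null(s)) next
      placed <- placed + 1L
      id <- length(sites) + 1L
      sites[[id]] <- data.frame(
        site_id = id, chrom = chrom, start = s, end = s + w,
        strand = sample(c("+", "-"), 1L),
        class = if (placed %% 2 == 0) "CTCF" else "RNAPII",
        in_loop = FALSE, stringsAsFactors = FALSE)
    }
    structure(list(
      sites = do.call(rbind, c(sites, list(make.row.names = FALSE))),
      loops = if (length(loops)) {
        do.call(rbind, c(loops, list(make.row.names = FALSE)))
      } else {
        data.frame(loop_id = integer(0), chrom = character(0),
                   site1 = integer(0), site2 = integer(0),
                   anchor1_pos = integer(0), anchor2_pos = integer(0),
                   orientation = character(0))
      }
    ), class = "sim_truth")
  })
}

#' Simulate ligation junction events
#'
#' Signal events pick a planted loop uniformly and draw one restriction
#' fragment arm adjacent to each anchor (the cut site nearest the anchor
#' center, with a random fragment side). Noise events draw two cut sites
#' uniformly, on different chromosomes with probability
#' `trans_fraction`. Each arm has a sonication length uniform in
#' `arm_range` (clipped at chromosome ends) and an independent random
#' orientation.
#'
#' @param truth a `sim_truth` from [plant_sites_and_loops()].
#' @param genome genome from [make_genome()].
#' @param config a [sim_config()].
#' @return data.frame of events: `event_id, type, loop_id,
#'   chrom1, cut1, side1, armlen1, flip1, chrom2, cut2, side2, armlen2,
#'   flip2`, with attribute `n_redrawn` (events re-drawn because an
#'   anchor had no nearby cut site).
#' @export
simulate_ligation_events <- function(truth, genome, config) {
  stopifnot(inherits(config, "sim_config"))
  dig <- digest_genome(genome, config$enzyme)
  cuts_by_chrom <- split(dig$cut_sites$pos, dig$cut_sites$chrom)
  chroms <- names(genome)
  chrom_len <- nchar(genome[[1]])
  n_redrawn <- 0L
  with_seed(sub_seed(config$seed, "events"), {
    nearest_cut <- function(chrom, pos, max_dist = 2000L) {
      cuts <- cuts_by_chrom[[chrom]]
      if (is.null(cuts) || !length(cuts)) return(NA_integer_)
      i <- findInterval(pos, cuts)
      cand <- cuts[pmax(pmin(c(i, i + 1L), length(cuts)), 1L)]
      best <- cand[which.min(abs(cand - pos))]
      if (abs(best - pos) > max_dist) NA_integer_ else best
    }
    ns <- config$pairs_signal
    nn <- config$pairs_noise
    # signal: loops sampled uniformly; anchor cut sites precomputed per loop
    sig <- NULL
    if (ns > 0) {
      if (nrow(truth$loops) == 0) stop("no loops planted but pairs_signal > 0")
      anchor_cut1 <- vapply(seq_len(nrow(truth$loops)), function(l) {
        nearest_cut(truth$loops$chrom[l], truth$loops$anchor1_pos[l])
      }, numeric(1))
      anchor_cut2 <- vapply(seq_len(nrow(truth$loops)), function(l) {
        nearest_cut(truth$loops$chrom[l], truth$loops$anchor2_pos[l])
      }, numeric(1))
      usable_loops <- which(!is.na(anchor_cut1) & !is.na(anchor_cut2))
      if (!length(usable_loops)) stop("no loop anchor has a nearby cut site")
      li <- sample(usable_loops, ns, replace = TRUE)
      n_redrawn <- n_redrawn +
        (nrow(truth$loops) - length(usable_loops))
      sig <- data.frame(
        type = "signal", loop_id = truth$loops$loop_id[li],
        chrom1 = truth$loops$chrom[li], cut1 = anchor_cut1[li],
        chrom2 = truth$loops$chrom[li], cut2 = anchor_cut2[li],
        stringsAsFactors = FALSE)
    }
    # noise: uniform cut sites, cross-chromosome with prob trans_fraction
    noi <- NULL
    if (nn > 0) {
      ch1 <- sample(chroms, nn, replace = TRUE)
      is_trans <- runif(nn) < config$trans_fraction & config$n_chroms > 1
      ch2 <- ifelse(is_trans,
                    vapply(ch1, function(x) {
                      sample(setdiff(chroms, x), 1L)
                    }, character(1)),
                    ch1)
      pick_cut <- function(chrom) {
        cuts <- cuts_by_chrom[[chrom]]
        cuts[sample.int(length(cuts), 1L)]
      }
      cut1 <- vapply(ch1, pick_cut, numeric(1))
      cut2 <- vapply(ch2, pick_cut, numeric(1))
      # avoid degenerate identical-end events
      same <- ch1 == ch2 & cut1 == cut2
      while (any(same)) {
        cut2[same] <- vapply(ch2[same], pick_cut, numeric(1))
        same <- ch1 == ch2 & cut1 == cut2
      }
      noi <- data.frame(type = "noise", loop_id = NA_integer_,
                        chrom1 = ch1, cut1 = cut1, chrom2 = ch2, cut2 = cut2,
                        stringsAsFactors = FALSE)
    }
    ev <- rbind(sig, noi)
    rownames(ev) <- NULL
    n <- nrow(ev)
    ev <- cbind(
      data.frame(event_id = seq_len(n)),
      ev,
      data.frame(
        side1 = sample(c("left", "right"), n, replace = TRUE),
        armlen1 = sample(seq(config$arm_range[1], config$arm_range[2]), n,
                         replace = TRUE),
        flip1 = runif(n) < 0.5,
        side2 = sample(c("left", "right"), n, replace = TRUE),
        armlen2 = sample(seq(config$arm_range[1], config$arm_range[2]), n,
                         replace = TRUE),
        flip2 = runif(n) < 0.5,
        stringsAsFactors = FALSE
      )
    )
    # clip arms at chromosome ends
    ev$armlen1 <- with(ev, ifelse(side1 == "left", pmin(armlen1, cut1),
                                  pmin(armlen1, chrom_len - cut1)))
    ev$armlen2 <- with(ev, ifelse(side2 == "left", pmin(armlen2, cut2),
                                  pmin(armlen2, chrom_len - cut2)))
    attr(ev, "n_redrawn") <- n_redrawn
    ev
  })
}

# Junction insert between the two arms: half_A + revcomp(half_B) for
# two-step (each mate then reads one 15-mer half), the full 20-mer for
# one-step. Randomly inverted per molecule (linker orientation in the
# junction is not controlled by ligation).
linker_insert <- function(linkers) {
  if (linkers$mode == "two-step") {
    paste0(linkers$half_A, revcomp(linkers$half_B))
  } else {
    linkers$full
  }
}

#' Emit paired reads for junction molecules
#'
#' Builds each junction molecule as `arm1' + linker insert + arm2'`
#' (arms oriented toward the junction, independently flipped per the
#' event table, linker insert inverted with probability 0.5), injects
#' duplicate molecules at `duplicate_rate`, reads `read_length` bases
#' from both molecule ends (mate 2 reverse-complemented; reads are
#' truncated for short molecules), and applies i.i.d. substitution
#' errors. Every read pair has one provenance record.
#'
#' @param events event table from [simulate_ligation_events()].
#' @param genome genome from [make_genome()].
#' @param config a [sim_config()].
#' @param linkers a [linker_set()]; defaults to the configured mode.
#' @return list of class `sim_reads` with `reads1`, `reads2`, `read_ids`
#'   and `provenance` (data.frame; one row per read pair with the source
#'   `event_id`, `molecule_id`, `is_duplicate`, per-mate tag length,
#'   linker offset (`NA` when the junction lies beyond the read),
#'   error counts in the tag region and in the first
#'   `min(15, linker length)` junction bases).
#' @export
emit_reads <- function(events, genome, config,
                       linkers = linker_set(config$linker_mode)) {
  stopifnot(inherits(config, "sim_config"))
  insert <- linker_insert(linkers)
  ins_len <- nchar(insert)
  rl <- config$read_length
  if (rl < config$arm_range[1]) {
    stop("read_length shorter than the minimum sonication arm is infeasible")
  }
  with_seed(sub_seed(config$seed, "reads"), {
    n_ev <- nrow(events)
    n_dup <- rbinom(1, n_ev, config$duplicate_rate)
    dup_src <- if (n_dup > 0) sample.int(n_ev, n_dup, replace = TRUE) else
      integer(0)
    mol_src <- c(seq_len(n_ev), dup_src)
    n_mol <- length(mol_src)

    arm_seq <- function(chrom, cut, side, armlen, flip) {
      # arm adjacent to the cut, oriented toward the junction:
      # left fragment reads '+' into the cut, right fragment reads
      # revcomp away from it; `flip` inverts the arm (opposite strand
      # sequenced)
      s <- ifelse(side == "left", cut - armlen, cut)
      seqs <- character(length(chrom))
      for (ch in unique(chrom)) {
        i <- chrom == ch
        seqs[i] <- substring(genome[[ch]], s[i] + 1, s[i] + armlen[i])
      }
      toward <- ifelse(side == "left", seqs, revcomp(seqs))
      ifelse(flip, revcomp(toward), toward)
    }
    ev <- events[mol_src, , drop = FALSE]
    arm1 <- arm_seq(ev$chrom1, ev$cut1, ev$side1, ev$armlen1, ev$flip1)
    arm2 <- arm_seq(ev$chrom2, ev$cut2, ev$side2, ev$armlen2, ev$flip2)
    ins_flip <- runif(n_mol) < 0.5
    ins <- ifelse(ins_flip, revcomp(insert), insert)
    molecule <- paste0(arm1, ins, arm2)
    mol_len <- nchar(molecule)

    r1_len <- pmin(rl, mol_len)
    r2_len <- pmin(rl, mol_len)
    reads1 <- substr(molecule, 1L, r1_len)
    reads2 <- revcomp(substring(molecule, mol_len - r2_len + 1L, mol_len))

    # i.i.d. substitution errors; returns per-read error positions
    add_errors <- function(reads) {
      lens <- nchar(reads)
      nerr <- rbinom(length(reads), lens, config$error_rate)
      err_pos <- vector("list", length(reads))
      idx <- which(nerr > 0)
      bases <- c("A", "C", "G", "T")
      for (i in idx) {
        pos <- sample.int(lens[i], nerr[i])
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        for (p in pos) {
          ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        }
        reads[i] <- paste(ch, collapse = "")
        err_pos[[i]] <- sort(pos)
      }
      list(reads = reads, err_pos = err_pos)
    }
    e1 <- add_errors(reads1)
    e2 <- add_errors(reads2)

    # provenance: junction offsets and error bookkeeping per mate
    arm1_len <- nchar(arm1)
    arm2_len <- nchar(arm2)
    tag1_len <- pmin(arm1_len, r1_len)
    tag2_len <- pmin(arm2_len, r2_len)
    half_len <- min(15L, ins_len)
    linker_off1 <- ifelse(arm1_len + half_len <= r1_len, arm1_len,
                          NA_integer_)
    linker_off2 <- ifelse(arm2_len + half_len <= r2_len, arm2_len,
                          NA_integer_)
    count_in <- function(err_pos, lo, hi) {
      vapply(seq_along(err_pos), function(i) {
        if (is.null(err_pos[[i]])) 0L else
          sum(err_pos[[i]] > lo[i] & err_pos[[i]] <= hi[i])
      }, integer(1))
    }
    zero <- rep(0L, n_mol)
    prov <- data.frame(
      read_id = sprintf("pair%06d", seq_len(n_mol)),
      molecule_id = mol_src,
      event_id = ev$event_id,
      type = ev$type,
      loop_id = ev$loop_id,
      is_duplicate = seq_len(n_mol) > n_ev,
      tag1_len = tag1_len, tag2_len = tag2_len,
      linker_off1 = linker_off1, linker_off2 = linker_off2,
      err_tag1 = count_in(e1$err_pos, zero, tag1_len),
      err_tag2 = count_in(e2$err_pos, zero, tag2_len),
      err_linker1 = count_in(e1$err_pos, arm1_len,
                             pmin(arm1_len + half_len, r1_len)),
      err_linker2 = count_in(e2$err_pos, arm2_len,
                             pmin(arm2_len + half_len, r2_len)),
      read1_len = r1_len, read2_len = r2_len,
      stringsAsFactors = FALSE
    )
    structure(list(reads1 = e1$reads, reads2 = e2$reads,
                   read_ids = prov$read_id, provenance = prov),
              class = "sim_reads")
  })
}

#' Simulate a complete synthetic library
#'
#' Runs [plant_sites_and_loops()], [make_genome()],
#' [simulate_ligation_events()] and [emit_reads()] under the config's
#' master seed. Optionally writes FASTA, chrom.sizes, paired FASTQ and
#' truth tables to `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list of class `sim_library`: `config`, `genome`, `truth`,
#'   `events`, `reads`.
#' @export
simulate_library <- function(config = sim_config(), out_dir = NULL) {
  truth <- plant_sites_and_loops(config)
  genome <- make_genome(config, truth)
  events <- simulate_ligation_events(truth, genome, config)
  reads <- emit_reads(events, genome, config)
  lib <- structure(list(config = config, genome = genome, truth = truth,
                        events = events, reads = reads),
                   class = "sim_library")
  if (!is.null(out_dir)) write_sim_library(lib, out_dir)
  lib
}

#' @exportS3Method base::print
print.sim_library <- function(x, ...) {
  cat(sprintf(
    "sim_library: %g bp on %d chroms, %d sites, %d loops, %d read pairs\n",
    x$config$genome_length, x$config$n_chroms, nrow(x$truth$sites),
    nrow(x$truth$loops), length(x$reads$reads1)))
  invisible(x)
}

#' Write a simulated library to disk
#'
#' Emits `genome.fa`, `chrom.sizes`, `reads_1.fastq`, `reads_2.fastq`,
#' `sites.bed`, `loops.bedpe`, `provenance.tsv` and `config.json`.
#'
#' @param lib a `sim_library`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_sim_library <- function(lib, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- Biostrings::DNAStringSet(unclass(lib$genome))
  Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
  sizes <- attr(lib$genome, "chrom_sizes")
  utils::write.table(
    data.frame(chrom = names(sizes), size = as.integer(sizes)),
    file.path(out_dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_fastq(lib$reads$reads1, lib$reads$read_ids,
              file.path(out_dir, "reads_1.fastq"))
  write_fastq(lib$reads$reads2, lib$reads$read_ids,
              file.path(out_dir, "reads_2.fastq"))
  sites <- lib$truth$sites
  utils::write.table(
    data.frame(sites$chrom, sites$start, sites$end,
               paste0("site", sites$site_id), 0L, sites$strand),
    file.path(out_dir, "sites.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  loops <- lib$truth$loops
  w <- lib$config$site_width
  utils::write.table(
    data.frame(loops$chrom, loops$anchor1_pos - w, loops$anchor1_pos + w,
               loops$chrom, loops$anchor2_pos - w, loops$anchor2_pos + w,
               paste0("loop", loops$loop_id)),
    file.path(out_dir, "loops.bedpe"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(lib$reads$provenance,
                     file.path(out_dir, "provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- lib$config
  cfg$enzyme <- unclass(cfg$enzyme)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Designed recoverable fraction of a simulated library
#'
#' From the generator's own provenance: a mate is recoverable when its
#' genomic tag is at least `min_tag_len`, error-free, and either the
#' junction lies beyond the read (the whole read is genomic) or the
#' half-linker carries at most `max_mismatch` errors (so trimming finds
#' the planted junction). A pair is designed-recoverable when both mates
#' are recoverable and the pair is not a near-diagonal
#' (self-ligation-like) cis event. Because deduplication works on mapped
#' coordinates, recoverable pairs are reduced to their expected PET
#' coordinate tuples (the tag 5' position is the sonication breakpoint
#' or the cut site, depending on arm side and orientation) and distinct
#' tuples are counted. This is the yardstick the processing pipeline's
#' `unique_pet_fraction` is compared against.
#'
#' @param lib a `sim_library`.
#' @param min_tag_len minimum usable tag length.
#' @param max_mismatch linker mismatch tolerance assumed for detection.
#' @param self_ligation_cutoff cis distance excluded as self-ligation.
#' @return list with `recoverable_fraction` (distinct expected PETs /
#'   total read pairs), `n_recoverable`, `n_pairs` and the designed
#'   `cis_fraction` among distinct recoverable PETs.
#' @export
designed_recovery <- function(lib, min_tag_len = 15L, max_mismatch = 1L,
                              self_ligation_cutoff = 1000L) {
  pv <- lib$reads$provenance
  mate_ok <- function(tag_len, read_len, off, err_tag, err_linker) {
    full_genomic <- is.na(off) & tag_len == read_len
    with_junction <- !is.na(off)
    ok_full <- full_genomic & err_tag == 0
    ok_junc <- with_junction & err_tag == 0 & err_linker <= max_mismatch
    (ok_full | ok_junc) & tag_len >= min_tag_len
  }
  ok1 <- mate_ok(pv$tag1_len, pv$read1_len, pv$linker_off1, pv$err_tag1,
                 pv$err_linker1)
  ok2 <- mate_ok(pv$tag2_len, pv$read2_len, pv$linker_off2, pv$err_tag2,
                 pv$err_linker2)
  ev <- lib$events[pv$event_id, ]
  self_lig <- ev$chrom1 == ev$chrom2 &
    abs(ev$cut2 - ev$cut1) < self_ligation_cutoff
  ok <- ok1 & ok2 & !self_lig
  # expected tag 5' coordinate and strand per mate, mirroring the aligner's
  # conventions (arms read toward the junction; `flip` inverts the arm)
  end_coord <- function(cut, side, armlen, flip) {
    pos <- ifelse(side == "left",
                  ifelse(flip, cut - 1L, cut - armlen),
                  ifelse(flip, cut, cut + armlen - 1L))
    strand <- ifelse(side == "left",
                     ifelse(flip, "-", "+"),
                     ifelse(flip, "+", "-"))
    list(pos = pos, strand = strand)
  }
  e1 <- end_coord(ev$cut1, ev$side1, ev$armlen1, ev$flip1)
  e2 <- end_coord(ev$cut2, ev$side2, ev$armlen2, ev$flip2)
  swap <- ev$chrom1 > ev$chrom2 |
    (ev$chrom1 == ev$chrom2 & e1$pos > e2$pos)
  key <- ifelse(swap,
                paste(ev$chrom2, e2$pos, e2$strand,
                      ev$chrom1, e1$pos, e1$strand),
                paste(ev$chrom1, e1$pos, e1$strand,
                      ev$chrom2, e2$pos, e2$strand))
  rec_keys <- unique(key[ok])
  cis <- (ev$chrom1 == ev$chrom2)[ok][!duplicated(key[ok])]
  list(
    recoverable_fraction = length(rec_keys) / nrow(pv),
    n_recoverable = length(rec_keys),
    n_pairs = nrow(pv),
    cis_fraction = mean(cis)
  )
}

#' Write reads as FASTQ
#'
#' Constant quality strings; quality-aware processing is out of scope.
#'
#' @param reads character vector of read sequences.
#' @param ids read identifiers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, ids, path) {
  qual <- vapply(nchar(reads), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1))
  lines <- as.vector(rbind(paste0("@", ids), reads, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 mate FASTQ paths.
#' @return list with `reads1`, `reads2`, `ids`.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  list(reads1 = unname(as.character(r1)), reads2 = unname(as.character(r2)),
       ids = sub(" .*", "", names(r1)))
}
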