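# Independent brute-force oracles used by the property tests.

# leftmost occurrence of `pattern` in `text` with <= k substitutions;
# returns c(position (0-based), mismatches) or NULL
naive_hamming_search <- function(text, pattern, k) {
  tr <- charToRaw(text)
  pr <- charToRaw(pattern)
  n <- length(tr)
  m <- length(pr)
  if (m == 0 || m > n) return(NULL)
  for (s in 0:(n - m)) {
    mm <- sum(tr[(s + 1):(s + m)] != pr)
    if (mm <= k) return(c(s, mm))
  }
  NULL
}

# all occurrence start positions (0-based, overlapping) of `pattern`
naive_find_all <- function(text, pattern) {
  tr <- charToRaw(text)
  pr <- charToRaw(pattern)
  n <- length(tr)
  m <- length(pr)
  if (m > n) return(integer(0))
  which(vapply(0:(n - m), function(s) {
    all(tr[(s + 1):(s + m)] == pr)
  }, logical(1))) - 1L
}

# O(n*m) interval overlap: for each query row, does it overlap any subject?
# intervals are 0-based half-open data.frames chrom/start/end
naive_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small simulated library shared across test files (built once)
small_lib <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 2e5, n_chroms = 2, n_sites = 40,
                        n_loops = 10, pairs_signal = 4500, pairs_noise = 500,
                        seed = 7)
      cache <<- simulate_library(cfg)
    }
    cache
  }
})

small_processed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lib <- small_lib()
      cache <<- process_library(lib$reads$reads1, lib$reads$reads2,
                                lib$genome,
                                linkers = linker_set(lib$config$linker_mode))
    }
    cache
  }
})
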