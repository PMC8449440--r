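# Independent oracles used across the suite.  Each re-derives the expected
# quantity by a different route than the implementation (exhaustive
# dynamic programming, transitive chaining, direct string comparison).

# Optimal global alignment score by exhaustive three-state dynamic
# programming over all alignment paths; a gap of length k costs
# open + k * ext (the convention the package documents).
oracle_align_score <- function(a, b, match = 5, mismatch = -4,
                               open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {  # gap in b
      cost <- ext + if (last != "D") open else 0
      best <- max(best, -cost + rec(i + 1, j, "D"))
    }
    if (j <= m) {  # gap in a
      cost <- ext + if (last != "I") open else 0
      best <- max(best, -cost + rec(i, j + 1, "I"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# Transitive chaining of sorted hits: merge consecutive elements whose
# intervening gap is within [0, max_gap]; clusters are components of
# size >= 2.  Returns a list of member element_id vectors, in genomic
# order.
oracle_chain_clusters <- function(hits, max_gap = 100) {
  out <- list()
  for (sq in unique(hits$seqid)) {
    h <- hits[hits$seqid == sq, ]
    h <- h[order(h$start, h$end), ]
    n <- nrow(h)
    if (n < 2) next
    comp <- seq_len(n)
    for (i in seq_len(n - 1)) {
      gap <- h$start[i + 1] - h$end[i] - 1L
      if (gap >= 0 && gap <= max_gap) {
        comp[comp == comp[i + 1]] <- comp[i]
      }
    }
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      if (length(idx) >= 2) out[[length(out) + 1]] <- h$element_id[idx]
    }
  }
  out
}

# Random hit table on one sequence for layout-based tests.
random_layout <- function(n, slen = 50000, elem_len = c(100, 500)) {
  starts <- sort(sample(slen - elem_len[2], n))
  lens <- sample(seq(elem_len[1], elem_len[2]), n, replace = TRUE)
  ends <- pmin(starts + lens - 1L, slen)
  data.frame(element_id = sprintf("R%03d", seq_len(n)), seqid = "chrT",
             start = starts, end = ends,
             strand = sample(c("+", "-"), n, replace = TRUE),
             family = "FAM", cons_start = 1L, cons_end = 100L,
             cons_length = 100L, stringsAsFactors = FALSE)
}

# Hamming distance of equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Small shared fixture: one modest synthetic genome reused by several
# files (rebuilt once per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(genome_length = 150000, n_genes = 6,
                              n_mt = 16, n_ml = 6, n_other = 4,
                              n_ms_tracts = 6,
                              divergence_grid = list(c(0, 0), c(0.05, 0.02)),
                              seed = 404)
      cache <<- build_genome(cfg)
    }
    cache
  }
})
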