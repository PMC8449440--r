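# Element-versus-consensus divergence: global alignment, transition and
# transversion site proportions, Kimura two-parameter distance,
# conservation, coverage, and the binned divergence landscape.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (EMBOSS-Needle-style scoring defaults:
#' match +5, mismatch -4, gap open 10, gap extend 0.5) computed with the
#' Biostrings alignment engine.  A gap of length k costs
#' \code{gap_open + k * gap_extend}.
#'
#' @param seq_a,seq_b DNA strings (non-empty).
#' @param match Match score.
#' @param mismatch Mismatch score.
#' @param gap_open Gap opening cost (positive).
#' @param gap_extend Per-base gap extension cost (positive).
#' @return List of class \code{mitesat_alignment}: aligned_a, aligned_b
#'   (gapped strings of equal length), score.
#' @export
align_global <- function(seq_a, seq_b, match = 5, mismatch = -4,
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b,
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend,
                                       type = "global")
  out <- list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
              aligned_b = as.character(Biostrings::alignedSubject(aln)),
              score = Biostrings::score(aln))
  class(out) <- "mitesat_alignment"
  out
}

#' @export
print.mitesat_alignment <- function(x, ...) {
  cat("Global alignment, score", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Transition and transversion site proportions of an alignment
#'
#' Computed over columns with a base in both rows; gap and N columns are
#' excluded from the denominator.  Transitions are A<->G and C<->T;
#' transversions are all other mismatches.
#'
#' @param alignment A \code{mitesat_alignment}.
#' @return Named numeric vector c(p, q).
#' @export
count_p_q <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  usable <- a %in% BASES & b %in% BASES
  if (!any(usable)) stop("no usable (gap-free, non-N) alignment columns")
  a <- a[usable]; b <- b[usable]
  diff <- a != b
  purine <- c("A", "G")
  same_type <- (a %in% purine) == (b %in% purine)
  p <- sum(diff & same_type) / length(a)
  q <- sum(diff & !same_type) / length(a)
  c(p = p, q = q)
}

#' Kimura two-parameter distance
#'
#' K = -1/2 ln(1 - 2p - q) - 1/4 ln(1 - 2q), where p and q are the
#' proportions of transition and transversion sites.  Outside the formula's
#' domain (1 - 2p - q <= 0 or 1 - 2q <= 0) the divergence is saturated:
#' by default an error is raised; if \code{cap} is given, that value is
#' returned instead.
#'
#' @param p Transition site proportion (vectorized).
#' @param q Transversion site proportion (vectorized).
#' @param cap Optional finite value returned on domain violation.
#' @return Kimura distance(s).
#' @export
kimura_distance <- function(p, q, cap = NULL) {
  stopifnot(length(p) == length(q))
  if (any(p < 0 | q < 0)) stop("p and q must be non-negative")
  bad <- (1 - 2 * p - q) <= 0 | (1 - 2 * q) <= 0
  if (any(bad) && is.null(cap)) {
    stop("saturated divergence: 1 - 2p - q or 1 - 2q is not positive")
  }
  k <- -0.5 * log(pmax(1 - 2 * p - q, .Machine$double.xmin)) -
    0.25 * log(pmax(1 - 2 * q, .Machine$double.xmin))
  if (any(bad)) k[bad] <- cap
  k
}

#' Percent identity of an alignment
#'
#' Identical columns divided by total alignment length (gap columns count
#' in the denominator), times 100.
#'
#' @param alignment A \code{mitesat_alignment}.
#' @return Percent in [0, 100].
#' @export
conservation <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Percent of the consensus covered by a hit
#'
#' @param hits Hit table.
#' @return Numeric vector of percents.
#' @export
coverage <- function(hits) {
  validate_hits(hits)
  100 * (hits$cons_end - hits$cons_start + 1) / hits$cons_length
}

#' Per-element divergence statistics against the family consensus
#'
#' Aligns each element (reverse-complemented first for minus-strand hits)
#' globally to its family consensus and reports p, q, Kimura distance,
#' percent conservation and percent consensus coverage.
#'
#' @param hits Hit table.
#' @param genome Named character vector of sequences.
#' @param consensi Named character vector of family consensus sequences.
#' @param cap Optional cap forwarded to [kimura_distance()].
#' @return Data frame: element_id, family, p, q, K, conservation, coverage.
#' @export
divergence_stats <- function(hits, genome, consensi, cap = NULL) {
  validate_hits(hits)
  cov <- coverage(hits)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    seq <- subseq_checked(genome[[h$seqid]], h$start, h$end)
    if (h$strand == "-") seq <- revcomp(seq)
    aln <- align_global(seq, consensi[[h$family]])
    pq <- count_p_q(aln)
    data.frame(element_id = h$element_id, family = h$family,
               p = pq[["p"]], q = pq[["q"]],
               K = kimura_distance(pq[["p"]], pq[["q"]], cap = cap),
               conservation = conservation(aln), coverage = cov[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binned Kimura divergence landscape
#'
#' Counts elements per half-open K bin [k, k + bin_width), per family and
#' (optionally) per class.
#'
#' @param stats Result of [divergence_stats()].
#' @param bin_width Bin width on the K axis.
#' @param classes Optional classification table (element_id, label).
#' @return Data frame: family, class, bin_start, count.
#' @export
divergence_landscape <- function(stats, bin_width = 0.01, classes = NULL) {
  if (!nrow(stats)) {
    return(data.frame(family = character(0), class = character(0),
                      bin_start = numeric(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  cls <- if (is.null(classes)) {
    rep("all", nrow(stats))
  } else {
    classes$label[match(stats$element_id, classes$element_id)]
  }
  bin <- floor(stats$K / bin_width) * bin_width
  agg <- stats::aggregate(list(count = rep(1L, nrow(stats))),
                          by = list(family = stats$family, class = cls,
                                    bin_start = bin), FUN = sum)
  agg <- agg[order(agg$family, agg$class, agg$bin_start), ]
  rownames(agg) <- NULL
  agg
}
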