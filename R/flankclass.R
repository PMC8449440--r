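# Flanking-microsatellite and TSD evidence, and the mt / ml / other call.
#
# Classification rule: an element flanked by dinucleotide microsatellite
# runs on BOTH sides is microsatellite-targeting (mt); an element with NO
# flanking run on either side but a 9/10-bp target site duplication is
# Mutator-like (ml); everything else is "other".

CANONICAL_MOTIF <- c(TA = "TA", AT = "TA", GA = "GA", AG = "GA",
                     CT = "CT", TC = "CT")

canonicalize_motifs <- function(motifs) {
  unknown <- setdiff(motifs, names(CANONICAL_MOTIF))
  if (length(unknown)) stop("unsupported motif: ", paste(unknown, collapse = ","))
  unique(unname(CANONICAL_MOTIF[motifs]))
}

#' Find dinucleotide microsatellite runs
#'
#' Detects maximal, non-extendable runs of alternating dinucleotides.
#' A run is seeded by a perfect alternation of the two motif letters and,
#' when \code{max_mismatch_per_run > 0}, may absorb up to that many
#' single-base interruptions between perfect segments.  The motif is
#' reported in canonical phase (TA, GA, CT; the actual phase is the first
#' base at the run start).  Overlapping candidate runs of different motifs
#' are resolved to the longer run, ties to the leftmost.
#'
#' The defaults (perfect runs of at least 8 units, i.e. 16 bp) approximate
#' a Tandem Repeats Finder screen for dinucleotide repeats at minimum
#' alignment score 30 with match weight 2, but are reproducible and
#' dependency-free.
#'
#' @param sequence A DNA string.
#' @param motifs Dinucleotide motifs to scan (any phase; canonicalized).
#' @param min_units Minimum number of repeat units (>= 2).
#' @param max_mismatch_per_run Interior mismatches tolerated per run.
#' @return Data frame: start, end, motif, unit_count, purity.
#' @export
find_dinucleotide_runs <- function(sequence,
                                   motifs = c("TA", "GA", "CT"),
                                   min_units = 8,
                                   max_mismatch_per_run = 0) {
  stopifnot(min_units >= 2)
  motifs <- canonicalize_motifs(motifs)
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit_count = integer(0),
                      purity = numeric(0), stringsAsFactors = FALSE)
  if (n < 2 * min_units) return(empty)
  chars <- strsplit(sequence, "")[[1]]

  runs_for_motif <- function(motif) {
    letters2 <- c(substr(motif, 1, 1), substr(motif, 2, 2))
    ok <- chars %in% letters2
    alt <- c(TRUE, chars[-1] != chars[-n])
    cont <- ok & c(FALSE, ok[-n]) & alt
    newrun <- ok & !cont
    if (!any(ok)) return(NULL)
    gid <- cumsum(newrun)
    starts <- which(newrun)
    ends <- vapply(split(which(ok), gid[ok]), max, 1L)
    segs <- data.frame(start = starts, end = unname(ends))
    segs$mism <- 0L
    if (max_mismatch_per_run > 0 && nrow(segs) > 1) {
      # absorb single-base interruptions while the budget allows
      merged <- segs[1, ]
      for (i in 2:nrow(segs)) {
        last <- nrow(merged)
        gap <- segs$start[i] - merged$end[last] - 1L
        # one imputed base can restore alternation only when the characters
        # flanking the gap are equal (s[i-1] != s[i] != s[i+1] forces it)
        phase_ok <- gap == 1L &&
          chars[merged$end[last]] == chars[segs$start[i]]
        if (phase_ok && merged$mism[last] + 1L <= max_mismatch_per_run) {
          merged$end[last] <- segs$end[i]
          merged$mism[last] <- merged$mism[last] + 1L
        } else {
          merged <- rbind(merged, segs[i, ])
        }
      }
      segs <- merged
    }
    segs$motif <- motif
    segs
  }

  cand <- do.call(rbind, lapply(motifs, runs_for_motif))
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand$len <- cand$end - cand$start + 1L
  cand$unit_count <- cand$len %/% 2L
  cand <- cand[cand$unit_count >= min_units, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  # longer run wins overlaps; ties go to the leftmost
  cand <- cand[order(-cand$len, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & cand$start <= cand$end[i] & cand$end >= cand$start[i]
    keep[i] <- !any(ov)
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  data.frame(start = cand$start, end = cand$end, motif = cand$motif,
             unit_count = cand$unit_count,
             purity = (cand$len - cand$mism) / cand$len,
             stringsAsFactors = FALSE)
}

#' Profile the microsatellite flanks of one element
#'
#' Scans \code{search_window} bp on each side of the element for
#' dinucleotide runs.  A run counts as flanking when its inner edge lies
#' within \code{max_offset} bp of the element terminus.  (GA)n-at-5'-end
#' and (CT)n-at-3'-end flags are computed strand-aware: for a minus-strand
#' element the 5' flank is the right genomic flank and motifs are read in
#' reverse complement.
#'
#' @param hit One-row hit table (element coordinates).
#' @param genome Named character vector of sequences.
#' @param search_window Flank window scanned on each side, bp.
#' @param max_offset Maximum gap (bp) between run edge and element
#'   terminus for the run to count as flanking.
#' @param min_units,max_mismatch_per_run Passed to
#'   [find_dinucleotide_runs()].
#' @return One-row data frame: element_id, left_motif, left_units,
#'   right_motif, right_units, ta_sides, ga_5prime, ct_3prime,
#'   insufficient_flank.
#' @export
profile_flanks <- function(hit, genome, search_window = 60, max_offset = 2,
                           min_units = 8, max_mismatch_per_run = 0) {
  seq <- genome[[hit$seqid]]
  n <- nchar(seq)
  res <- data.frame(element_id = hit$element_id,
                    left_motif = NA_character_, left_units = NA_integer_,
                    right_motif = NA_character_, right_units = NA_integer_,
                    ta_sides = "none", ga_5prime = FALSE, ct_3prime = FALSE,
                    insufficient_flank = FALSE, stringsAsFactors = FALSE)
  if (hit$start - search_window < 1 || hit$end + search_window > n) {
    res$insufficient_flank <- TRUE
    return(res)
  }
  left_seq <- substring(seq, hit$start - search_window, hit$start - 1L)
  right_seq <- substring(seq, hit$end + 1L, hit$end + search_window)
  lruns <- find_dinucleotide_runs(left_seq, min_units = min_units,
                                  max_mismatch_per_run = max_mismatch_per_run)
  rruns <- find_dinucleotide_runs(right_seq, min_units = min_units,
                                  max_mismatch_per_run = max_mismatch_per_run)
  # flanking = inner edge within max_offset of the terminus
  lruns <- lruns[search_window - lruns$end <= max_offset, , drop = FALSE]
  rruns <- rruns[rruns$start - 1L <= max_offset, , drop = FALSE]
  lrun <- if (nrow(lruns)) lruns[which.max(lruns$end), ] else NULL
  rrun <- if (nrow(rruns)) rruns[which.min(rruns$start), ] else NULL
  if (!is.null(lrun)) {
    res$left_motif <- lrun$motif
    res$left_units <- lrun$unit_count
  }
  if (!is.null(rrun)) {
    res$right_motif <- rrun$motif
    res$right_units <- rrun$unit_count
  }
  lta <- !is.null(lrun) && lrun$motif == "TA"
  rta <- !is.null(rrun) && rrun$motif == "TA"
  res$ta_sides <- if (lta && rta) "both" else if (lta) "left" else
    if (rta) "right" else "none"
  if (hit$strand == "+") {
    res$ga_5prime <- !is.null(lrun) && lrun$motif == "GA"
    res$ct_3prime <- !is.null(rrun) && rrun$motif == "CT"
  } else {
    # 5' flank of a minus-strand element is the right genomic flank;
    # (GA)n on the element strand reads as (TC)n -> canonical CT on the
    # plus strand, and vice versa
    res$ga_5prime <- !is.null(rrun) && rrun$motif == "CT"
    res$ct_3prime <- !is.null(lrun) && lrun$motif == "GA"
  }
  res
}

#' Detect a 9/10-bp target site duplication
#'
#' Compares the k bases immediately left of the element with the k bases
#' immediately right, for k = 10 then k = 9 (longer duplication
#' preferred).  A call is made when the two sides differ at no more than
#' \code{max_mismatch} positions.
#'
#' @param hit One-row hit table.
#' @param genome Named character vector of sequences.
#' @param lengths Candidate duplication lengths, tried longest first.
#' @param max_mismatch Maximum Hamming mismatches for a call.
#' @return One-row data frame: element_id, tsd_length (NA when no call),
#'   left_seq, right_seq, mismatches.
#' @export
detect_tsd <- function(hit, genome, lengths = c(10L, 9L), max_mismatch = 1) {
  seq <- genome[[hit$seqid]]
  n <- nchar(seq)
  res <- data.frame(element_id = hit$element_id, tsd_length = NA_integer_,
                    left_seq = NA_character_, right_seq = NA_character_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  lengths <- sort(as.integer(lengths), decreasing = TRUE)
  for (k in lengths) {
    if (hit$start - k < 1 || hit$end + k > n) next
    left <- substring(seq, hit$start - k, hit$start - 1L)
    right <- substring(seq, hit$end + 1L, hit$end + k)
    mism <- sum(strsplit(left, "")[[1]] != strsplit(right, "")[[1]])
    if (mism <= max_mismatch) {
      res$tsd_length <- k
      res$left_seq <- left
      res$right_seq <- right
      res$mismatches <- mism
      return(res)
    }
  }
  res
}

#' Classify one element from its flank profile and TSD call
#'
#' mt: flanking dinucleotide runs on both sides.  ml: no flanking run on
#' either side and a 9/10-bp TSD.  other: everything else.  If both sets
#' of evidence were somehow present, mt takes precedence.
#'
#' @param profile One-row result of [profile_flanks()].
#' @param tsd One-row result of [detect_tsd()].
#' @return One of "mt", "ml", "other".
#' @export
classify_element <- function(profile, tsd) {
  has_left <- !is.na(profile$left_motif)
  has_right <- !is.na(profile$right_motif)
  if (has_left && has_right) return("mt")
  if (!has_left && !has_right && !is.na(tsd$tsd_length)) return("ml")
  "other"
}

#' Classify all elements in a hit table
#'
#' Runs [profile_flanks()], [detect_tsd()] and [classify_element()] over
#' every hit and returns the per-element classification table.
#'
#' @param hits Hit table.
#' @param genome Named character vector of sequences.
#' @param search_window,max_offset,min_units,max_mismatch_per_run Flank
#'   profiling parameters.
#' @param tsd_lengths,tsd_max_mismatch TSD detection parameters.
#' @return Data frame: element_id, label, ta_sides, left_motif,
#'   right_motif, tsd_length, tsd_mismatches, ga_5prime, ct_3prime,
#'   insufficient_flank.
#' @export
classify_elements <- function(hits, genome, search_window = 60,
                              max_offset = 2, min_units = 8,
                              max_mismatch_per_run = 0,
                              tsd_lengths = c(10L, 9L),
                              tsd_max_mismatch = 1) {
  validate_hits(hits)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    prof <- profile_flanks(h, genome, search_window, max_offset,
                           min_units, max_mismatch_per_run)
    tsd <- detect_tsd(h, genome, tsd_lengths, tsd_max_mismatch)
    data.frame(element_id = h$element_id,
               label = classify_element(prof, tsd),
               ta_sides = prof$ta_sides,
               left_motif = prof$left_motif,
               right_motif = prof$right_motif,
               tsd_length = tsd$tsd_length,
               tsd_mismatches = tsd$mismatches,
               ga_5prime = prof$ga_5prime, ct_3prime = prof$ct_3prime,
               insufficient_flank = prof$insufficient_flank,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
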