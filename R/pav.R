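# Presence/absence-variation calling.
#
# Element level: the element plus 200-bp flanks is extracted from the
# source genome and searched in the target genome; "present" requires the
# whole query (flanks and element co-located) to be found with at least
# 90% identity.  Cluster level: the four-condition rule (member number and
# order, family and orientation, pairwise member identity >= 90%, flank
# identity >= 90%) with deletion / insertion / substitution event calls.
# Read level: a properly paired fragment span must cover the element plus
# 50-bp margins.

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  out <- Biostrings::DNAStringSet(unlist(x))
  if (is.null(names(out))) names(out) <- names(x)
  out
}

#' Extract an element query with flanks
#'
#' @param hit One-row hit table.
#' @param genome Named character vector of sequences.
#' @param flank Flank length each side, bp.
#' @return List: seq, elem_start, elem_end (element offsets inside the
#'   query, 1-based).
#' @export
extract_query <- function(hit, genome, flank = 200) {
  flank <- as.integer(flank)
  seq <- genome[[hit$seqid]]
  if (hit$start - flank < 1 || hit$end + flank > nchar(seq)) {
    stop("insufficient flank for element ", hit$element_id)
  }
  list(seq = substring(seq, hit$start - flank, hit$end + flank),
       elem_start = flank + 1L,
       elem_end = flank + (hit$end - hit$start + 1L))
}

#' Search a query sequence in a target genome
#'
#' Seed-and-extend homology search: exact k-mer anchors from the query are
#' located in the target, chained by diagonal, and each candidate window
#' is aligned locally to the query (match +5, mismatch -4, gap 10 + 0.5/bp).
#' The best hit by identity x query coverage is returned, or NULL when no
#' hit reaches both thresholds.  Identity is matches over alignment
#' columns; coverage is the aligned fraction of the query, so a match of
#' the flanks alone cannot mimic presence of the element.
#'
#' @param query DNA string.
#' @param target Named character vector of sequences (or DNAStringSet).
#' @param min_identity Minimum identity in [0, 1].
#' @param min_query_coverage Minimum aligned query fraction.
#' @param kmer Anchor length, bp.
#' @param anchor_step Distance between anchor start positions (default
#'   spreads ~16 anchors over the query).
#' @param all_hits If TRUE, return every candidate hit passing the
#'   thresholds (used for window re-annotation), not just the best.
#' @return One-row data frame (t_seqid, t_start, t_end, q_start, q_end,
#'   identity, coverage, score), a multi-row frame when
#'   \code{all_hits = TRUE}, or NULL.
#' @export
search_homolog <- function(query, target, min_identity = 0.90,
                           min_query_coverage = 0.90, kmer = 15,
                           anchor_step = NULL, all_hits = FALSE) {
  qlen <- nchar(query)
  if (qlen < kmer) stop("query shorter than kmer")
  tset <- as_dna_set(target)
  if (is.null(anchor_step)) {
    anchor_step <- max(1L, as.integer(ceiling((qlen - kmer + 1) / 16)))
  }
  apos <- unique(c(seq(1L, qlen - kmer + 1L, by = anchor_step), qlen - kmer + 1L))
  # low-complexity anchors (e.g. inside a dinucleotide tract) would seed at
  # every such tract in the genome; drop them, like a dust-masked search
  complex_enough <- vapply(apos, function(a) {
    length(unique(strsplit(substring(query, a, a + kmer - 1L), "")[[1]])) > 2L
  }, TRUE)
  apos <- apos[complex_enough]
  if (!length(apos)) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = FALSE)
  hits <- NULL
  for (s in seq_along(tset)) {
    tseq <- tset[[s]]
    tlen <- length(tseq)
    diags <- integer(0)
    for (a in apos) {
      m <- Biostrings::matchPattern(substring(query, a, a + kmer - 1L), tseq)
      if (length(m) && length(m) <= 100L) {  # repeat-derived anchors seed everywhere
        diags <- c(diags, BiocGenerics::start(m) - a + 1L)
      }
    }
    if (!length(diags)) next
    support <- table(diags)
    diags <- sort(unique(diags))
    # diagonals within half a query length belong to one candidate locus;
    # nearby family copies on more distant diagonals must stay separate
    gap_thr <- max(60L, min(400L, qlen %/% 2L))
    grp <- cumsum(c(TRUE, diff(diags) > gap_thr))
    # candidate loci ranked by anchor support; the true locus carries
    # anchors from flanks and element alike, dispersed family copies only
    # element-body anchors
    grp_support <- vapply(split(as.integer(support[as.character(diags)]), grp),
                          sum, 1L)
    grp_order <- order(-grp_support)
    if (!all_hits) grp_order <- grp_order[seq_len(min(8L, length(grp_order)))]
    done <- FALSE
    for (g in as.integer(names(grp_support))[grp_order]) {
      if (done) break
      d <- diags[grp == g]
      lo <- max(1L, min(d) - 200L)
      hi <- min(tlen, max(d) + qlen + 200L)
      if (hi - lo + 1L > 60000L) next  # runaway window; not a real locus
      win <- Biostrings::subseq(tseq, lo, hi)
      aln <- Biostrings::pairwiseAlignment(query, win,
                                           substitutionMatrix = mat,
                                           gapOpening = 10, gapExtension = 0.5,
                                           type = "local")
      acols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- Biostrings::nmatch(aln) / acols
      qr <- c(BiocGenerics::start(Biostrings::pattern(aln)),
              BiocGenerics::end(Biostrings::pattern(aln)))
      cov <- (qr[2] - qr[1] + 1) / qlen
      if (ident < min_identity || cov < min_query_coverage) next
      tr <- c(BiocGenerics::start(Biostrings::subject(aln)),
              BiocGenerics::end(Biostrings::subject(aln)))
      hits <- rbind(hits, data.frame(
        t_seqid = names(tset)[s], t_start = as.integer(lo + tr[1] - 1),
        t_end = as.integer(lo + tr[2] - 1),
        q_start = as.integer(qr[1]), q_end = as.integer(qr[2]),
        identity = ident, coverage = cov,
        score = Biostrings::score(aln), stringsAsFactors = FALSE))
      if (!all_hits && ident >= 0.98 && cov >= 0.98) done <- TRUE
    }
  }
  if (is.null(hits)) return(NULL)
  if (all_hits) return(hits)
  hits[which.max(hits$identity * hits$coverage), ]
}

#' Element-level presence/absence calls between two genomes
#'
#' @param hits Hit table in the source genome (full-length elements).
#' @param source_genome,target_genome Named character vectors.
#' @param flank Flank length each side, bp.
#' @param min_identity,min_query_coverage Thresholds for
#'   [search_homolog()].
#' @return Data frame: element_id, status ("present"/"absent"), t_seqid,
#'   t_start, t_end, identity.
#' @export
call_element_pav <- function(hits, source_genome, target_genome,
                             flank = 200, min_identity = 0.90,
                             min_query_coverage = 0.90) {
  validate_hits(hits)
  tset <- as_dna_set(target_genome)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    q <- extract_query(h, source_genome, flank)
    best <- search_homolog(q$seq, tset, min_identity, min_query_coverage)
    present <- !is.null(best) &&
      best$q_start <= q$elem_start && best$q_end >= q$elem_end
    data.frame(element_id = h$element_id,
               status = if (present) "present" else "absent",
               t_seqid = if (present) best$t_seqid else NA_character_,
               t_start = if (present) best$t_start else NA_integer_,
               t_end = if (present) best$t_end else NA_integer_,
               identity = if (!is.null(best)) best$identity else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Re-annotate elements inside a target window by aligning each family
# consensus (both orientations) and keeping non-overlapping hits.
annotate_window <- function(window_seq, consensi, min_identity = 0.70,
                            min_coverage = 0.80) {
  if (nchar(window_seq) < 20) {
    return(data.frame(start = integer(0), end = integer(0),
                      family = character(0), strand = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  win <- Biostrings::DNAStringSet(window_seq)
  names(win) <- "w"
  cand <- NULL
  for (fam in names(consensi)) {
    for (strand in c("+", "-")) {
      cons <- if (strand == "+") consensi[[fam]] else revcomp(consensi[[fam]])
      h <- tryCatch(search_homolog(cons, win, min_identity, min_coverage,
                                   kmer = 12, all_hits = TRUE),
                    error = function(e) NULL)
      if (is.null(h)) next
      h$family <- fam
      h$strand <- strand
      cand <- rbind(cand, h)
    }
  }
  if (is.null(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      family = character(0), strand = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  cand <- cand[order(-cand$identity * cand$coverage, cand$t_start), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & cand$t_start <= cand$t_end[i] & cand$t_end >= cand$t_start[i]
    keep[i] <- !any(ov)
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$t_start), ]
  data.frame(start = cand$t_start, end = cand$t_end, family = cand$family,
             strand = cand$strand, identity = cand$identity,
             stringsAsFactors = FALSE)
}

# Longest common subsequence between source and target member lists under
# a pairwise compatibility matrix; returns the matched index pairs.
lcs_match <- function(compatible) {
  n <- nrow(compatible); m <- ncol(compatible)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1, j + 1] <- max(L[i, j] + as.integer(compatible[i, j]),
                             L[i, j + 1], L[i + 1, j])
    }
  }
  pairs <- NULL
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (compatible[i, j] && L[i + 1, j + 1] == L[i, j] + 1L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (L[i, j + 1] >= L[i + 1, j]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  pairs
}

#' Cluster-level presence/absence call with event classification
#'
#' Locates the target locus through the cluster's 200-bp flanks,
#' re-annotates elements in the target window against the family
#' consensus sequences, and matches source and target member lists by an
#' order-preserving longest common subsequence (members are compatible
#' when family and orientation agree and their sequences align at >= 90
#' percent identity).  The cluster is present when the flanks are found,
#' member number and order are identical and every member matches;
#' otherwise it is absent with deletion, insertion and substitution events
#' (an unmatched source/target pair at the same position is a
#' substitution).
#'
#' @param members_hits Hit table of the cluster's members (one cluster).
#' @param source_genome,target_genome Named character vectors.
#' @param consensi Named character vector of family consensus sequences.
#' @param flank Flank length, bp.
#' @param min_identity Identity floor for flanks and member pairs.
#' @return List: status ("present"/"absent"), locus_found, events (data
#'   frame: type, source_element_id, target_start, target_end,
#'   target_family), target_window (genome coordinates or NA).
#' @export
call_cluster_pav <- function(members_hits, source_genome, target_genome,
                             consensi, flank = 200, min_identity = 0.90) {
  validate_hits(members_hits)
  h <- members_hits[order(members_hits$start), ]
  sq <- h$seqid[1]
  span <- c(min(h$start), max(h$end))
  src <- source_genome[[sq]]
  if (span[1] - flank < 1 || span[2] + flank > nchar(src)) {
    stop("insufficient flank for cluster span")
  }
  empty_events <- data.frame(type = character(0),
                             source_element_id = character(0),
                             target_start = integer(0),
                             target_end = integer(0),
                             target_family = character(0),
                             stringsAsFactors = FALSE)
  tset <- as_dna_set(target_genome)
  lflank <- substring(src, span[1] - flank, span[1] - 1L)
  rflank <- substring(src, span[2] + 1L, span[2] + flank)
  lhit <- search_homolog(lflank, tset, min_identity, 0.9)
  rhit <- search_homolog(rflank, tset, min_identity, 0.9)
  locus_found <- !is.null(lhit) && !is.null(rhit) &&
    lhit$t_seqid == rhit$t_seqid && rhit$t_start > lhit$t_end
  if (!locus_found) {
    return(list(status = "absent", locus_found = FALSE,
                events = empty_events, target_window = c(NA, NA)))
  }
  tseq <- as.character(tset[[lhit$t_seqid]])
  wlo <- lhit$t_end + 1L
  whi <- rhit$t_start - 1L
  window_seq <- if (whi >= wlo) substring(tseq, wlo, whi) else ""
  ann <- annotate_window(window_seq, consensi)

  src_seqs <- vapply(seq_len(nrow(h)), function(i) {
    substring(src, h$start[i], h$end[i])
  }, "")
  tgt_seqs <- if (nrow(ann)) vapply(seq_len(nrow(ann)), function(j) {
    substring(window_seq, ann$start[j], ann$end[j])
  }, "") else character(0)

  n <- nrow(h); m <- nrow(ann)
  compatible <- matrix(FALSE, n, max(m, 1))[, seq_len(m), drop = FALSE]
  pair_identity <- matrix(NA_real_, n, max(m, 1))[, seq_len(m), drop = FALSE]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (h$family[i] != ann$family[j] || h$strand[i] != ann$strand[j]) next
      ident <- conservation(align_global(src_seqs[i], tgt_seqs[j])) / 100
      pair_identity[i, j] <- ident
      compatible[i, j] <- ident >= min_identity
    }
  }
  pairs <- if (n > 0 && m > 0) lcs_match(compatible) else NULL
  n_matched <- if (is.null(pairs)) 0L else nrow(pairs)
  present <- n == m && n_matched == n
  events <- empty_events
  if (!present) {
    # walk the gaps between consecutive matched pairs; unmatched source and
    # target members pair up in order as substitutions, leftovers are
    # deletions (source only) or insertions (target only)
    anchors <- rbind(c(0L, 0L),
                     if (!is.null(pairs)) pairs,
                     c(n + 1L, m + 1L))
    for (k in seq_len(nrow(anchors) - 1)) {
      si <- seq(anchors[k, 1] + 1L, length.out = anchors[k + 1, 1] - anchors[k, 1] - 1L)
      tj <- seq(anchors[k, 2] + 1L, length.out = anchors[k + 1, 2] - anchors[k, 2] - 1L)
      n_sub <- min(length(si), length(tj))
      if (n_sub > 0) {
        for (u in seq_len(n_sub)) {
          events <- rbind(events, data.frame(
            type = "substitution", source_element_id = h$element_id[si[u]],
            target_start = wlo + ann$start[tj[u]] - 1L,
            target_end = wlo + ann$end[tj[u]] - 1L,
            target_family = ann$family[tj[u]], stringsAsFactors = FALSE))
        }
      }
      if (length(si) > n_sub) {
        for (u in si[seq(n_sub + 1L, length(si))]) {
          events <- rbind(events, data.frame(
            type = "deletion", source_element_id = h$element_id[u],
            target_start = NA_integer_, target_end = NA_integer_,
            target_family = NA_character_, stringsAsFactors = FALSE))
        }
      }
      if (length(tj) > n_sub) {
        for (u in tj[seq(n_sub + 1L, length(tj))]) {
          events <- rbind(events, data.frame(
            type = "insertion", source_element_id = NA_character_,
            target_start = wlo + ann$start[u] - 1L,
            target_end = wlo + ann$end[u] - 1L,
            target_family = ann$family[u], stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(status = if (present) "present" else "absent",
       locus_found = TRUE, events = events,
       target_window = c(wlo, whi))
}

#' Read-pair presence/absence calls
#'
#' An element is present when at least one properly paired fragment span
#' covers the element plus \code{margin} bp on each side.
#'
#' @param hits Hit table.
#' @param read_pairs Read-pair table (see [simulate_read_pairs()] /
#'   [read_pairs_sam()]).
#' @param margin Required flanking margin, bp.
#' @return Data frame: element_id, status.
#' @export
call_read_pav <- function(hits, read_pairs, margin = 50) {
  validate_hits(hits)
  rp <- read_pairs[read_pairs$proper_pair, , drop = FALSE]
  status <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    ok <- rp$reference == h$seqid &
      rp$outer_start <= h$start - margin &
      rp$outer_end >= h$end + margin
    if (any(ok)) "present" else "absent"
  }, "")
  data.frame(element_id = hits$element_id, status = status,
             stringsAsFactors = FALSE)
}

#' Summarize presence fractions per class
#'
#' @param calls PAV call table (element_id, status, and optionally an
#'   accession/group column named by \code{group_col}).
#' @param classes Classification table (element_id, label).
#' @param group_col Optional name of a grouping column in \code{calls}.
#' @return Data frame: label (, group), n, n_present, fraction_present.
#' @export
pav_summary <- function(calls, classes, group_col = NULL) {
  calls$label <- classes$label[match(calls$element_id, classes$element_id)]
  by <- list(label = calls$label)
  if (!is.null(group_col)) by[[group_col]] <- calls[[group_col]]
  agg <- stats::aggregate(list(n = rep(1L, nrow(calls)),
                               n_present = calls$status == "present"),
                          by = by, FUN = sum)
  agg$fraction_present <- agg$n_present / agg$n
  agg
}
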