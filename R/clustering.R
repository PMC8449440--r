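# Adjacent-insertion clusters: maximal chains of full-length elements whose
# consecutive inter-element gaps are at most max_gap (default 100 bp,
# "within 100 bp" read inclusively).

#' Find adjacent-insertion clusters
#'
#' Chains full-length hits along each sequence: two consecutive elements
#' belong to the same chain when the gap between them (bases strictly
#' between the end of one and the start of the next) is at most
#' \code{max_gap}.  Maximal chains with at least two members are clusters;
#' singletons are excluded.  Overlapping or nested hits break the chain
#' and are flagged.
#'
#' @param hits Hit table (full-length elements; sorted internally).
#' @param max_gap Maximum inter-element gap in bp (inclusive).
#' @param genome Optional genome; when given, each cluster is additionally
#'   screened for tandem-duplication suspicion (consecutive members >= 99
#'   percent identical and identical inter-element sequences).
#' @return List with \code{clusters} (cluster_id, seqid, start, end,
#'   n_members, gaps, duplication_suspect), \code{members} (cluster_id,
#'   element_id, member_order) and \code{overlapping} (element ids that
#'   overlap a neighbour and were not chained).
#' @export
find_clusters <- function(hits, max_gap = 100, genome = NULL) {
  validate_hits(hits)
  empty <- list(
    clusters = data.frame(cluster_id = character(0), seqid = character(0),
                          start = integer(0), end = integer(0),
                          n_members = integer(0), gaps = character(0),
                          duplication_suspect = logical(0),
                          stringsAsFactors = FALSE),
    members = data.frame(cluster_id = character(0), element_id = character(0),
                         member_order = integer(0), stringsAsFactors = FALSE),
    overlapping = character(0))
  if (nrow(hits) < 2) return(empty)
  hits <- hits[order(hits$seqid, hits$start, hits$end), ]
  clusters <- empty$clusters
  members <- empty$members
  overlapping <- character(0)
  cid <- 0L
  for (sq in unique(hits$seqid)) {
    h <- hits[hits$seqid == sq, ]
    n <- nrow(h)
    if (n == 1) next
    gap <- h$start[-1] - h$end[-n] - 1L
    overlapping <- c(overlapping,
                     unique(c(h$element_id[-n][gap < 0], h$element_id[-1][gap < 0])))
    linked <- gap >= 0 & gap <= max_gap
    # chain ids: break where not linked
    chain <- cumsum(c(TRUE, !linked))
    for (ch in unique(chain)) {
      idx <- which(chain == ch)
      if (length(idx) < 2) next
      cid <- cid + 1L
      id <- sprintf("CL%04d", cid)
      gaps_ch <- gap[idx[-length(idx)]]
      clusters <- rbind(clusters, data.frame(
        cluster_id = id, seqid = sq,
        start = h$start[idx[1]], end = h$end[idx[length(idx)]],
        n_members = length(idx),
        gaps = paste(gaps_ch, collapse = ","),
        duplication_suspect = if (is.null(genome)) NA else
          is_duplication_suspect(h[idx, ], genome),
        stringsAsFactors = FALSE))
      members <- rbind(members, data.frame(
        cluster_id = id, element_id = h$element_id[idx],
        member_order = seq_along(idx), stringsAsFactors = FALSE))
    }
  }
  list(clusters = clusters, members = members,
       overlapping = unique(overlapping))
}

# Tandem-duplication screen: consecutive members >= 99% identical AND the
# inter-element sequences between them identical.
is_duplication_suspect <- function(h, genome) {
  n <- nrow(h)
  if (n < 2) return(FALSE)
  seqs <- vapply(seq_len(n), function(i) {
    subseq_checked(genome[[h$seqid[i]]], h$start[i], h$end[i])
  }, "")
  inter <- vapply(seq_len(n - 1), function(i) {
    if (h$start[i + 1] - h$end[i] <= 1) "" else
      subseq_checked(genome[[h$seqid[i]]], h$end[i] + 1L, h$start[i + 1] - 1L)
  }, "")
  for (i in seq_len(n - 1)) {
    ident <- conservation(align_global(seqs[i], seqs[i + 1]))
    if (ident < 99) next
    # tandem duplication would also copy the spacer: the inter-element
    # sequences on both sides of the pair (where both exist) must match
    spacers_equal <- (i == 1 || inter[i - 1] == inter[i]) &&
      (i == n - 1 || inter[i] == inter[i + 1])
    if (spacers_equal) return(TRUE)
  }
  FALSE
}

#' Cluster composition and global clustering summary
#'
#' @param found Result of [find_clusters()].
#' @param classes Classification table (element_id, label).
#' @param n_full_length Total number of full-length elements considered
#'   (denominator of the clustered fraction).
#' @return List with \code{per_cluster} (cluster_id, n_members, n_mt,
#'   n_ml, n_other) and \code{summary} (n_clusters, clustered_elements,
#'   clustered_fraction, clustered_mt).
#' @export
cluster_stats <- function(found, classes, n_full_length) {
  mem <- found$members
  if (!nrow(mem)) {
    return(list(per_cluster = data.frame(cluster_id = character(0),
                                         n_members = integer(0),
                                         n_mt = integer(0), n_ml = integer(0),
                                         n_other = integer(0),
                                         stringsAsFactors = FALSE),
                summary = data.frame(n_clusters = 0L, clustered_elements = 0L,
                                     clustered_fraction = 0,
                                     clustered_mt = 0L)))
  }
  mem$label <- classes$label[match(mem$element_id, classes$element_id)]
  per <- do.call(rbind, lapply(split(mem, mem$cluster_id), function(m) {
    data.frame(cluster_id = m$cluster_id[1], n_members = nrow(m),
               n_mt = sum(m$label == "mt", na.rm = TRUE),
               n_ml = sum(m$label == "ml", na.rm = TRUE),
               n_other = sum(m$label == "other", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_cluster = per,
       summary = data.frame(
         n_clusters = nrow(per),
         clustered_elements = nrow(mem),
         clustered_fraction = nrow(mem) / n_full_length,
         clustered_mt = sum(per$n_mt)))
}

#' Distance to the nearest neighbouring element
#'
#' For every element, the gap (bases strictly between) to its nearest
#' neighbouring element of any class on the same sequence.  Elements alone
#' on their sequence are omitted.
#'
#' @param hits Hit table.
#' @param classes Optional classification table to carry a label column.
#' @return Data frame: element_id, label (if classes given), distance.
#' @export
adjacent_distance_distribution <- function(hits, classes = NULL) {
  validate_hits(hits)
  out <- NULL
  for (sq in unique(hits$seqid)) {
    h <- hits[hits$seqid == sq, ]
    h <- h[order(h$start, h$end), ]
    n <- nrow(h)
    if (n < 2) next
    gap_prev <- c(NA, h$start[-1] - h$end[-n] - 1L)
    gap_next <- c(h$start[-1] - h$end[-n] - 1L, NA)
    d <- pmin(gap_prev, gap_next, na.rm = TRUE)
    out <- rbind(out, data.frame(element_id = h$element_id,
                                 distance = pmax(d, 0L),
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(element_id = character(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(classes)) {
    out$label <- classes$label[match(out$element_id, classes$element_id)]
  }
  rownames(out) <- NULL
  out
}
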