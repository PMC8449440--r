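# Genomic-context analyses: sliding-window density tracks and their
# correlations, gene-context categories, gene grouping by nearby element
# class, RPKM expression normalization, per-element methylation levels,
# and the Welch t comparison used for group contrasts.

#' Sliding-window density track
#'
#' Windows of fixed width advance by \code{step} from position 1;
#' trailing partial windows are included.  In count mode an interval is
#' counted in every window containing its midpoint; in bp mode each
#' window sums the overlapping bases.
#'
#' @param intervals Data frame with seqid, start, end (1-based closed).
#' @param seq_lengths Named vector of sequence lengths.
#' @param window Window width, bp (default 500 kb).
#' @param step Step between window starts, bp (default 100 kb).
#' @param mode "count" (midpoints) or "bp" (overlap bases).
#' @return Data frame: seqid, window_start, value.
#' @export
window_density <- function(intervals, seq_lengths, window = 500000,
                           step = 100000, mode = c("count", "bp")) {
  mode <- match.arg(mode)
  out <- lapply(names(seq_lengths), function(sq) {
    len <- seq_lengths[[sq]]
    starts <- seq(1L, max(1L, len), by = as.integer(step))
    iv <- intervals[intervals$seqid == sq, , drop = FALSE]
    if (mode == "count") {
      mids <- sort(as.integer((iv$start + iv$end) %/% 2))
      value <- vapply(starts, function(ws) {
        we <- min(ws + window - 1, len)
        sum(mids >= ws & mids <= we)
      }, 1)
    } else {
      value <- vapply(starts, function(ws) {
        we <- min(ws + window - 1, len)
        ov <- pmin(iv$end, we) - pmax(iv$start, ws) + 1
        sum(ov[ov > 0])
      }, 1)
    }
    data.frame(seqid = sq, window_start = starts, value = value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation between two aligned window tracks
#'
#' @param track_a,track_b Tracks from [window_density()] over the same
#'   windows.
#' @return List: r, r_squared.
#' @export
pearson_r2 <- function(track_a, track_b) {
  if (nrow(track_a) != nrow(track_b) ||
      any(track_a$seqid != track_b$seqid) ||
      any(track_a$window_start != track_b$window_start)) {
    stop("tracks are not over the same windows")
  }
  if (stats::sd(track_a$value) == 0 || stats::sd(track_b$value) == 0) {
    stop("zero variance track; correlation undefined")
  }
  r <- stats::cor(track_a$value, track_b$value)
  list(r = r, r_squared = r^2)
}

#' Gene-context categories for each element
#'
#' Categories are not mutually exclusive: an element counts as upstream /
#' downstream of every gene whose strand-aware 2-kb flank it overlaps, and
#' as intronic when it overlaps any intron.  Exon overlap is recorded as a
#' separate flag outside the four categories.  Intergenic applies when no
#' category (and no exon overlap) does.  Distance is 0 for elements
#' overlapping a gene body, otherwise the gap to the nearest gene.
#'
#' @param hits Hit table.
#' @param gene_models List with \code{genes} and \code{exons} (see
#'   [read_gff3()]).
#' @param flank Flank width defining upstream/downstream, bp.
#' @return Data frame: element_id, upstream, intron, downstream, exon,
#'   intergenic, nearest_gene_id, distance.
#' @export
assign_gene_context <- function(hits, gene_models, flank = 2000) {
  validate_hits(hits)
  genes <- gene_models$genes
  introns <- derive_introns(gene_models)
  exons <- gene_models$exons
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    g <- genes[genes$seqid == h$seqid, , drop = FALSE]
    if (!nrow(g)) {
      return(data.frame(element_id = h$element_id, upstream = FALSE,
                        intron = FALSE, downstream = FALSE, exon = FALSE,
                        intergenic = TRUE, nearest_gene_id = NA_character_,
                        distance = NA_integer_, stringsAsFactors = FALSE))
    }
    ov <- function(s, e) h$start <= e & h$end >= s
    up_start <- ifelse(g$strand == "+", g$start - flank, g$end + 1L)
    up_end <- ifelse(g$strand == "+", g$start - 1L, g$end + flank)
    dn_start <- ifelse(g$strand == "+", g$end + 1L, g$start - flank)
    dn_end <- ifelse(g$strand == "+", g$end + flank, g$start - 1L)
    upstream <- any(ov(up_start, up_end))
    downstream <- any(ov(dn_start, dn_end))
    gi <- introns[introns$gene_id %in% g$gene_id, , drop = FALSE]
    ge <- exons[exons$gene_id %in% g$gene_id, , drop = FALSE]
    intron <- nrow(gi) > 0 && any(ov(gi$start, gi$end))
    exon <- nrow(ge) > 0 && any(ov(ge$start, ge$end))
    gap <- pmax(g$start - h$end, h$start - g$end, 0L)
    nearest <- which.min(gap)
    data.frame(element_id = h$element_id, upstream = upstream,
               intron = intron, downstream = downstream, exon = exon,
               intergenic = !(upstream || intron || downstream || exon),
               nearest_gene_id = g$gene_id[nearest],
               distance = gap[nearest], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group genes by the class of nearby elements
#'
#' Per gene: U-MT / D-MT (an mt element overlapping the strand-aware
#' upstream / downstream flank), U-ML / D-ML likewise for ml elements,
#' and AWAY when no classified element overlaps the flanks or the gene
#' body.  Labels other than AWAY are not mutually exclusive.
#'
#' @param gene_models List with \code{genes} and \code{exons}.
#' @param hits Hit table.
#' @param classes Classification table (element_id, label).
#' @param flank Flank width, bp.
#' @return Data frame: gene_id, u_mt, d_mt, u_ml, d_ml, away.
#' @export
group_genes <- function(gene_models, hits, classes, flank = 2000) {
  validate_hits(hits)
  genes <- gene_models$genes
  hits$label <- classes$label[match(hits$element_id, classes$element_id)]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    h <- hits[hits$seqid == g$seqid, , drop = FALSE]
    ov <- function(s, e) h$start <= e & h$end >= s
    if (g$strand == "+") {
      up <- ov(g$start - flank, g$start - 1L)
      dn <- ov(g$end + 1L, g$end + flank)
    } else {
      up <- ov(g$end + 1L, g$end + flank)
      dn <- ov(g$start - flank, g$start - 1L)
    }
    body <- ov(g$start, g$end)
    data.frame(gene_id = g$gene_id,
               u_mt = any(up & h$label == "mt"),
               d_mt = any(dn & h$label == "mt"),
               u_ml = any(up & h$label == "ml"),
               d_ml = any(dn & h$label == "ml"),
               away = !any(up | dn | body), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reciprocal (1/n) counts for multi-mapped reads
#'
#' Each read contributes 1/n to each of the n features it maps to.
#'
#' @param assignments Data frame with read_id and feature_id (one row per
#'   mapping).
#' @return Data frame: feature_id, count (fractional).
#' @export
reciprocal_counts <- function(assignments) {
  n_loc <- table(assignments$read_id)
  w <- 1 / as.numeric(n_loc[assignments$read_id])
  agg <- stats::aggregate(list(count = w),
                          by = list(feature_id = assignments$feature_id),
                          FUN = sum)
  agg
}

#' RPKM normalization
#'
#' RPKM = count x 10^9 / (length_bp x total_mapped).
#'
#' @param counts Numeric vector of (possibly fractional) read counts.
#' @param lengths_bp Feature lengths in bp.
#' @param total_mapped Total mapped reads in the library.
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(counts, lengths_bp, total_mapped) {
  stopifnot(length(counts) == length(lengths_bp), total_mapped > 0)
  counts * 1e9 / (lengths_bp * total_mapped)
}

#' Per-element methylation levels
#'
#' Sites with fewer than \code{min_reads} or more than \code{max_reads}
#' supporting reads are removed; the level of a kept site is
#' C / (C + T).  Each element's level is the mean over its kept sites,
#' reported per methylation context; elements with no kept site in a
#' context are omitted.
#'
#' @param sites Data frame: seqid, position, context, count_c, count_t.
#' @param hits Hit table.
#' @param classes Optional classification table to carry labels.
#' @param min_reads,max_reads Site depth filter (defaults 4 and 1000).
#' @return Data frame: element_id, label (if classes), context, n_sites,
#'   level.
#' @export
methylation_by_element <- function(sites, hits, classes = NULL,
                                   min_reads = 4, max_reads = 1000) {
  validate_hits(hits)
  depth <- sites$count_c + sites$count_t
  sites <- sites[depth >= min_reads & depth <= max_reads, , drop = FALSE]
  sites$level <- sites$count_c / (sites$count_c + sites$count_t)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    s <- sites[sites$seqid == h$seqid & sites$position >= h$start &
                 sites$position <= h$end, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    agg <- stats::aggregate(list(level = s$level),
                            by = list(context = s$context), FUN = mean)
    agg$n_sites <- as.integer(table(s$context)[agg$context])
    agg$element_id <- h$element_id
    agg
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(element_id = character(0), context = character(0),
                      n_sites = integer(0), level = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(classes)) {
    out$label <- classes$label[match(out$element_id, classes$element_id)]
  }
  out[, c("element_id", if (!is.null(classes)) "label", "context",
          "n_sites", "level")]
}

#' Welch's unequal-variance t test
#'
#' The two-group comparison used for expression and methylation
#' contrasts: Welch's statistic with Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @return List: t, df, p.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
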