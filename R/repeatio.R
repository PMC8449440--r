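# Readers and writers for the standard formats the pipeline touches, plus
# the full-length element caller.
#
# Internal coordinate convention: 1-based, closed intervals on both genome
# and consensus, as everywhere else in R/Bioconductor.  BED (0-based,
# half-open) is converted at the read/write boundary and nowhere else.

#' Read a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns plain uppercase
#' character strings keyed by sequence id (first whitespace-delimited token
#' of the header).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence id in ", path)
  out <- toupper(as.character(set))
  names(out) <- ids
  if (!is_dna(out)) stop("non-IUPAC character in ", path)
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path. Lines are wrapped at 60 columns.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Canonical empty hit table; every reader/constructor returns these columns.
empty_hits <- function() {
  data.frame(
    element_id = character(0), seqid = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    family = character(0), cons_start = integer(0), cons_end = integer(0),
    cons_length = integer(0), stringsAsFactors = FALSE
  )
}

validate_hits <- function(hits) {
  need <- names(empty_hits())
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  if (any(hits$start > hits$end)) stop("hit with start > end")
  if (any(hits$cons_start < 1 | hits$cons_start > hits$cons_end |
          hits$cons_end > hits$cons_length)) {
    stop("hit with invalid consensus coordinates")
  }
  invisible(hits)
}

#' Call full-length (intact) elements
#'
#' An element is full-length when its alignment to the family consensus is
#' missing at most \code{max_missing} bp from each terminus: the aligned
#' consensus interval must start within \code{max_missing} bp of position 1
#' and end within \code{max_missing} bp of the consensus length.  The
#' default of 10 bp is the rule used throughout the cluster and PAV
#' analyses ("intact" and "full-length" are synonyms here).
#'
#' @param hits Hit table (see [read_repeatmasker_out()]).
#' @param max_missing Maximum bp missing from each terminus (default 10).
#' @return Logical vector, one flag per hit.
#' @export
classify_full_length <- function(hits, max_missing = 10) {
  validate_hits(hits)
  (hits$cons_start - 1L) <= max_missing &
    (hits$cons_length - hits$cons_end) <= max_missing
}

#' Read RepeatMasker .out annotations
#'
#' Parses the classic 15-column RepeatMasker \code{.out} dialect (score,
#' divergence, deletion, insertion, query, query begin/end, query left,
#' strand, repeat name, repeat class, repeat begin/end/left, id).  The
#' customary 2-3 header lines are skipped.  Minus-strand rows (strand
#' \code{"C"}, consensus coordinates printed as \code{(left) end begin})
#' are normalized to strand \code{"-"} with ascending consensus
#' coordinates.
#'
#' @param path Path to a .out file.
#' @param consensus_lengths Optional named vector of consensus lengths per
#'   family, used to cross-check the parenthesized "left" fields.
#' @return Hit table with columns element_id, seqid, start, end, strand,
#'   family, cons_start, cons_end, cons_length.
#' @export
read_repeatmasker_out <- function(path, consensus_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # header lines: the two banner lines and anything not starting with a score
  lines <- lines[grepl("^\\s*\\d", lines)]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(fields, length, 1L)
  if (any(bad < 14 | bad > 16)) stop("malformed RepeatMasker row in ", path)
  strip <- function(x) as.integer(gsub("[()]", "", x))
  rows <- lapply(fields, function(f) {
    strand <- f[[9]]
    if (strand == "C" || strand == "-") {
      # minus strand: columns 12:14 are (left) end begin
      cons_left <- strip(f[[12]]); cons_end <- strip(f[[13]]); cons_start <- strip(f[[14]])
      strand <- "-"
    } else {
      cons_start <- strip(f[[12]]); cons_end <- strip(f[[13]]); cons_left <- strip(f[[14]])
      strand <- "+"
    }
    data.frame(
      element_id = if (length(f) >= 15) f[[15]] else NA_character_,
      seqid = f[[5]],
      start = as.integer(f[[6]]), end = as.integer(f[[7]]),
      strand = strand, family = f[[10]],
      cons_start = cons_start, cons_end = cons_end,
      cons_length = cons_end + cons_left,
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, rows)
  if (!is.null(consensus_lengths)) {
    known <- hits$family %in% names(consensus_lengths)
    hits$cons_length[known] <- as.integer(consensus_lengths[hits$family[known]])
  }
  validate_hits(hits)
  hits
}

#' Write hits in RepeatMasker .out dialect
#'
#' @param hits Hit table.
#' @param path Output path.
#' @param class Repeat class string written in the class column.
#' @export
write_repeatmasker_out <- function(hits, path, class = "DNA/MITE") {
  validate_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query      position in query     matching  repeat          position in repeat",
    "score   div. del. ins.  sequence   begin end    (left)   repeat    class/family  begin end  (left)    ID",
    ""
  ), con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    qleft <- 0L  # query-left unknown at this layer; readers ignore it
    if (h$strand == "+") {
      rep_cols <- sprintf("%d %d (%d)", h$cons_start, h$cons_end,
                          h$cons_length - h$cons_end)
      strand <- "+"
    } else {
      rep_cols <- sprintf("(%d) %d %d", h$cons_length - h$cons_end,
                          h$cons_end, h$cons_start)
      strand <- "C"
    }
    writeLines(sprintf("%5d %6.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %s %s",
                       1000L, 0, 0, 0, h$seqid, h$start, h$end, qleft, strand,
                       h$family, class, rep_cols, h$element_id), con)
  }
  invisible(path)
}

#' Write hits as BED6
#'
#' Converts from internal 1-based closed coordinates to BED's 0-based
#' half-open convention.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  validate_hits(hits)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   hits$seqid, hits$start - 1L, hits$end,
                   hits$element_id, 0L, hits$strand)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED6 file into a hit-style interval table
#'
#' @param path Path to a BED6 file.
#' @return Data frame with seqid, start, end (1-based closed), name, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(seqid = f[, 1], start = as.integer(f[, 2]) + 1L,
             end = as.integer(f[, 3]), name = f[, 4], strand = f[, 6],
             stringsAsFactors = FALSE)
}

#' Read gene models from GFF3
#'
#' Understands the simple gene/exon dialect written by [write_gff3()]:
#' \code{gene} rows with an \code{ID} attribute and \code{exon} rows with a
#' \code{Parent} attribute.  Introns are derived as the gaps between
#' consecutive exons.
#'
#' @param path Path to a GFF3 file.
#' @return List with \code{genes} (data frame: gene_id, seqid, start, end,
#'   strand) and \code{exons} (data frame: gene_id, start, end).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(list(
      genes = data.frame(gene_id = character(0), seqid = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), stringsAsFactors = FALSE),
      exons = data.frame(gene_id = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
    ))
  }
  f <- do.call(rbind, strsplit(lines, "\t"))
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[[2]] else NA_character_, "")
  }
  type <- f[, 3]
  genes <- data.frame(
    gene_id = attr_field(f[type == "gene", 9], "ID"),
    seqid = f[type == "gene", 1],
    start = as.integer(f[type == "gene", 4]),
    end = as.integer(f[type == "gene", 5]),
    strand = f[type == "gene", 7], stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = attr_field(f[type == "exon", 9], "Parent"),
    start = as.integer(f[type == "exon", 4]),
    end = as.integer(f[type == "exon", 5]), stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$gene_id, exons$start), ]
  rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write gene models as GFF3
#'
#' @param genes Data frame with gene_id, seqid, start, end, strand.
#' @param exons Data frame with gene_id, start, end.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tmitesat\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$seqid, g$start, g$end, g$strand, g$gene_id), con)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tmitesat\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$seqid, ex$start[j], ex$end[j], g$strand, g$gene_id),
                 con)
    }
  }
  invisible(path)
}

#' Derive introns from gene models
#'
#' @param gene_models List as returned by [read_gff3()].
#' @return Data frame with gene_id, start, end — one row per intron.
#' @export
derive_introns <- function(gene_models) {
  ex <- gene_models$exons
  out <- lapply(split(ex, ex$gene_id), function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1],
               start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a table as TSV
#'
#' @param table Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Path to a TSV file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}
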