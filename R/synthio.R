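# Synthetic genomes with planted microsatellite-associated MITEs and a
# ground-truth ledger.  The generator is first-class code: every downstream
# module (classification, divergence, clustering, PAV, context) is validated
# against the truth tables produced here.

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483629)
}

#' Configuration for the synthetic-genome generator
#'
#' Defaults mirror the structure of the system the pipeline targets: two
#' MITE families whose consensus lengths (540 and 240 bp) fall inside the
#' published 510-570 / 210-270 bp family ranges, sharing the first 55 bp of
#' their terminal inverted repeats; mt-type insertions split a (TA)n tract
#' so the element is flanked by pure dinucleotide repeats on both sides;
#' ml-type insertions carry an exact 9- or 10-bp target site duplication
#' and no flanking microsatellite; a configurable fraction of mt insertions
#' is laid down in adjacent runs whose inter-element tracts are at most
#' 100 bp.
#'
#' @param genome_length Background genome length in bp (features are added
#'   on top, so the final genome is longer).
#' @param gc_content Background GC fraction; bases are i.i.d. so that
#'   microsatellite and TSD detectors have a computable false-positive rate.
#' @param n_genes Number of gene models planted in the background.
#' @param gene_length_range Gene length range in bp.
#' @param n_families Number of MITE families (>= 1).
#' @param consensus_lengths Consensus length per family, bp.
#' @param tir_length Terminal inverted repeat length, bp.
#' @param n_mt Number of microsatellite-targeting (mt) insertions.
#' @param n_ml Number of Mutator-like (ml) insertions (9/10-bp TSD).
#' @param n_other Number of plain insertions with neither flanking tract
#'   nor TSD.
#' @param n_ms_tracts Number of standalone (TA)n/(GA)n/(CT)n tracts planted
#'   without an element.
#' @param ms_unit_range Range of repeat units per flanking tract side.
#' @param divergence_grid List of c(p, q) targets applied to element bodies
#'   (transition and transversion site proportions).
#' @param cluster_fraction Fraction of mt insertions placed in adjacent
#'   runs of two or more elements.
#' @param cluster_size_range Range of members per planted cluster
#'   (default pairs).
#' @param cluster_gap_range Range (bp) of the (TA)n tract separating
#'   adjacent cluster members.  The lower bound defaults to 16 bp so the
#'   planted class stays recoverable: a flanking-run detector at the
#'   default minimum of 8 units needs a 16-bp tract to fire.
#' @param ml_near_genes If TRUE, ml insertions are placed within 2 kb of a
#'   gene (used to emulate differential gene proximity of the two classes).
#' @param mt_far_from_genes If TRUE, mt insertions are kept at least 10 kb
#'   away from every gene.
#' @param seed Integer seed; mandatory, so fixtures are bit-reproducible.
#' @return A validated configuration object of class
#'   \code{mitesat_config}.
#' @export
synthetic_config <- function(genome_length = 200000, gc_content = 0.4,
                             n_genes = 10, gene_length_range = c(1000, 3000),
                             n_families = 2, consensus_lengths = c(540, 240),
                             tir_length = 55,
                             n_mt = 30, n_ml = 10, n_other = 5,
                             n_ms_tracts = 10, ms_unit_range = c(8, 20),
                             divergence_grid = list(c(0, 0)),
                             cluster_fraction = 0.5,
                             cluster_size_range = c(2, 2),
                             cluster_gap_range = c(16, 100),
                             ml_near_genes = FALSE, mt_far_from_genes = FALSE,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(genome_length = as.integer(genome_length),
              gc_content = gc_content, n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_families = as.integer(n_families),
              consensus_lengths = as.integer(consensus_lengths),
              tir_length = as.integer(tir_length),
              n_mt = as.integer(n_mt), n_ml = as.integer(n_ml),
              n_other = as.integer(n_other),
              n_ms_tracts = as.integer(n_ms_tracts),
              ms_unit_range = as.integer(ms_unit_range),
              divergence_grid = divergence_grid,
              cluster_fraction = cluster_fraction,
              cluster_size_range = as.integer(cluster_size_range),
              cluster_gap_range = as.integer(cluster_gap_range),
              ml_near_genes = ml_near_genes,
              mt_far_from_genes = mt_far_from_genes,
              seed = as.integer(seed))
  class(cfg) <- "mitesat_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_mt, cfg$n_ml, cfg$n_other, cfg$n_ms_tracts)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$gc_content < 0 || cfg$gc_content > 1) stop("gc_content outside [0, 1]")
  if (length(cfg$consensus_lengths) != cfg$n_families) {
    stop("consensus_lengths must have one entry per family")
  }
  if (any(cfg$consensus_lengths < 2 * cfg$tir_length)) {
    stop("consensus too short for two TIRs")
  }
  for (pq in cfg$divergence_grid) {
    if (length(pq) != 2 || any(pq < 0) || 2 * pq[1] + pq[2] >= 1) {
      stop("divergence grid point must satisfy p >= 0, q >= 0, 2p + q < 1")
    }
  }
  if (cfg$cluster_fraction < 0 || cfg$cluster_fraction > 1) {
    stop("cluster_fraction outside [0, 1]")
  }
  if (cfg$cluster_gap_range[1] < 2 || cfg$cluster_gap_range[2] > 100) {
    stop("cluster_gap_range must lie within [2, 100]")
  }
  if (cfg$cluster_size_range[1] < 2) {
    stop("clusters need at least 2 members")
  }
  # rough capacity check: planted features plus separation must fit
  n_feat <- cfg$n_mt + cfg$n_ml + cfg$n_other + cfg$n_ms_tracts
  needed <- cfg$n_genes * (cfg$gene_length_range[2] + 1000) + n_feat * 600 + 2000
  if (cfg$genome_length < needed) {
    stop(sprintf("genome_length %d too small for planted features (need ~%d)",
                 cfg$genome_length, needed))
  }
  invisible(cfg)
}

#' Generate a family consensus sequence
#'
#' The first \code{tir_length} bases are the reverse complement of the last
#' \code{tir_length} bases (a perfect TIR).  Families beyond the first
#' reuse the first family's initial 55 bp of TIR with light divergence, so
#' all families share terminal sequence similarity while their interiors
#' differ.
#'
#' @param config A \code{mitesat_config}.
#' @param family_index Family number (1-based).
#' @return A single DNA string.
#' @export
generate_consensus <- function(config, family_index) {
  L <- config$consensus_lengths[family_index]
  t <- config$tir_length
  if (L < 2 * t) stop("consensus length too short for TIRs")
  shared_len <- min(t, 55L)
  shared <- with_seed(derive_seed(config$seed, 1L),
                      random_dna(shared_len, config$gc_content))
  with_seed(derive_seed(config$seed, 100L + family_index), {
    head55 <- shared
    if (family_index > 1) {
      # light divergence in the shared block (2 substitutions, >= 96% id)
      chars <- strsplit(head55, "")[[1]]
      pos <- sample(shared_len, min(2L, shared_len))
      chars[pos] <- unname(TRANSITION[chars[pos]])
      head55 <- paste(chars, collapse = "")
    }
    tir5 <- paste0(head55,
                   if (t > shared_len) random_dna(t - shared_len, config$gc_content) else "")
    interior <- random_dna(L - 2L * t, config$gc_content)
    paste0(tir5, interior, revcomp(tir5))
  })
}

#' Mutate a sequence to exact transition/transversion targets
#'
#' Applies exactly \code{round(p_target * L)} transitions and
#' \code{round(q_target * L)} transversions at distinct positions, with no
#' indels, so the observed (p, q) recomputed from the pair equal the
#' targets to within 1/L.
#'
#' @param consensus Input DNA string.
#' @param p_target Transition site proportion.
#' @param q_target Transversion site proportion.
#' @param seed Integer seed.
#' @return Mutated copy of \code{consensus}.
#' @export
mutate_copy <- function(consensus, p_target, q_target, seed) {
  L <- nchar(consensus)
  n_ts <- round(p_target * L)
  n_tv <- round(q_target * L)
  if (n_ts + n_tv > L) stop("mutation targets exceed sequence length")
  if (n_ts + n_tv == 0) return(consensus)
  with_seed(seed, {
    chars <- strsplit(consensus, "")[[1]]
    pos <- sample(L, n_ts + n_tv)
    ts_pos <- pos[seq_len(n_ts)]
    tv_pos <- pos[setdiff(seq_along(pos), seq_len(n_ts))]
    chars[ts_pos] <- unname(TRANSITION[chars[ts_pos]])
    if (length(tv_pos)) {
      chars[tv_pos] <- vapply(chars[tv_pos],
                              function(b) sample(TRANSVERSION[[b]], 1), "")
    }
    paste(chars, collapse = "")
  })
}

# --- cassette builders -------------------------------------------------

ta_tract <- function(units) {
  paste(rep("TA", units), collapse = "")
}

# One planted feature: a cassette string plus relative element records.
# Returns list(seq, elements = data.frame(rel_start, rel_end, strand,
# family, class, p, q, tsd, units_left, units_right, cluster_size)).
build_cassette <- function(kind, config, consensi, rng_state) {
  draw_pq <- function() {
    config$divergence_grid[[sample(length(config$divergence_grid), 1)]]
  }
  draw_units <- function() {
    sample(seq(config$ms_unit_range[1], config$ms_unit_range[2]), 1)
  }
  new_elem <- function(fam, pq) {
    strand <- sample(c("+", "-"), 1)
    body <- mutate_copy(consensi[[fam]], pq[1], pq[2],
                        sample.int(2147483600L, 1))
    if (strand == "-") body <- revcomp(body)
    list(fam = fam, strand = strand, body = body, p = pq[1], q = pq[2])
  }
  elem_row <- function(e, rel_start, class, tsd = NA_character_,
                       units_left = NA_integer_, units_right = NA_integer_) {
    data.frame(rel_start = rel_start, rel_end = rel_start + nchar(e$body) - 1L,
               strand = e$strand, family = e$fam, class = class,
               p = e$p, q = e$q, tsd = tsd,
               units_left = units_left, units_right = units_right,
               stringsAsFactors = FALSE)
  }
  fams <- names(consensi)
  if (kind == "mt") {
    e <- new_elem(sample(fams, 1), draw_pq())
    ul <- draw_units(); ur <- draw_units()
    seq <- paste0(ta_tract(ul), e$body, ta_tract(ur))
    rows <- elem_row(e, 2L * ul + 1L, "mt",
                     units_left = ul, units_right = ur)
  } else if (kind == "ml") {
    e <- new_elem(sample(fams, 1), draw_pq())
    tsd_len <- sample(c(9L, 10L), 1)
    tsd <- random_dna(tsd_len, config$gc_content)
    seq <- paste0(tsd, e$body, tsd)
    rows <- elem_row(e, tsd_len + 1L, "ml", tsd = tsd)
  } else if (kind == "other") {
    e <- new_elem(sample(fams, 1), draw_pq())
    seq <- e$body
    rows <- elem_row(e, 1L, "other")
  } else if (kind == "tract") {
    motif <- sample(c("TA", "GA", "CT"), 1)
    units <- draw_units()
    seq <- paste(rep(motif, units), collapse = "")
    rows <- NULL
  } else if (kind == "cluster") {
    size <- rng_state$cluster_size
    ul <- draw_units(); ur <- draw_units()
    gaps <- sample(seq(config$cluster_gap_range[1], config$cluster_gap_range[2]),
                   size - 1, replace = TRUE)
    gaps <- gaps - gaps %% 2L  # even, so inter-element tracts are pure (TA)n
    gaps[gaps < config$cluster_gap_range[1]] <-
      gaps[gaps < config$cluster_gap_range[1]] + 2L
    parts <- ta_tract(ul)
    rows <- NULL
    pos <- nchar(parts)
    for (i in seq_len(size)) {
      e <- new_elem(sample(fams, 1), draw_pq())
      rows_i <- elem_row(e, pos + 1L, "mt",
                         units_left = if (i == 1) ul else gaps[i - 1] %/% 2L,
                         units_right = if (i == size) ur else gaps[i] %/% 2L)
      rows <- rbind(rows, rows_i)
      parts <- paste0(parts, e$body,
                      if (i < size) ta_tract(gaps[i] %/% 2L) else ta_tract(ur))
      pos <- nchar(parts)
    }
    seq <- parts
  } else {
    stop("unknown cassette kind: ", kind)
  }
  list(seq = seq, elements = rows)
}

# Partition n clustered elements into cluster sizes within the range.
plan_cluster_sizes <- function(n, range = c(2L, 2L)) {
  # sample() would misread a single candidate as 1:x
  draw <- function(x) x[sample.int(length(x), 1)]
  sizes <- integer(0)
  while (n >= 2) {
    s <- min(n, draw(seq(range[1], range[2])))
    if (n - s == 1) s <- s + 1  # never leave a singleton behind
    if (s > n) s <- n
    sizes <- c(sizes, s)
    n <- n - s
  }
  sizes
}

#' Build a synthetic genome with planted elements and ground truth
#'
#' Plants mt insertions inside split (TA)n tracts, ml insertions with exact
#' 9/10-bp target site duplications, plain insertions with neither, bare
#' microsatellite tracts, adjacent-insertion clusters of mt elements, and
#' gene models, all on an i.i.d. background.  No insertions are nested.
#'
#' @param config A \code{mitesat_config}.
#' @return List with \code{genome} (named character vector, one sequence),
#'   \code{consensi} (named character vector per family), \code{hits} (hit
#'   table as in the repeat-annotation readers), \code{genes} and
#'   \code{exons} (gene models), \code{truth} (per-element ledger:
#'   coordinates, strand, family, class, applied p and q, cluster id, TSD,
#'   flanking tract units, fate), \code{tracts} (standalone tract table)
#'   and \code{config}.
#' @export
build_genome <- function(config) {
  validate_config(config)
  fams <- paste0("MITE", seq_len(config$n_families))
  consensi <- vapply(seq_len(config$n_families),
                     function(i) generate_consensus(config, i), "")
  names(consensi) <- fams

  with_seed(derive_seed(config$seed, 2L), {
    background <- random_dna(config$genome_length, config$gc_content)

    # gene intervals in background coordinates
    genes <- place_genes(config)

    # feature plan
    n_clustered <- round(config$cluster_fraction * config$n_mt)
    if (n_clustered == 1) n_clustered <- 0
    sizes <- plan_cluster_sizes(n_clustered, config$cluster_size_range)
    n_clustered <- sum(sizes)
    n_single_mt <- config$n_mt - n_clustered
    kinds <- c(rep("cluster", length(sizes)),
               rep("mt", n_single_mt),
               rep("ml", config$n_ml),
               rep("other", config$n_other),
               rep("tract", config$n_ms_tracts))
    cluster_size_of <- c(sizes, rep(NA_integer_, length(kinds) - length(sizes)))

    # insertion points in background coordinates, respecting gene placement
    pts <- place_points(length(kinds), kinds, genes, config, background)

    ord <- order(pts)
    pts <- pts[ord]; kinds <- kinds[ord]; cluster_size_of <- cluster_size_of[ord]

    cassettes <- lapply(seq_along(kinds), function(i) {
      build_cassette(kinds[i], config, as.list(consensi),
                     list(cluster_size = cluster_size_of[i]))
    })

    # splice cassettes into the background after each point
    lens <- vapply(cassettes, function(x) nchar(x$seq), 1L)
    offsets <- c(0L, cumsum(lens))[seq_along(pts)]
    segs <- character(2 * length(pts) + 1)
    prev <- 1L
    for (i in seq_along(pts)) {
      segs[2 * i - 1] <- substring(background, prev, pts[i])
      segs[2 * i] <- cassettes[[i]]$seq
      prev <- pts[i] + 1L
    }
    segs[2 * length(pts) + 1] <- substring(background, prev, config$genome_length)
    genome_seq <- paste(segs, collapse = "")

    # truth table in final coordinates
    truth <- NULL
    tracts <- NULL
    cluster_counter <- 0L
    for (i in seq_along(pts)) {
      cass_start <- pts[i] + offsets[i] + 1L  # final coord of cassette base 1
      el <- cassettes[[i]]$elements
      if (kinds[i] == "tract") {
        tracts <- rbind(tracts, data.frame(
          seqid = "chr1", start = as.integer(cass_start),
          end = as.integer(cass_start + lens[i] - 1L),
          stringsAsFactors = FALSE))
        next
      }
      if (is.null(el)) next
      cid <- NA_character_
      if (kinds[i] == "cluster") {
        cluster_counter <- cluster_counter + 1L
        cid <- sprintf("TC%03d", cluster_counter)
      }
      el$start <- as.integer(el$rel_start + cass_start - 1L)
      el$end <- as.integer(el$rel_end + cass_start - 1L)
      el$cluster_id <- cid
      truth <- rbind(truth, el)
    }
    if (is.null(truth)) {
      truth <- data.frame(element_id = character(0), seqid = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), family = character(0),
                          class = character(0), p = numeric(0),
                          q = numeric(0), cluster_id = character(0),
                          tsd = character(0), units_left = integer(0),
                          units_right = integer(0), fate = character(0),
                          stringsAsFactors = FALSE)
    } else {
      truth <- truth[order(truth$start), ]
      truth$element_id <- sprintf("E%04d", seq_len(nrow(truth)))
      truth$seqid <- "chr1"
      truth$fate <- "retained"
      truth <- truth[, c("element_id", "seqid", "start", "end", "strand",
                         "family", "class", "p", "q", "cluster_id", "tsd",
                         "units_left", "units_right", "fate")]
      rownames(truth) <- NULL
    }

    # gene coordinates shifted by cassettes inserted before them
    shift <- function(x) x + vapply(x, function(v) sum(lens[pts < v]), 1)
    genes$start <- as.integer(shift(genes$start))
    genes$end <- as.integer(shift(genes$end))
    exons <- make_exons(genes)

    hits <- if (nrow(truth) == 0) empty_hits() else data.frame(
      element_id = truth$element_id, seqid = truth$seqid,
      start = truth$start, end = truth$end, strand = truth$strand,
      family = truth$family, cons_start = 1L,
      cons_end = nchar(consensi)[match(truth$family, fams)],
      cons_length = nchar(consensi)[match(truth$family, fams)],
      stringsAsFactors = FALSE
    )

    genome <- c(chr1 = genome_seq)
    list(genome = genome, consensi = consensi, hits = hits,
         genes = genes, exons = exons, truth = truth,
         tracts = tracts, config = config)
  })
}

place_genes <- function(config) {
  if (config$n_genes == 0) {
    return(data.frame(gene_id = character(0), seqid = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  glen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 config$n_genes, replace = TRUE)
  starts <- integer(0)
  tries <- 0
  for (i in seq_len(config$n_genes)) {
    repeat {
      tries <- tries + 1
      if (tries > 10000) stop("gene placement failed; genome too small")
      s <- sample(config$genome_length - glen[i] - 3000L, 1) + 1500L
      ok <- !length(starts) ||
        all(s > starts + glen[seq_along(starts)] + 2500L | s + glen[i] + 2500L < starts)
      if (ok) { starts <- c(starts, s); break }
    }
  }
  data.frame(gene_id = sprintf("G%03d", seq_len(config$n_genes)),
             seqid = "chr1", start = starts, end = starts + glen - 1L,
             strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

make_exons <- function(genes) {
  if (!nrow(genes)) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start + 1L
    e1_end <- g$start + as.integer(len * 0.4)
    e2_start <- g$end - as.integer(len * 0.4)
    data.frame(gene_id = g$gene_id,
               start = c(g$start, e2_start), end = c(e1_end, g$end),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

place_points <- function(n, kinds, genes, config, background) {
  min_sep <- 400L
  margin <- 1000L
  pts <- integer(0)
  near_gene <- function(x, d) {
    nrow(genes) > 0 && any(x >= genes$start - d & x <= genes$end + d)
  }
  in_gene <- function(x) {
    nrow(genes) > 0 && any(x >= genes$start - 200L & x <= genes$end + 200L)
  }
  # a plain insertion at x joins background [x-k+1, x] and [x+1, x+k]; if
  # those happen to look like a 9/10-bp duplication the planted "other"
  # class would not be recoverable, so such points are rejected
  chance_tsd <- function(x) {
    for (k in c(10L, 9L)) {
      l <- strsplit(substring(background, x - k + 1L, x), "")[[1]]
      r <- strsplit(substring(background, x + 1L, x + k), "")[[1]]
      if (sum(l != r) <= 1L) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n)) {
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > 20000) stop("feature placement failed; genome too small")
      x <- sample(config$genome_length - 2L * margin, 1) + margin
      if (in_gene(x)) next
      if (config$ml_near_genes && kinds[i] == "ml" && !near_gene(x, 2000L)) next
      if (config$mt_far_from_genes && kinds[i] %in% c("mt", "cluster") &&
          near_gene(x, 10000L)) next
      if (length(pts) && any(abs(pts - x) < min_sep)) next
      if (kinds[i] == "other" && chance_tsd(x)) next
      pts <- c(pts, x)
      break
    }
  }
  pts
}

#' Write a synthetic dataset to disk
#'
#' Emits genome FASTA (60-column wrap), hits as BED6 and RepeatMasker .out
#' dialect, gene models as GFF3, family consensus FASTA, and the truth
#' ledger as TSV.
#'
#' @param sim Result of [build_genome()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_fasta(sim$consensi, file.path(dir, "consensus.fa"))
  write_bed(sim$hits, file.path(dir, "hits.bed"))
  write_repeatmasker_out(sim$hits, file.path(dir, "hits.out"))
  write_gff3(sim$genes, sim$exons, file.path(dir, "genes.gff3"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Derive a second genome by deleting and inserting elements
#'
#' Deletes a chosen set (or random fraction) of planted elements — removing
#' exactly the element bases so the flanks heal — and inserts new elements
#' absent from the first genome.  The ground-truth ledger records every
#' element's fate and its coordinates in the derived genome.
#'
#' @param sim Result of [build_genome()].
#' @param deletion_fraction Fraction of planted elements to delete.
#' @param insertion_count Number of new elements to insert at random
#'   background positions.
#' @param seed Integer seed.
#' @param delete_ids Optional explicit element ids to delete (overrides
#'   \code{deletion_fraction}).
#' @param substitute_ids Optional element ids whose body is replaced by a
#'   fresh copy of a different family's consensus (a substitution event at
#'   the same locus).
#' @param insert_into_cluster_ids Optional cluster ids that each receive
#'   one additional member, inserted at the midpoint of the tract between
#'   the first two members (an insertion event inside the cluster).
#' @return List with \code{genome} (derived genome), \code{truth} (ledger
#'   with fate and derived-genome coordinates \code{start2}/\code{end2};
#'   inserted elements appear as new rows with fate "inserted") and
#'   \code{config}.
#' @export
derive_genome <- function(sim, deletion_fraction = 0, insertion_count = 0,
                          seed, delete_ids = NULL, substitute_ids = NULL,
                          insert_into_cluster_ids = NULL) {
  stopifnot(deletion_fraction >= 0, deletion_fraction <= 1)
  truth <- sim$truth
  g <- sim$genome[[1]]
  with_seed(seed, {
    if (is.null(delete_ids) && deletion_fraction > 0) {
      n_del <- round(deletion_fraction * nrow(truth))
      delete_ids <- truth$element_id[sample(nrow(truth), n_del)]
    }
    delete_ids <- setdiff(delete_ids, substitute_ids)

    # edit list: (start, end) replaced by repl; insertions have end = start-1
    edits <- NULL
    add_edit <- function(start, end, repl, note) {
      rbind(edits, data.frame(start = start, end = end, repl = repl,
                              note = note, stringsAsFactors = FALSE))
    }
    for (id in delete_ids) {
      r <- truth[truth$element_id == id, ]
      edits <- add_edit(r$start, r$end, "", paste0("del:", id))
    }
    fams <- names(sim$consensi)
    for (id in substitute_ids) {
      r <- truth[truth$element_id == id, ]
      other_fam <- if (length(fams) > 1) {
        sample(setdiff(fams, r$family), 1)
      } else {
        fams
      }
      body <- mutate_copy(sim$consensi[[other_fam]], 0, 0, 1L)
      if (r$strand == "-") body <- revcomp(body)
      edits <- add_edit(r$start, r$end, body, paste0("sub:", id, ":", other_fam))
    }
    new_rows <- NULL
    for (cid in insert_into_cluster_ids) {
      mem <- truth[!is.na(truth$cluster_id) & truth$cluster_id == cid, ]
      mem <- mem[order(mem$start), ]
      if (nrow(mem) < 2) stop("cluster ", cid, " has fewer than 2 members")
      gap_mid <- (mem$end[1] + mem$start[2]) %/% 2L
      fam <- sample(fams, 1)
      body <- mutate_copy(sim$consensi[[fam]], 0, 0,
                          sample.int(2147483600L, 1))
      edits <- add_edit(gap_mid + 1L, gap_mid, body, paste0("insC:", cid, ":", fam))
      new_rows <- rbind(new_rows, data.frame(
        element_id = NA_character_, seqid = "chr1",
        start = NA_integer_, end = NA_integer_, strand = "+",
        family = fam, class = "mt", p = 0, q = 0, cluster_id = cid,
        tsd = NA_character_, units_left = NA_integer_,
        units_right = NA_integer_, fate = "inserted",
        src_start = gap_mid + 1L, body_len = nchar(body),
        stringsAsFactors = FALSE))
    }
    if (insertion_count > 0) {
      occupied <- sort(c(truth$start, truth$end))
      for (k in seq_len(insertion_count)) {
        repeat {
          x <- sample(nchar(g) - 2000L, 1) + 1000L
          if (all(abs(c(truth$start, truth$end) - x) > 900L)) break
        }
        fam <- sample(fams, 1)
        body <- mutate_copy(sim$consensi[[fam]], 0, 0,
                            sample.int(2147483600L, 1))
        edits <- add_edit(x + 1L, x, body, paste0("insF:", fam))
        new_rows <- rbind(new_rows, data.frame(
          element_id = NA_character_, seqid = "chr1",
          start = NA_integer_, end = NA_integer_, strand = "+",
          family = fam, class = "other", p = 0, q = 0,
          cluster_id = NA_character_, tsd = NA_character_,
          units_left = NA_integer_, units_right = NA_integer_,
          fate = "inserted", src_start = x + 1L, body_len = nchar(body),
          stringsAsFactors = FALSE))
      }
    }

    if (is.null(edits)) {
      truth$fate <- "retained"
      truth$start2 <- truth$start
      truth$end2 <- truth$end
      return(list(genome = c(chr1 = g), truth = truth, config = sim$config))
    }
    edits <- edits[order(edits$start), ]
    if (nrow(edits) > 1 &&
        any(edits$start[-1] <= edits$end[-nrow(edits)])) {
      # overlapping edits cannot arise from distinct non-nested elements
      stop("conflicting edits")
    }

    # apply edits left to right
    segs <- character(0)
    prev <- 1L
    for (i in seq_len(nrow(edits))) {
      segs <- c(segs, substring(g, prev, edits$start[i] - 1L), edits$repl[i])
      prev <- edits$end[i] + 1L
    }
    segs <- c(segs, substring(g, prev, nchar(g)))
    g2 <- paste(segs, collapse = "")

    # coordinate shift for positions after each edit
    delta <- nchar(edits$repl) - (edits$end - edits$start + 1L)
    shift_of <- function(x) {
      vapply(x, function(v) sum(delta[edits$end < v]), 1)
    }

    truth$fate <- "retained"
    truth$fate[truth$element_id %in% delete_ids] <- "deleted"
    truth$fate[truth$element_id %in% substitute_ids] <- "substituted"
    truth$start2 <- NA_integer_
    truth$end2 <- NA_integer_
    keep <- truth$fate == "retained"
    truth$start2[keep] <- as.integer(truth$start[keep] + shift_of(truth$start[keep]))
    truth$end2[keep] <- truth$start2[keep] + (truth$end[keep] - truth$start[keep])

    if (!is.null(new_rows)) {
      # shift from edits strictly upstream of the insertion point (its own
      # zero-length edit at end = src_start - 1 must not count)
      shift_ins <- vapply(new_rows$src_start,
                          function(v) sum(delta[edits$end < v - 1L]), 1)
      new_rows$start2 <- as.integer(new_rows$src_start + shift_ins)
      new_rows$end2 <- new_rows$start2 + new_rows$body_len - 1L
      new_rows$element_id <- sprintf("N%04d", seq_len(nrow(new_rows)))
      new_rows$src_start <- NULL
      new_rows$body_len <- NULL
      truth <- rbind(truth, new_rows)
    }
    list(genome = c(chr1 = g2), truth = truth, config = sim$config)
  })
}

#' Simulate mapped read-pair spans
#'
#' Emits mapped-pair records directly (reference, outer span, mate
#' intervals) with no sequencing-error model — the read-pair PAV rule only
#' needs fragment spans.  Either a fixed number of random pairs or a
#' deterministic tiling is produced.
#'
#' @param genome Named character vector of sequences (or a single string).
#' @param insert_size_mean Mean outer fragment size, bp.
#' @param insert_size_sd Fragment size standard deviation (random mode).
#' @param n_pairs Number of random pairs (random mode).
#' @param tiling_step If set, deterministic tiling: one pair every
#'   \code{tiling_step} bp at exactly \code{insert_size_mean} span.
#' @param read_length Read length, bp.
#' @param seed Integer seed (random mode).
#' @return Data frame: reference, outer_start, outer_end, mate1_start,
#'   mate1_end, mate2_start, mate2_end, proper_pair.
#' @export
simulate_read_pairs <- function(genome, insert_size_mean = 500,
                                insert_size_sd = 50, n_pairs = NULL,
                                tiling_step = NULL, read_length = 150,
                                seed = NULL) {
  if (insert_size_mean <= 2 * read_length) {
    stop("insert_size_mean must exceed 2 * read_length")
  }
  read_length <- as.integer(read_length)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  one_ref <- function(ref) {
    L <- nchar(genome[[ref]])
    if (!is.null(tiling_step)) {
      span <- as.integer(insert_size_mean)
      if (L < span) return(NULL)
      starts <- seq(1L, L - span + 1L, by = as.integer(tiling_step))
      spans <- rep(span, length(starts))
    } else {
      if (is.null(n_pairs)) stop("give n_pairs or tiling_step")
      if (n_pairs == 0) return(NULL)
      spans <- pmax(as.integer(round(
        stats::rnorm(n_pairs, insert_size_mean, insert_size_sd))),
        2L * read_length)
      spans <- pmin(spans, as.integer(L))
      starts <- vapply(spans, function(s) sample(L - s + 1L, 1), 1L)
    }
    data.frame(reference = ref, outer_start = starts,
               outer_end = starts + spans - 1L,
               mate1_start = starts, mate1_end = starts + read_length - 1L,
               mate2_start = starts + spans - read_length,
               mate2_end = starts + spans - 1L,
               proper_pair = TRUE, stringsAsFactors = FALSE)
  }
  empty <- data.frame(reference = character(0), outer_start = integer(0),
                      outer_end = integer(0), mate1_start = integer(0),
                      mate1_end = integer(0), mate2_start = integer(0),
                      mate2_end = integer(0), proper_pair = logical(0),
                      stringsAsFactors = FALSE)
  build <- function() {
    out <- do.call(rbind, lapply(names(genome), one_ref))
    if (is.null(out)) empty else out
  }
  if (is.null(tiling_step)) with_seed(seed, build()) else build()
}

#' Write read pairs as minimal SAM
#'
#' One properly-paired alignment line per mate, coordinates pre-filled from
#' the simulated spans; sequences and qualities are starred out.
#'
#' @param pairs Read-pair table from [simulate_read_pairs()].
#' @param seq_lengths Named vector of reference lengths for the header.
#' @param path Output path.
#' @export
write_pairs_sam <- function(pairs, seq_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (s in names(seq_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", s, as.integer(seq_lengths[[s]])), con)
  }
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    rl1 <- p$mate1_end - p$mate1_start + 1L
    rl2 <- p$mate2_end - p$mate2_start + 1L
    tlen <- p$outer_end - p$outer_start + 1L
    qn <- sprintf("pair%06d", i)
    writeLines(sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                       qn, p$reference, p$mate1_start, rl1, p$mate2_start, tlen), con)
    writeLines(sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                       qn, p$reference, p$mate2_start, rl2, p$mate1_start, -tlen), con)
  }
  invisible(path)
}

#' Read paired alignments from SAM text into a read-pair table
#'
#' Uses reference, position, CIGAR-free mate length and template length
#' only; one record per pair is reconstructed from the forward mate
#' (TLEN > 0).
#'
#' @param path Path to a SAM file.
#' @return Read-pair table as from [simulate_read_pairs()].
#' @export
read_pairs_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(reference = character(0), outer_start = integer(0),
                      outer_end = integer(0), mate1_start = integer(0),
                      mate1_end = integer(0), mate2_start = integer(0),
                      mate2_end = integer(0), proper_pair = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t")
  rows <- lapply(f, function(x) {
    flag <- as.integer(x[[2]])
    tlen <- as.integer(x[[9]])
    if (tlen <= 0) return(NULL)  # keep the forward mate of each pair
    rl <- as.integer(sub("M$", "", x[[6]]))
    pos <- as.integer(x[[4]])
    data.frame(reference = x[[3]], outer_start = pos,
               outer_end = pos + tlen - 1L,
               mate1_start = pos, mate1_end = pos + rl - 1L,
               mate2_start = as.integer(x[[8]]),
               mate2_end = pos + tlen - 1L,
               proper_pair = bitwAnd(flag, 2L) > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}
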