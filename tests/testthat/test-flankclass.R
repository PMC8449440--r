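test_that("dinucleotide run finder reports canonical motifs and maximal runs", {
  runs <- find_dinucleotide_runs(strrep("TA", 8), min_units = 8)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$motif, "TA")
  expect_identical(runs$unit_count, 8L)
  expect_identical(runs$start, 1L)
  expect_identical(runs$end, 16L)

  runs <- find_dinucleotide_runs(strrep("GA", 8), min_units = 8)
  expect_identical(runs$motif, "GA")
  expect_false(any(runs$motif == "TA"))

  # AT phase canonicalizes to TA; odd-length runs keep full extent
  runs <- find_dinucleotide_runs(paste0("CCG", strrep("AT", 9), "A", "GCC"),
                                 min_units = 8)
  expect_identical(runs$motif, "TA")
  expect_identical(runs$end - runs$start + 1L, 19L)
  expect_identical(runs$unit_count, 9L)

  # embedded run is located exactly
  set.seed(1)
  seq <- paste0(random_dna(50, 0.5), strrep("CT", 10), random_dna(50, 0.5))
  runs <- find_dinucleotide_runs(seq, min_units = 8)
  ct <- runs[runs$motif == "CT", ]
  expect_identical(nrow(ct), 1L)
  expect_lte(abs(ct$start - 51L), 2L)  # background may chance-extend a base
})

test_that("run finder stays silent on i.i.d. background", {
  # expected maximal-run count at >= 16 alternating bases is of order
  # L * 4 * (1/4)^16: far below one event in 100 kb
  set.seed(99)
  for (i in 1:10) {
    bg <- random_dna(10000, 0.5)
    expect_identical(nrow(find_dinucleotide_runs(bg, min_units = 8)), 0L)
  }
})

test_that("interior mismatches are absorbed only within budget", {
  seq <- paste0(strrep("TA", 6), "C", "A", strrep("TA", 5))  # TA...C interrupt
  expect_identical(nrow(find_dinucleotide_runs(seq, min_units = 8,
                                               max_mismatch_per_run = 0)), 0L)
  runs <- find_dinucleotide_runs(seq, min_units = 8, max_mismatch_per_run = 1)
  expect_identical(nrow(runs), 1L)
  expect_lt(runs$purity, 1)
})

test_that("flank profiling requires runs adjacent to the element terminus", {
  sim <- shared_sim()
  tr <- sim$truth
  # planted mt elements sit mid-tract: both sides flanked
  mt_id <- tr$element_id[tr$class == "mt"][1]
  prof <- profile_flanks(sim$hits[sim$hits$element_id == mt_id, ], sim$genome)
  expect_identical(prof$ta_sides, "both")

  # constructed element with TA only on the left
  g <- c(chrX = paste0(random_dna(100, 0.5), strrep("TA", 10),
                       strrep("G", 60), random_dna(100, 0.5)))
  hit <- data.frame(element_id = "x", seqid = "chrX", start = 121L,
                    end = 180L, strand = "+", family = "f",
                    cons_start = 1L, cons_end = 60L, cons_length = 60L,
                    stringsAsFactors = FALSE)
  expect_identical(profile_flanks(hit, g)$ta_sides, "left")

  # a GA run whose inner edge is 3 bp from the terminus is not flanking at
  # max_offset 2, but is at 3
  g2 <- c(chrX = paste0(random_dna(60, 0.5), strrep("GA", 10), "CCC",
                        strrep("T", 40), random_dna(80, 0.5)))
  hit2 <- data.frame(element_id = "y", seqid = "chrX", start = 84L,
                     end = 123L, strand = "+", family = "f",
                     cons_start = 1L, cons_end = 40L, cons_length = 40L,
                     stringsAsFactors = FALSE)
  expect_false(profile_flanks(hit2, g2, max_offset = 2)$ga_5prime)
  expect_true(profile_flanks(hit2, g2, max_offset = 3)$ga_5prime)

  # insufficient flank near the contig end is flagged
  hit3 <- hit2
  hit3$start <- 5L; hit3$end <- 44L
  expect_true(profile_flanks(hit3, g2)$insufficient_flank)
})

test_that("flank profiling is strand symmetric", {
  sim <- shared_sim()
  hits <- sim$hits
  g <- sim$genome
  n <- nchar(g[[1]])
  g_rc <- c(chr1 = revcomp(g[[1]]))
  for (i in seq_len(min(nrow(hits), 12))) {
    h <- hits[i, ]
    p1 <- profile_flanks(h, g)
    h2 <- h
    h2$start <- n - h$end + 1L
    h2$end <- n - h$start + 1L
    h2$strand <- if (h$strand == "+") "-" else "+"
    p2 <- profile_flanks(h2, g_rc)
    if (p1$ta_sides %in% c("both", "none")) {
      expect_identical(p2$ta_sides, p1$ta_sides)
    } else {
      expect_identical(p2$ta_sides, setdiff(c("left", "right"), p1$ta_sides))
    }
    expect_identical(p2$ga_5prime, p1$ga_5prime)
    expect_identical(p2$ct_3prime, p1$ct_3prime)
  }
})

test_that("TSD detection calls planted duplications and resists noise", {
  sim <- shared_sim()
  tr <- sim$truth
  ml <- tr[tr$class == "ml", ]
  for (i in seq_len(nrow(ml))) {
    hit <- sim$hits[sim$hits$element_id == ml$element_id[i], ]
    call <- detect_tsd(hit, sim$genome)
    expect_identical(call$tsd_length, nchar(ml$tsd[i]))
    expect_identical(call$mismatches, 0L)
  }

  # one-mismatch pair still called at max_mismatch = 1
  g <- c(chrX = paste0(random_dna(40, 0.2), "ACGTACGTAG",
                       strrep("G", 30), "ACGTACGTAC", random_dna(40, 0.2)))
  hit <- data.frame(element_id = "z", seqid = "chrX", start = 51L, end = 80L,
                    strand = "+", family = "f", cons_start = 1L,
                    cons_end = 30L, cons_length = 30L, stringsAsFactors = FALSE)
  call <- detect_tsd(hit, g, max_mismatch = 1)
  expect_identical(call$tsd_length, 10L)
  expect_identical(call$mismatches, 1L)
  expect_true(is.na(detect_tsd(hit, g, max_mismatch = 0)$tsd_length))

  # i.i.d. flanks: no-call rate above 99.9% (binomial tail over both k)
  set.seed(42)
  calls <- 0L
  for (i in 1:2000) {
    gg <- c(chrR = random_dna(60, 0.5))
    h <- data.frame(element_id = "r", seqid = "chrR", start = 21L, end = 40L,
                    strand = "+", family = "f", cons_start = 1L,
                    cons_end = 20L, cons_length = 20L, stringsAsFactors = FALSE)
    if (!is.na(detect_tsd(h, gg)$tsd_length)) calls <- calls + 1L
  }
  expect_lt(calls / 2000, 0.001)
})

test_that("classification rule table: mt needs both flanks, ml needs TSD alone", {
  prof <- function(lm, rm) {
    data.frame(element_id = "e", left_motif = lm, right_motif = rm,
               ta_sides = "none", ga_5prime = FALSE, ct_3prime = FALSE,
               insufficient_flank = FALSE, stringsAsFactors = FALSE)
  }
  tsd <- function(len) data.frame(element_id = "e", tsd_length = len,
                                  stringsAsFactors = FALSE)
  expect_identical(classify_element(prof("TA", "TA"), tsd(NA_integer_)), "mt")
  expect_identical(classify_element(prof("TA", "GA"), tsd(NA_integer_)), "mt")
  expect_identical(classify_element(prof(NA, NA), tsd(9L)), "ml")
  expect_identical(classify_element(prof(NA, NA), tsd(10L)), "ml")
  expect_identical(classify_element(prof("TA", NA), tsd(NA_integer_)), "other")
  expect_identical(classify_element(prof(NA, "TA"), tsd(10L)), "other")
  expect_identical(classify_element(prof(NA, NA), tsd(NA_integer_)), "other")
  # mt precedence when both kinds of evidence are present
  expect_identical(classify_element(prof("TA", "TA"), tsd(10L)), "mt")
})

test_that("classification recovers every planted class on the shared genome", {
  sim <- shared_sim()
  cls <- classify_elements(sim$hits, sim$genome)
  m <- merge(cls, sim$truth[, c("element_id", "class")], by = "element_id")
  expect_identical(nrow(m), nrow(sim$hits))
  expect_true(all(m$label == m$class))
  # labels are exhaustive and exclusive
  expect_true(all(cls$label %in% c("mt", "ml", "other")))
})
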