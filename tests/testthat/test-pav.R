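# Shared PAV fixture: a clusterless genome pair with known fates (element
# PAV isolates flank evidence per element, so members of adjacent-insertion
# clusters are tested separately at the cluster level).
pav_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(genome_length = 120000, n_genes = 0,
                              n_mt = 12, n_ml = 5, n_other = 3,
                              n_ms_tracts = 4, cluster_fraction = 0,
                              divergence_grid = list(c(0.02, 0.01)),
                              seed = 501)
      sim <- build_genome(cfg)
      der <- derive_genome(sim, deletion_fraction = 0.5,
                           insertion_count = 2, seed = 502)
      cache <<- list(sim = sim, der = der)
    }
    cache
  }
})

test_that("query extraction records element offsets and demands flanks", {
  sim <- pav_fixture()$sim
  h <- sim$hits[1, ]
  q <- extract_query(h, sim$genome, flank = 200)
  expect_identical(nchar(q$seq), as.integer(h$end - h$start + 1L + 400L))
  expect_identical(q$elem_start, 201L)
  expect_identical(substring(q$seq, q$elem_start, q$elem_end),
                   substring(sim$genome[[1]], h$start, h$end))
  near_end <- h
  near_end$start <- 100L
  near_end$end <- 250L
  expect_error(extract_query(near_end, sim$genome, flank = 200),
               "insufficient")
})

test_that("homolog search finds verbatim queries and rejects flank-only matches", {
  set.seed(77)
  target <- c(chrA = random_dna(20000, 0.45))
  query <- substring(target[[1]], 5001, 5640)
  hit <- search_homolog(query, target)
  expect_identical(hit$t_start, 5001L)
  expect_identical(hit$t_end, 5640L)
  expect_identical(hit$identity, 1)

  # flank-only survivor: drop the middle 240 bp from the target
  target2 <- c(chrA = paste0(substring(target[[1]], 1, 5200),
                             substring(target[[1]], 5441, 20000)))
  expect_null(search_homolog(query, target2))

  # 5% substitutions still found above the 90% identity floor
  mut <- mutate_copy(query, 0.03, 0.02, seed = 9)
  hit <- search_homolog(mut, target)
  expect_identical(hit$t_start, 5001L)
  expect_gte(hit$identity, 0.90)
})

test_that("homolog search agrees with a whole-genome alignment oracle", {
  set.seed(88)
  target <- c(chrA = random_dna(10000, 0.5))
  mat <- Biostrings::nucleotideSubstitutionMatrix(5, -4, baseOnly = FALSE)
  for (rep in 1:20) {
    qs <- sample(9000, 1)
    qlen <- sample(200:800, 1)
    query <- mutate_copy(substring(target[[1]], qs, qs + qlen - 1),
                         0.02, 0.01, seed = rep)
    got <- search_homolog(query, target)
    # oracle: local alignment against the entire target, no anchoring
    aln <- Biostrings::pairwiseAlignment(query, target[[1]],
                                         substitutionMatrix = mat,
                                         gapOpening = 10, gapExtension = 0.5,
                                         type = "local")
    expect_identical(got$t_start,
                     BiocGenerics::start(Biostrings::subject(aln)))
    expect_identical(got$t_end,
                     BiocGenerics::end(Biostrings::subject(aln)))
  }
})

test_that("element PAV equals ground-truth fate on a derived genome", {
  fx <- pav_fixture()
  calls <- call_element_pav(fx$sim$hits, fx$sim$genome, fx$der$genome)
  m <- merge(calls, fx$der$truth[fx$der$truth$fate != "inserted",
                                 c("element_id", "fate")],
             by = "element_id")
  expect_identical(nrow(m), nrow(fx$sim$hits))
  expect_true(all(m$status[m$fate == "retained"] == "present"))  # sensitivity 1
  expect_true(all(m$status[m$fate == "deleted"] == "absent"))    # specificity 1
  # present calls land on the recorded derived coordinates
  kept <- merge(m[m$fate == "retained", ], fx$der$truth, by = "element_id")
  pres <- merge(calls, kept[, c("element_id", "start2", "end2")],
                by = "element_id")
  expect_true(all(pres$t_start <= pres$start2 - 150))
  expect_true(all(pres$t_end >= pres$end2 + 150))
})

test_that("cluster PAV applies the four-condition rule with exact events", {
  # members carry enough divergence that distinct copies fall below the
  # 90% pairing floor: event attribution is then unambiguous
  cfg <- synthetic_config(genome_length = 250000, n_genes = 0, n_mt = 20,
                          n_ml = 0, n_other = 0, n_ms_tracts = 0,
                          cluster_fraction = 1, cluster_size_range = c(3, 4),
                          divergence_grid = list(c(0.05, 0.03)),
                          seed = 601)
  sim <- build_genome(cfg)
  tr <- sim$truth
  cl <- unique(tr$cluster_id[!is.na(tr$cluster_id)])
  expect_gte(length(cl), 4L)
  members <- function(k) {
    sim$hits[sim$hits$element_id %in%
               tr$element_id[!is.na(tr$cluster_id) & tr$cluster_id == cl[k]], ]
  }
  del_id <- tr$element_id[!is.na(tr$cluster_id) & tr$cluster_id == cl[1]][2]
  sub_id <- tr$element_id[!is.na(tr$cluster_id) & tr$cluster_id == cl[2]][1]
  der <- derive_genome(sim, seed = 602, delete_ids = del_id,
                       substitute_ids = sub_id,
                       insert_into_cluster_ids = cl[3])

  # untouched cluster: present, no events, symmetric under genome swap
  r4 <- call_cluster_pav(members(4), sim$genome, der$genome, sim$consensi)
  expect_identical(r4$status, "present")
  expect_identical(nrow(r4$events), 0L)

  r1 <- call_cluster_pav(members(1), sim$genome, der$genome, sim$consensi)
  expect_identical(r1$status, "absent")
  expect_identical(r1$events$type, "deletion")
  expect_identical(r1$events$source_element_id, del_id)

  r2 <- call_cluster_pav(members(2), sim$genome, der$genome, sim$consensi)
  expect_identical(r2$status, "absent")
  expect_identical(r2$events$type, "substitution")
  expect_identical(r2$events$source_element_id, sub_id)
  # the substituted copy in the derived genome is the other family
  expect_false(r2$events$target_family ==
                 tr$family[tr$element_id == sub_id])

  r3 <- call_cluster_pav(members(3), sim$genome, der$genome, sim$consensi)
  expect_identical(r3$status, "absent")
  expect_identical(r3$events$type, "insertion")
  ins <- der$truth[der$truth$fate == "inserted", ]
  expect_identical(r3$events$target_start, ins$start2)
  expect_identical(r3$events$target_end, ins$end2)
})

test_that("cluster PAV is symmetric for untouched genome pairs", {
  cfg <- synthetic_config(genome_length = 150000, n_genes = 0, n_mt = 8,
                          n_ml = 0, n_other = 0, n_ms_tracts = 0,
                          cluster_fraction = 1, cluster_size_range = c(2, 3),
                          seed = 603)
  sim <- build_genome(cfg)
  der <- derive_genome(sim, seed = 604)  # no edits
  tr <- sim$truth
  cl <- unique(tr$cluster_id[!is.na(tr$cluster_id)])
  mh <- sim$hits[sim$hits$element_id %in%
                   tr$element_id[!is.na(tr$cluster_id) & tr$cluster_id == cl[1]], ]
  fwd <- call_cluster_pav(mh, sim$genome, der$genome, sim$consensi)
  rev <- call_cluster_pav(mh, der$genome, sim$genome, sim$consensi)
  expect_identical(fwd$status, "present")
  expect_identical(rev$status, "present")
})

test_that("read-pair PAV obeys the 50-bp margin exactly", {
  sim <- pav_fixture()$sim
  rp <- simulate_read_pairs(sim$genome, insert_size_mean = 800,
                            tiling_step = 1, read_length = 150)
  calls <- call_read_pav(sim$hits, rp, margin = 50)
  expect_true(all(calls$status == "present"))

  # boundary arithmetic on a single synthetic pair
  h <- sim$hits[1, ]
  exact <- data.frame(reference = h$seqid, outer_start = h$start - 50L,
                      outer_end = h$end + 50L, mate1_start = h$start - 50L,
                      mate1_end = h$start + 99L, mate2_start = h$end - 99L,
                      mate2_end = h$end + 50L, proper_pair = TRUE,
                      stringsAsFactors = FALSE)
  expect_identical(call_read_pav(h, exact)$status, "present")
  short_left <- transform(exact, outer_start = h$start - 49L)
  expect_identical(call_read_pav(h, short_left)$status, "absent")
  short_right <- transform(exact, outer_end = h$end + 49L)
  expect_identical(call_read_pav(h, short_right)$status, "absent")
  improper <- transform(exact, proper_pair = FALSE)
  expect_identical(call_read_pav(h, improper)$status, "absent")
  expect_identical(call_read_pav(h, exact[0, ])$status, "absent")
})

test_that("read-pair PAV matches fate on the derived genome at tiling coverage", {
  fx <- pav_fixture()
  rp2 <- simulate_read_pairs(fx$der$genome, insert_size_mean = 800,
                             tiling_step = 1, read_length = 150)
  tr2 <- fx$der$truth
  kept <- tr2[tr2$fate == "retained", ]
  hits2 <- data.frame(element_id = kept$element_id, seqid = kept$seqid,
                      start = kept$start2, end = kept$end2,
                      strand = kept$strand, family = kept$family,
                      cons_start = 1L, cons_end = 100L, cons_length = 100L,
                      stringsAsFactors = FALSE)
  expect_true(all(call_read_pav(hits2, rp2)$status == "present"))
  # deleted elements no longer exist in the derived genome: reads simulated
  # from it cannot span their source coordinates plus margins after shift,
  # so PAV over source coordinates of deleted elements uses genome-1 reads
  rp1 <- simulate_read_pairs(fx$sim$genome, insert_size_mean = 800,
                             tiling_step = 1, read_length = 150)
  expect_true(all(call_read_pav(fx$sim$hits, rp1)$status == "present"))
})

test_that("presence fractions summarize per class", {
  calls <- data.frame(element_id = sprintf("E%02d", 1:10),
                      status = c(rep("present", 6), rep("absent", 4)),
                      stringsAsFactors = FALSE)
  classes <- data.frame(element_id = sprintf("E%02d", 1:10),
                        label = rep(c("mt", "ml"), each = 5),
                        stringsAsFactors = FALSE)
  s <- pav_summary(calls, classes)
  expect_equal(s$fraction_present[s$label == "mt"], 1.0)
  expect_equal(s$fraction_present[s$label == "ml"], 0.2)
  expect_true(all(s$fraction_present >= 0 & s$fraction_present <= 1))
})
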