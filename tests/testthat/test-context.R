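test_that("window tracks count midpoints and sum bp as specified", {
  ivs <- data.frame(seqid = "chr1", start = 120100L, end = 120300L,
                    stringsAsFactors = FALSE)
  lens <- c(chr1 = 1000000)
  # empty set: all-zero track
  tr0 <- window_density(ivs[0, ], lens, window = 500000, step = 100000)
  expect_true(all(tr0$value == 0))
  # one midpoint (120200) falls in every window whose start is within
  # width of it: starts 1, 100001 (two windows at step 100k before it)
  tr <- window_density(ivs, lens, window = 500000, step = 100000)
  expect_identical(sum(tr$value), 2)
  expect_identical(tr$value[tr$window_start %in% c(1, 100001)], c(1, 1))
  # step = width partitions: midpoint counts total the interval count
  set.seed(3)
  ivs2 <- data.frame(seqid = "chr1",
                     start = sort(sample(900000, 200)),
                     stringsAsFactors = FALSE)
  ivs2$end <- ivs2$start + 99L
  trp <- window_density(ivs2, lens, window = 100000, step = 100000)
  expect_identical(sum(trp$value), 200)
  # bp mode with step = width sums to total interval bp (all internal)
  ivs3 <- ivs2[ivs2$end < 999000, ]
  trb <- window_density(ivs3, lens, window = 100000, step = 100000,
                        mode = "bp")
  expect_identical(sum(trb$value), sum(ivs3$end - ivs3$start + 1))
})

test_that("pearson r2 behaves under identity, negation and affine rescale", {
  a <- data.frame(seqid = "c", window_start = 1:10, value = c(1:9, 20))
  b <- a
  expect_equal(pearson_r2(a, b)$r_squared, 1)
  neg <- transform(a, value = -value)
  r <- pearson_r2(a, neg)
  expect_equal(r$r, -1)
  expect_equal(r$r_squared, 1)
  scaled <- transform(a, value = 3 * value + 7)
  expect_equal(pearson_r2(a, scaled)$r, 1)
  const <- transform(a, value = 5)
  expect_error(pearson_r2(a, const), "variance")
  expect_error(pearson_r2(a, a[1:5, ]), "windows")
})

test_that("gene context categories are non-exclusive and distances exact", {
  genes <- data.frame(gene_id = c("gL", "gR"), seqid = "chr1",
                      start = c(10000L, 14500L), end = c(12000L, 16500L),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gL", "gL", "gR"),
                      start = c(10000L, 11500L, 14500L),
                      end = c(10800L, 12000L, 16500L),
                      stringsAsFactors = FALSE)
  gm <- list(genes = genes, exons = exons)
  hit <- function(s, e) {
    data.frame(element_id = "e", seqid = "chr1", start = as.integer(s),
               end = as.integer(e), strand = "+", family = "f",
               cons_start = 1L, cons_end = 100L, cons_length = 100L,
               stringsAsFactors = FALSE)
  }
  # 1 kb before gL (plus strand): upstream only
  a <- assign_gene_context(hit(8900, 9000), gm)
  expect_true(a$upstream)
  expect_false(a$downstream || a$intron || a$exon || a$intergenic)
  expect_identical(a$distance, 1000L)
  # between the genes, ~1.2 kb from each: downstream of gL, upstream of gR
  b <- assign_gene_context(hit(13250, 13350), gm)
  expect_true(b$upstream && b$downstream)
  expect_false(b$intergenic)
  # inside gL's intron (10801..11499)
  ci <- assign_gene_context(hit(10900, 11000), gm)
  expect_true(ci$intron)
  expect_identical(ci$distance, 0L)
  # exon overlap is a separate flag, outside the four categories
  ce <- assign_gene_context(hit(10100, 10200), gm)
  expect_true(ce$exon)
  expect_false(ce$intergenic)
  # far away: intergenic with exact distance
  d <- assign_gene_context(hit(26500, 26600), gm)
  expect_true(d$intergenic)
  expect_identical(d$distance, 10000L)
  # minus-strand gene flips upstream/downstream
  gm2 <- gm
  gm2$genes$strand <- c("-", "-")
  a2 <- assign_gene_context(hit(8900, 9000), gm2)
  expect_true(a2$downstream)
  expect_false(a2$upstream)
})

test_that("gene groups follow nearby element classes and AWAY is exhaustive", {
  cfg <- synthetic_config(genome_length = 250000, n_genes = 8, n_mt = 10,
                          n_ml = 8, n_other = 0, n_ms_tracts = 0,
                          cluster_fraction = 0, ml_near_genes = TRUE,
                          mt_far_from_genes = TRUE, seed = 702)
  sim <- build_genome(cfg)
  cls <- classify_elements(sim$hits, sim$genome)
  gm <- list(genes = sim$genes, exons = sim$exons)
  grp <- group_genes(gm, sim$hits, cls)
  expect_identical(nrow(grp), 8L)
  # exhaustive: every gene is AWAY or carries at least one label (no
  # body-only overlaps arise from this generator layout)
  labelled <- grp$u_mt | grp$d_mt | grp$u_ml | grp$d_ml
  expect_true(all(grp$away | labelled))
  expect_true(all(!(grp$away & labelled)))
  # ml elements were planted near genes: some gene carries an ml label
  expect_true(any(grp$u_ml | grp$d_ml))
  # mt elements were kept 10 kb away: no gene carries an mt label
  expect_false(any(grp$u_mt | grp$d_mt))

  # brute-force check of one labelled gene
  gid <- grp$gene_id[which(grp$u_ml | grp$d_ml)[1]]
  g <- sim$genes[sim$genes$gene_id == gid, ]
  ml_hits <- sim$hits[cls$label == "ml", ]
  near <- any(ml_hits$start <= g$end + 2000 & ml_hits$end >= g$start - 2000)
  expect_true(near)
})

test_that("mt elements sit farther from genes than ml when planted that way", {
  cfg <- synthetic_config(genome_length = 600000, n_genes = 10, n_mt = 60,
                          n_ml = 60, n_other = 0, n_ms_tracts = 0,
                          cluster_fraction = 0, ml_near_genes = TRUE,
                          mt_far_from_genes = TRUE, seed = 703)
  sim <- build_genome(cfg)
  cls <- classify_elements(sim$hits, sim$genome)
  gm <- list(genes = sim$genes, exons = sim$exons)
  ctx <- assign_gene_context(sim$hits, gm)
  ctx$label <- cls$label[match(ctx$element_id, cls$element_id)]
  d_mt <- ctx$distance[ctx$label == "mt"]
  d_ml <- ctx$distance[ctx$label == "ml"]
  # sign test for stochastic dominance of mt distances over ml distances
  n_pairs <- min(length(d_mt), length(d_ml))
  wins <- sum(sample(d_mt, n_pairs) > sample(d_ml, n_pairs))
  pval <- stats::binom.test(wins, n_pairs, alternative = "greater")$p.value
  expect_lt(pval, 0.01)
})

test_that("RPKM and reciprocal multi-mapping arithmetic", {
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_equal(rpkm(0, 500, 1e6), 0)
  asg <- data.frame(read_id = c("r1", "r2", "r2", "r3"),
                    feature_id = c("A", "A", "B", "B"),
                    stringsAsFactors = FALSE)
  rc <- reciprocal_counts(asg)
  expect_equal(rc$count[rc$feature_id == "A"], 1.5)
  expect_equal(rc$count[rc$feature_id == "B"], 1.5)
  expect_equal(sum(rc$count), 3)  # reads are conserved
})

test_that("methylation levels apply the 4-1000 read filter per site", {
  hits <- data.frame(element_id = c("e1", "e2"), seqid = "chr1",
                     start = c(1000L, 5000L), end = c(1999L, 5999L),
                     strand = "+", family = "f", cons_start = 1L,
                     cons_end = 100L, cons_length = 100L,
                     stringsAsFactors = FALSE)
  sites <- data.frame(
    seqid = "chr1",
    position = c(1100L, 1200L, 1300L, 1400L, 5500L, 8000L),
    context = c("CpG", "CpG", "CpG", "CHH", "CpG", "CpG"),
    count_c = c(8L, 6L, 2L, 5L, 1500L, 4L),
    count_t = c(2L, 4L, 1L, 5L, 10L, 0L), stringsAsFactors = FALSE)
  lv <- methylation_by_element(sites, hits)
  e1 <- lv[lv$element_id == "e1", ]
  # kept CpG sites at e1: 0.8 and 0.6 -> mean 0.7; 3-read site dropped
  expect_equal(e1$level[e1$context == "CpG"], 0.7)
  expect_identical(e1$n_sites[e1$context == "CpG"], 2L)
  expect_equal(e1$level[e1$context == "CHH"], 0.5)
  # e2's only site exceeds 1000 reads: element omitted
  expect_false("e2" %in% lv$element_id)
})

test_that("Welch t behaves at the reference points", {
  a <- c(1.2, 1.9, 2.6, 3.1, 2.2)
  r <- welch_t_test(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- welch_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(r2$p, 0.01)
  r3 <- welch_t_test(c(11, 12, 13), c(1, 2, 3))
  expect_equal(r3$t, -r2$t)
  # cross-check statistic against the closed form
  x <- c(2.1, 3.4, 1.9, 4.2); y <- c(5.5, 6.1, 4.9)
  rf <- welch_t_test(x, y)
  se <- sqrt(stats::var(x) / 4 + stats::var(y) / 3)
  expect_equal(rf$t, (mean(x) - mean(y)) / se)
})
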