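test_that("midpoints follow the strand-aware +75 rule and conserve counts", {
  lens <- c(chr1 = 2000L)
  plus <- read_intervals("chr1", 1000, 1050, "+")
  minus <- read_intervals("chr1", 1000, 1050, "-")
  mp <- estimate_midpoints(plus, lens)
  mm <- estimate_midpoints(minus, lens)
  expect_equal(which(mp$counts$chr1 == 1) - 1L, 1075L)
  expect_equal(which(mm$counts$chr1 == 1) - 1L, 974L)
  # literal-start flag reproduces the strand-naive reading
  ml <- estimate_midpoints(minus, lens, literal_start = TRUE)
  expect_equal(which(ml$counts$chr1 == 1) - 1L, 1075L)
  # off-chromosome midpoint dropped and logged
  edge <- read_intervals("chr1", 1950, 2000, "+")
  expect_message(me <- estimate_midpoints(edge, lens), "dropped")
  expect_equal(me$n_midpoints, 0L)
  expect_equal(me$n_dropped, 1L)
  # conservation: sum of per-base midpoints = retained reads
  set.seed(7)
  n <- 500
  starts <- sample(0:1900, n, replace = TRUE)
  rds <- read_intervals("chr1", starts, starts + 50,
                        sample(c("+", "-"), n, replace = TRUE))
  m <- suppressMessages(estimate_midpoints(rds, lens))
  expect_equal(sum(m$counts$chr1), m$n_midpoints)
  expect_equal(m$n_midpoints + m$n_dropped, n)
})

test_that("track building scales to counts per million and subtracts", {
  lens <- c(chr1 = 1000L)
  mk <- function(pos) {
    r <- read_intervals("chr1", pos - 75, pos - 25, "+")
    estimate_midpoints(r, lens)
  }
  same <- mk(rep(500L, 10))
  tr0 <- build_track(same, same)
  expect_true(all(tr0$signal$chr1 == 0))
  # one IP midpoint among n at p, none in input at p: CPM arithmetic
  ip <- mk(c(500L, rep(100L, 9)))
  input <- mk(rep(100L, 10))
  tr <- build_track(ip, input)
  expect_equal(tr$signal$chr1[501], 1e6 / 10)
  expect_error(build_track(mk(integer(0)), input), "non-empty")
  # scaling invariance: duplicating every read leaves the track unchanged
  ip2 <- mk(rep(c(500L, rep(100L, 9)), 2))
  expect_equal(build_track(ip2, input)$signal$chr1, tr$signal$chr1)
})

test_that("track equals a brute-force dictionary-of-counts difference", {
  lens <- c(chr1 = 5000L)
  set.seed(8)
  ip_pos <- sample(100:4900, 400, replace = TRUE)
  in_pos <- sample(100:4900, 300, replace = TRUE)
  mk <- function(pos) estimate_midpoints(
    read_intervals("chr1", pos - 75, pos - 25, "+"), lens)
  tr <- build_track(mk(ip_pos), mk(in_pos))
  brute <- numeric(5000)
  for (p in ip_pos) brute[p + 1] <- brute[p + 1] + 1e6 / length(ip_pos)
  for (p in in_pos) brute[p + 1] <- brute[p + 1] - 1e6 / length(in_pos)
  expect_equal(tr$signal$chr1, brute)
})

test_that("enrichment metaplot applies the opposite-end exclusion", {
  lens <- c(chr1 = 10000L)
  flat <- structure(list(
    signal = list(chr1 = rep(2, 10000)),
    ip_library = 1e6, input_library = 1e6), class = "enrichment_track")
  long <- gene_models("g1", "chr1", 4000, 8000, "+")
  mp <- enrichment_metaplot(flat, long, "five_prime", 1000, 3000, 50, 1000)
  expect_true(all(mp$value == 2))
  # gene of length 1800 with 1 kb exclusion: only offsets [-1000, 800)
  short <- gene_models("g2", "chr1", 4000, 5800, "+")
  mp2 <- enrichment_metaplot(flat, short, "five_prime", 1000, 3000, 50, 1000)
  expect_true(all(mp2$n_bases[mp2$offset < 800] > 0))
  expect_true(all(mp2$n_bases[mp2$offset >= 800] == 0))
  # mirror symmetry on a random track
  set.seed(9)
  sig <- rnorm(10000)
  tr <- structure(list(signal = list(chr1 = sig), ip_library = 1,
                       input_library = 1), class = "enrichment_track")
  genes <- gene_models(c("a", "b"), "chr1", c(1200, 6000), c(4800, 9500),
                       c("+", "-"))
  m_tr <- structure(list(signal = list(chr1 = rev(sig)), ip_library = 1,
                         input_library = 1), class = "enrichment_track")
  m_genes <- mirror_features(genes, c(chr1 = 10000L))
  for (anchor in c("five_prime", "three_prime")) {
    a <- enrichment_metaplot(tr, genes, anchor)
    b <- enrichment_metaplot(m_tr, m_genes, anchor)
    expect_equal(a$value, b$value)
    expect_equal(a$n_bases, b$n_bases)
  }
})

test_that("gene scores average the three stated windows", {
  lens <- c(chr1 = 10000L)
  const <- structure(list(signal = list(chr1 = rep(2, 10000)),
                          ip_library = 1, input_library = 1),
                     class = "enrichment_track")
  g <- gene_models("g1", "chr1", 3000, 6000, "+")
  sc <- gene_scores(const, g)
  expect_equal(sc$tss_score, 2)
  expect_equal(sc$body_score, 2)
  expect_equal(sc$sort_body_score, 2)
  # genes under 2.1 kb have no body score
  g2 <- gene_models("g2", "chr1", 3000, 5000, "+")
  expect_true(is.na(gene_scores(const, g2)$body_score))
  # triangular track: means equal hand-computed averages (minus strand)
  tri <- structure(list(signal = list(chr1 = seq_len(10000) / 1000),
                        ip_library = 1, input_library = 1),
                   class = "enrichment_track")
  gm <- gene_models("g3", "chr1", 3000, 6000, "-")
  sc3 <- gene_scores(tri, gm)
  expect_equal(sc3$tss_score, mean((5501:6000) / 1000))
  expect_equal(sc3$body_score, mean((4001:5000) / 1000))
  expect_equal(sc3$sort_body_score, mean((3501:5500) / 1000))
})

test_that("the nine-cluster partition is deterministic and balanced", {
  grid <- expand.grid(tss = c(1, 5, 9), body = c(1, 5, 9))
  sc <- data.frame(id = sprintf("g%d", 1:9), tss_score = grid$tss,
                   body_score = grid$body, feature_class = "gene")
  cl <- nine_cluster_partition(sc)
  expect_equal(sort(cl$cluster), as.character(1:9))
  # all-equal scores: stable id tie-break, tercile sizes differ by <= 1
  sc2 <- data.frame(id = sprintf("g%02d", 1:10), tss_score = 1,
                    body_score = 1, feature_class = "gene")
  cl2 <- nine_cluster_partition(sc2)
  tss_sizes <- table(cl2$tss_tier)
  expect_true(max(tss_sizes) - min(tss_sizes) <= 1)
  expect_identical(cl2, nine_cluster_partition(sc2))
  # 999 distinct scores: each marginal tier exactly 333
  set.seed(10)
  sc3 <- data.frame(id = sprintf("g%04d", 1:999),
                    tss_score = sample(seq_len(999)),
                    body_score = sample(seq_len(999)),
                    feature_class = "gene")
  cl3 <- nine_cluster_partition(sc3)
  expect_equal(unname(table(cl3$tss_tier)), rep(333L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(table(cl3$body_tier)), rep(333L, 3),
               ignore_attr = TRUE)
  # completeness: every eligible gene in exactly one cluster, pseudogenes
  # in their own group
  sc4 <- rbind(sc3, data.frame(id = "pg1", tss_score = 0, body_score = 0,
                               feature_class = "pseudogene"))
  cl4 <- nine_cluster_partition(sc4)
  expect_equal(nrow(cl4), 1000)
  expect_equal(cl4$cluster[cl4$id == "pg1"], "pG")
  expect_false(any(duplicated(cl4$id)))
  expect_error(nine_cluster_partition(sc2[1:5, ]), "at least 9")
})

test_that("heat-map rows sort by body score and difference mode nulls out", {
  lens <- c(chr1 = 30000L)
  set.seed(11)
  sig <- rnorm(30000)
  tr <- structure(list(signal = list(chr1 = sig), ip_library = 1,
                       input_library = 1), class = "enrichment_track")
  genes <- gene_models(c("g1", "g2", "g3"), "chr1",
                       c(2000, 10000, 18000), c(7000, 15000, 23000), "+")
  hm <- heatmap_matrix(tr, genes)
  sb <- gene_scores(tr, genes)$sort_body_score
  expect_equal(rownames(hm), genes$id[order(sb, genes$id)])
  dm <- heatmap_matrix(tr, genes, track2 = tr)
  expect_true(all(dm[!is.na(dm)] == 0))
  # row means over covered bins reproduce a per-base loop
  hm_unsorted <- heatmap_matrix(tr, genes, sort = "none")
  g <- genes[2, ]
  brute <- sapply(seq(-1000, 2950, by = 50), function(off0) {
    offs <- off0:(off0 + 49)
    offs <- offs[offs < (g$end - g$start) - 1000]
    if (length(offs) == 0) return(NA_real_)
    mean(sig[g$start + offs + 1])
  })
  expect_equal(unname(hm_unsorted["g2", ]), brute)
})

test_that("designed enrichment tiers are recovered by the partition", {
  cfg <- sim_config(seed = 31, n_genes = 135, n_tes = 0, n_pseudogenes = 6)
  gen <- generate_genome(cfg)
  chap <- generate_chap(gen$genome, gen$models, cfg)
  lens <- chrom_lengths(gen$genome)
  track <- build_track(suppressMessages(estimate_midpoints(chap$ip, lens)),
                       suppressMessages(estimate_midpoints(chap$input, lens)))
  sc <- gene_scores(track, gen$models)
  cl <- nine_cluster_partition(sc)
  m <- merge(cl[cl$cluster != "pG", ], chap$truth, by = "id")
  acc <- mean(m$tss_tier.x == m$tss_tier.y & m$body_tier.x == m$body_tier.y)
  expect_gte(acc, 0.9)
})
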