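test_that("membership criteria: 2-sigma windows, strand signature, insert", {
  m <- test_model(sigma_is = 10)
  cl <- list(chrom1 = "chr1", chrom2 = "chr1", strand1 = "+", strand2 = "-",
             mu_alpha = 1000, mu_beta = 9000, mu_is = 8050)
  p <- mk_pairs(alpha = 1000L, beta = 9000L, insert = 8050L)[1, ]
  expect_true(is_member(p, cl, 10))
  # alpha 21 beyond the 20 bp window
  p <- mk_pairs(alpha = 1021L, beta = 9000L, insert = 8050L)[1, ]
  expect_false(is_member(p, cl, 10))
  # strand signature mismatch (FF vs FR)
  p <- mk_pairs(alpha = 1000L, beta = 9000L, insert = 8050L,
                strand1 = "+", strand2 = "+")[1, ]
  expect_false(is_member(p, cl, 10))
  # insert beyond the window
  p <- mk_pairs(alpha = 1000L, beta = 9000L, insert = 8075L)[1, ]
  expect_false(is_member(p, cl, 10))
})

test_that("clustering groups compact sets and separates distant ones", {
  m <- test_model(sigma_is = 100)
  # 5 pairs within 2 sigma of each other -> one cluster with exact mean
  a <- c(1000L, 1050L, 1100L, 1150L, 1200L)
  p <- mk_pairs(alpha = a, beta = a + 7950L, insert = 8000L)
  cl <- cluster_discordant(p, m)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 5L)
  expect_equal(cl$mu_alpha, mean(a))
  expect_equal(cl$mu_beta, mean(a + 7950))

  # two groups 10 sigma apart -> two clusters
  a2 <- a + 10L * 100L * 2L
  p <- mk_pairs(alpha = c(a, a2), beta = c(a + 7950L, a2 + 7950L),
                insert = 8000L)
  cl <- cluster_discordant(p, m)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$support, c(5L, 5L))

  # unsorted input rejected
  p_bad <- mk_pairs(alpha = rev(a), beta = rev(a) + 7950L, insert = 8000L,
                    sort = FALSE)
  expect_error(cluster_discordant(p_bad, m), "sorted")
})

test_that("pairs join the closest matching cluster; assignment is unique", {
  m <- test_model(sigma_is = 100)
  # two seeds 300 apart; a pair equidistant in alpha but closer in beta to
  # the second cluster joins the second
  p <- mk_pairs(alpha = c(1000L, 1100L, 1200L),
                beta = c(9000L, 9300L, 9150L),
                insert = c(8050L, 8250L, 8150L))
  cl <- cluster_discordant(p, m)
  expect_equal(nrow(cl), 2L)
  second <- which(vapply(cl$members, function(x) "t00002" %in% x, TRUE))
  expect_true("t00003" %in% cl$members[[second]])
  expect_equal(sum(cl$support), nrow(p))
})

test_that("streaming clusterer matches the brute-force reference", {
  for (seed in 1:25) {
    inst <- random_cluster_instance(seed)
    m <- test_model(sigma_is = inst$sigma)
    stream <- cluster_discordant(inst$pairs, m)
    ref <- oracle_cluster(inst$pairs, inst$sigma)
    expect_equal(partition_of(stream$members),
                 partition_of(lapply(ref, `[[`, "members")),
                 info = paste("seed", seed))
    # means agree cluster by cluster
    ref_mu <- vapply(ref, `[[`, 0, "mu_a")
    names(ref_mu) <- vapply(ref, function(cl)
      paste(sort(cl$members), collapse = ","), "")
    got_mu <- stream$mu_alpha
    names(got_mu) <- vapply(stream$members,
                            function(x) paste(sort(x), collapse = ","), "")
    expect_equal(got_mu[names(ref_mu)], ref_mu, info = paste("seed", seed))
  }
})

test_that("frozen means keep the seed coordinates", {
  m <- test_model(sigma_is = 100)
  a <- c(1000L, 1100L, 1200L)
  p <- mk_pairs(alpha = a, beta = a + 7950L, insert = 8000L)
  cl <- cluster_discordant(p, m, freeze_means = TRUE)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$mu_alpha, 1000)
  expect_equal(cl$support, 3L)
})

test_that("support cutoff follows the coverage heuristic", {
  expect_equal(min_support_cutoff(0), 2L)
  expect_equal(min_support_cutoff(30), 3L)
  expect_equal(min_support_cutoff(100, floor = 4), 10L)
  expect_error(min_support_cutoff(-1), "mean_coverage")
})

test_that("support filter keeps order and is monotone", {
  m <- test_model(sigma_is = 10)
  groups <- list(1L, 2L, 3L, 5L, 8L)
  alpha <- integer(0L); beta <- integer(0L)
  for (i in seq_along(groups)) {
    n <- groups[[i]]
    alpha <- c(alpha, rep(10000L * i, n))
    beta <- c(beta, rep(10000L * i + 50000L, n))
  }
  p <- mk_pairs(alpha = alpha, beta = beta, insert = 50050L)
  cl <- cluster_discordant(p, m)
  expect_equal(cl$support, c(1L, 2L, 3L, 5L, 8L))
  f2 <- filter_by_support(cl, 2)
  expect_equal(nrow(f2), 4L)
  expect_equal(filter_by_support(cl, 1)$cluster_id, cl$cluster_id)
  prev <- cl$cluster_id
  for (ms in 1:9) {
    cur <- filter_by_support(cl, ms)$cluster_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("breakpoint intervals: stated construction, fallback, strand geometry", {
  m <- test_model()  # median 3000, sigma 300, FR
  # identical pairs alpha = 1000, beta = 9000, read 50
  p <- mk_pairs(alpha = rep(1000L, 4), beta = rep(9000L, 4), insert = 11050L)
  cl <- cluster_discordant(p, m)
  bp <- breakpoint_intervals(cl[1, ], m, read_len = 50)
  expect_equal(bp$left$lo, 1050); expect_equal(bp$left$hi, 4000)
  expect_equal(bp$right$lo, 6050); expect_equal(bp$right$hi, 9000)
  expect_true(bp$left$lo < bp$left$hi && bp$right$lo < bp$right$hi)
  # support 1 is an error
  p1 <- cluster_discordant(p[1, ], m)
  expect_error(breakpoint_intervals(p1[1, ], m, 50), "support")

  # degenerate: median_is shorter than the read -> fallback width 4 sigma
  m2 <- test_model(median_is = 40, sigma_is = 25)
  bp <- breakpoint_intervals(cl[1, ], m2, read_len = 50)
  expect_equal(bp$left$hi - bp$left$lo, 100)
  expect_equal(bp$right$hi - bp$right$lo, 100)

  # everted cluster (RF in an FR library): junction flanks mirror
  pe <- mk_pairs(alpha = rep(5000L, 4), beta = rep(12000L, 4),
                 insert = 7050L, strand1 = "-", strand2 = "+")
  cle <- cluster_discordant(pe, m)
  bpe <- breakpoint_intervals(cle[1, ], m, read_len = 50)
  # alpha side: breakpoint left of the reads
  expect_lte(bpe$left$lo, 5000); expect_gte(bpe$left$hi, 5000)
  # beta side: breakpoint right of the reads
  expect_gte(bpe$right$hi, 12050); expect_lte(bpe$right$lo, 12500)
})

test_that("cluster means stay inside member extremes on simulated data", {
  set.seed(3)
  inst <- random_cluster_instance(99)
  m <- test_model(sigma_is = inst$sigma)
  cl <- cluster_discordant(inst$pairs, m)
  expect_true(all(cl$min_alpha <= cl$mu_alpha & cl$mu_alpha <= cl$max_alpha))
  expect_true(all(cl$min_beta <= cl$mu_beta & cl$mu_beta <= cl$max_beta))
  expect_equal(sum(cl$support), nrow(inst$pairs))
})

test_that("clusters export to BEDPE", {
  m <- test_model(sigma_is = 100)
  a <- c(1000L, 1100L)
  p <- mk_pairs(alpha = a, beta = a + 7950L, insert = 8000L)
  cl <- add_breakpoint_intervals(cluster_discordant(p, m), m, 50)
  path <- tempfile(fileext = ".bedpe")
  write_clusters_bedpe(cl, path)
  got <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(got), 1L)
  expect_equal(got$V1, "chr1")
  expect_equal(got$V8, 2L)
  expect_equal(got$V2, cl$bp1_lo)
})
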