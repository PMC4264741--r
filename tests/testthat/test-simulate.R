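test_that("reference generation is seeded and composition-balanced", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  r1 <- make_reference(c(chr1 = 50000L), seed = 5, path = f1)
  r2 <- make_reference(c(chr1 = 50000L), seed = 5, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- make_reference(c(chr1 = 50000L), seed = 6)
  expect_false(as.character(r1$seqs[[1]]) == as.character(r3$seqs[[1]]))
  # base composition ~uniform (binomial bound at n = 1e6 is well under 1%)
  big <- make_reference(c(chr1 = 1000000L), seed = 7)
  comp <- Biostrings::letterFrequency(big$seqs[[1]], c("A", "C", "G", "T"),
                                      as.prob = TRUE)
  expect_true(all(abs(comp - 0.25) < 0.01))
})

test_that("donor construction splices each event type correctly", {
  ref <- make_reference(c(chr1 = 40000L, chr2 = 40000L), seed = 8)
  # identity
  sim0 <- apply_svs(ref, data.frame(svtype = character(0L),
                                    chrom = character(0L), pos = integer(0L),
                                    length = integer(0L)))
  expect_equal(as.character(sim0$donor[["chr1"]]),
               as.character(ref$seqs[["chr1"]]))

  specs <- data.frame(
    svtype = c("DEL", "INV", "DUP", "INS"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(5000L, 20000L, 10000L, 30000L),
    length = c(2000L, 3000L, 1500L, 800L),
    chrom2 = NA, pos2 = NA, copies = c(NA, NA, 2L, NA),
    stringsAsFactors = FALSE)
  sim <- apply_svs(ref, specs, seed = 9)
  # DEL shortens by L; DUP with 2 extra copies lengthens by 2L; INS by its L
  expect_equal(length(sim$donor[["chr1"]]), 40000L - 2000L)
  expect_equal(length(sim$donor[["chr2"]]),
               40000L + 2L * 1500L + 800L)
  # INV region is the reverse complement of the reference segment
  donor1 <- sim$donor[["chr1"]]
  inv_donor_start <- 20000L - 2000L  # after the upstream deletion
  seg <- Biostrings::subseq(donor1, inv_donor_start + 1L,
                            inv_donor_start + 3000L)
  refseg <- Biostrings::subseq(ref$seqs[["chr1"]], 20001L, 23000L)
  expect_equal(as.character(seg),
               as.character(Biostrings::reverseComplement(refseg)))
  # manifest records breakpoints in reference coordinates
  types <- vapply(sim$manifest, `[[`, "", "svtype")
  expect_setequal(types, c("DEL", "INV", "DUP", "INS"))
  del <- sim$manifest[[which(types == "DEL")]]
  expect_equal(c(del$bp1, del$bp2), c(5000L, 7000L))

  # overlapping specs are rejected with the conflict named
  bad <- data.frame(svtype = c("DEL", "INV"), chrom = "chr1",
                    pos = c(5000L, 6000L), length = c(2000L, 500L),
                    stringsAsFactors = FALSE)
  expect_error(apply_svs(ref, bad), "overlapping")

  # reciprocal translocation swaps arms between chromosomes
  tra <- data.frame(svtype = "TRA", chrom = "chr1", pos = 10000L,
                    length = NA, chrom2 = "chr2", pos2 = 25000L,
                    stringsAsFactors = FALSE)
  simt <- apply_svs(ref, tra)
  expect_equal(length(simt$donor[["chr1"]]), 10000L + 15000L)
  expect_equal(length(simt$donor[["chr2"]]), 25000L + 30000L)
  expect_equal(as.character(Biostrings::subseq(simt$donor[["chr1"]], 1, 10000)),
               as.character(Biostrings::subseq(ref$seqs[["chr1"]], 1, 10000)))
  expect_equal(as.character(Biostrings::subseq(simt$donor[["chr1"]], 10001,
                                               25000)),
               as.character(Biostrings::subseq(ref$seqs[["chr2"]], 25001,
                                               40000)))
})

test_that("read sampling is seed-reproducible with the stated geometry", {
  sc <- list(lengths = c(chr1 = 80000L),
             specs = data.frame(svtype = character(0L), chrom = character(0L),
                                pos = integer(0L), length = integer(0L)),
             coverage = 10, insert_mean = 3000, insert_sd = 300,
             read_len = 50, orientation = "RF", error_rate = 0.005)
  d1 <- tempfile("s1"); d2 <- tempfile("s2")
  r1 <- simulate_run(sc, seed = 21, dir = d1)
  r2 <- simulate_run(sc, seed = 21, dir = d2)
  expect_identical(readLines(r1$sam), readLines(r2$sam))

  # insert sizes follow the requested Normal distribution (KS at n ~ 8000)
  p <- load_read_pairs(r1$sam)
  ks <- suppressWarnings(stats::ks.test(p$insert_size, "pnorm", 3000, 300))
  expect_gt(ks$p.value, 0.001)
  # orientation as requested, no spanning pairs without SVs
  expect_true(all(p$orientation == "RF"))
  expect_false(any(r1$pairs$spanning))
  # mean coverage within 5% of requested
  expect_lt(abs(2 * nrow(p) * 50 / 80000 - 10) / 10, 0.05)
})

test_that("deletion-spanning pairs carry the enlarged-insert signature", {
  sc <- list(lengths = c(chr1 = 100000L),
             specs = data.frame(svtype = "DEL", chrom = "chr1", pos = 40000L,
                                length = 10000L, stringsAsFactors = FALSE),
             coverage = 30, insert_mean = 3000, insert_sd = 300,
             read_len = 50, orientation = "RF", error_rate = 0)
  run <- simulate_run(sc, seed = 31, emit_seq = FALSE)
  p <- load_read_pairs(run$sam)
  span_ids <- run$pairs$qname[run$pairs$spanning]
  sp <- p[p$pair_id %in% span_ids, ]
  expect_gt(nrow(sp), 50L)
  # inserts inflated by ~ the deleted length
  expect_lt(abs(median(sp$insert_size) - 13000) / 13000, 0.05)
  expect_true(all(sp$orientation == "RF"))
  # spanning-pair count matches the physical-coverage expectation within
  # Poisson bounds: lambda ~ n_pairs * (insert - 2 * read_len) / donor_len
  donor_len <- 90000L
  lambda <- run$n_pairs * (3000 - 100) / donor_len
  expect_lt(abs(nrow(sp) - lambda), 5 * sqrt(lambda))
})

test_that("the default scenario is the documented study condition", {
  sc <- default_scenario()
  expect_equal(unname(sc$lengths), c(2000000L, 2000000L))
  expect_equal(table(sc$specs$svtype)[["DEL"]], 2L)
  expect_equal(sc$coverage, 30)
  expect_equal(sc$insert_mean, 3000)
  expect_equal(sc$orientation, "RF")
  expect_true(all(sc$specs$length >= 5000, na.rm = TRUE))
  expect_true(all(sc$specs$length <= 20000, na.rm = TRUE))
})

test_that("FASTQ emission recovers original read sequences", {
  sc <- list(lengths = c(chr1 = 40000L),
             specs = data.frame(svtype = character(0L), chrom = character(0L),
                                pos = integer(0L), length = integer(0L)),
             coverage = 3, insert_mean = 2000, insert_sd = 200,
             read_len = 50, orientation = "FR", error_rate = 0)
  run <- simulate_run(sc, seed = 91)
  fq <- sam_to_fastq(run$sam, tempfile("fq"))
  r1 <- readLines(fq[1]); r2 <- readLines(fq[2])
  expect_equal(length(r1), length(r2))
  expect_equal(length(r1) %% 4L, 0L)
  expect_equal(length(r1) / 4L, run$n_pairs)
  # error-free FR reads: read 1 matches the reference at its truth locus
  ids <- sub("/1$", "", sub("^@", "", r1[seq(1, length(r1), by = 4)]))
  i <- match(run$pairs$qname[1], ids)
  truth <- run$pairs[1, ]
  refseq <- as.character(Biostrings::subseq(
    Biostrings::readDNAStringSet(run$fasta)[[1]],
    truth$posA + 1L, truth$posA + 50L))
  got <- r1[(i - 1) * 4 + 2]
  expect_true(got == refseq ||
                got == as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(refseq))))
  # sequences-free SAM is rejected
  run2 <- simulate_run(sc, seed = 91, emit_seq = FALSE)
  expect_error(sam_to_fastq(run2$sam, tempfile("fq")), "emit_seq")
})
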