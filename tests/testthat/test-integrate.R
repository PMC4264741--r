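mk_call <- function(id, svtype, chrom = "chr1", pos1, pos2,
                    ci = 200L, support = 10L, evidence = "cluster",
                    log2_ratio = NA_real_, imprecise = FALSE,
                    strand1 = "+", strand2 = "-", chrom2 = chrom) {
  structure(data.frame(
    id = id, svtype = svtype, chrom1 = chrom, pos1 = pos1,
    ci1_lo = pos1 - ci, ci1_hi = pos1 + ci, chrom2 = chrom2, pos2 = pos2,
    ci2_lo = pos2 - ci, ci2_hi = pos2 + ci,
    length = if (chrom == chrom2) pos2 - pos1 else NA_integer_,
    strand1 = strand1, strand2 = strand2, evidence = evidence,
    support = support, log2_ratio = log2_ratio, imprecise = imprecise,
    filters = "", stringsAsFactors = FALSE),
    contigs = c(chr1 = 10000000L, chr2 = 10000000L),
    class = c("sv_calls", "data.frame"))
}

test_that("evidence merging follows the reciprocal-overlap and sign rules", {
  clus <- mk_call("c1", "DEL", pos1 = 10000L, pos2 = 20000L)
  seg <- doc_to_calls(data.frame(chrom = "chr1", start = 11000L, end = 19000L,
                                 mean_log2_ratio = -1.1, direction = "loss",
                                 n_windows = 8L), window_size = 1000L)
  out <- merge_calls(clus, seg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$evidence, "cluster,doc")
  expect_equal(out$log2_ratio, -1.1)
  expect_equal(out$support, 10L)     # cluster coordinates/support retained
  expect_equal(out$pos1, 10000L)

  # sign conflict: both calls survive, cluster call tagged
  gain <- doc_to_calls(data.frame(chrom = "chr1", start = 11000L, end = 19000L,
                                  mean_log2_ratio = 0.9, direction = "gain",
                                  n_windows = 8L), window_size = 1000L)
  out <- merge_calls(clus, gain)
  expect_equal(nrow(out), 2L)
  del <- out[out$svtype == "DEL", ]
  expect_match(del$filters, "discordant_evidence")
  expect_equal(del$evidence, "cluster")

  # below the overlap threshold nothing merges
  far <- doc_to_calls(data.frame(chrom = "chr1", start = 17000L, end = 40000L,
                                 mean_log2_ratio = -1, direction = "loss",
                                 n_windows = 23L), window_size = 1000L)
  out <- merge_calls(clus, far)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$evidence, c("cluster", "doc"))

  # INV never merges with DOC segments
  inv <- mk_call("c2", "INV", pos1 = 11000L, pos2 = 19000L,
                 strand1 = "+", strand2 = "+")
  out <- merge_calls(inv, seg)
  expect_equal(nrow(out), 2L)

  # conservation: outputs represent every input exactly once
  many_c <- rbind(mk_call("c1", "DEL", pos1 = 10000L, pos2 = 20000L),
                  mk_call("c3", "DUP", pos1 = 50000L, pos2 = 60000L))
  class(many_c) <- c("sv_calls", "data.frame")
  attr(many_c, "contigs") <- c(chr1 = 10000000L)
  many_d <- doc_to_calls(data.frame(
    chrom = "chr1", start = c(11000L, 51000L, 80000L),
    end = c(19000L, 59000L, 90000L),
    mean_log2_ratio = c(-1, 1, 1), direction = c("loss", "gain", "gain"),
    n_windows = 8L), window_size = 1000L)
  out <- merge_calls(many_c, many_d)
  expect_equal(nrow(out), 3L)  # 2 merged + 1 doc-only
  expect_lte(nrow(out), nrow(many_c) + nrow(many_d))
  expect_equal(sum(out$evidence == "cluster,doc"), 2L)
  # sorted by position
  expect_false(is.unsorted(out$pos1[out$chrom1 == "chr1"]))
})

test_that("VCF output follows the anchor convention and round-trips", {
  skip_if_not_installed("VariantAnnotation")
  contigs <- c(chr1 = 10000000L, chr2 = 10000000L)
  calls <- rbind(
    mk_call("d1", "DEL", pos1 = 999L, pos2 = 4999L, ci = 150L),
    mk_call("u1", "DUP", pos1 = 30000L, pos2 = 42000L,
            strand1 = "-", strand2 = "+"),
    mk_call("v1", "INV", pos1 = 60000L, pos2 = 75000L,
            strand1 = "+", strand2 = "+"),
    mk_call("t1", "TRA", chrom = "chr1", chrom2 = "chr2",
            pos1 = 90000L, pos2 = 50000L, strand1 = "+", strand2 = "-"))
  class(calls) <- c("sv_calls", "data.frame")
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, contigs, path)

  v <- VariantAnnotation::readVcf(path)
  expect_equal(nrow(v), 5L)   # 3 symbolic + 2 BND
  info <- VariantAnnotation::info(v)
  rr <- SummarizedExperiment::rowRanges(v)
  d <- which(names(rr) == "d1")
  expect_equal(BiocGenerics::start(rr)[d], 999L)      # POS = 0-based breakpoint
  expect_equal(info$END[[d]], 4999L)
  expect_equal(info$SVLEN[[d]], -4000L)
  expect_equal(as.character(rr$ALT@unlistData[d]), "<DEL>")
  expect_equal(info$SVTYPE[[d]], "DEL")
  u <- which(names(rr) == "u1")
  expect_equal(info$SVLEN[[u]], 12000L)
  # breakends cross-reference each other
  b1 <- which(names(rr) == "t1_bnd1"); b2 <- which(names(rr) == "t1_bnd2")
  expect_length(b1, 1L); expect_length(b2, 1L)
  expect_equal(info$MATEID[[b1]], "t1_bnd2")
  expect_equal(info$MATEID[[b2]], "t1_bnd1")
  alt1 <- as.character(rr$ALT@unlistData[b1])
  expect_match(alt1, "^[ACGTN]\\[chr2:50000\\[$")

  # CIPOS offsets reproduce the stored confidence interval
  expect_equal(unlist(info$CIPOS[d]), c(-150L, 150L), ignore_attr = TRUE)

  # determinism: a rerun writes byte-identical output
  path2 <- tempfile(fileext = ".vcf")
  write_vcf(calls, contigs, path2)
  expect_identical(readLines(path), readLines(path2))

  # chromosomes absent from the contig list are an error
  expect_error(write_vcf(calls, c(chr1 = 1e7), tempfile()), "chr2")
})

test_that("BEDPE export parses back losslessly", {
  calls <- rbind(
    mk_call("a", "DEL", pos1 = 1000L, pos2 = 9000L),
    mk_call("b", "TRA", chrom = "chr1", chrom2 = "chr2",
            pos1 = 5000L, pos2 = 7000L))
  path <- tempfile(fileext = ".bedpe")
  write_calls_bedpe(calls, path)
  got <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(got), 2L)
  expect_equal(got$V1, c("chr1", "chr1"))
  expect_equal(got$V4, c("chr1", "chr2"))
  expect_equal(got$V2, calls$ci1_lo)
  expect_equal(got$V5, calls$ci2_lo)
  expect_equal(got$V8, calls$support)
})

test_that("pipeline runs sample-only, skipping DOC with a notice", {
  sc <- list(lengths = c(chr1 = 120000L),
             specs = data.frame(svtype = "DEL", chrom = "chr1", pos = 50000L,
                                length = 8000L, stringsAsFactors = FALSE),
             coverage = 15, insert_mean = 3000, insert_sd = 300,
             read_len = 50, orientation = "RF", error_rate = 0)
  run <- simulate_run(sc, seed = 77, emit_seq = FALSE)
  out_dir <- tempfile("po")
  res <- suppressMessages(run_pipeline(run$sam, out_dir = out_dir))
  expect_null(res$doc)
  expect_true(file.exists(res$paths$vcf))
  expect_true(file.exists(res$paths$log))
  log <- readLines(res$paths$log)
  expect_true(any(grepl("doc: skipped", log)))
  expect_true(any(grepl("param k_discordant = 3", log)))
  expect_true(all(res$calls$svtype == "DEL"))
  # deterministic rerun: identical VCF
  res2 <- suppressMessages(run_pipeline(run$sam, out_dir = tempfile("po2")))
  expect_identical(readLines(res$paths$vcf), readLines(res2$paths$vcf))
})
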