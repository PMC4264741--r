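# Fixture builders shared across the test files. Everything is generated in
# code; no binary data.

test_model <- function(median_is = 3000, sigma_is = 300, orientation = "FR",
                       k = 3) {
  structure(list(median_is = median_is, sigma_is = sigma_is,
                 expected_orientation = orientation, k_discordant = k,
                 n_pairs_sampled = 1000L, robust = TRUE),
            class = "insert_size_model")
}

# Minimal read_pairs table (already classified as discordant where used for
# clustering). Vectors are recycled to the length of `alpha`.
mk_pairs <- function(alpha, beta, chrom1 = "chr1", chrom2 = chrom1,
                     strand1 = "+", strand2 = "-", insert = NULL,
                     read_len = 50L,
                     contigs = c(chr1 = 1000000L, chr2 = 1000000L),
                     sort = TRUE) {
  n <- length(alpha)
  df <- data.frame(
    pair_id = sprintf("t%05d", seq_len(n)),
    chrom1 = rep_len(chrom1, n), alpha = alpha,
    end1 = alpha + read_len, strand1 = rep_len(strand1, n), mapq1 = 60L,
    chrom2 = rep_len(chrom2, n), beta = beta,
    end2 = beta + read_len, strand2 = rep_len(strand2, n), mapq2 = 60L,
    is_duplicate = FALSE, stringsAsFactors = FALSE)
  same <- df$chrom1 == df$chrom2
  if (is.null(insert)) insert <- df$beta - df$alpha + read_len
  df$insert_size <- ifelse(same, rep_len(insert, n), NA_integer_)
  df$orientation <- ifelse(same,
                           svcallr:::pair_orientation(df$strand1, df$strand2),
                           NA_character_)
  if (sort) {
    df <- df[order(match(df$chrom1, names(contigs)), df$alpha), ]
    rownames(df) <- NULL
  }
  structure(df, contigs = contigs, read_len = read_len,
            class = c("read_pairs", "data.frame"))
}

# Hand-written SAM files for loader tests. Each record: list(qname, chrom,
# pos (0-based), strand, mchrom, mpos, first, mapq, dup, mate_unmapped).
write_test_sam <- function(recs, path, contigs = c(chr1 = 100000L,
                                                   chr2 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", unname(contigs)))
  lines <- vapply(recs, function(r) {
    flag <- 1L + (if (isTRUE(r$first)) 64L else 128L) +
      (if (r$strand == "-") 16L else 0L) +
      (if (isTRUE(r$dup)) 1024L else 0L) +
      (if (isTRUE(r$mate_unmapped)) 8L else 0L) +
      (if (!is.null(r$mstrand) && r$mstrand == "-") 32L else 0L)
    paste(r$qname, flag, r$chrom, r$pos + 1L, r$mapq %||% 60L, "50M",
          if (!isTRUE(r$mate_unmapped) && r$mchrom == r$chrom) "=" else
            if (isTRUE(r$mate_unmapped)) "=" else r$mchrom,
          (r$mpos %||% r$pos) + 1L, 0L,
          paste(rep("A", 50L), collapse = ""), strrep("I", 50L), sep = "\t")
  }, character(1L))
  writeLines(c(hdr, lines), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A proper FR pair as two SAM records in coordinate order.
sam_pair <- function(qname, chrom, pos1, pos2, strand1 = "+", strand2 = "-",
                     mapq = 60L, dup = FALSE) {
  list(list(qname = qname, chrom = chrom, pos = pos1, strand = strand1,
            mchrom = chrom, mpos = pos2, mstrand = strand2, first = TRUE,
            mapq = mapq, dup = dup),
       list(qname = qname, chrom = chrom, pos = pos2, strand = strand2,
            mchrom = chrom, mpos = pos1, mstrand = strand1, first = FALSE,
            mapq = mapq, dup = dup))
}

# interleave records of several pairs into coordinate-sorted order
sort_recs <- function(recs, contigs = c(chr1 = 100000L, chr2 = 100000L)) {
  recs[order(match(vapply(recs, `[[`, "", "chrom"), names(contigs)),
             vapply(recs, `[[`, 0, "pos"))]
}
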