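#' Load mate pairs from a coordinate-sorted SAM/BAM file
#'
#' Reads primary alignments, reconstructs mate pairs by query name and
#' returns one record per pair whose both mates are mapped with sufficient
#' mapping quality. Secondary and supplementary alignments are skipped;
#' duplicate-flagged pairs (FLAG 0x400) are dropped when `drop_duplicates`
#' is set. Reads with MAPQ 0 are treated as non-uniquely mapped and
#' excluded regardless of `min_mapq`. The insert size is the outer distance
#' (rightmost aligned end minus leftmost start), recomputed from the
#' alignments rather than trusted from TLEN.
#'
#' @param path SAM or BAM file, coordinate-sorted, with mate information.
#' @param min_mapq Minimum MAPQ for either mate (default 20).
#' @param drop_duplicates Drop pairs where either mate is duplicate-flagged.
#' @param keep_seq Keep read sequences (needed by [realignment_rescue()]).
#' @return A `read_pairs` data.frame sorted by (chrom1, alpha), one row per
#'   pair, with 0-based half-open coordinates: `alpha`/`beta` are the
#'   leftmost positions of the first/second read in coordinate order,
#'   `end1`/`end2` the corresponding exclusive ends, `insert_size` the outer
#'   distance (NA for inter-chromosomal pairs), `orientation` one of
#'   FR/RF/FF/RR for same-chromosome pairs. Attributes: `contigs` (named
#'   lengths), `n_orphans`, `n_dup_removed`, `n_lowmapq`, `read_len`.
#' @export
load_read_pairs <- function(path, min_mapq = 20L, drop_duplicates = TRUE,
                            keep_seq = FALSE) {
  stopifnot(file.exists(path), min_mapq >= 0)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]
  contigs <- hdr$targets
  if (!length(contigs)) stop("no @SQ contigs in header of ", path)

  what <- c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq")
  if (keep_seq) what <- c(what, "seq")
  param <- Rsamtools::ScanBamParam(
    what = what,
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  if (!n) stop("no mapped paired primary alignments in ", path)

  rname <- as.character(x$rname)
  .check_coordinate_sorted(rname, x$pos, x$qname)

  flag <- x$flag
  is_dup <- bitwAnd(flag, 1024L) != 0L
  mapq_ok <- !is.na(x$mapq) & x$mapq >= max(min_mapq, 1L)

  # reads whose mate is unmapped or fails the MAPQ filter surface as
  # singletons in the pairing step below and are reported as orphans
  keep <- mapq_ok
  n_lowmapq <- sum(!mapq_ok)
  df <- data.frame(
    qname = x$qname[keep], chrom = rname[keep], pos = x$pos[keep] - 1L,
    width = GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar[keep]),
    strand = as.character(x$strand[keep]), mapq = x$mapq[keep],
    dup = is_dup[keep], stringsAsFactors = FALSE)
  if (keep_seq) df$seq <- as.character(x$seq[keep])

  # hash-based mate pairing: primary alignments occur at most twice per qname
  first_ix <- match(df$qname, df$qname)
  second <- which(first_ix != seq_along(first_ix))
  ia <- first_ix[second]
  ib <- second
  n_orphans <- nrow(df) - 2L * length(second)
  # coordinate-order the mates of each pair
  ra <- chrom_rank(df$chrom[ia], names(contigs))
  rb <- chrom_rank(df$chrom[ib], names(contigs))
  swap <- rb < ra | (rb == ra & df$pos[ib] < df$pos[ia])
  i1 <- ifelse(swap, ib, ia)
  i2 <- ifelse(swap, ia, ib)

  pairs <- data.frame(
    pair_id = df$qname[i1],
    chrom1 = df$chrom[i1], alpha = df$pos[i1], end1 = df$pos[i1] + df$width[i1],
    strand1 = df$strand[i1], mapq1 = df$mapq[i1],
    chrom2 = df$chrom[i2], beta = df$pos[i2], end2 = df$pos[i2] + df$width[i2],
    strand2 = df$strand[i2], mapq2 = df$mapq[i2],
    is_duplicate = df$dup[i1] | df$dup[i2],
    stringsAsFactors = FALSE)
  if (keep_seq) { pairs$seq1 <- df$seq[i1]; pairs$seq2 <- df$seq[i2] }

  same <- pairs$chrom1 == pairs$chrom2
  pairs$insert_size <- ifelse(same,
                              pmax(pairs$end1, pairs$end2) -
                                pmin(pairs$alpha, pairs$beta), NA_integer_)
  pairs$orientation <- ifelse(same,
                              pair_orientation(pairs$strand1, pairs$strand2),
                              NA_character_)

  n_dup_removed <- 0L
  if (drop_duplicates) {
    n_dup_removed <- sum(pairs$is_duplicate)
    pairs <- pairs[!pairs$is_duplicate, ]
  }
  pairs <- pairs[order(chrom_rank(pairs$chrom1, names(contigs)), pairs$alpha), ]
  rownames(pairs) <- NULL
  structure(pairs,
            contigs = contigs, n_orphans = n_orphans,
            n_dup_removed = n_dup_removed, n_lowmapq = n_lowmapq,
            read_len = if (nrow(pairs)) stats::median(df$width) else NA_real_,
            class = c("read_pairs", "data.frame"))
}

# Error (naming the first offending record) unless records appear in
# coordinate order: positions non-decreasing within each chromosome block and
# no chromosome block repeated.
.check_coordinate_sorted <- function(rname, pos, qname) {
  if (length(rname) < 2L) return(invisible(TRUE))
  new_chrom <- rname[-1L] != rname[-length(rname)]
  bad_pos <- !new_chrom & pos[-1L] < pos[-length(pos)]
  if (any(bad_pos)) {
    i <- which(bad_pos)[1L] + 1L
    stop("input not coordinate-sorted: record '", qname[i], "' at ",
         rname[i], ":", pos[i], " follows position ", pos[i - 1L])
  }
  blocks <- rle(rname)$values
  if (anyDuplicated(blocks)) {
    ch <- blocks[duplicated(blocks)][1L]
    i <- which(new_chrom & rname[-1L] == ch)[1L] + 1L
    stop("input not coordinate-sorted: chromosome ", ch,
         " recurs at record '", qname[i], "'")
  }
  invisible(TRUE)
}

#' Estimate the library insert-size model
#'
#' Builds the insert-size distribution from same-chromosome pairs in the
#' library's majority orientation and derives the thresholds used to flag
#' discordant pairs. The location is the median; the scale is by default the
#' robust standard deviation 1.4826 x MAD, so that SV-generated outliers do
#' not inflate it (set `robust = FALSE` for the plain standard deviation).
#' The scale is floored at 1 bp. The majority orientation is auto-detected
#' so both paired-end (FR) and mate-pair (RF) libraries work unflagged.
#'
#' @param pairs A `read_pairs` data.frame.
#' @param k_discordant Multiplier k: pairs with insert size outside
#'   median +/- k * sigma are discordant (default 3).
#' @param max_sample Cap on the number of pairs used (default 100000).
#' @param min_pairs Minimum usable pairs required (default 50).
#' @param robust Use 1.4826 x MAD (default) instead of the plain SD.
#' @return An `insert_size_model`: list with `median_is`, `sigma_is`,
#'   `expected_orientation`, `k_discordant`, `n_pairs_sampled`, `robust`.
#' @export
estimate_insert_model <- function(pairs, k_discordant = 3, max_sample = 100000L,
                                  min_pairs = 50L, robust = TRUE) {
  same <- !is.na(pairs$orientation)
  if (!any(same)) stop("no same-chromosome pairs; cannot estimate insert model")
  orient_tab <- table(pairs$orientation[same])
  expected <- names(orient_tab)[which.max(orient_tab)]
  usable <- which(same & pairs$orientation == expected)
  if (length(usable) > max_sample) usable <- usable[seq_len(max_sample)]
  if (length(usable) < min_pairs) {
    stop("only ", length(usable), " usable pairs (< ", min_pairs,
         "); insert-size thresholds cannot be estimated reliably")
  }
  is <- pairs$insert_size[usable]
  med <- stats::median(is)
  sigma <- if (robust) stats::mad(is) else stats::sd(is)
  sigma <- max(sigma, 1)
  structure(list(median_is = med, sigma_is = sigma,
                 expected_orientation = expected,
                 k_discordant = k_discordant,
                 n_pairs_sampled = length(usable), robust = robust),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat("Insert-size model: median", x$median_is, "bp, sigma", round(x$sigma_is, 1),
      "bp (", if (x$robust) "robust" else "plain", "),",
      x$expected_orientation, "library,",
      "k =", x$k_discordant, ", n =", x$n_pairs_sampled, "\n")
  invisible(x)
}

#' Classify pairs as concordant or discordant
#'
#' A pair is discordant if its mates map to different chromosomes, if its
#' orientation deviates from the library's expectation, or if its insert
#' size falls outside median +/- k * sigma (the lower bound floored at 0, so
#' no pair is flagged `small_insert` when median - k*sigma < 0). Reasons
#' combine.
#'
#' @param pairs A `read_pairs` data.frame.
#' @param model An `insert_size_model`.
#' @return `pairs` with added columns `status` ("concordant"/"discordant")
#'   and `reasons` (comma-separated subset of `large_insert`, `small_insert`,
#'   `orientation`, `inter_chromosomal`; empty for concordant pairs).
#' @export
classify_pairs <- function(pairs, model) {
  stopifnot(inherits(model, "insert_size_model"))
  hi <- model$median_is + model$k_discordant * model$sigma_is
  lo <- max(0, model$median_is - model$k_discordant * model$sigma_is)
  inter <- pairs$chrom1 != pairs$chrom2
  orient <- !inter & pairs$orientation != model$expected_orientation
  large <- !inter & pairs$insert_size > hi
  small <- !inter & pairs$insert_size < lo
  reasons <- character(nrow(pairs))
  add <- function(reasons, cond, tag) {
    ifelse(cond, ifelse(reasons == "", tag, paste(reasons, tag, sep = ",")),
           reasons)
  }
  reasons <- add(reasons, large, "large_insert")
  reasons <- add(reasons, small, "small_insert")
  reasons <- add(reasons, orient, "orientation")
  reasons <- add(reasons, inter, "inter_chromosomal")
  pairs$status <- ifelse(reasons == "", "concordant", "discordant")
  pairs$reasons <- reasons
  pairs
}

#' Classify a single pair
#' @param pair One-row `read_pairs` data.frame (or a list with the same
#'   fields).
#' @param model An `insert_size_model`.
#' @return List with `status` and `reasons` (character vector).
#' @export
classify_pair <- function(pair, model) {
  p <- classify_pairs(as.data.frame(pair, stringsAsFactors = FALSE), model)
  list(status = p$status[1L],
       reasons = if (p$reasons[1L] == "") character(0L)
                 else strsplit(p$reasons[1L], ",", fixed = TRUE)[[1L]])
}

#' Extract the discordant subset of a classified stream
#' @param pairs A `read_pairs` data.frame.
#' @param model An `insert_size_model`.
#' @return The discordant pairs, classification columns attached, input
#'   order (chrom1, alpha) preserved.
#' @export
discordant_pairs <- function(pairs, model) {
  cl <- classify_pairs(pairs, model)
  out <- cl[cl$status == "discordant", ]
  rownames(out) <- NULL
  for (a in c("contigs", "read_len")) attr(out, a) <- attr(pairs, a)
  out
}
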