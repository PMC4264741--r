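#' Load an annotation track from BED
#'
#' Reads a BED3+ file and merges overlapping intervals (union), the form
#' required by [overlap_fraction()]. Typical tracks: segmental
#' duplications, RepeatMasker regions, self-chain records.
#'
#' @param path BED file (0-based half-open).
#' @param name Track name (defaults to the file base name).
#' @return A [GenomicRanges::GRanges] with metadata `name`.
#' @export
read_track <- function(path, name = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(gr)
  S4Vectors::metadata(gr)$name <- name %||%
    tools::file_path_sans_ext(basename(path))
  gr
}

#' Fraction of an interval covered by a track
#'
#' Exact interval arithmetic: the fraction of `[start, end)` bases covered
#' by the union of the track's intervals on the same chromosome.
#'
#' @param chrom,start,end The query interval (0-based half-open); vectors
#'   are accepted and processed in parallel.
#' @param track A `GRanges` (will be reduced if not already disjoint).
#' @return Numeric fraction(s) in `[0, 1]`.
#' @export
overlap_fraction <- function(chrom, start, end, track) {
  stopifnot(all(end > start))
  track <- GenomicRanges::reduce(track)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  # a track with no intervals on a query chromosome simply contributes zero
  # overlap; silence the disjoint-seqlevels notice findOverlaps emits then
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, track))
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(q)[S4Vectors::queryHits(hits)],
    IRanges::ranges(track)[S4Vectors::subjectHits(hits)]))
  tot <- numeric(length(q))
  if (length(hits)) {
    s <- tapply(ov, S4Vectors::queryHits(hits), sum)
    tot[as.integer(names(s))] <- s
  }
  tot / (end - start)
}

#' Annotate or remove calls overlapping repeat-like tracks
#'
#' Computes, for every call, the fraction of its interval covered by each
#' track; calls exceeding a track's threshold gain a FILTER tag
#' `<track>_overlap`. Intra-chromosomal calls are evaluated over their full
#' span `[pos1, pos2)`; translocations over each breakpoint confidence
#' interval, tagged if either side exceeds the threshold. In `annotate`
#' mode nothing is removed; in `remove` mode tagged calls are dropped.
#'
#' @param calls An `sv_calls` data.frame (see [merge_calls()]).
#' @param tracks Named list of `GRanges` tracks.
#' @param max_frac Scalar threshold or named per-track thresholds in
#'   `[0, 1]` (default 0.5).
#' @param mode `"annotate"` (default) or `"remove"`.
#' @return The call table with per-track `ovl_<name>` columns and updated
#'   `filters`; possibly shortened in remove mode.
#' @export
apply_track_filters <- function(calls, tracks, max_frac = 0.5,
                                mode = c("annotate", "remove")) {
  mode <- match.arg(mode)
  if (!length(tracks) || !nrow(calls)) {
    for (nm in names(tracks)) calls[[paste0("ovl_", nm)]] <- numeric(nrow(calls))
    return(calls)
  }
  stopifnot(!is.null(names(tracks)))
  thr <- if (length(max_frac) == 1L && is.null(names(max_frac))) {
    stats::setNames(rep(max_frac, length(tracks)), names(tracks))
  } else max_frac
  stopifnot(all(thr >= 0 & thr <= 1))
  inter <- calls$chrom1 != calls$chrom2
  tagged <- rep(FALSE, nrow(calls))
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    frac <- numeric(nrow(calls))
    if (any(!inter)) {
      frac[!inter] <- overlap_fraction(calls$chrom1[!inter],
                                       calls$pos1[!inter],
                                       calls$pos2[!inter], tr)
    }
    if (any(inter)) {
      f1 <- overlap_fraction(calls$chrom1[inter], calls$ci1_lo[inter],
                             calls$ci1_hi[inter], tr)
      f2 <- overlap_fraction(calls$chrom2[inter], calls$ci2_lo[inter],
                             calls$ci2_hi[inter], tr)
      frac[inter] <- pmax(f1, f2)
    }
    calls[[paste0("ovl_", nm)]] <- frac
    hit <- frac > thr[[nm]]
    tagged <- tagged | hit
    tag <- paste0(nm, "_overlap")
    calls$filters <- ifelse(hit,
                            ifelse(calls$filters == "", tag,
                                   paste(calls$filters, tag, sep = ";")),
                            calls$filters)
  }
  if (mode == "remove") {
    calls <- calls[!tagged, ]
    rownames(calls) <- NULL
  }
  calls
}

#' Rescue falsely discordant pairs by local realignment
#'
#' For each discordant pair, attempts to place each mate concordantly
#' relative to the other: the mate's sequence (and its reverse complement)
#' is locally realigned, with affine gap penalties, against the reference
#' window where a concordant placement would fall (the other mate's
#' position +/- the median insert +/- `search_margin`). If an alignment
#' covering at least 90% of the read with identity at least
#' `min_identity_frac` exists for either mate, the pair is considered a
#' mapping artifact of an actually concordant fragment and is discarded
#' from the discordant set.
#'
#' @param pairs Discordant `read_pairs` rows with `seq1`/`seq2` columns
#'   (load with `keep_seq = TRUE`).
#' @param fasta Reference genome FASTA (indexed; indexed on the fly if not).
#' @param model An `insert_size_model`.
#' @param search_margin Extra margin around the concordant window (default
#'   `4 * sigma_is`).
#' @param min_identity_frac Minimum alignment identity (default 0.9).
#' @param min_read_frac Minimum fraction of the read that must be aligned
#'   (default 0.9).
#' @return Logical vector, `TRUE` = keep (genuinely discordant), `FALSE` =
#'   discard (rescued as concordant).
#' @export
realignment_rescue <- function(pairs, fasta, model,
                               search_margin = 4 * model$sigma_is,
                               min_identity_frac = 0.9,
                               min_read_frac = 0.9) {
  stopifnot(inherits(model, "insert_size_model"))
  if (is.null(pairs$seq1) || is.null(pairs$seq2))
    stop("read sequences required: load pairs with keep_seq = TRUE")
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  idx <- Rsamtools::scanFaIndex(fa)
  clen <- stats::setNames(BiocGenerics::width(idx),
                          as.character(GenomicRanges::seqnames(idx)))
  med <- model$median_is
  half <- med + search_margin

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln_ok <- function(read_seq, win_seq) {
    if (nchar(read_seq) == 0L || length(win_seq) == 0L) return(FALSE)
    rl <- nchar(read_seq)
    for (s in c(read_seq,
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(read_seq))))) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), win_seq, type = "local",
        substitutionMatrix = submat, gapOpening = 2, gapExtension = 1)
      p <- Biostrings::pattern(al)
      covered <- (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) >=
        min_read_frac * rl
      ident <- Biostrings::pid(al, type = "PID1") / 100
      if (covered && ident >= min_identity_frac) return(TRUE)
    }
    FALSE
  }

  window_seq <- function(chrom, center) {
    if (!chrom %in% names(clen))
      stop("reference contig missing from FASTA: ", chrom)
    lo <- max(1, center - half)
    hi <- min(unname(clen[chrom]), center + half)
    Rsamtools::scanFa(fa, GenomicRanges::GRanges(
      chrom, IRanges::IRanges(lo, hi)))[[1L]]
  }

  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    # mate 1 tested against the concordant window implied by mate 2, and
    # vice versa; one successful placement rescues the pair
    w2 <- window_seq(pairs$chrom2[i], pairs$beta[i] + 1L)
    if (aln_ok(pairs$seq1[i], w2)) { keep[i] <- FALSE; next }
    w1 <- window_seq(pairs$chrom1[i], pairs$alpha[i] + 1L)
    keep[i] <- !aln_ok(pairs$seq2[i], w1)
  }
  keep
}
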