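#' Window size from overall coverage and genome size
#'
#' Picks the window so that the less-covered of the two samples contributes
#' about `target_reads_per_window` reads per window:
#' `genome_size * target / min(total_sample, total_ref)`, rounded up to the
#' nearest 100 bp.
#'
#' @param total_mapped_reads_sample,total_mapped_reads_ref Total mapped
#'   read counts.
#' @param genome_size Genome size in bp.
#' @param target_reads_per_window Target reads per window (default 100).
#' @return Window size in bp.
#' @export
choose_window_size <- function(total_mapped_reads_sample,
                               total_mapped_reads_ref,
                               genome_size, target_reads_per_window = 100L) {
  for (v in c(total_mapped_reads_sample, total_mapped_reads_ref,
              genome_size, target_reads_per_window)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("all inputs to choose_window_size must be positive")
  }
  raw <- genome_size * target_reads_per_window /
    min(total_mapped_reads_sample, total_mapped_reads_ref)
  as.integer(ceiling(raw / 100) * 100)
}

#' Per-read 5'-anchor positions of a pair stream
#'
#' Each pair contributes two reads; a read is anchored at its 5'-most
#' mapped base (leftmost position for + strand reads, rightmost aligned
#' base for - strand reads), the single-point assignment used for window
#' counting.
#'
#' @param pairs A `read_pairs` data.frame.
#' @return data.frame with `chrom` and `anchor` (0-based), two rows per pair.
#' @export
read_anchors <- function(pairs) {
  a1 <- ifelse(pairs$strand1 == "+", pairs$alpha, pairs$end1 - 1L)
  a2 <- ifelse(pairs$strand2 == "+", pairs$beta, pairs$end2 - 1L)
  data.frame(chrom = c(pairs$chrom1, pairs$chrom2),
             anchor = c(a1, a2), stringsAsFactors = FALSE)
}

#' Count reads in sliding windows
#'
#' Tiles each chromosome with windows of size `window` advanced by `step`
#' (terminal windows are truncated at the chromosome end) and counts, for
#' every window, the reads whose 5' anchor falls inside it. With
#' `step == window` the windows partition the chromosome and counts sum to
#' the number of reads.
#'
#' @param reads data.frame with `chrom` and `anchor` (see [read_anchors()]).
#' @param contigs Named vector of chromosome lengths.
#' @param window Window size (bp).
#' @param step Step between window starts (bp), `step <= window`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `count`.
#' @export
count_in_windows <- function(reads, contigs, window, step = window) {
  stopifnot(step >= 1, step <= window)
  out <- lapply(names(contigs), function(ch) {
    len <- unname(contigs[[ch]])
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    ends <- pmin(starts + window, len)
    anchors <- reads$anchor[reads$chrom == ch]
    win <- IRanges::IRanges(start = starts + 1L, end = ends)
    pts <- IRanges::IRanges(start = anchors + 1L, width = 1L)
    cnt <- IRanges::countOverlaps(win, pts)
    data.frame(chrom = ch, start = starts, end = ends, count = cnt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Copy-number ratio and probability per window
#'
#' For each window, the log2 ratio of library-size-normalised counts,
#' `log2((count_sample/total_sample) / (count_ref/total_ref))`, and a
#' two-sided probability of a ratio at least this extreme under the
#' no-change null. The null model treats both counts as Poisson, giving the
#' log ratio an approximate Gaussian distribution with variance
#' `(1/count_sample + 1/count_ref)` on the natural-log scale, i.e.
#' `(1/count_sample + 1/count_ref)/ln(2)^2` on the log2 scale. Windows with
#' a zero count keep `log2_ratio = NA` (flagged) and get their probability
#' and a continuity-corrected ratio (`log2_ratio_cc`) from counts + 0.5.
#'
#' @param windows data.frame with matched `count_sample` and `count_ref`
#'   columns (or a window table from [count_in_windows()] for the sample
#'   plus `count_ref`).
#' @param total_sample,total_ref Total read counts of the two libraries.
#' @return `windows` with columns `log2_ratio`, `log2_ratio_cc`, `p_value`,
#'   `flagged`.
#' @export
ratio_and_probability <- function(windows, total_sample, total_ref) {
  stopifnot(total_sample > 0, total_ref > 0)
  cs <- windows$count_sample; cr <- windows$count_ref
  norm <- log2(total_ref / total_sample)
  both <- cs > 0 & cr > 0
  lr <- ifelse(both, log2(cs / cr) + norm, NA_real_)
  lr_cc <- log2((cs + 0.5) / (cr + 0.5)) + norm
  use_cs <- ifelse(both, cs, cs + 0.5)
  use_cr <- ifelse(both, cr, cr + 0.5)
  se <- sqrt(1 / use_cs + 1 / use_cr) / log(2)
  z <- ifelse(both, lr, lr_cc) / se
  windows$log2_ratio <- lr
  windows$log2_ratio_cc <- lr_cc
  windows$p_value <- 2 * stats::pnorm(-abs(z))
  windows$flagged <- !both
  windows
}

#' Rule-based CNV segment calls from windowed ratios
#'
#' Maximal runs of at least `min_consecutive` consecutive windows whose
#' absolute log2 ratio exceeds `ratio_threshold` with a consistent sign
#' become segments; segment bounds run from the first window's start to the
#' last window's end. Zero-count (flagged) windows participate through
#' their continuity-corrected ratio so that deep losses do not break runs.
#'
#' @param windows Output of [ratio_and_probability()], sorted by position.
#' @param ratio_threshold Absolute log2-ratio threshold (default 0.3).
#' @param min_consecutive Minimum run length in windows (default 3).
#' @return data.frame of segments: `chrom`, `start`, `end`,
#'   `mean_log2_ratio`, `direction` ("gain"/"loss"), `n_windows`.
#' @export
call_segments <- function(windows, ratio_threshold = 0.3, min_consecutive = 3L) {
  stopifnot(min_consecutive >= 1)
  segs <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$start), ]
    r <- ifelse(is.na(w$log2_ratio), w$log2_ratio_cc, w$log2_ratio)
    state <- ifelse(is.na(r) | abs(r) <= ratio_threshold, 0L, sign(r))
    rl <- rle(state)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    keep <- rl$values != 0L & rl$lengths >= min_consecutive
    if (!any(keep)) return(NULL)
    data.frame(chrom = w$chrom[1L],
               start = w$start[starts[keep]],
               end = w$end[ends[keep]],
               mean_log2_ratio = vapply(which(keep), function(k) {
                 mean(r[starts[k]:ends[k]])
               }, 0),
               direction = ifelse(rl$values[keep] > 0L, "gain", "loss"),
               n_windows = rl$lengths[keep],
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
  if (is.null(segs)) {
    segs <- data.frame(chrom = character(0L), start = integer(0L),
                       end = integer(0L), mean_log2_ratio = numeric(0L),
                       direction = character(0L), n_windows = integer(0L),
                       stringsAsFactors = FALSE)
  }
  rownames(segs) <- NULL
  segs
}

#' Depth-of-coverage ratio analysis of a sample against a reference sample
#'
#' End-to-end DOC: chooses the window size from the totals and genome size,
#' counts 5' read anchors in sliding windows for both samples, computes the
#' normalised log2 ratio and its probability per window, and calls gain and
#' loss segments. GC-content and mapability corrections are not applied;
#' the method relies on a matched reference sequenced under comparable
#' conditions.
#'
#' @param sample_reads,ref_reads Anchor tables from [read_anchors()] (or any
#'   data.frame with `chrom`, `anchor`).
#' @param contigs Named chromosome lengths.
#' @param target_reads_per_window Target reads per window (default 100).
#' @param step_frac Step as a fraction of the window (default 0.5, i.e.
#'   half-overlapping windows); use 1 for disjoint windows.
#' @param ratio_threshold,min_consecutive Segmentation parameters, see
#'   [call_segments()].
#' @return A `doc_result` list: `windows`, `segments`, `window_size`,
#'   `step`, totals.
#' @export
doc_analysis <- function(sample_reads, ref_reads, contigs,
                         target_reads_per_window = 100L, step_frac = 0.5,
                         ratio_threshold = 0.3, min_consecutive = 3L) {
  ts <- nrow(sample_reads); tr <- nrow(ref_reads)
  win <- choose_window_size(ts, tr, sum(contigs), target_reads_per_window)
  step <- max(1L, as.integer(round(win * step_frac)))
  ws <- count_in_windows(sample_reads, contigs, win, step)
  wr <- count_in_windows(ref_reads, contigs, win, step)
  stopifnot(nrow(ws) == nrow(wr))
  w <- ws
  names(w)[names(w) == "count"] <- "count_sample"
  w$count_ref <- wr$count
  w <- ratio_and_probability(w, ts, tr)
  segs <- call_segments(w, ratio_threshold, min_consecutive)
  structure(list(windows = w, segments = segs, window_size = win, step = step,
                 total_sample = ts, total_ref = tr),
            class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
  cat("DOC analysis:", nrow(x$windows), "windows of", x$window_size,
      "bp (step", x$step, "),", nrow(x$segments), "segments\n")
  invisible(x)
}

#' Write windowed log2 ratios as bedGraph
#' @param windows Window table from [doc_analysis()].
#' @param path Output path.
#' @export
write_bedgraph <- function(windows, path) {
  r <- ifelse(is.na(windows$log2_ratio), windows$log2_ratio_cc,
              windows$log2_ratio)
  lines <- c("track type=bedGraph name=log2_ratio",
             paste(windows$chrom, windows$start, windows$end,
                   formatC(r, format = "g", digits = 6), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write the full window table as TSV
#' @param windows Window table.
#' @param path Output path.
#' @export
write_windows_tsv <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write CNV segments as BED
#' @param segments Segment table from [call_segments()].
#' @param path Output path.
#' @export
write_segments_bed <- function(segments, path) {
  lines <- paste(segments$chrom, segments$start, segments$end,
                 paste0(segments$direction, "_",
                        formatC(segments$mean_log2_ratio, format = "f",
                                digits = 3)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
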