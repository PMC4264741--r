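#' Turn typed clusters into SV calls
#'
#' Converts a typed, support-filtered cluster table (with breakpoint
#' intervals attached) into the unified call representation. Breakpoint
#' point estimates are the interval midpoints; the intervals themselves
#' become the confidence intervals.
#'
#' @param clusters An `sv_clusters` data.frame with `svtype` and
#'   `bp1_lo`/`bp1_hi`/`bp2_lo`/`bp2_hi` columns (see [assign_types()],
#'   [add_breakpoint_intervals()]).
#' @return An `sv_calls` data.frame.
#' @export
clusters_to_calls <- function(clusters) {
  stopifnot(!is.null(clusters$svtype), !is.null(clusters$bp1_lo))
  n <- nrow(clusters)
  pos1 <- if (!is.null(clusters$bp1_point)) clusters$bp1_point else
    as.integer(floor((clusters$bp1_lo + clusters$bp1_hi) / 2))
  pos2 <- if (!is.null(clusters$bp2_point)) clusters$bp2_point else
    as.integer(floor((clusters$bp2_lo + clusters$bp2_hi) / 2))
  intra <- clusters$chrom1 == clusters$chrom2
  calls <- data.frame(
    id = clusters$cluster_id,
    svtype = clusters$svtype,
    chrom1 = clusters$chrom1, pos1 = pos1,
    ci1_lo = clusters$bp1_lo, ci1_hi = clusters$bp1_hi,
    chrom2 = clusters$chrom2, pos2 = pos2,
    ci2_lo = clusters$bp2_lo, ci2_hi = clusters$bp2_hi,
    length = ifelse(intra & clusters$svtype != "INS", pos2 - pos1, NA_integer_),
    strand1 = clusters$strand1, strand2 = clusters$strand2,
    evidence = "cluster",
    support = clusters$support,
    log2_ratio = NA_real_,
    imprecise = FALSE,
    filters = "",
    stringsAsFactors = FALSE)
  structure(calls, contigs = attr(clusters, "contigs"),
            class = c("sv_calls", "data.frame"))
}

#' Turn DOC segments into copy-number SV calls
#'
#' Gain segments become `DUP`, loss segments `DEL`; these calls carry DOC
#' evidence only, `support = 0`, and are imprecise: the confidence interval
#' of each boundary is one window either side.
#'
#' @param segments Segment table from [call_segments()].
#' @param window_size Window size used (bp), sets the boundary CI width.
#' @return An `sv_calls` data.frame.
#' @export
doc_to_calls <- function(segments, window_size) {
  n <- nrow(segments)
  calls <- data.frame(
    id = if (n) sprintf("doc%04d", seq_len(n)) else character(0L),
    svtype = ifelse(segments$direction == "gain", "DUP", "DEL"),
    chrom1 = segments$chrom, pos1 = segments$start,
    ci1_lo = pmax(0L, segments$start - window_size),
    ci1_hi = segments$start + window_size,
    chrom2 = segments$chrom, pos2 = segments$end,
    ci2_lo = pmax(0L, segments$end - window_size),
    ci2_hi = segments$end + window_size,
    length = segments$end - segments$start,
    strand1 = rep(NA_character_, n), strand2 = rep(NA_character_, n),
    evidence = rep("doc", n),
    support = rep(0L, n),
    log2_ratio = segments$mean_log2_ratio,
    imprecise = rep(TRUE, n),
    filters = rep("", n),
    stringsAsFactors = FALSE)
  structure(calls, class = c("sv_calls", "data.frame"))
}

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1), ov / (e2 - s2)))
}

#' Merge cluster-derived and DOC-derived calls
#'
#' A DEL/DUP cluster call absorbs a sign-consistent DOC segment call
#' (DEL with loss, DUP with gain) on the same chromosome when their
#' reciprocal overlap reaches `min_reciprocal_overlap`; the merged call
#' keeps the cluster's (more precise) coordinates and gains
#' `evidence = "cluster,doc"` plus the segment's mean log2 ratio. Matching
#' is one-to-one, best reciprocal overlap first. A sign-INCONSISTENT
#' overlapping segment leaves both calls in the output and tags the
#' cluster call `discordant_evidence`. INV/TRA/INS never merge with DOC
#' segments. Unmatched calls pass through with their single evidence
#' class.
#'
#' @param cluster_calls,doc_calls `sv_calls` tables (see
#'   [clusters_to_calls()], [doc_to_calls()]).
#' @param min_reciprocal_overlap Reciprocal-overlap threshold (default 0.5).
#' @return A combined `sv_calls` table sorted by (chrom1, pos1), ids
#'   renumbered `sv1`, `sv2`, ...
#' @export
merge_calls <- function(cluster_calls, doc_calls = NULL,
                        min_reciprocal_overlap = 0.5) {
  contigs <- attr(cluster_calls, "contigs")
  if (is.null(doc_calls) || nrow(doc_calls) == 0L) {
    out <- cluster_calls
  } else {
    consumed <- rep(FALSE, nrow(doc_calls))
    cc <- cluster_calls
    cand <- which(cc$svtype %in% c("DEL", "DUP") & cc$chrom1 == cc$chrom2)
    if (length(cand)) {
      grid <- expand.grid(ci = cand, di = seq_len(nrow(doc_calls)))
      grid <- grid[cc$chrom1[grid$ci] == doc_calls$chrom1[grid$di], ,
                   drop = FALSE]
      if (nrow(grid)) {
        grid$ro <- .reciprocal_overlap(cc$pos1[grid$ci], cc$pos2[grid$ci],
                                       doc_calls$pos1[grid$di],
                                       doc_calls$pos2[grid$di])
        grid <- grid[grid$ro >= min_reciprocal_overlap, , drop = FALSE]
        grid$same_sign <- cc$svtype[grid$ci] == doc_calls$svtype[grid$di]
        grid <- grid[order(-grid$ro), , drop = FALSE]
        taken_c <- rep(FALSE, nrow(cc))
        for (g in seq_len(nrow(grid))) {
          ci <- grid$ci[g]; di <- grid$di[g]
          if (consumed[di] || taken_c[ci]) next
          if (grid$same_sign[g]) {
            cc$evidence[ci] <- "cluster,doc"
            cc$log2_ratio[ci] <- doc_calls$log2_ratio[di]
            consumed[di] <- TRUE
            taken_c[ci] <- TRUE
          } else {
            cc$filters[ci] <- ifelse(cc$filters[ci] == "",
                                     "discordant_evidence",
                                     paste(cc$filters[ci],
                                           "discordant_evidence", sep = ";"))
          }
        }
      }
    }
    out <- rbind(cc, doc_calls[!consumed, ])
  }
  if (nrow(out)) {
    ord <- if (!is.null(contigs)) {
      order(chrom_rank(out$chrom1, names(contigs)), out$pos1)
    } else order(out$chrom1, out$pos1)
    out <- out[ord, ]
    out$id <- sprintf("sv%d", seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  structure(out, contigs = contigs, class = c("sv_calls", "data.frame"))
}

#' @export
print.sv_calls <- function(x, ...) {
  cat("sv_calls:", nrow(x), "calls\n")
  if (nrow(x) && !is.null(x$svtype) && !is.null(x$evidence)) {
    print(table(svtype = x$svtype, evidence = x$evidence))
  } else if (nrow(x)) {
    print.data.frame(x, ...)
  }
  invisible(x)
}

# 1-based anchor base before a 0-based breakpoint b is position b; fetch the
# reference base there when a FASTA is available, else "N".
.anchor_base <- function(fa, chrom, pos1b) {
  if (is.null(fa)) return(rep("N", length(chrom)))
  vapply(seq_along(chrom), function(i) {
    p <- max(1L, pos1b[i])
    as.character(Rsamtools::scanFa(fa, GenomicRanges::GRanges(
      chrom[i], IRanges::IRanges(p, p)))[[1L]])
  }, character(1L))
}

#' Write SV calls as VCF 4.2
#'
#' Intra-chromosomal calls are written as symbolic records
#' (`<DEL>`, `<DUP>`, `<INV>`, `<INS>`; COMPLEX cluster calls as `<CPX>`),
#' translocations as paired BND records with bracket notation and MATEID
#' cross-references. POS is the base before the breakpoint (so a 0-based
#' breakpoint b prints as POS = b); CIPOS/CIEND carry the full
#' breakpoint-interval uncertainty as offsets. INFO keys: SVTYPE, END,
#' SVLEN, SUPPORT, LOG2R, EVIDENCE, CIPOS, CIEND, IMPRECISE, MATEID.
#' No timestamp is written, so reruns are byte-identical.
#'
#' @param calls An `sv_calls` data.frame.
#' @param contigs Named vector of chromosome lengths covering all call
#'   chromosomes.
#' @param path Output path.
#' @param sample_name Recorded in a `##SAMPLE` header line.
#' @param fasta Optional reference FASTA for REF anchor bases (else `N`).
#' @return The path, invisibly.
#' @export
write_vcf <- function(calls, contigs, path, sample_name = "SAMPLE",
                      fasta = NULL) {
  miss <- setdiff(unique(c(calls$chrom1, calls$chrom2)), names(contigs))
  if (length(miss))
    stop("call chromosome(s) absent from contigs: ", paste(miss, collapse = ", "))
  fa <- NULL
  if (!is.null(fasta)) {
    if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
    fa <- Rsamtools::FaFile(fasta)
  }
  filter_tags <- setdiff(unique(unlist(strsplit(calls$filters, ";"))), "")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svcallr",
    paste0("##SAMPLE=<ID=", sample_name, ">"),
    paste0("##contig=<ID=", names(contigs), ",length=",
           unname(as.integer(contigs)), ">"),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=CPX,Description=\"Complex rearrangement\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
    "##INFO=<ID=LOG2R,Number=1,Type=Float,Description=\"Mean log2 coverage ratio\">",
    "##INFO=<ID=EVIDENCE,Number=.,Type=String,Description=\"Evidence classes\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"CI around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"CI around END\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##FILTER=<ID=discordant_evidence,Description=\"Cluster and coverage evidence disagree in sign\">",
    if (length(filter_tags)) {
      paste0("##FILTER=<ID=",
             setdiff(filter_tags, "discordant_evidence"),
             ",Description=\"Overlap with annotation track beyond threshold\">")
    },
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  hdr <- hdr[!is.na(hdr) & hdr != ""]

  recs <- character(0L)
  filt_str <- ifelse(calls$filters == "", "PASS", calls$filters)
  for (i in seq_len(nrow(calls))) {
    ca <- calls[i, ]
    cip <- paste0("CIPOS=", ca$ci1_lo - ca$pos1, ",", ca$ci1_hi - ca$pos1)
    cie <- paste0("CIEND=", ca$ci2_lo - ca$pos2, ",", ca$ci2_hi - ca$pos2)
    ev <- paste0("EVIDENCE=", ca$evidence)
    sup <- paste0("SUPPORT=", ca$support)
    l2r <- if (!is.na(ca$log2_ratio))
      paste0("LOG2R=", formatC(ca$log2_ratio, format = "g", digits = 6)) else NULL
    imp <- if (isTRUE(ca$imprecise)) "IMPRECISE" else NULL
    if (ca$svtype == "TRA") {
      ref1 <- .anchor_base(fa, ca$chrom1, ca$pos1)
      ref2 <- .anchor_base(fa, ca$chrom2, ca$pos2)
      s1 <- if (is.null(ca$strand1) || is.na(ca$strand1)) "+" else ca$strand1
      s2 <- if (is.null(ca$strand2) || is.na(ca$strand2)) "-" else ca$strand2
      br <- .bnd_alts(s1, s2, ref1, ref2,
                      ca$chrom1, ca$pos1, ca$chrom2, ca$pos2)
      id1 <- paste0(ca$id, "_bnd1"); id2 <- paste0(ca$id, "_bnd2")
      info1 <- paste(c("SVTYPE=BND", paste0("MATEID=", id2), cip, sup, ev, imp),
                     collapse = ";")
      info2 <- paste(c("SVTYPE=BND", paste0("MATEID=", id1), cie, sup, ev, imp),
                     collapse = ";")
      recs <- c(recs,
                paste(ca$chrom1, ca$pos1, id1, ref1, br[1L], ".", filt_str[i],
                      info1, sep = "\t"),
                paste(ca$chrom2, ca$pos2, id2, ref2, br[2L], ".", filt_str[i],
                      info2, sep = "\t"))
    } else {
      alt <- paste0("<", if (ca$svtype == "COMPLEX") "CPX" else ca$svtype, ">")
      svlen <- if (is.na(ca$length)) NULL else
        paste0("SVLEN=", if (ca$svtype == "DEL") -ca$length else ca$length)
      info <- paste(c(paste0("SVTYPE=", ca$svtype),
                      paste0("END=", ca$pos2), svlen, sup, l2r, ev,
                      cip, cie, imp), collapse = ";")
      recs <- c(recs, paste(ca$chrom1, max(1L, ca$pos1), ca$id,
                            .anchor_base(fa, ca$chrom1, ca$pos1), alt, ".",
                            filt_str[i], info, sep = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# Bracket notation for a breakend pair given the cluster's strand signature.
# The local strand decides where the anchor base sits (+ : "t[" forms);
# the partner strand decides bracket direction ('-' partner joins forward
# sequence right of its position -> '[', '+' partner joins reverse-
# complemented sequence left of it -> ']').
.bnd_alts <- function(s1, s2, ref1, ref2, c1, p1, c2, p2) {
  mk <- function(own, partner, refbase, pc, pp) {
    br <- if (partner == "-") paste0("[", pc, ":", pp, "[")
          else paste0("]", pc, ":", pp, "]")
    if (own == "+") paste0(refbase, br) else paste0(br, refbase)
  }
  c(mk(s1, s2, ref1, c2, p2), mk(s2, s1, ref2, c1, p1))
}

#' Write SV calls as BEDPE
#' @param calls An `sv_calls` data.frame.
#' @param path Output path.
#' @export
write_calls_bedpe <- function(calls, path) {
  lines <- paste(calls$chrom1, calls$ci1_lo, calls$ci1_hi,
                 calls$chrom2, calls$ci2_lo, calls$ci2_hi,
                 paste0(calls$id, "_", calls$svtype), calls$support,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
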