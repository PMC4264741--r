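#' Run the full SV discovery pipeline
#'
#' Orchestrates the analytical stages: load pairs, estimate the insert-size
#' model, classify and (optionally) realignment-rescue discordant pairs,
#' cluster, apply the coverage-scaled support cutoff, type clusters, derive
#' breakpoint intervals, run the depth-of-coverage comparison when a
#' reference alignment is supplied, merge the evidence, apply annotation
#' track filters and write VCF/BEDPE (plus bedGraph and window TSV when DOC
#' ran). All effective parameters are written to `run.log`. The pipeline is
#' deterministic: rerunning on identical inputs reproduces identical
#' outputs byte for byte.
#'
#' @param sam Sample SAM/BAM (coordinate-sorted).
#' @param ref_sam Optional reference-sample SAM/BAM for DOC; when absent the
#'   DOC stage is skipped with a logged notice.
#' @param fasta Optional reference FASTA; enables realignment rescue and VCF
#'   REF anchor bases.
#' @param tracks Named list of BED paths (or `GRanges`) used as overlap
#'   filters.
#' @param out_dir Output directory (created).
#' @param min_mapq,drop_duplicates Passed to [load_read_pairs()].
#' @param k_discordant Discordancy multiplier k (default 3).
#' @param min_support Cluster support cutoff; `NULL` (default) derives it
#'   from mean coverage via [min_support_cutoff()].
#' @param target_reads_per_window,step_frac,ratio_threshold,min_consecutive
#'   DOC parameters, see [doc_analysis()].
#' @param min_reciprocal_overlap Evidence merge threshold (default 0.5).
#' @param filter_mode `"annotate"` or `"remove"` for track filters.
#' @param max_frac Track overlap threshold(s) (default 0.5).
#' @param realign Apply realignment rescue when sequences and a FASTA are
#'   available (default TRUE).
#' @return List with `calls`, `clusters`, `model`, `doc` (or NULL), and
#'   output `paths`.
#' @export
run_pipeline <- function(sam, ref_sam = NULL, fasta = NULL, tracks = list(),
                         out_dir = tempfile("svrun"),
                         min_mapq = 20L, drop_duplicates = TRUE,
                         k_discordant = 3, min_support = NULL,
                         target_reads_per_window = 100L, step_frac = 0.5,
                         ratio_threshold = 0.3, min_consecutive = 3L,
                         min_reciprocal_overlap = 0.5,
                         filter_mode = c("annotate", "remove"),
                         max_frac = 0.5, realign = TRUE) {
  filter_mode <- match.arg(filter_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon), add = TRUE)
  note <- function(...) {
    msg <- paste0("[", "svcallr", "] ", ...)
    writeLines(msg, logcon)
    message(msg)
  }
  note("svcallr ", as.character(utils::packageVersion("svcallr")))
  params <- list(sam = sam, ref_sam = ref_sam %||% "(none)",
                 fasta = fasta %||% "(none)",
                 tracks = paste(names(tracks), collapse = ",") ,
                 min_mapq = min_mapq, drop_duplicates = drop_duplicates,
                 k_discordant = k_discordant,
                 min_support = min_support %||% "auto",
                 target_reads_per_window = target_reads_per_window,
                 step_frac = step_frac, ratio_threshold = ratio_threshold,
                 min_consecutive = min_consecutive,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 filter_mode = filter_mode, max_frac = max_frac,
                 realign = realign)
  for (nm in names(params)) note("param ", nm, " = ", params[[nm]])

  keep_seq <- realign && !is.null(fasta)
  note("stage alignments: loading ", sam)
  pairs <- load_read_pairs(sam, min_mapq = min_mapq,
                           drop_duplicates = drop_duplicates,
                           keep_seq = keep_seq)
  contigs <- attr(pairs, "contigs")
  read_len <- attr(pairs, "read_len")
  note("loaded ", nrow(pairs), " pairs (", attr(pairs, "n_orphans"),
       " orphans, ", attr(pairs, "n_dup_removed"), " duplicates removed)")

  model <- estimate_insert_model(pairs, k_discordant = k_discordant)
  note("insert model: median ", model$median_is, " sigma ",
       round(model$sigma_is, 1), " orientation ", model$expected_orientation)

  disc <- discordant_pairs(pairs, model)
  note("stage classify: ", nrow(disc), " discordant of ", nrow(pairs), " pairs")

  if (keep_seq && nrow(disc)) {
    keep <- realignment_rescue(disc, fasta, model)
    note("stage realignment rescue: discarded ", sum(!keep), " of ",
         nrow(disc), " discordant pairs")
    disc <- disc[keep, ]
    rownames(disc) <- NULL
    for (a in c("contigs", "read_len")) attr(disc, a) <- attr(pairs, a)
  } else if (realign && is.null(fasta)) {
    note("stage realignment rescue: skipped (no reference FASTA)")
  }

  clusters <- cluster_discordant(disc, model)
  genome_size <- sum(contigs)
  # support at a junction scales with the fragment-span (physical) coverage,
  # which for long-insert libraries far exceeds the base coverage
  phys_cov <- nrow(pairs) * model$median_is / genome_size
  ms <- min_support %||% min_support_cutoff(phys_cov)
  note("stage clustering: ", nrow(clusters), " raw clusters; physical coverage ",
       round(phys_cov, 1), "x -> min support ", ms)
  clusters <- filter_by_support(clusters, ms)
  clusters <- assign_types(clusters, model)
  clusters <- add_breakpoint_intervals(clusters, model, read_len)
  note("stage typing: ", nrow(clusters), " clusters after support filter (",
       paste(names(table(clusters$svtype)), table(clusters$svtype),
             sep = ":", collapse = " "), ")")
  cluster_calls <- clusters_to_calls(clusters)

  doc <- NULL; doc_calls <- NULL
  if (!is.null(ref_sam)) {
    note("stage doc: loading reference sample ", ref_sam)
    ref_pairs <- load_read_pairs(ref_sam, min_mapq = min_mapq,
                                 drop_duplicates = drop_duplicates)
    doc <- doc_analysis(read_anchors(pairs), read_anchors(ref_pairs), contigs,
                        target_reads_per_window = target_reads_per_window,
                        step_frac = step_frac,
                        ratio_threshold = ratio_threshold,
                        min_consecutive = min_consecutive)
    note("stage doc: ", nrow(doc$windows), " windows of ", doc$window_size,
         " bp, ", nrow(doc$segments), " segments")
    doc_calls <- doc_to_calls(doc$segments, doc$window_size)
  } else {
    note("stage doc: skipped (no reference sample)")
  }

  calls <- merge_calls(cluster_calls, doc_calls,
                       min_reciprocal_overlap = min_reciprocal_overlap)
  note("stage merge: ", nrow(calls), " unified calls")

  if (length(tracks)) {
    grs <- lapply(seq_along(tracks), function(i) {
      t <- tracks[[i]]
      if (is.character(t)) read_track(t, names(tracks)[i]) else t
    })
    names(grs) <- names(tracks)
    n0 <- nrow(calls)
    calls <- apply_track_filters(calls, grs, max_frac = max_frac,
                                 mode = filter_mode)
    note("stage track filters (", filter_mode, "): ", n0, " -> ",
         nrow(calls), " calls")
  }

  paths <- list(vcf = file.path(out_dir, "calls.vcf"),
                bedpe = file.path(out_dir, "calls.bedpe"),
                clusters_bedpe = file.path(out_dir, "clusters.bedpe"),
                log = logfile)
  write_vcf(calls, contigs, paths$vcf, fasta = fasta)
  write_calls_bedpe(calls, paths$bedpe)
  write_clusters_bedpe(clusters, paths$clusters_bedpe)
  if (!is.null(doc)) {
    paths$bedgraph <- file.path(out_dir, "doc.bedgraph")
    paths$windows_tsv <- file.path(out_dir, "doc_windows.tsv")
    paths$segments_bed <- file.path(out_dir, "doc_segments.bed")
    write_bedgraph(doc$windows, paths$bedgraph)
    write_windows_tsv(doc$windows, paths$windows_tsv)
    write_segments_bed(doc$segments, paths$segments_bed)
  }
  note("done: outputs in ", out_dir)
  invisible(list(calls = calls, clusters = clusters, model = model, doc = doc,
                 pairs_n = nrow(pairs), discordant_n = nrow(disc),
                 paths = paths))
}
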