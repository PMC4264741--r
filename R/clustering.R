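#' Test cluster membership for a discordant pair
#'
#' A pair is a candidate member of a cluster when both of its read start
#' positions fall within twice the insert-size standard deviation of the
#' cluster's running mean start positions, its strand signature matches,
#' and (for same-chromosome pairs) its insert size is within the same
#' 2-sigma window of the cluster's running mean insert size.
#'
#' @param pair One-row data.frame or list with `alpha`, `beta`, `strand1`,
#'   `strand2`, `chrom1`, `chrom2`, `insert_size`.
#' @param cluster List or one-row data.frame with `mu_alpha`, `mu_beta`,
#'   `mu_is`, `strand1`, `strand2`, `chrom1`, `chrom2`.
#' @param sigma_is Insert-size standard deviation (bp).
#' @return `TRUE` or `FALSE`.
#' @export
is_member <- function(pair, cluster, sigma_is) {
  w <- 2 * sigma_is
  if (pair$chrom1 != cluster$chrom1 || pair$chrom2 != cluster$chrom2) return(FALSE)
  if (pair$strand1 != cluster$strand1 || pair$strand2 != cluster$strand2) return(FALSE)
  if (abs(pair$alpha - cluster$mu_alpha) > w) return(FALSE)
  if (abs(pair$beta - cluster$mu_beta) > w) return(FALSE)
  if (pair$chrom1 == pair$chrom2 &&
      abs(pair$insert_size - cluster$mu_is) > w) return(FALSE)
  TRUE
}

#' Cluster discordant pairs by position, strand signature and insert size
#'
#' Streams pairs sorted by (chrom1, alpha) and hard-assigns each to exactly
#' one cluster: among all open clusters passing the membership criteria
#' (see [is_member()]) the pair joins the closest one, measured by Euclidean
#' distance in the (alpha, beta) plane to the cluster's running means, ties
#' broken in favour of the earlier-created cluster; otherwise it seeds a new
#' cluster. Cluster means are updated incrementally after each addition
#' (set `freeze_means = TRUE` to keep means at their seed values). Clusters
#' whose mean alpha falls more than `2 * sigma_is` behind the scan position
#' are closed and never reopened, which bounds memory without excluding any
#' pair the alpha window could admit. Strand signature and the chromosome
#' pair are hard clustering keys; inter-chromosomal clusters use the same
#' positional windows and no insert-size criterion.
#'
#' @param pairs Discordant `read_pairs` rows sorted by (chrom1, alpha), as
#'   returned by [discordant_pairs()].
#' @param model An `insert_size_model` (supplies `sigma_is`).
#' @param freeze_means Keep cluster means fixed at the seeding pair.
#' @return An `sv_clusters` data.frame: one row per cluster with
#'   `cluster_id`, `chrom1`, `chrom2`, `strand1`, `strand2`, running means
#'   `mu_alpha`/`mu_beta`/`mu_is`, member extremes `min_alpha`/`max_alpha`/
#'   `min_beta`/`max_beta`, `support`, `orientation`, and a `members`
#'   list-column of pair ids. Creation order preserved.
#' @export
cluster_discordant <- function(pairs, model, freeze_means = FALSE) {
  stopifnot(inherits(model, "insert_size_model"))
  n <- nrow(pairs)
  contigs <- attr(pairs, "contigs")
  if (n && !is.null(contigs)) {
    o <- order(chrom_rank(pairs$chrom1, names(contigs)), pairs$alpha)
  } else {
    o <- seq_len(n)
  }
  if (n && any(o != seq_len(n))) stop("input pairs not sorted by (chrom1, alpha)")
  if (n > 1L) {
    same <- pairs$chrom1[-1L] == pairs$chrom1[-n]
    if (any(same & pairs$alpha[-1L] < pairs$alpha[-n]))
      stop("input pairs not sorted by (chrom1, alpha)")
  }
  sigma <- model$sigma_is
  w <- 2 * sigma

  # open-cluster pool, grown geometrically
  cap <- 256L
  mu_a <- mu_b <- mu_is <- numeric(cap)
  min_a <- max_a <- min_b <- max_b <- numeric(cap)
  cnt <- integer(cap); cid <- integer(cap)
  key <- character(cap)   # chrom1|chrom2|s1|s2
  open <- logical(cap)
  members <- vector("list", cap)
  n_open <- 0L; next_id <- 0L
  closed <- list()
  cur_chrom <- NA_character_

  close_idx <- function(idx) {
    for (j in idx) {
      closed[[length(closed) + 1L]] <<- list(
        id = cid[j], key = key[j], mu_alpha = mu_a[j], mu_beta = mu_b[j],
        mu_is = mu_is[j], min_alpha = min_a[j], max_alpha = max_a[j],
        min_beta = min_b[j], max_beta = max_b[j], support = cnt[j],
        members = members[[j]])
      open[j] <<- FALSE
      members[j] <<- list(NULL)
    }
  }

  same_chrom <- pairs$chrom1 == pairs$chrom2
  keys <- paste(pairs$chrom1, pairs$chrom2, pairs$strand1, pairs$strand2,
                sep = "|")
  for (i in seq_len(n)) {
    a <- pairs$alpha[i]; b <- pairs$beta[i]
    if (!identical(cur_chrom, pairs$chrom1[i])) {
      close_idx(which(open[seq_len(n_open)]))
      cur_chrom <- pairs$chrom1[i]
    } else {
      evict <- which(open[seq_len(n_open)] & mu_a[seq_len(n_open)] < a - w)
      if (length(evict)) close_idx(evict)
    }
    live <- which(open[seq_len(n_open)] & key[seq_len(n_open)] == keys[i] &
                    abs(mu_a[seq_len(n_open)] - a) <= w &
                    abs(mu_b[seq_len(n_open)] - b) <= w)
    if (same_chrom[i] && length(live)) {
      live <- live[abs(pairs$insert_size[i] - mu_is[live]) <= w]
    }
    if (length(live)) {
      d <- (a - mu_a[live])^2 + (b - mu_b[live])^2
      # ties: earliest-created cluster; pool index order equals creation order
      j <- live[which.min(d)]
      k <- cnt[j] + 1L
      if (!freeze_means) {
        mu_a[j] <- mu_a[j] + (a - mu_a[j]) / k
        mu_b[j] <- mu_b[j] + (b - mu_b[j]) / k
        if (same_chrom[i])
          mu_is[j] <- mu_is[j] + (pairs$insert_size[i] - mu_is[j]) / k
      }
      cnt[j] <- k
      min_a[j] <- min(min_a[j], a); max_a[j] <- max(max_a[j], a)
      min_b[j] <- min(min_b[j], b); max_b[j] <- max(max_b[j], b)
      members[[j]] <- c(members[[j]], pairs$pair_id[i])
    } else {
      if (n_open == cap) {
        cap <- cap * 2L
        length(mu_a) <- cap; length(mu_b) <- cap; length(mu_is) <- cap
        length(min_a) <- cap; length(max_a) <- cap
        length(min_b) <- cap; length(max_b) <- cap
        length(cnt) <- cap; length(cid) <- cap; length(key) <- cap
        length(open) <- cap; length(members) <- cap
      }
      n_open <- n_open + 1L; next_id <- next_id + 1L
      j <- n_open
      mu_a[j] <- a; mu_b[j] <- b
      mu_is[j] <- if (same_chrom[i]) pairs$insert_size[i] else NA_real_
      min_a[j] <- max_a[j] <- a; min_b[j] <- max_b[j] <- b
      cnt[j] <- 1L; cid[j] <- next_id; key[j] <- keys[i]
      open[j] <- TRUE
      members[[j]] <- pairs$pair_id[i]
    }
    # compact the pool when it is mostly dead
    if (n_open > 512L && sum(open[seq_len(n_open)]) < n_open / 4L) {
      liveix <- which(open[seq_len(n_open)])
      m <- length(liveix)
      mu_a[seq_len(m)] <- mu_a[liveix]; mu_b[seq_len(m)] <- mu_b[liveix]
      mu_is[seq_len(m)] <- mu_is[liveix]
      min_a[seq_len(m)] <- min_a[liveix]; max_a[seq_len(m)] <- max_a[liveix]
      min_b[seq_len(m)] <- min_b[liveix]; max_b[seq_len(m)] <- max_b[liveix]
      cnt[seq_len(m)] <- cnt[liveix]; cid[seq_len(m)] <- cid[liveix]
      key[seq_len(m)] <- key[liveix]
      members[seq_len(m)] <- members[liveix]
      open[seq_len(m)] <- TRUE
      if (m < n_open) open[seq(m + 1L, n_open)] <- FALSE
      n_open <- m
    }
  }
  close_idx(which(open[seq_len(n_open)]))

  if (!length(closed)) {
    out <- data.frame(cluster_id = character(0L))
  } else {
    ord <- order(vapply(closed, `[[`, 0L, "id"))
    closed <- closed[ord]
    kk <- strsplit(vapply(closed, `[[`, "", "key"), "|", fixed = TRUE)
    out <- data.frame(
      cluster_id = sprintf("c%05d", vapply(closed, `[[`, 0L, "id")),
      chrom1 = vapply(kk, `[[`, "", 1L), chrom2 = vapply(kk, `[[`, "", 2L),
      strand1 = vapply(kk, `[[`, "", 3L), strand2 = vapply(kk, `[[`, "", 4L),
      mu_alpha = vapply(closed, `[[`, 0, "mu_alpha"),
      mu_beta = vapply(closed, `[[`, 0, "mu_beta"),
      mu_is = vapply(closed, `[[`, 0, "mu_is"),
      min_alpha = vapply(closed, `[[`, 0, "min_alpha"),
      max_alpha = vapply(closed, `[[`, 0, "max_alpha"),
      min_beta = vapply(closed, `[[`, 0, "min_beta"),
      max_beta = vapply(closed, `[[`, 0, "max_beta"),
      support = vapply(closed, `[[`, 0L, "support"),
      stringsAsFactors = FALSE)
    out$orientation <- ifelse(out$chrom1 == out$chrom2,
                              pair_orientation(out$strand1, out$strand2),
                              NA_character_)
    out$members <- lapply(closed, `[[`, "members")
  }
  structure(out, sigma_is = sigma, contigs = attr(pairs, "contigs"),
            read_len = attr(pairs, "read_len"),
            class = c("sv_clusters", "data.frame"))
}

#' @export
print.sv_clusters <- function(x, ...) {
  cat("sv_clusters:", nrow(x), "clusters,",
      if (nrow(x)) sum(x$support) else 0L, "member pairs\n")
  if (nrow(x)) print(table(support = x$support))
  invisible(x)
}

#' Minimum cluster-support cutoff from coverage
#'
#' Coverage-scaled read-count cutoff used to discard clusters with too few
#' supporting pairs: `max(floor, round(mean_coverage / 10))`.
#'
#' @param mean_coverage Mean fold-coverage of the sample.
#' @param floor Minimum cutoff (default 2: a cluster needs at least two
#'   similar pairs).
#' @return Integer cutoff.
#' @export
min_support_cutoff <- function(mean_coverage, floor = 2L) {
  stopifnot_scalar_num(mean_coverage, "mean_coverage", min = 0)
  max(as.integer(floor), as.integer(round(mean_coverage / 10)))
}

#' Filter clusters by support
#' @param clusters An `sv_clusters` data.frame.
#' @param min_support Minimum member count (>= 1).
#' @return Clusters with `support >= min_support`, order preserved.
#' @export
filter_by_support <- function(clusters, min_support) {
  stopifnot(min_support >= 1)
  out <- clusters[clusters$support >= min_support, ]
  rownames(out) <- NULL
  for (a in c("sigma_is", "contigs", "read_len")) attr(out, a) <- attr(clusters, a)
  out
}

#' Breakpoint intervals of a cluster
#'
#' Derives, from the member read positions and the insert-size model, the
#' two genomic intervals guaranteed (up to model assumptions) to contain
#' the breakpoints. The direction in which the fragment extends from a
#' side's reads toward the junction follows from that side's read strand:
#' when it matches the strand a concordant pair's left (alpha side) or
#' right (beta side) read would have, the member reads tile up to the
#' junction from the left (alpha: breakpoint in `[max(alpha) + read_len,
#' max(alpha) + median_is)`) or from the right (beta: breakpoint in
#' `[min(beta) - median_is + read_len, min(beta))`). When the strand is
#' flipped — as on the everted side of a tandem duplication or inside an
#' inversion — the construction mirrors: alpha-side breakpoint in
#' `[min(alpha) - median_is + read_len, min(alpha)]`, beta-side in
#' `[max(beta) + read_len, max(beta) + median_is)`. If a construction
#' empties an interval, a fallback window of width `4 * sigma_is` is
#' centred on the cluster mean of that side.
#'
#' @param cluster One-row `sv_clusters` data.frame (or equivalent list).
#' @param model An `insert_size_model`.
#' @param read_len Read length (bp).
#' @return List of two `BreakpointInterval` lists: `left` and `right`, each
#'   with `chrom`, `lo`, `hi` (0-based half-open, `lo < hi`).
#' @export
breakpoint_intervals <- function(cluster, model, read_len) {
  if (cluster$support < 2L)
    stop("breakpoint intervals require support >= 2 (got ", cluster$support, ")")
  v <- add_breakpoint_intervals(as.data.frame(cluster, stringsAsFactors = FALSE),
                                model, read_len)
  list(left = list(chrom = v$chrom1[1L], lo = v$bp1_lo[1L], hi = v$bp1_hi[1L]),
       right = list(chrom = v$chrom2[1L], lo = v$bp2_lo[1L], hi = v$bp2_hi[1L]))
}

#' Attach breakpoint-interval columns to a cluster table
#' @param clusters An `sv_clusters` data.frame.
#' @param model An `insert_size_model`.
#' @param read_len Read length (bp).
#' @return `clusters` with columns `bp1_lo`, `bp1_hi`, `bp2_lo`, `bp2_hi`.
#' @export
add_breakpoint_intervals <- function(clusters, model, read_len) {
  med <- model$median_is; w <- 2 * model$sigma_is
  left_strand <- if (model$expected_orientation == "FR") "+" else "-"
  right_strand <- if (model$expected_orientation == "FR") "-" else "+"
  fwd1 <- clusters$strand1 == left_strand
  fwd2 <- clusters$strand2 == right_strand
  lo1 <- ifelse(fwd1, clusters$max_alpha + read_len,
                clusters$min_alpha - med + read_len)
  hi1 <- ifelse(fwd1, clusters$max_alpha + med, clusters$min_alpha + 1)
  pt1 <- ifelse(fwd1, clusters$max_alpha + read_len, clusters$min_alpha)
  bad <- !(lo1 < hi1)
  ctr <- ifelse(fwd1, clusters$mu_alpha + read_len, clusters$mu_alpha)
  lo1[bad] <- ctr[bad] - w; hi1[bad] <- ctr[bad] + w; pt1[bad] <- ctr[bad]
  lo2 <- ifelse(fwd2, clusters$min_beta - med + read_len,
                clusters$max_beta + read_len)
  hi2 <- ifelse(fwd2, clusters$min_beta, clusters$max_beta + med)
  pt2 <- ifelse(fwd2, clusters$min_beta, clusters$max_beta + read_len)
  bad <- !(lo2 < hi2)
  ctr <- ifelse(fwd2, clusters$mu_beta, clusters$mu_beta + read_len)
  lo2[bad] <- ctr[bad] - w; hi2[bad] <- ctr[bad] + w; pt2[bad] <- ctr[bad]
  clusters$bp1_lo <- pmax(0, floor(lo1)); clusters$bp1_hi <- ceiling(hi1)
  clusters$bp2_lo <- pmax(0, floor(lo2)); clusters$bp2_hi <- ceiling(hi2)
  clusters$bp1_point <- pmax(0, as.integer(round(pt1)))
  clusters$bp2_point <- pmax(0, as.integer(round(pt2)))
  clusters
}

#' Export clusters as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, support,
#' strand1, strand2. Breakpoint intervals are used when present (see
#' [add_breakpoint_intervals()]); otherwise the member read spans.
#'
#' @param clusters An `sv_clusters` data.frame.
#' @param path Output path.
#' @export
write_clusters_bedpe <- function(clusters, path) {
  if (!is.null(clusters$bp1_lo)) {
    s1 <- clusters$bp1_lo; e1 <- clusters$bp1_hi
    s2 <- clusters$bp2_lo; e2 <- clusters$bp2_hi
  } else {
    rl <- attr(clusters, "read_len") %||% 0
    s1 <- clusters$min_alpha; e1 <- clusters$max_alpha + rl
    s2 <- clusters$min_beta; e2 <- clusters$max_beta + rl
  }
  lines <- paste(clusters$chrom1, s1, e1, clusters$chrom2, s2, e2,
                 clusters$cluster_id, clusters$support,
                 clusters$strand1, clusters$strand2, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
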