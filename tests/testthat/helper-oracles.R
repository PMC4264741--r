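# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the clusterer is a direct transcription of
# the similarity criteria over ALL clusters (no streaming, no eviction), and
# the overlap oracle counts covered bases one by one.

oracle_cluster <- function(pairs, sigma, freeze_means = FALSE) {
  w <- 2 * sigma
  clusters <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$alpha[i]; b <- pairs$beta[i]
    same <- pairs$chrom1[i] == pairs$chrom2[i]
    cand <- Filter(function(k) {
      cl <- clusters[[k]]
      cl$chrom1 == pairs$chrom1[i] && cl$chrom2 == pairs$chrom2[i] &&
        cl$strand1 == pairs$strand1[i] && cl$strand2 == pairs$strand2[i] &&
        abs(a - cl$mu_a) <= w && abs(b - cl$mu_b) <= w &&
        (!same || abs(pairs$insert_size[i] - cl$mu_is) <= w)
    }, seq_along(clusters))
    if (length(cand)) {
      d <- vapply(cand, function(k) {
        (a - clusters[[k]]$mu_a)^2 + (b - clusters[[k]]$mu_b)^2
      }, 0)
      k <- cand[which.min(d)]   # which.min takes the earliest on ties
      cl <- clusters[[k]]
      m <- length(cl$members) + 1L
      if (!freeze_means) {
        cl$mu_a <- cl$mu_a + (a - cl$mu_a) / m
        cl$mu_b <- cl$mu_b + (b - cl$mu_b) / m
        if (same) cl$mu_is <- cl$mu_is + (pairs$insert_size[i] - cl$mu_is) / m
      }
      cl$members <- c(cl$members, pairs$pair_id[i])
      clusters[[k]] <- cl
    } else {
      clusters[[length(clusters) + 1L]] <- list(
        chrom1 = pairs$chrom1[i], chrom2 = pairs$chrom2[i],
        strand1 = pairs$strand1[i], strand2 = pairs$strand2[i],
        mu_a = a, mu_b = b,
        mu_is = if (same) pairs$insert_size[i] else NA_real_,
        members = pairs$pair_id[i])
    }
  }
  clusters
}

# per-base covered fraction of [start, end) by a set of (start, end) rows
oracle_overlap_fraction <- function(start, end, track_df) {
  covered <- logical(end - start)
  for (j in seq_len(nrow(track_df))) {
    lo <- max(start, track_df$start[j]); hi <- min(end, track_df$end[j])
    if (hi > lo) covered[(lo - start + 1L):(hi - start)] <- TRUE
  }
  mean(covered)
}

# random clustering instance: g groups of pairs plus scattered singletons,
# alphas confined so everything fits one scan window
random_cluster_instance <- function(seed, n_max = 200L) {
  set.seed(seed)
  g <- sample(2:6, 1L)
  sigma <- sample(c(50, 100, 300), 1L)
  sig_choices <- list(c("+", "-"), c("-", "+"), c("+", "+"), c("-", "-"))
  alpha <- integer(0L); beta <- integer(0L)
  s1 <- character(0L); s2 <- character(0L); ins <- integer(0L)
  for (k in seq_len(g)) {
    m <- sample(2:20, 1L)
    ca <- sample(1000:20000, 1L); cb <- ca + sample(5000:50000, 1L)
    sg <- sig_choices[[sample(4L, 1L)]]
    alpha <- c(alpha, ca + sample(-sigma:sigma, m, replace = TRUE))
    beta <- c(beta, cb + sample(-sigma:sigma, m, replace = TRUE))
    s1 <- c(s1, rep(sg[1L], m)); s2 <- c(s2, rep(sg[2L], m))
    ins <- c(ins, (cb - ca) + sample(-sigma:sigma, m, replace = TRUE))
  }
  n_noise <- sample(0:15, 1L)
  if (n_noise) {
    alpha <- c(alpha, sample(1000:30000, n_noise))
    beta <- c(beta, sample(40000:90000, n_noise))
    sg <- sample(4L, n_noise, replace = TRUE)
    s1 <- c(s1, vapply(sg, function(j) sig_choices[[j]][1L], ""))
    s2 <- c(s2, vapply(sg, function(j) sig_choices[[j]][2L], ""))
    ins <- c(ins, sample(2000:60000, n_noise))
  }
  keep <- seq_len(min(length(alpha), n_max))
  p <- mk_pairs(alpha[keep], beta[keep], strand1 = s1[keep], strand2 = s2[keep],
                insert = ins[keep])
  list(pairs = p, sigma = sigma)
}

# canonical form of a partition: sorted member lists, sorted
partition_of <- function(member_lists) {
  sets <- lapply(member_lists, function(m) paste(sort(m), collapse = ","))
  sort(unlist(sets))
}
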