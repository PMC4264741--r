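#' Generate a random reference genome
#'
#' Writes a FASTA of i.i.d. uniform A/C/G/T sequence, one record per
#' chromosome, and indexes it. Reproducible from `seed`.
#'
#' @param lengths Integer vector of chromosome lengths in bp; names are used
#'   as chromosome names (default `chr1`, `chr2`, ...).
#' @param seed Integer seed controlling the sequence.
#' @param path Output FASTA path.
#' @return Invisibly, a list with `fasta` (path) and `seqs`
#'   (a [Biostrings::DNAStringSet]).
#' @export
make_reference <- function(lengths, seed = 1L, path = tempfile(fileext = ".fa")) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1))
  nms <- names(lengths) %||% paste0("chr", seq_along(lengths))
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1L)))
  names(seqs) <- nms
  Biostrings::writeXStringSet(seqs, path)
  Rsamtools::indexFa(path)
  invisible(list(fasta = path, seqs = seqs))
}

# Split the block at row `i` of `blocks` so that reference position `refpos`
# (which must fall strictly inside a '+' block) becomes a block boundary.
.split_block <- function(blocks, i, refpos) {
  b <- blocks[i, ]
  stopifnot(b$strand == "+", refpos > b$ref_start, refpos < b$ref_end)
  left <- b; left$ref_end <- refpos
  right <- b; right$ref_start <- refpos
  rbind(blocks[seq_len(i - 1L), ], left, right,
        blocks[seq(i + 1L, length.out = nrow(blocks) - i), ])
}

.new_block <- function(ref_chrom, ref_start, ref_end, strand = "+", novel = NA_character_) {
  data.frame(ref_chrom = ref_chrom, ref_start = ref_start, ref_end = ref_end,
             strand = strand, novel = novel, stringsAsFactors = FALSE)
}

.block_len <- function(blocks) {
  ifelse(is.na(blocks$novel), blocks$ref_end - blocks$ref_start,
         nchar(blocks$novel))
}

# Locate the donor chromosome and block index of a '+' block fully containing
# the reference interval [lo, hi) on `chrom`.
.locate_block <- function(block_sets, chrom, lo, hi) {
  for (dc in names(block_sets)) {
    b <- block_sets[[dc]]
    hit <- which(is.na(b$novel) & b$strand == "+" & b$ref_chrom == chrom &
                   b$ref_start <= lo & b$ref_end >= hi)
    if (length(hit)) return(list(donor_chrom = dc, idx = hit[1L]))
  }
  stop("no donor block contains reference interval ", chrom, ":", lo, "-", hi,
       " (events overlapping or out of bounds?)")
}

#' Build a rearranged donor genome from structural-variant specs
#'
#' Splices the reference according to a table of SV specifications:
#' deletions remove the segment, tandem duplications insert `copies` extra
#' copies after the original, inversions reverse-complement in place,
#' insertions add random novel sequence, and translocations reciprocally
#' exchange the chromosome arms distal to the two breakpoints. A truth
#' manifest records every breakpoint in reference coordinates together with
#' the discordant read-pair signature the event is expected to produce.
#'
#' @param reference Result of [make_reference()] or a named
#'   [Biostrings::DNAStringSet].
#' @param specs data.frame with columns `svtype` (DEL/DUP/INV/INS/TRA),
#'   `chrom`, `pos`, `length`, and optionally `chrom2`, `pos2` (TRA) and
#'   `copies` (DUP, default 1 extra copy). Coordinates 0-based. Events must
#'   not overlap.
#' @param seed Seed for novel insertion sequence.
#' @return List with `donor` (DNAStringSet), `blocks` (per donor chromosome,
#'   the reference provenance of each spliced segment), `manifest` (truth
#'   records), `ref_seqs`, `ref_lengths`.
#' @export
apply_svs <- function(reference, specs, seed = 1L) {
  ref_seqs <- if (is.list(reference)) reference$seqs else reference
  stopifnot(inherits(ref_seqs, "DNAStringSet"), !is.null(names(ref_seqs)))
  ref_lengths <- stats::setNames(Biostrings::width(ref_seqs), names(ref_seqs))
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  for (col in c("chrom2", "pos2", "copies", "length")) {
    if (is.null(specs[[col]])) specs[[col]] <- rep(NA, nrow(specs))
  }
  .check_spec_overlap(specs, ref_lengths)

  block_sets <- lapply(names(ref_lengths), function(ch) {
    .new_block(ch, 0L, unname(ref_lengths[ch]))
  })
  names(block_sets) <- names(ref_lengths)
  set.seed(seed)
  manifest <- list()

  # Translocations first: they operate at the whole-arm level, then the
  # intra-chromosomal events are spliced into whichever arm now holds their
  # reference coordinates.
  for (i in which(specs$svtype == "TRA")) {
    s <- specs[i, ]
    locA <- .locate_block(block_sets, s$chrom, s$pos, s$pos)
    locB <- .locate_block(block_sets, s$chrom2, s$pos2, s$pos2)
    if (locA$donor_chrom == locB$donor_chrom)
      stop("translocation breakpoints resolve to the same donor chromosome")
    bsA <- block_sets[[locA$donor_chrom]]; bsB <- block_sets[[locB$donor_chrom]]
    cutA <- .split_point(bsA, locA$idx, s$pos)
    cutB <- .split_point(bsB, locB$idx, s$pos2)
    block_sets[[locA$donor_chrom]] <- rbind(cutA$head, cutB$tail)
    block_sets[[locB$donor_chrom]] <- rbind(cutB$head, cutA$tail)
    manifest[[length(manifest) + 1L]] <- list(
      svtype = "TRA", chrom1 = s$chrom, bp1 = s$pos,
      chrom2 = s$chrom2, bp2 = s$pos2, length = NA_integer_,
      signature = "inter_chromosomal")
  }

  for (i in which(specs$svtype != "TRA")) {
    s <- specs[i, ]
    lo <- s$pos
    hi <- if (s$svtype == "INS") s$pos else s$pos + s$length
    loc <- .locate_block(block_sets, s$chrom, lo, hi)
    b <- block_sets[[loc$donor_chrom]]
    blk <- b[loc$idx, ]
    pre  <- if (lo > blk$ref_start) .new_block(s$chrom, blk$ref_start, lo) else NULL
    post <- if (hi < blk$ref_end) .new_block(s$chrom, hi, blk$ref_end) else NULL
    mid <- switch(s$svtype,
      DEL = NULL,
      DUP = {
        copies <- if (is.na(s$copies)) 1L else as.integer(s$copies)
        do.call(rbind, rep(list(.new_block(s$chrom, lo, hi)), 1L + copies))
      },
      INV = .new_block(s$chrom, lo, hi, strand = "-"),
      INS = .new_block(s$chrom, lo, lo, novel = paste(
        sample(c("A", "C", "G", "T"), s$length, replace = TRUE), collapse = "")),
      stop("unknown svtype: ", s$svtype))
    b <- rbind(b[seq_len(loc$idx - 1L), ], pre, mid, post,
               b[seq(loc$idx + 1L, length.out = nrow(b) - loc$idx), ])
    block_sets[[loc$donor_chrom]] <- b
    manifest[[length(manifest) + 1L]] <- list(
      svtype = s$svtype, chrom1 = s$chrom, bp1 = lo, chrom2 = s$chrom,
      bp2 = hi, length = if (s$svtype == "INS") s$length else hi - lo,
      signature = switch(s$svtype, DEL = "large_insert", DUP = "everted",
                         INV = "same_strand", INS = "small_insert"))
  }

  # donor coordinates and sequence assembly
  donor <- Biostrings::DNAStringSet(lapply(block_sets, function(b) {
    parts <- lapply(seq_len(nrow(b)), function(j) {
      if (!is.na(b$novel[j])) return(Biostrings::DNAString(b$novel[j]))
      s <- Biostrings::subseq(ref_seqs[[b$ref_chrom[j]]],
                              b$ref_start[j] + 1L, b$ref_end[j])
      if (b$strand[j] == "-") Biostrings::reverseComplement(s) else s
    })
    do.call(Biostrings::xscat, parts)
  }))
  names(donor) <- names(block_sets)
  block_sets <- lapply(block_sets, function(b) {
    w <- .block_len(b)
    b$donor_start <- cumsum(c(0L, w))[seq_len(nrow(b))]
    b$donor_end <- b$donor_start + w
    b
  })
  structure(list(donor = donor, blocks = block_sets, manifest = manifest,
                 ref_seqs = ref_seqs, ref_lengths = ref_lengths),
            class = "sv_simulation")
}

# head/tail split of a block list at a reference position inside block idx
.split_point <- function(blocks, idx, refpos) {
  blk <- blocks[idx, ]
  if (refpos > blk$ref_start && refpos < blk$ref_end) {
    blocks <- .split_block(blocks, idx, refpos)
    idx <- idx + 1L
  } else if (refpos == blk$ref_end) {
    idx <- idx + 1L
  }
  list(head = blocks[seq_len(idx - 1L), ],
       tail = blocks[seq(idx, length.out = nrow(blocks) - idx + 1L), ])
}

.check_spec_overlap <- function(specs, ref_lengths) {
  iv <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (!s$chrom %in% names(ref_lengths))
      stop("spec chromosome not in reference: ", s$chrom)
    hi <- if (s$svtype %in% c("INS", "TRA")) s$pos + 1 else s$pos + s$length
    iv[[length(iv) + 1L]] <- c(i, match(s$chrom, names(ref_lengths)), s$pos, hi)
    if (s$svtype == "TRA")
      iv[[length(iv) + 1L]] <- c(i, match(s$chrom2, names(ref_lengths)),
                                 s$pos2, s$pos2 + 1)
    if (hi > ref_lengths[[s$chrom]]) stop("spec ", i, " exceeds chromosome end")
  }
  m <- do.call(rbind, iv)
  if (is.null(m) || nrow(m) < 2L) return(invisible(TRUE))
  o <- order(m[, 2L], m[, 3L])
  m <- m[o, , drop = FALSE]
  same <- m[-nrow(m), 2L] == m[-1L, 2L]
  clash <- same & (m[-1L, 3L] < m[-nrow(m), 4L])
  if (any(clash)) {
    k <- which(clash)[1L]
    stop("overlapping SV specs: rows ", m[k, 1L], " and ", m[k + 1L, 1L])
  }
  invisible(TRUE)
}

#' Sample mate pairs from a donor genome with truth-coordinate placement
#'
#' Draws fragments uniformly from the donor, with fragment (outer insert)
#' length Normal(`insert_mean`, `insert_sd`) truncated at `2*read_len`, and
#' reports each read at its exact reference-coordinate mapping derived from
#' the donor's block provenance — no aligner involved. Pairs spanning a
#' rearrangement junction therefore exhibit the canonical discordant
#' signatures. Reads that would cross a junction within the read itself
#' (split-read territory) or fall in novel insertion sequence are resampled.
#' Output is a coordinate-sorted SAM with correct FLAG/RNEXT/PNEXT/TLEN.
#'
#' @param sim An `sv_simulation` from [apply_svs()].
#' @param coverage Target mean sequence coverage (fold).
#' @param insert_mean,insert_sd Outer insert size distribution (bp).
#' @param read_len Read length (bp).
#' @param orientation `"FR"` (paired-end) or `"RF"` (mate-pair): the
#'   orientation a concordant pair presents in coordinate order.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param sam_path Output SAM path.
#' @param emit_seq If `FALSE`, SEQ/QUAL are written as `*` (much faster for
#'   large runs where base-level sequence is not needed).
#' @return Invisibly, list with `sam`, `pairs` (per-pair truth/provenance
#'   table with reference placements and a `spanning` flag) and `n_pairs`.
#' @export
sample_pairs <- function(sim, coverage = 30, insert_mean = 3000, insert_sd = 300,
                         read_len = 50, orientation = c("RF", "FR"),
                         error_rate = 0.005, seed = 1L,
                         sam_path = tempfile(fileext = ".sam"),
                         emit_seq = TRUE) {
  stopifnot(inherits(sim, "sv_simulation"))
  orientation <- match.arg(orientation)
  if (insert_mean <= 2 * read_len) stop("insert_mean must exceed 2*read_len")
  stopifnot_scalar_num(coverage, "coverage", min = 1e-9)
  set.seed(seed)

  rl <- as.integer(read_len)
  per_chrom <- lapply(names(sim$donor), function(dc) {
    b <- sim$blocks[[dc]]
    dlen <- b$donor_end[nrow(b)]
    nfrag <- as.integer(round(coverage * dlen / (2 * rl)))
    if (nfrag < 1L) return(NULL)
    dstart <- b$donor_start

    draw <- function(n) {
      fl <- pmax(2L * rl, as.integer(round(stats::rnorm(n, insert_mean, insert_sd))))
      fl <- pmin(fl, dlen)
      st <- as.integer(floor(stats::runif(n) * (dlen - fl + 1)))
      list(st = st, fl = fl)
    }
    d <- draw(nfrag)
    st <- d$st; fl <- d$fl
    ok <- rep(FALSE, nfrag)
    blkA <- blkB <- integer(nfrag)
    for (try in 1:25) {
      idx <- which(!ok)
      if (!length(idx)) break
      a <- findInterval(st[idx], dstart)
      bb <- findInterval(st[idx] + fl[idx] - 1L, dstart)
      valid <- st[idx] + rl <= b$donor_end[a] &
        st[idx] + fl[idx] - rl >= b$donor_start[bb] &
        is.na(b$novel[a]) & is.na(b$novel[bb])
      blkA[idx[valid]] <- a[valid]; blkB[idx[valid]] <- bb[valid]
      ok[idx[valid]] <- TRUE
      bad <- idx[!valid]
      if (length(bad)) { r <- draw(length(bad)); st[bad] <- r$st; fl[bad] <- r$fl }
    }
    keep <- ok
    st <- st[keep]; fl <- fl[keep]; blkA <- blkA[keep]; blkB <- blkB[keep]

    map_read <- function(s, blk) {
      # donor interval [s, s+rl) inside block blk -> reference pos, flip flag
      plus <- b$strand[blk] == "+"
      refpos <- ifelse(plus, b$ref_start[blk] + (s - b$donor_start[blk]),
                       b$ref_end[blk] - (s + rl - b$donor_start[blk]))
      list(chrom = b$ref_chrom[blk], pos = as.integer(refpos), flip = !plus)
    }
    sA <- if (orientation == "FR") "+" else "-"
    sB <- if (orientation == "FR") "-" else "+"
    mA <- map_read(st, blkA)
    mB <- map_read(st + fl - rl, blkB)
    flip_strand <- function(s, flip) ifelse(flip, ifelse(s == "+", "-", "+"), s)
    data.frame(donor_chrom = dc, frag_start = st, frag_len = fl,
               spanning = blkA != blkB,
               chromA = mA$chrom, posA = mA$pos, strandA = flip_strand(sA, mA$flip),
               chromB = mB$chrom, posB = mB$pos, strandB = flip_strand(sB, mB$flip),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, per_chrom)
  n <- nrow(pairs)
  pairs$qname <- sprintf("p%07d", seq_len(n))

  contigs <- names(sim$ref_lengths)
  reads <- data.frame(
    qname = rep(pairs$qname, 2L),
    first = rep(c(TRUE, FALSE), each = n),
    chrom = c(pairs$chromA, pairs$chromB),
    pos = c(pairs$posA, pairs$posB),
    strand = c(pairs$strandA, pairs$strandB),
    mchrom = c(pairs$chromB, pairs$chromA),
    mpos = c(pairs$posB, pairs$posA),
    mstrand = c(pairs$strandB, pairs$strandA),
    stringsAsFactors = FALSE)

  if (emit_seq) {
    seq_chr <- character(nrow(reads))
    for (ch in unique(reads$chrom)) {
      idx <- which(reads$chrom == ch)
      s <- Biostrings::extractAt(sim$ref_seqs[[ch]],
                                 IRanges::IRanges(reads$pos[idx] + 1L, width = rl))
      seq_chr[idx] <- as.character(s)
    }
    if (error_rate > 0) {
      nb <- nrow(reads) * rl
      nerr <- stats::rbinom(1L, nb, error_rate)
      if (nerr > 0L) {
        posg <- sample.int(nb, nerr)
        ri <- (posg - 1L) %/% rl + 1L
        off <- (posg - 1L) %% rl + 1L
        bases <- c("A", "C", "G", "T")
        while (length(ri)) {
          d <- !duplicated(ri)
          i <- ri[d]; o <- off[d]
          old <- substr(seq_chr[i], o, o)
          new <- sample(bases, length(i), replace = TRUE)
          redo <- new == old
          while (any(redo)) {
            new[redo] <- sample(bases, sum(redo), replace = TRUE)
            redo <- new == old
          }
          x <- seq_chr[i]; substr(x, o, o) <- new; seq_chr[i] <- x
          ri <- ri[!d]; off <- off[!d]
        }
      }
    }
    reads$seq <- seq_chr
    reads$qual <- strrep("I", rl)
  } else {
    reads$seq <- "*"; reads$qual <- "*"
  }

  flag <- 1L + ifelse(reads$first, 64L, 128L) +
    ifelse(reads$strand == "-", 16L, 0L) + ifelse(reads$mstrand == "-", 32L, 0L)
  same <- reads$chrom == reads$mchrom
  outer <- pmax(reads$pos, reads$mpos) + rl - pmin(reads$pos, reads$mpos)
  tlen <- ifelse(!same, 0L,
                 ifelse(reads$pos < reads$mpos |
                          (reads$pos == reads$mpos & reads$first),
                        outer, -outer))
  lines <- paste(reads$qname, flag, reads$chrom, reads$pos + 1L, 60L,
                 paste0(rl, "M"), ifelse(same, "=", reads$mchrom),
                 reads$mpos + 1L, tlen, reads$seq, reads$qual, sep = "\t")
  o <- order(chrom_rank(reads$chrom, contigs), reads$pos)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", contigs, "\tLN:", unname(sim$ref_lengths)))
  writeLines(c(hdr, lines[o]), sam_path)
  invisible(list(sam = sam_path, pairs = pairs, n_pairs = n))
}

#' Default simulation scenario
#'
#' Two 2-Mb chromosomes carrying 2 deletions, 1 tandem duplication,
#' 1 inversion (5-20 kb each) and 1 reciprocal translocation, sequenced at
#' 30x as an RF mate-pair library with 3000 +/- 300 bp inserts, 50 bp reads
#' and 0.5% substitution error.
#' @return A scenario list consumed by [simulate_run()].
#' @export
default_scenario <- function() {
  list(
    lengths = c(chr1 = 2000000L, chr2 = 2000000L),
    specs = data.frame(
      svtype = c("DEL", "DUP", "DEL", "INV", "TRA"),
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr1"),
      pos = c(300000L, 600000L, 1200000L, 500000L, 1700000L),
      length = c(10000L, 10000L, 8000L, 12000L, NA),
      chrom2 = c(NA, NA, NA, NA, "chr2"),
      pos2 = c(NA, NA, NA, NA, 1500000L),
      copies = c(NA, 1L, NA, NA, NA),
      stringsAsFactors = FALSE),
    coverage = 30, insert_mean = 3000, insert_sd = 300, read_len = 50,
    orientation = "RF", error_rate = 0.005)
}

#' Scaled-down simulation scenario
#'
#' Same SV types, sizes, coverage and library as [default_scenario()] on two
#' 400-kb chromosomes; used for replicate studies where many independent
#' simulations are run.
#' @return A scenario list consumed by [simulate_run()].
#' @export
scaled_scenario <- function() {
  list(
    lengths = c(chr1 = 400000L, chr2 = 400000L),
    specs = data.frame(
      svtype = c("DEL", "DUP", "DEL", "INV", "TRA"),
      chrom = c("chr1", "chr1", "chr2", "chr2", "chr1"),
      pos = c(60000L, 150000L, 80000L, 200000L, 300000L),
      length = c(8000L, 10000L, 6000L, 8000L, NA),
      chrom2 = c(NA, NA, NA, NA, "chr2"),
      pos2 = c(NA, NA, NA, NA, 320000L),
      copies = c(NA, 1L, NA, NA, NA),
      stringsAsFactors = FALSE),
    coverage = 30, insert_mean = 3000, insert_sd = 300, read_len = 50,
    orientation = "RF", error_rate = 0.005)
}

#' Run a complete simulation scenario
#'
#' Builds the reference, applies the SV specs, samples reads and writes the
#' SAM plus truth outputs (BEDPE of breakpoints and a JSON manifest).
#'
#' @param scenario A list as returned by [default_scenario()].
#' @param seed Integer seed (drives reference, donor and read sampling).
#' @param dir Output directory.
#' @param emit_seq Passed to [sample_pairs()].
#' @return List with `fasta`, `sam`, `truth_bedpe`, `manifest_json`, `sim`
#'   (the `sv_simulation`), and the read-pair provenance table.
#' @export
simulate_run <- function(scenario = default_scenario(), seed = 1L,
                         dir = tempfile("simrun"), emit_seq = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(scenario$lengths, seed = seed,
                        path = file.path(dir, "reference.fa"))
  sim <- apply_svs(ref, scenario$specs, seed = seed + 1L)
  sp <- sample_pairs(sim, coverage = scenario$coverage,
                     insert_mean = scenario$insert_mean,
                     insert_sd = scenario$insert_sd,
                     read_len = scenario$read_len,
                     orientation = scenario$orientation,
                     error_rate = scenario$error_rate,
                     seed = seed + 2L,
                     sam_path = file.path(dir, "sample.sam"),
                     emit_seq = emit_seq)
  bedpe <- file.path(dir, "truth.bedpe")
  man <- file.path(dir, "truth.json")
  write_truth_bedpe(sim$manifest, bedpe)
  jsonlite::write_json(sim$manifest, man, auto_unbox = TRUE, digits = NA)
  invisible(list(fasta = ref$fasta, sam = sp$sam, truth_bedpe = bedpe,
                 manifest_json = man, sim = sim, pairs = sp$pairs,
                 n_pairs = sp$n_pairs, scenario = scenario))
}

#' Convert a simulated SAM to paired FASTQ
#'
#' Optional emitter for full-stack tests through a real aligner: recovers
#' the original read sequences (reverse-complementing reverse-strand
#' alignments) and writes `<prefix>_1.fastq` / `<prefix>_2.fastq`. The SAM
#' must carry sequences (`emit_seq = TRUE`).
#'
#' @param sam_path SAM produced by [sample_pairs()].
#' @param prefix Output path prefix.
#' @return Character vector of the two FASTQ paths, invisibly.
#' @export
sam_to_fastq <- function(sam_path, prefix) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  seq <- vapply(f, `[[`, "", 10L)
  qual <- vapply(f, `[[`, "", 11L)
  if (any(seq == "*"))
    stop("SAM has no sequences; simulate with emit_seq = TRUE")
  rev <- bitwAnd(flag, 16L) != 0L
  seq[rev] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq[rev])))
  qual[rev] <- vapply(lapply(strsplit(qual[rev], NULL), rev), paste,
                      "", collapse = "")
  first <- bitwAnd(flag, 64L) != 0L
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (k in 1:2) {
    sel <- if (k == 1L) first else !first
    o <- order(qname[sel])
    writeLines(paste0("@", qname[sel][o], "/", k, "\n", seq[sel][o],
                      "\n+\n", qual[sel][o]),
               paths[k])
  }
  invisible(paths)
}

#' Write a truth manifest as BEDPE
#' @param manifest Manifest list from [apply_svs()].
#' @param path Output path.
#' @export
write_truth_bedpe <- function(manifest, path) {
  rows <- vapply(seq_along(manifest), function(i) {
    m <- manifest[[i]]
    paste(m$chrom1, m$bp1, m$bp1 + 1L, m$chrom2, m$bp2, m$bp2 + 1L,
          paste0(tolower(m$svtype), i), m$svtype, sep = "\t")
  }, character(1L))
  writeLines(rows, path)
  invisible(path)
}
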