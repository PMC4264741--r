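# Internal helpers shared across modules. Coordinates are 0-based,
# half-open everywhere inside the package; 1-based only when printing VCF.

# Orientation of a pair given the strands of the leftmost and rightmost read
# (coordinate order). "FR" = innie (paired-end), "RF" = outie (mate-pair),
# "FF"/"RR" = same strand.
pair_orientation <- function(strand_left, strand_right) {
  out <- rep(NA_character_, length(strand_left))
  out[strand_left == "+" & strand_right == "-"] <- "FR"
  out[strand_left == "-" & strand_right == "+"] <- "RF"
  out[strand_left == "+" & strand_right == "+"] <- "FF"
  out[strand_left == "-" & strand_right == "-"] <- "RR"
  out
}

# The everted counterpart of a library's expected orientation.
everted_orientation <- function(orientation) {
  switch(orientation, FR = "RF", RF = "FR",
         stop("expected orientation must be FR or RF, got ", orientation))
}

chrom_rank <- function(chrom, contigs) {
  r <- match(chrom, contigs)
  if (anyNA(r)) {
    stop("chromosome(s) not in contig list: ",
         paste(unique(chrom[is.na(r)]), collapse = ", "))
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(name, " must be a single number >= ", min)
  }
  invisible(x)
}
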