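#' Assign a structural-variant type to each cluster
#'
#' The type follows from the read signature of the cluster's members:
#'
#' * mates on different chromosomes -> `TRA` (translocation);
#' * both mates on the same strand (FF or RR) -> `INV` (inversion);
#' * expected orientation with insert size above `median + k*sigma` ->
#'   `DEL` (deletion: the pair spans removed sequence);
#' * expected orientation with insert size below `median - k*sigma` ->
#'   `INS` (insertion shorter than the library insert);
#' * everted orientation (RF in a paired-end library, FR in a mate-pair
#'   library) -> `DUP` (tandem duplication);
#' * anything else -> `COMPLEX`.
#'
#' Signatures are defined relative to the library's expected orientation,
#' so paired-end (FR) and mate-pair (RF) libraries yield identical calls on
#' the same variants.
#'
#' @param clusters An `sv_clusters` data.frame.
#' @param model An `insert_size_model` (expected orientation, median, sigma
#'   and multiplier k).
#' @return `clusters` with an added `svtype` column (one of DEL, DUP, INV,
#'   INS, TRA, COMPLEX).
#' @export
assign_types <- function(clusters, model) {
  stopifnot(inherits(model, "insert_size_model"))
  exp_o <- model$expected_orientation
  ev_o <- everted_orientation(exp_o)
  hi <- model$median_is + model$k_discordant * model$sigma_is
  lo <- model$median_is - model$k_discordant * model$sigma_is
  svtype <- rep("COMPLEX", nrow(clusters))
  inter <- clusters$chrom1 != clusters$chrom2
  samestrand <- !inter & clusters$strand1 == clusters$strand2
  expected <- !inter & !samestrand & clusters$orientation == exp_o
  everted <- !inter & !samestrand & clusters$orientation == ev_o
  svtype[inter] <- "TRA"
  svtype[samestrand] <- "INV"
  svtype[expected & clusters$mu_is > hi] <- "DEL"
  svtype[expected & clusters$mu_is < lo] <- "INS"
  svtype[everted] <- "DUP"
  clusters$svtype <- svtype
  clusters
}

#' Type a single cluster
#' @param cluster One-row `sv_clusters` data.frame or equivalent list.
#' @param model An `insert_size_model`.
#' @return The SV type as a string.
#' @export
assign_type <- function(cluster, model) {
  assign_types(as.data.frame(cluster, stringsAsFactors = FALSE), model)$svtype[1L]
}
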