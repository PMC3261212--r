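#' Assembly parameters for fingerprint contig building
#'
#' Presets follow the published build schedules. AFLP mode: band tolerance 5
#' (0.5 bp), gel length 5501 distinct mobilities for the 100.0-650.0 bp
#' window, build cut-off 1e-09, DQ resplit steps 1e-10/1e-11/1e-12 and
#' end-merge rounds at 1e-08 then 1e-07. WGP mode: tolerance 0 (exact tag-ID
#' matches), gel length 53706 (pseudo-ID range 1000-54705), build cut-off
#' 1e-21, DQ steps 1e-24/1e-27/1e-30 and merges at 1e-21 then 1e-18. Both
#' maps convert aligned consensus bands to length with 3477 bp per band.
#'
#' @param mode `"aflp"` or `"wgp"`; sets all defaults.
#' @param tolerance integer band-matching tolerance (mobility units).
#' @param gel_length number of distinct mobility values.
#' @param build_cutoff Sulston probability threshold for joining clones.
#' @param dq_cutoffs stricter thresholds for resplitting Q-rich contigs.
#' @param dq_max_q maximum tolerated questionable clones per contig.
#' @param merge_cutoffs relaxed thresholds for end-to-end merging.
#' @param min_merge_shared minimum significant clone pairs to merge contigs.
#' @param bp_per_band genome base pairs represented per consensus band.
#' @param haploid_genome_mb haploid genome size in Mb.
#' @param q_threshold flag a clone questionable when less than this fraction
#'   of its bands agrees with the contig consensus.
#' @param end_depth clones within this offset distance (band units) of a
#'   contig end participate in end-to-end merging.
#' @return a list of class `assembly_params`
#' @export
assembly_params <- function(mode = c("aflp", "wgp"),
                            tolerance = NULL, gel_length = NULL,
                            build_cutoff = NULL, dq_cutoffs = NULL,
                            dq_max_q = 5L, merge_cutoffs = NULL,
                            min_merge_shared = 2L, bp_per_band = 3477,
                            haploid_genome_mb = 850,
                            q_threshold = 0.5, end_depth = 45L) {
  mode <- match.arg(mode)
  if (mode == "aflp") {
    if (is.null(tolerance)) tolerance <- 5L
    if (is.null(gel_length)) gel_length <- 5501
    if (is.null(build_cutoff)) build_cutoff <- 1e-09
    if (is.null(dq_cutoffs)) dq_cutoffs <- c(1e-10, 1e-11, 1e-12)
    if (is.null(merge_cutoffs)) merge_cutoffs <- c(1e-08, 1e-07)
  } else {
    if (is.null(tolerance)) tolerance <- 0L
    if (is.null(gel_length)) gel_length <- 54705 - 1000 + 1
    if (is.null(build_cutoff)) build_cutoff <- 1e-21
    if (is.null(dq_cutoffs)) dq_cutoffs <- c(1e-24, 1e-27, 1e-30)
    if (is.null(merge_cutoffs)) merge_cutoffs <- c(1e-21, 1e-18)
  }
  stopifnot(all(dq_cutoffs < build_cutoff),
            all(merge_cutoffs >= build_cutoff),
            bp_per_band > 0, tolerance >= 0)
  structure(list(mode = mode, tolerance = as.integer(tolerance),
                 gel_length = gel_length, build_cutoff = build_cutoff,
                 dq_cutoffs = sort(dq_cutoffs, decreasing = TRUE),
                 dq_max_q = as.integer(dq_max_q),
                 merge_cutoffs = merge_cutoffs,
                 min_merge_shared = as.integer(min_merge_shared),
                 bp_per_band = bp_per_band,
                 haploid_genome_mb = haploid_genome_mb,
                 q_threshold = q_threshold,
                 end_depth = as.integer(end_depth)),
            class = "assembly_params")
}

#' Sulston probability score of a fingerprint overlap
#'
#' Counts shared bands `m` by greedy one-to-one matching of the sorted band
#' lists within the tolerance, then scores the probability that at least `m`
#' of the smaller fingerprint's `nL` bands would coincide by chance with the
#' larger fingerprint (`nH` bands). The per-band chance-match probability is
#' `p = (2t+1)/GL`, the any-match probability `q = 1-(1-p)^nH`, and
#' `S = P(Binom(nL, q) >= m)`. Low scores are evidence of genuine overlap;
#' an empty fingerprint yields `S = 1` (no evidence).
#'
#' @param f1,f2 integer band vectors (mobility units; need not be sorted).
#' @param params an [assembly_params]
#' @return list of class `overlap_result` with `m`, `nL`, `nH`, `p`, `q`, `S`
#' @export
sulston_score <- function(f1, f2, params = assembly_params("aflp")) {
  f1 <- sort(as.integer(f1)); f2 <- sort(as.integer(f2))
  n1 <- length(f1); n2 <- length(f2)
  nL <- min(n1, n2); nH <- max(n1, n2)
  p <- (2 * params$tolerance + 1) / params$gel_length
  if (nL == 0L)
    return(structure(list(m = 0L, nL = nL, nH = nH, p = p, q = NA_real_,
                          S = 1), class = "overlap_result"))
  m <- match_count_cpp(f1, f2, params$tolerance)
  q <- 1 - (1 - p)^nH
  S <- stats::pbinom(m - 1, nL, q, lower.tail = FALSE)
  structure(list(m = m, nL = nL, nH = nH, p = p, q = q, S = S),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: m=%d of nL=%d (nH=%d), S=%.3g\n",
              x$m, x$nL, x$nH, x$S))
  invisible(x)
}

# All significant pairs among the fingerprints of a band_set (or plain list),
# as a data.frame of clone ids with m and S.
overlap_edges <- function(fps, params, cutoff = params$build_cutoff) {
  bl <- if (inherits(fps, "band_set")) fps$bands else fps
  ed <- overlap_edges_cpp(bl, params$tolerance, params$gel_length, cutoff)
  ids <- names(bl)
  data.frame(a = ids[ed$i], b = ids[ed$j], m = ed$m, S = ed$S,
             stringsAsFactors = FALSE)
}
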