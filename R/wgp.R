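#' Assign pseudo band mobility IDs to WGP sequence tags
#'
#' Sequence tags are opaque identifiers; for fingerprint alignment each tag
#' is mapped to an integer pseudo-mobility ID drawn from `id_range`, with
#' each ID handed out to at most `tags_per_id` tags (different tags sharing
#' an ID produce rare spurious matches, which is tolerated). If the range's
#' capacity `tags_per_id * |id_range|` is exceeded, the excess tags receive
#' overflow IDs just above the range and are reported rather than dropped.
#'
#' @param tags vector of tag identifiers (character or integer)
#' @param id_range inclusive pseudo-ID range (default 1000-54705)
#' @param tags_per_id maximum tags per ID (default 6)
#' @param seed RNG seed
#' @return object of class `tag_universe`: list with `map` (named integer
#'   vector tag -> pseudo ID), `id_range`, `overflow` (tags given IDs above
#'   the range)
#' @export
assign_pseudo_ids <- function(tags, id_range = c(1000L, 54705L),
                              tags_per_id = 6L, seed = 1L) {
  tags <- as.character(tags)
  if (anyDuplicated(tags)) stop("tags must be unique")
  set.seed(seed)
  n <- length(tags)
  range_n <- id_range[2L] - id_range[1L] + 1L
  # IDs are shared between tags only when the range forces it: one tag per
  # ID while n <= |range|, then even packing up to tags_per_id, then
  # overflow IDs just above the range
  n_in <- min(n, range_n * tags_per_id)
  ids <- if (n <= range_n)
    sample(seq.int(id_range[1L], id_range[2L]), n)
  else sample(seq.int(id_range[1L], id_range[2L]), range_n)
  per_id <- ceiling(n_in / length(ids))
  slots <- rep(ids, each = per_id)[seq_len(n_in)]
  if (n > n_in) {
    n_over_ids <- ceiling((n - n_in) / tags_per_id)
    over_ids <- seq.int(id_range[2L] + 1L, id_range[2L] + n_over_ids)
    slots <- c(slots, rep(over_ids, each = tags_per_id)[seq_len(n - n_in)])
  }
  perm <- sample.int(n)
  assigned <- integer(n)
  assigned[perm] <- slots
  overflow <- tags[assigned > id_range[2L]]
  structure(list(map = stats::setNames(assigned, tags),
                 id_range = id_range, tags_per_id = tags_per_id,
                 overflow = overflow),
            class = "tag_universe")
}

#' @export
print.tag_universe <- function(x, ...) {
  cat(sprintf("tag_universe: %d tags -> IDs %d-%d (%d overflow)\n",
              length(x$map), x$id_range[1L], x$id_range[2L],
              length(x$overflow)))
  invisible(x)
}

#' Convert clone tag sets to WGP pseudo-band fingerprints
#'
#' @param clone_tag_sets named list: clone id -> vector of tags
#' @param universe a [assign_pseudo_ids()] result
#' @return a [band_set] of sorted unique pseudo-IDs, suitable for assembly
#'   with `assembly_params("wgp")` (tolerance 0)
#' @export
tags_to_fingerprints <- function(clone_tag_sets, universe) {
  bands <- lapply(names(clone_tag_sets), function(id) {
    tg <- as.character(clone_tag_sets[[id]])
    hit <- universe$map[tg]
    if (anyNA(hit))
      stop("unknown tag '", tg[is.na(hit)][1L], "' in clone ", id)
    sort(unique(unname(hit)))
  })
  names(bands) <- names(clone_tag_sets)
  band_set(bands)
}

#' Detect chimeric WGP fingerprints in a preliminary map
#'
#' A clone is flagged chimeric when it is an articulation point of its
#' contig's overlap graph whose removal leaves at least two components of
#' three or more clones, and its band set splits over those two components
#' with little cross-matching: at least 20% of its bands match only the
#' first component, at least 20% only the second, and fewer than 10% match
#' both.
#'
#' @param map a preliminary `physical_map`
#' @return character vector of flagged clone ids
#' @export
detect_chimeras <- function(map) {
  params <- map$params
  flagged <- character()
  for (ct in map$contigs) {
    if (length(ct$members) < 7L) next
    sub <- subset_bands(map$fps, ct$members)
    ed <- overlap_edges(sub, params, params$build_cutoff)
    g <- igraph::graph_from_data_frame(
      ed[, c("a", "b")], directed = FALSE,
      vertices = data.frame(name = ct$members))
    arts <- igraph::articulation_points(g)
    for (v in igraph::as_ids(arts)) {
      g2 <- igraph::delete_vertices(g, v)
      comp <- igraph::components(g2)
      big <- which(comp$csize >= 3L)
      if (length(big) < 2L) next
      big <- big[order(-comp$csize[big])][1:2]
      bv <- map$fps$bands[[v]]
      memb <- igraph::V(g2)$name
      bands_of <- function(k)
        sort(unique(unlist(map$fps$bands[memb[comp$membership == k]])))
      m1 <- vapply(bv, function(b)
        match_count_cpp(b, bands_of(big[1L]), params$tolerance) > 0L, TRUE)
      m2 <- vapply(bv, function(b)
        match_count_cpp(b, bands_of(big[2L]), params$tolerance) > 0L, TRUE)
      fb <- mean(m1 & m2)
      if (fb < 0.1 && mean(m1 & !m2) >= 0.2 && mean(m2 & !m1) >= 0.2)
        flagged <- c(flagged, v)
    }
  }
  unique(flagged)
}

#' Copy-number spectrum of WGP tags
#'
#' Counts, for each copy number k >= 2, how many tags occur in exactly k
#' clones. Tags seen in a single clone are excluded, matching how observed
#' tag datasets are reported.
#'
#' @param clone_tag_sets named list: clone id -> vector of tags
#' @return data.frame with columns `k`, `n_tags`
#' @export
tag_spectrum <- function(clone_tag_sets) {
  counts <- table(unlist(lapply(clone_tag_sets, unique)))
  tab <- table(as.integer(counts))
  k <- as.integer(names(tab))
  keep <- k >= 2L
  data.frame(k = k[keep], n_tags = as.integer(tab)[keep])
}

#' Average genomic spacing between unique sequence tags
#'
#' @param n_tags number of unique tags
#' @param haploid_mb haploid genome size in Mb
#' @return spacing in bp, rounded to the nearest integer (850 Mb over
#'   322434 tags gives 2636 bp)
#' @export
tag_spacing_bp <- function(n_tags, haploid_mb = 850) {
  round(haploid_mb * 1e6 / n_tags)
}

#' Truncated two-Poisson mixture for tag copy numbers
#'
#' With `G` genome equivalents of template, a homozygous tag (present on
#' both haplotypes) is sampled in a Poisson(G) number of clones while a
#' heterozygous tag (one haplotype) is sampled Poisson(G/2). The copy-number
#' pmf is `w Pois(k; G/2) + (1-w) Pois(k; G)` renormalised over the
#' truncated support `k >= 2` (singleton tags are excluded from observed
#' spectra). A het:hom ratio of 1.2:1 corresponds to `w = 1.2/2.2 = 0.545`.
#'
#' @param k copy numbers (integer, all `>= truncation_min`)
#' @param G genome equivalents of template DNA
#' @param w heterozygous tag fraction in `[0, 1]`
#' @param truncation_min lower truncation (default 2)
#' @param kmax support cap for normalisation (default 200)
#' @return pmf values at `k`
#' @export
mixture_pmf <- function(k, G, w, truncation_min = 2L, kmax = 200L) {
  stopifnot(G > 0, w >= 0, w <= 1, all(k >= truncation_min))
  supp <- seq.int(truncation_min, kmax)
  dens <- function(x) w * stats::dpois(x, G / 2) +
    (1 - w) * stats::dpois(x, G)
  dens(k) / sum(dens(supp))
}

#' Mode of the truncated mixture
#' @inheritParams mixture_pmf
#' @return integer copy number maximising the pmf
#' @export
mixture_mode <- function(G, w, truncation_min = 2L, kmax = 200L) {
  supp <- seq.int(truncation_min, kmax)
  supp[which.max(mixture_pmf(supp, G, w, truncation_min, kmax))]
}

#' Fit the truncated two-Poisson mixture to a tag spectrum
#'
#' Maximum likelihood on the truncated support (`k >= 2`), optimising over
#' `(G, w)` with `optim`. Invariance to scaling of the histogram counts
#' follows from the multinomial likelihood.
#'
#' @param spectrum data.frame with columns `k`, `n_tags` (a [tag_spectrum()])
#' @param truncation_min,kmax truncation and support cap
#' @return list with `G`, `w`, `logLik`
#' @export
fit_mixture <- function(spectrum, truncation_min = 2L, kmax = 200L) {
  stopifnot(nrow(spectrum) > 0, all(spectrum$k >= truncation_min))
  k <- spectrum$k; n <- spectrum$n_tags
  nll <- function(par) {
    G <- exp(par[1L]); w <- stats::plogis(par[2L])
    -sum(n * log(mixture_pmf(k, G, w, truncation_min, kmax) + 1e-300))
  }
  mean_k <- sum(k * n) / sum(n)
  fit <- stats::optim(c(log(mean_k * 1.3), 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("mixture fit did not converge: code ", fit$convergence)
  list(G = exp(fit$par[1L]), w = stats::plogis(fit$par[2L]),
       logLik = -fit$value)
}
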