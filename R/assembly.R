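# Contig building: single-linkage components at the Sulston cut-off, greedy
# seriation for clone order, consensus bands (CB) by transitive band matching
# (union-find), Q-clone flagging, DQ resplitting and end-to-end merging.

# Assemble one connected set of clone ids into a contig object given the
# significant edges among them.
contig_from_component <- function(ids, fps, edges, params) {
  bl <- fps$bands[ids]
  nb <- lengths(bl)
  n <- length(ids)
  ea <- match(edges$a, ids); eb <- match(edges$b, ids)
  eord <- order(edges$S, edges$a, edges$b)
  ea <- ea[eord]; eb <- eb[eord]; em <- edges$m[eord]
  # --- ordering: greedy seriation -----------------------------------------
  offsets <- rep(NA_integer_, n)
  if (length(ea)) {
    offsets[ea[1L]] <- 0L
    offsets[eb[1L]] <- max(0L, min(nb[ea[1L]], nb[eb[1L]]) - em[1L])
    repeat {
      placed <- !is.na(offsets)
      front <- which(xor(placed[ea], placed[eb]))
      if (!length(front)) break
      r <- front[1L]
      from <- if (placed[ea[r]]) ea[r] else eb[r]
      to <- if (placed[ea[r]]) eb[r] else ea[r]
      offsets[to] <- offsets[from] + max(0L, min(nb[from], nb[to]) - em[r])
    }
  }
  offsets[is.na(offsets)] <- 0L
  names(offsets) <- ids
  # --- consensus bands via constrained union-find (see cb_clusters_cpp):
  # matched bands unite into a consensus cluster unless the two clusters
  # already share a clone (a consensus band appears at most once per clone)
  # or their feasible position intervals are disjoint (distinct
  # co-migrating loci), processed strongest edges first.
  cl <- cb_clusters_cpp(bl, ea, eb, params$tolerance, as.numeric(offsets), 5)
  all_mob <- unlist(bl, use.names = FALSE)
  slot_clone <- rep(seq_len(n), nb)
  clf <- factor(cl, levels = seq_len(max(cl, 1L)))
  cb_mob <- vapply(split(all_mob, clf), mean, 1)
  support <- vapply(split(slot_clone, clf), function(x) length(unique(x)), 1L)
  # --- questionable clones: poor agreement with the shared consensus ------
  base <- cumsum(c(0L, nb[-n]))
  shared_frac <- vapply(seq_len(n), function(i) {
    if (!nb[i]) return(0)
    sl <- cl[seq.int(base[i] + 1L, base[i] + nb[i])]
    mean(support[sl] >= 2L)
  }, 1)
  q_clones <- ids[shared_frac < params$q_threshold]
  ord <- order(offsets, ids)
  list(members = ids[ord], offsets = offsets[ord],
       cb = list(mobility = unname(cb_mob), support = unname(support)),
       cb_length = max(cl), q_clones = q_clones)
}

# Cluster a set of fingerprints at a cut-off; returns contigs (>= 2 members)
# and singleton ids.
assemble_components <- function(ids, fps, params, cutoff) {
  sub <- subset_bands(fps, sort(ids))
  ed <- overlap_edges(sub, params, cutoff)
  g <- igraph::graph_from_data_frame(
    ed[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = names(sub$bands)))
  comp <- igraph::components(g)$membership
  contigs <- list(); singletons <- character()
  for (cid in seq_len(max(comp))) {
    mem <- names(comp)[comp == cid]
    if (length(mem) < 2L) { singletons <- c(singletons, mem); next }
    sube <- ed[ed$a %in% mem & ed$b %in% mem, , drop = FALSE]
    contigs[[length(contigs) + 1L]] <-
      contig_from_component(sort(mem), fps, sube, params)
  }
  list(contigs = contigs, singletons = singletons)
}

renumber_map <- function(map) {
  if (length(map$contigs)) {
    sz <- vapply(map$contigs, function(x) length(x$members), 1L)
    first <- vapply(map$contigs, function(x) x$members[1L], "")
    ord <- order(-sz, first)
    map$contigs <- map$contigs[ord]
    for (i in seq_along(map$contigs)) map$contigs[[i]]$id <- i
  }
  map$singletons <- sort(map$singletons)
  map
}

#' Build a physical map from fingerprints
#'
#' Clones are joined when their Sulston score is at or below the build
#' cut-off; contigs are the connected components of the resulting overlap
#' graph. Within each contig, clones are ordered by greedy seriation (seeded
#' at the best-scoring pair, extended by the strongest remaining overlap,
#' with the extending clone placed `nL - m` band units beyond its anchor) and
#' a consensus band (CB) set is derived by transitive band matching. Clones
#' whose bands agree poorly with the shared consensus are flagged
#' questionable (Q).
#'
#' @param fps a [band_set] of QC-passed fingerprints
#' @param params an [assembly_params]
#' @return an object of class `physical_map` with elements `contigs`,
#'   `singletons`, `fps`, `params`.
#' @export
build_contigs <- function(fps, params = assembly_params("aflp")) {
  res <- assemble_components(names(fps$bands), fps, params,
                             params$build_cutoff)
  map <- structure(list(contigs = res$contigs, singletons = res$singletons,
                        fps = fps, params = params),
                   class = "physical_map")
  renumber_map(map)
}

#' @export
print.physical_map <- function(x, ...) {
  st <- map_stats(x)
  cat(sprintf(paste0("physical_map (%s): %d contigs (%d clones), %d ",
                     "singletons, total %.0f Mb\n"),
              x$params$mode, st$n_contigs, st$n_clones_in_contigs,
              st$n_singletons, st$total_mb))
  invisible(x)
}

#' Questionable clones of a contig
#'
#' A clone is questionable when fewer than the `q_threshold` fraction of its
#' bands fall in consensus-band clusters supported by at least one other
#' clone, i.e. its fingerprint shows friction against the contig consensus.
#'
#' @param contig a contig element of a `physical_map`
#' @return character vector of Q clone ids
#' @export
identify_questionable <- function(contig) contig$q_clones

#' Resplit questionable-clone-rich contigs at stricter cut-offs
#'
#' Every contig carrying more than `dq_max_q` Q clones is dissolved and its
#' members re-assembled at the next stricter cut-off in `dq_cutoffs`;
#' the schedule is applied in order and contigs that still fail after the
#' last step are left as they are, keeping their Q flags.
#'
#' @param map a `physical_map`
#' @return a `physical_map`
#' @export
dq_resplit <- function(map) {
  params <- map$params
  for (co in params$dq_cutoffs) {
    nq <- vapply(map$contigs, function(x) length(x$q_clones), 1L)
    bad <- which(nq > params$dq_max_q)
    if (!length(bad)) break
    keep <- map$contigs[setdiff(seq_along(map$contigs), bad)]
    for (i in bad) {
      res <- assemble_components(map$contigs[[i]]$members, map$fps, params, co)
      keep <- c(keep, res$contigs)
      map$singletons <- c(map$singletons, res$singletons)
    }
    map$contigs <- keep
  }
  renumber_map(map)
}

# end-region clones of a contig: within end_depth band units of either end
end_clones <- function(contig, end_depth, nb) {
  off <- contig$offsets
  span_hi <- max(off + nb[contig$members])
  contig$members[off <= min(off) + end_depth |
                 (off + nb[contig$members]) >= span_hi - end_depth]
}

#' End-to-end merging of contigs at relaxed cut-offs
#'
#' Two contigs merge when at least `min_merge_shared` clone pairs between
#' their end regions score at or below the merge cut-off. Merging is
#' transitive within a round; the rounds use `merge_cutoffs` in order. Merged
#' contigs are re-assembled (order and consensus bands) at the round's
#' cut-off.
#'
#' @param map a `physical_map`
#' @return a `physical_map` with the same clones; the contig count never
#'   increases.
#' @export
end_merge <- function(map) {
  params <- map$params
  nb <- lengths(map$fps$bands)
  for (co in params$merge_cutoffs) {
    if (length(map$contigs) < 2L) break
    ends <- lapply(map$contigs, end_clones, end_depth = params$end_depth,
                   nb = nb)
    all_end <- unique(unlist(ends))
    contig_of <- stats::setNames(
      rep(seq_along(map$contigs), lengths(ends)), unlist(ends))
    ed <- overlap_edges(subset_bands(map$fps, sort(all_end)), params, co)
    if (!nrow(ed)) next
    ca <- contig_of[ed$a]; cb <- contig_of[ed$b]
    cross <- which(ca != cb)
    if (!length(cross)) next
    pair_key <- paste(pmin(ca[cross], cb[cross]), pmax(ca[cross], cb[cross]))
    tab <- table(pair_key)
    good <- names(tab)[tab >= params$min_merge_shared]
    if (!length(good)) next
    pk <- do.call(rbind, strsplit(good, " "))
    g <- igraph::graph_from_data_frame(
      data.frame(a = pk[, 1L], b = pk[, 2L]), directed = FALSE,
      vertices = data.frame(name = as.character(seq_along(map$contigs))))
    comp <- igraph::components(g)$membership
    new_contigs <- list()
    for (grp in unique(comp)) {
      idx <- as.integer(names(comp)[comp == grp])
      if (length(idx) == 1L) {
        new_contigs[[length(new_contigs) + 1L]] <- map$contigs[[idx]]
      } else {
        mem <- unlist(lapply(map$contigs[idx], `[[`, "members"))
        res <- assemble_components(mem, map$fps, params, co)
        # members stay together by construction (linked through the merge
        # edges), but guard against pathological splits
        new_contigs <- c(new_contigs, res$contigs)
        map$singletons <- c(map$singletons, res$singletons)
      }
    }
    map$contigs <- new_contigs
  }
  renumber_map(map)
}

#' Haploid genome equivalents represented by a clone set
#'
#' `n_clones * avg_clone_kb / 1000 / haploid_mb`, rounded to one decimal:
#' e.g. 78336 clones of 127 kb over an 850 Mb genome are 11.7 g.e., and
#' 64478 fingerprints are 9.6 g.e.
#'
#' @param n_clones number of clones
#' @param avg_clone_kb average clone insert size (kb)
#' @param haploid_mb haploid genome size (Mb)
#' @return genome equivalents (1 decimal)
#' @export
genome_equivalents <- function(n_clones, avg_clone_kb = 127,
                               haploid_mb = 850) {
  round(n_clones * avg_clone_kb / 1000 / haploid_mb, 1)
}

#' Physical-map length and size statistics
#'
#' Contig length in kb is `cb_length * bp_per_band / 1000`. N50 is the
#' contig length at which the cumulative length of the sorted (descending)
#' contigs reaches half the total. Inflation is total map length over the
#' haploid genome size. The size-class histogram counts contigs by member
#' clones in the standard classes (>=400, 200-399, 100-199, 50-99, 25-49,
#' 10-24, 3-9, exactly 2).
#'
#' @param map a `physical_map`
#' @param avg_clone_kb average clone size used for the clone-coverage genome
#'   equivalents (g.e.) statistic.
#' @return list of statistics
#' @export
map_stats <- function(map, avg_clone_kb = 127) {
  params <- map$params
  cl <- vapply(map$contigs, `[[`, 1L, "cb_length")
  sizes <- vapply(map$contigs, function(x) length(x$members), 1L)
  len_kb <- cl * params$bp_per_band / 1000
  total_mb <- sum(cl) * params$bp_per_band / 1e6
  n_fp <- length(map$fps$bands)
  n50 <- if (length(len_kb)) {
    s <- sort(len_kb, decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1L]]
  } else 0
  breaks <- c(2, 3, 10, 25, 50, 100, 200, 400, Inf)
  hist <- if (length(sizes)) {
    tab <- table(cut(sizes, breaks = breaks, right = FALSE,
                     include.lowest = TRUE))
    rev(as.integer(tab))
  } else integer(8)
  names(hist) <- c(">=400", "200-399", "100-199", "50-99", "25-49",
                   "10-24", "3-9", "=2")
  nq <- vapply(map$contigs, function(x) length(x$q_clones), 1L)
  list(n_contigs = length(map$contigs),
       n_clones_in_contigs = sum(sizes),
       n_singletons = length(map$singletons),
       singleton_pct = if (n_fp) round(100 * length(map$singletons) / n_fp, 1)
                       else 0,
       n_fingerprints = n_fp,
       avg_clones_per_contig = if (length(sizes)) round(mean(sizes), 1) else 0,
       avg_kb = if (length(len_kb)) round(mean(len_kb)) else 0,
       n50_kb = round(n50),
       total_mb = round(total_mb),
       coverage_ge = genome_equivalents(n_fp, avg_clone_kb,
                                        params$haploid_genome_mb),
       inflation = round(total_mb / params$haploid_genome_mb, 2),
       n_contigs_gt5q = sum(nq > 5L),
       size_class_hist = hist)
}
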