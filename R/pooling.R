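#' Random k-sets superpool design
#'
#' Each quarter-plate pool (QPP) is assigned to a unique set of `k` of the
#' `v` superpools. With `balanced = TRUE` the k-sets are drawn greedily from
#' the least-loaded superpools (random tie-breaking), which keeps superpool
#' loads within one of each other; at the default 764 QPPs over 90
#' superpools with k = 4 every superpool receives 33 or 34 QPPs.
#'
#' @param n_qpp number of QPPs (default 764 = 191 plates x 4 quarters).
#' @param v number of superpools.
#' @param k superpools per QPP.
#' @param seed RNG seed (the design is deterministic given the seed).
#' @param balanced balance superpool loads.
#' @param qpp_ids optional ids; default `"001Q1".."191Q4"` plate-major.
#' @return object of class `pooling_design`: list with `assignment` (n x k
#'   integer matrix, rows named by QPP id), `v`, `k`.
#' @export
generate_design <- function(n_qpp = 764L, v = 90L, k = 4L, seed = 1L,
                            balanced = TRUE, qpp_ids = NULL) {
  n_qpp <- as.integer(n_qpp); v <- as.integer(v); k <- as.integer(k)
  if (choose(v, k) < n_qpp)
    stop("infeasible design: choose(v, k) < n_qpp")
  if (is.null(qpp_ids)) {
    qpp_ids <- as.vector(t(outer(seq_len(ceiling(n_qpp / 4)), 1:4,
                                 function(p, q) sprintf("%03dQ%d", p, q))))
    qpp_ids <- qpp_ids[seq_len(n_qpp)]
  }
  stopifnot(length(qpp_ids) == n_qpp, !anyDuplicated(qpp_ids))
  set.seed(seed)
  asg <- matrix(0L, n_qpp, k, dimnames = list(qpp_ids, NULL))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  load <- rep(0L, v)
  for (i in seq_len(n_qpp)) {
    for (attempt in 1:100) {
      kset <- if (balanced) {
        ord <- order(load, stats::runif(v))
        sort(ord[seq_len(k)])
      } else sort(sample.int(v, k))
      key <- paste(kset, collapse = ",")
      if (is.null(seen[[key]])) { seen[[key]] <- TRUE; break }
      if (attempt == 100) stop("could not draw a distinct k-set")
    }
    asg[i, ] <- kset
    load[kset] <- load[kset] + 1L
  }
  structure(list(assignment = asg, v = v, k = k, qpp_ids = qpp_ids),
            class = "pooling_design")
}

#' @export
print.pooling_design <- function(x, ...) {
  ld <- superpool_loads(x)
  cat(sprintf("pooling_design: %d QPPs x k=%d over v=%d superpools (loads %d-%d)\n",
              nrow(x$assignment), x$k, x$v, min(ld), max(ld)))
  invisible(x)
}

#' Superpool loads of a design
#' @param design a `pooling_design`
#' @return integer vector of length `v`: QPPs per superpool
#' @export
superpool_loads <- function(design) {
  tabulate(design$assignment, nbins = design$v)
}

#' Apply pipetting-error corrections to a design
#'
#' @param design a `pooling_design`
#' @param overrides named list `qpp_id -> corrected k-set`
#' @return corrected `pooling_design`
#' @export
apply_design_overrides <- function(design, overrides) {
  for (id in names(overrides)) {
    ks <- sort(as.integer(overrides[[id]]))
    stopifnot(length(ks) == design$k, all(ks >= 1L & ks <= design$v))
    design$assignment[id, ] <- ks
  }
  design
}

#' Deconvolute positive superpools into candidate and resolved QPPs
#'
#' Candidates are the QPPs whose whole k-set lies inside the positive
#' superpool set. A candidate is a resolved positive when it is needed to
#' explain the superpool scores, i.e. it owns a positive superpool that no
#' other candidate covers. The remaining candidates are unresolved: they may
#' be true positives or chance false positives.
#'
#' @param positive_superpools integer vector of positive superpool indices
#' @param design a `pooling_design`
#' @return list of class `deconvolution_result` with `positive_superpools`,
#'   `candidates`, `resolved`, `unresolved` (QPP ids) and `uncovered`
#'   (positive superpools not covered by any candidate).
#' @export
deconvolute <- function(positive_superpools, design) {
  pos <- sort(unique(as.integer(positive_superpools)))
  stopifnot(all(pos >= 1L & pos <= design$v))
  asg <- design$assignment
  inpos <- matrix(asg %in% pos, nrow(asg), ncol(asg))
  cand_idx <- which(rowSums(inpos) == design$k)
  cands <- rownames(asg)[cand_idx]
  resolved <- character()
  if (length(cand_idx)) {
    cover <- tabulate(asg[cand_idx, , drop = FALSE], nbins = design$v)
    private <- matrix(cover[asg[cand_idx, , drop = FALSE]] == 1L,
                      length(cand_idx), design$k)
    resolved <- cands[rowSums(private) > 0L]
  }
  covered <- if (length(cand_idx))
    sort(unique(as.vector(asg[cand_idx, , drop = FALSE]))) else integer()
  structure(list(positive_superpools = pos, candidates = cands,
                 resolved = resolved,
                 unresolved = setdiff(cands, resolved),
                 uncovered = setdiff(pos, covered)),
            class = "deconvolution_result")
}

#' Monte-Carlo performance of a pooling design
#'
#' For each marker copy number `n`, draws `reps` random sets of `n` truly
#' positive QPPs, computes the positive superpools as the union of their
#' k-sets, deconvolutes, and classifies the output against the truth.
#'
#' @param design a `pooling_design`
#' @param n_positive_range copy numbers to simulate
#' @param reps repetitions per copy number
#' @param seed RNG seed
#' @return data.frame with columns n, mean_resolved, mean_unresolved_true,
#'   mean_false_positive, mean_candidates
#' @export
simulate_performance <- function(design, n_positive_range = 2:13,
                                 reps = 1000L, seed = 1L) {
  stopifnot(reps >= 1L)
  set.seed(seed)
  ids <- rownames(design$assignment)
  out <- lapply(n_positive_range, function(n) {
    res <- matrix(0, reps, 4L)
    for (r in seq_len(reps)) {
      truth <- sample(ids, n)
      pos <- unique(as.vector(design$assignment[truth, , drop = FALSE]))
      d <- deconvolute(pos, design)
      res[r, ] <- c(length(d$resolved),
                    length(setdiff(intersect(d$candidates, truth),
                                   d$resolved)),
                    length(setdiff(d$candidates, truth)),
                    length(d$candidates))
    }
    data.frame(n = n, mean_resolved = mean(res[, 1L]),
               mean_unresolved_true = mean(res[, 2L]),
               mean_false_positive = mean(res[, 3L]),
               mean_candidates = mean(res[, 4L]))
  })
  do.call(rbind, out)
}
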