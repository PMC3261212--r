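#' Fit the radioactive-to-capillary marker size conversion
#'
#' Markers mapped on radioactive gels shift mobility on capillary gels:
#' roughly constant below ~450 bp and increasingly larger above, up to about
#' +20 bp near 600 bp. The shift is fitted as a piecewise-linear function of
#' radioactive size with a single knot at `knot` bp, by least squares on the
#' basis `{1, max(0, size - knot)}`. The residual standard deviation sets
#' the half-width of marker scoring intervals, clamped to a 0.2-0.4 bp
#' total width.
#'
#' @param pairs data.frame with columns `radioactive_bp`, `capillary_bp`
#' @param knot knot position (bp)
#' @return object of class `size_calibration`
#' @export
fit_size_conversion <- function(pairs, knot = 450) {
  stopifnot(is.data.frame(pairs),
            all(c("radioactive_bp", "capillary_bp") %in% names(pairs)))
  if (nrow(pairs) < 4L) stop("need at least 4 calibration pairs")
  if (diff(range(pairs$radioactive_bp)) < 50)
    stop("calibration pairs do not span the size range")
  shift <- pairs$capillary_bp - pairs$radioactive_bp
  x <- pmax(0, pairs$radioactive_bp - knot)
  fit <- stats::lm(shift ~ x)
  co <- stats::coef(fit)
  if (is.na(co[2L])) co[2L] <- 0
  # predicted capillary = rad + a + b*max(0, rad-knot): monotone iff 1+b >= 0
  if (1 + co[2L] < 0)
    stop("degenerate calibration: fitted conversion is non-monotone")
  rsd <- stats::sd(stats::residuals(fit))
  width <- min(max(0.2, 4 * rsd), 0.4)
  structure(list(intercept = unname(co[1L]), slope = unname(co[2L]),
                 knot = knot, residual_sd = rsd, interval_width = width,
                 n = nrow(pairs)),
            class = "size_calibration")
}

#' Predict capillary size (and scoring interval) from radioactive size
#'
#' @param object a `size_calibration`
#' @param radioactive_bp radioactive gel sizes
#' @param ... unused
#' @return data.frame with capillary_bp, interval_low, interval_high
#' @export
predict.size_calibration <- function(object, radioactive_bp, ...) {
  shift <- object$intercept +
    object$slope * pmax(0, radioactive_bp - object$knot)
  cap <- radioactive_bp + shift
  hw <- object$interval_width / 2
  data.frame(capillary_bp = cap, interval_low = cap - hw,
             interval_high = cap + hw)
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf(paste0("size_calibration: shift = %.2f + %.3f*max(0, rad-%g) bp",
                     " (resid sd %.3f, interval width %.2f bp, n=%d)\n"),
              x$intercept, x$slope, x$knot, x$residual_sd,
              x$interval_width, x$n))
  invisible(x)
}

#' Score a marker interval in the superpool bands files
#'
#' A superpool is positive when it has at least one band inside the closed
#' scoring interval. The measured marker size is the mean of all in-interval
#' band sizes over the positive superpools. A marker whose interval overlaps
#' a denser neighbouring band cluster — two or more distinct band values in
#' the interval for more than half of the positive superpools — is flagged
#' unusable.
#'
#' @param superpool_fps a [band_set] with one fingerprint per superpool
#'   (clone ids `"SP1".."SPv"` or any names; order defines superpool index).
#' @param interval_bp closed scoring interval `c(low, high)` in bp.
#' @return list with `positives` (integer superpool indices), `avg_size_bp`,
#'   `status` (`"ok"`, `"failed"` when no superpool is positive, or
#'   `"unusable"` on neighbour-band interference)
#' @export
score_marker_in_superpools <- function(superpool_fps, interval_bp) {
  stopifnot(inherits(superpool_fps, "band_set"), length(interval_bp) == 2L,
            interval_bp[1] < interval_bp[2])
  lo <- round(interval_bp[1] * 10); hi <- round(interval_bp[2] * 10)
  inb <- lapply(superpool_fps$bands, function(b) b[b >= lo & b <= hi])
  pos <- unname(which(lengths(inb) > 0L))
  if (!length(pos))
    return(list(positives = integer(), avg_size_bp = NA_real_,
                status = "failed"))
  multi <- vapply(inb[pos], function(b) length(unique(b)) >= 2L, TRUE)
  status <- if (mean(multi) > 0.5) "unusable" else "ok"
  list(positives = pos,
       avg_size_bp = mean(unlist(inb[pos])) / 10,
       status = status)
}

#' Anchor a marker to a physical-map contig (KeyMaps in-silico search)
#'
#' Given the deconvoluted candidate QPPs of a marker and its measured
#' capillary size, each contig is scored by its member clones that (a)
#' reside in a candidate QPP and (b) carry a fingerprint band within
#' `band_tol_bp` of the marker size. The marker anchors to the unique contig
#' with at least `min_clones` such positive clones; several qualifying
#' contigs give status `ambiguous`, at most one candidate QPP gives
#' `omitted_single_qpp`, and no qualifying contig gives `failed`. When the
#' anchored contig shows fewer positives than candidate QPPs, singleton
#' clones that overlap the contig (Sulston score at or below the build
#' cut-off against a member) are searched for additional positives. Markers
#' below 100 bp are matched against the unclipped fingerprints retained by
#' [preprocess()].
#'
#' @param marker_size_bp measured capillary marker size (bp)
#' @param deconv a [deconvolute()] result
#' @param map a `physical_map`
#' @param clone_qpp named character vector clone_id -> qpp id
#' @param band_tol_bp band match tolerance in bp (default 0.4)
#' @param min_clones minimum positive clones for an anchor (default 2)
#' @param marker_id optional id carried into the record
#' @return list of class `anchor_record`: marker_id, contig_id,
#'   positive_clones, n_candidate_qpps, n_matched_qpps, status
#' @export
keymaps_anchor <- function(marker_size_bp, deconv, map, clone_qpp,
                           band_tol_bp = 0.4, min_clones = 2L,
                           marker_id = NA_character_) {
  rec <- function(status, contig_id = NA_integer_, pos = character()) {
    qpps <- unique(clone_qpp[pos])
    structure(list(marker_id = marker_id, contig_id = contig_id,
                   positive_clones = pos,
                   n_candidate_qpps = length(deconv$candidates),
                   n_matched_qpps = length(qpps), status = status),
              class = "anchor_record")
  }
  if (length(deconv$candidates) <= 1L) return(rec("omitted_single_qpp"))
  tol <- as.integer(round(band_tol_bp * 10))
  target <- as.integer(round(marker_size_bp * 10))
  bands <- if (marker_size_bp < 100 && !is.null(attr(map$fps, "unclipped")))
    attr(map$fps, "unclipped") else map$fps$bands
  has_band <- function(id) {
    b <- bands[[id]]
    length(b) && any(abs(b - target) <= tol)
  }
  in_cand <- function(ids) ids[!is.na(clone_qpp[ids]) &
                               clone_qpp[ids] %in% deconv$candidates]
  nb_all <- lengths(map$fps$bands)
  pos_by_contig <- lapply(map$contigs, function(ct) {
    ids <- in_cand(ct$members)
    ids <- ids[vapply(ids, has_band, TRUE)]
    if (length(ids) < 2L) return(ids)
    # the positive clones must overlap each other (they share the marker
    # fragment): keep the largest subset whose offsets fall within one
    # clone length
    off <- sort(ct$offsets[ids])
    win <- max(nb_all[ids])
    best <- 0L; lo <- 1L; best_set <- character()
    for (j in seq_along(off)) {
      while (off[j] - off[lo] > win) lo <- lo + 1L
      if (j - lo + 1L > best) {
        best <- j - lo + 1L
        best_set <- names(off)[lo:j]
      }
    }
    best_set
  })
  npos <- lengths(pos_by_contig)
  qual <- which(npos >= min_clones)
  if (!length(qual)) return(rec("failed"))
  if (length(qual) > 1L)
    return(rec("ambiguous", qual[which.max(npos[qual])],
               pos_by_contig[[qual[which.max(npos[qual])]]]))
  best <- qual
  pos <- pos_by_contig[[best]]
  if (length(pos) < length(deconv$candidates) && length(map$singletons)) {
    extra <- in_cand(map$singletons)
    extra <- extra[vapply(extra, has_band, TRUE)]
    if (length(extra)) {
      members <- map$contigs[[best]]$members
      keep <- vapply(extra, function(s) {
        any(vapply(members, function(m)
          sulston_score(map$fps$bands[[s]], map$fps$bands[[m]],
                        map$params)$S <= map$params$build_cutoff, TRUE))
      }, TRUE)
      pos <- c(pos, extra[keep])
    }
  }
  rec("anchored", best, pos)
}

#' Validate anchors and summarise per chromosome
#'
#' Contigs carrying two or more anchors are screened for conflicts: anchors
#' whose genetic position disagrees with the contig majority — a different
#' chromosome, or more than `max_bin_distance` bins from the contig median
#' bin — are flagged invalid. Rates are reported as percentages to one
#' decimal.
#'
#' @param anchors list of `anchor_record`s
#' @param markers marker table (marker_id, chromosome, bin as columns)
#' @param map the `physical_map` the anchors refer to
#' @param max_bin_distance bin-distance threshold for conflicts (default 10)
#' @return list with `table` (data.frame per anchor), `per_chromosome`,
#'   `invalid` (marker ids), `success_rate_pct`, `error_rate_pct`
#' @export
validate_and_summarize <- function(anchors, markers, map,
                                   max_bin_distance = 10L) {
  df <- do.call(rbind, lapply(anchors, function(a)
    data.frame(marker_id = a$marker_id, contig_id = a$contig_id,
               status = a$status, n_positive = length(a$positive_clones),
               stringsAsFactors = FALSE)))
  df <- merge(df, markers[, c("marker_id", "chromosome", "bin")],
              by = "marker_id", all.x = TRUE, sort = TRUE)
  anch <- df[df$status == "anchored", , drop = FALSE]
  invalid <- character()
  for (cid in unique(anch$contig_id)) {
    rows <- anch[anch$contig_id == cid, , drop = FALSE]
    if (nrow(rows) < 2L) next
    chr_tab <- sort(table(rows$chromosome), decreasing = TRUE)
    maj_chr <- as.integer(names(chr_tab)[1L])
    bad_chr <- rows$chromosome != maj_chr
    med_bin <- stats::median(rows$bin[!bad_chr])
    bad_bin <- !bad_chr & abs(rows$bin - med_bin) > max_bin_distance
    invalid <- c(invalid, rows$marker_id[bad_chr | bad_bin])
  }
  attempted <- sum(df$status != "omitted_single_qpp")
  n_anch <- nrow(anch)
  pos_by_marker <- stats::setNames(
    lapply(anchors, `[[`, "positive_clones"),
    vapply(anchors, `[[`, "", "marker_id"))
  per_chr <- do.call(rbind, lapply(sort(unique(anch$chromosome)),
    function(ch) {
      rows <- anch$chromosome == ch
      data.frame(chromosome = ch, markers = sum(rows),
                 contigs = length(unique(anch$contig_id[rows])),
                 bacs = length(unique(unlist(
                   pos_by_marker[anch$marker_id[rows]]))))
    }))
  list(table = df, per_chromosome = per_chr, invalid = invalid,
       success_rate_pct = anchor_rate_pct(n_anch, attempted),
       error_rate_pct = anchor_rate_pct(length(invalid), n_anch))
}

#' Percentage rate rounded to one decimal
#'
#' Rate arithmetic as printed in map summaries, e.g. 50 invalid anchors out
#' of 1770 anchoring markers is 2.8 (percent), and 12781 singletons out of
#' 65919 fingerprints is 19.4.
#'
#' @param numerator,denominator counts
#' @return percentage to one decimal (0 when the denominator is 0)
#' @export
anchor_rate_pct <- function(numerator, denominator) {
  if (!denominator) return(0)
  round(100 * numerator / denominator, 1)
}
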