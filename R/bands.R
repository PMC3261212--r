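#' Fingerprint band sets
#'
#' A `band_set` holds one fingerprint per clone: a sorted vector of integer
#' band mobilities. AFLP mobilities are stored in 0.1-bp units (capillary
#' sizes multiplied by 10, so that the 16-bit integer contract of classic
#' fingerprint-alignment software is met without losing the decimal digit);
#' WGP fingerprints use pseudo-mobility tag IDs directly. Optional parallel
#' peak heights and per-clone QC flags travel with the bands.
#'
#' @param bands named list of integer vectors (band mobilities, any order;
#'   stored sorted ascending).
#' @param heights optional named list of numeric vectors parallel to `bands`.
#' @param library optional character vector (one per clone) naming the source
#'   BAC library.
#' @param flags optional named list of character vectors of QC flags.
#' @return An object of class `band_set`.
#' @export
band_set <- function(bands, heights = NULL, library = NULL, flags = NULL) {
  stopifnot(is.list(bands))
  ids <- names(bands)
  if (length(bands) == 0L) ids <- character()
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every fingerprint must be named by its clone id")
  names(bands) <- ids
  if (anyDuplicated(ids))
    stop("duplicate clone id: ", ids[duplicated(ids)][1L])
  ord <- lapply(bands, function(b) {
    b <- as.integer(b)
    if (length(b) && (anyNA(b) || any(b <= 0L) || any(b > 65535L)))
      stop("band mobilities must be positive integers <= 65535")
    sort(b)
  })
  if (!is.null(heights)) {
    # heights are reordered with their bands
    heights <- lapply(ids, function(id) {
      h <- heights[[id]]
      if (is.null(h)) return(rep(NA_real_, length(ord[[id]])))
      if (length(h) != length(bands[[id]]))
        stop("peak heights not parallel to bands for clone ", id)
      h[order(as.integer(bands[[id]]))]
    })
    names(heights) <- ids
  }
  structure(
    list(bands = ord, heights = heights,
         library = if (is.null(library)) rep(NA_character_, length(ids))
                   else rep_len(library, length(ids)),
         flags = if (is.null(flags)) stats::setNames(vector("list", length(ids)), ids)
                 else flags),
    class = "band_set")
}

#' @export
length.band_set <- function(x) length(x$bands)

#' @export
names.band_set <- function(x) names(x$bands)

#' @export
print.band_set <- function(x, ...) {
  nb <- lengths(x$bands)
  cat(sprintf("band_set: %d fingerprints, %s bands/clone (median %s)\n",
              length(nb),
              if (length(nb)) paste0(min(nb), "-", max(nb)) else "0",
              if (length(nb)) stats::median(nb) else 0))
  invisible(x)
}

#' Subset a band set by clone id
#' @param x a `band_set`
#' @param ids clone ids to keep (order preserved)
#' @return a `band_set`
#' @export
subset_bands <- function(x, ids) {
  stopifnot(inherits(x, "band_set"))
  keep <- match(ids, names(x$bands))
  if (anyNA(keep)) stop("unknown clone id: ", ids[is.na(keep)][1L])
  band_set(x$bands[keep],
           heights = if (!is.null(x$heights)) x$heights[keep] else NULL,
           library = x$library[keep],
           flags = x$flags[keep])
}

#' Read an extended bands file
#'
#' The dialect is a plain-text format with, per clone, a header line
#' `<clone_id><whitespace><n_bands>` followed by `n_bands` rows of
#' `<mobility><whitespace><peak_height>`. Mobilities are decimal base pairs
#' with one decimal (e.g. `324.1`) and are scaled by 10 to integer units on
#' read; WGP pseudo-band files carry whole numbers which are read verbatim
#' when `scale10 = FALSE`.
#'
#' @param path file to read.
#' @param scale10 multiply mobilities by 10 on read (AFLP convention).
#' @return a [band_set]
#' @export
read_bands_file <- function(path, scale10 = TRUE) {
  if (!file.exists(path)) stop("no such bands file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  bands <- list(); heights <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(hdr) < 2L || is.na(suppressWarnings(as.integer(hdr[2L]))))
      stop("malformed clone header at line ", i, ": ", lines[i])
    id <- hdr[1L]; nb <- as.integer(hdr[2L])
    if (!is.null(bands[[id]])) stop("duplicate clone id in file: ", id)
    if (i + nb > length(lines)) stop("truncated record for clone ", id)
    mob <- numeric(nb); hei <- numeric(nb)
    for (r in seq_len(nb)) {
      fld <- strsplit(trimws(lines[i + r]), "[ \t]+")[[1L]]
      v <- suppressWarnings(as.numeric(fld))
      if (length(v) < 2L || anyNA(v[1:2]))
        stop("malformed band row at line ", i + r, ": ", lines[i + r])
      mob[r] <- v[1L]; hei[r] <- v[2L]
    }
    bands[[id]] <- as.integer(round(mob * if (scale10) 10 else 1))
    heights[[id]] <- hei
    i <- i + nb + 1L
  }
  band_set(bands, heights = heights)
}

#' Write an extended bands file
#'
#' Inverse of [read_bands_file()]: mobilities are divided by 10 and printed
#' with one decimal unless `scale10 = FALSE`.
#'
#' @param fps a [band_set]
#' @param path output file
#' @param scale10 divide integer mobilities by 10 on write (AFLP convention).
#' @export
write_bands_file <- function(fps, path, scale10 = TRUE) {
  stopifnot(inherits(fps, "band_set"))
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(fps$bands)) {
    b <- fps$bands[[id]]
    h <- if (!is.null(fps$heights)) fps$heights[[id]] else NULL
    if (is.null(h) || !length(h)) h <- rep(0, length(b))
    h[is.na(h)] <- 0
    writeLines(sprintf("%s\t%d", id, length(b)), con)
    if (length(b)) {
      mob <- if (scale10) sprintf("%.1f", b / 10) else sprintf("%d", b)
      writeLines(paste0(mob, "\t", format(h, trim = TRUE)), con)
    }
  }
  invisible(path)
}

#' QC parameters for fingerprint filtering
#'
#' Defaults follow the published filter: a 100-650 bp band size window
#' (inclusive at both ends, stored as 1000-6500 in 0.1-bp units) and a
#' 10-100 band count requirement inside that window.
#'
#' @param window_bp closed band-size window in bp.
#' @param min_bands,max_bands band-count bounds after clipping.
#' @param profile_match_threshold fraction of a reference profile's bands
#'   that must be present (within `tol_units`) to flag a fingerprint.
#' @param neighbour_shared_fraction fraction of the smaller fingerprint's
#'   bands shared between adjacent wells that flags both as contaminated.
#' @param tol_units matching tolerance in 0.1-bp units.
#' @return a list of class `qc_params`
#' @export
qc_params <- function(window_bp = c(100, 650), min_bands = 10L,
                      max_bands = 100L, profile_match_threshold = 0.8,
                      neighbour_shared_fraction = 0.8, tol_units = 5L) {
  stopifnot(length(window_bp) == 2L, window_bp[1] < window_bp[2],
            min_bands < max_bands,
            profile_match_threshold > 0, profile_match_threshold <= 1,
            neighbour_shared_fraction > 0, neighbour_shared_fraction <= 1)
  structure(list(window_bp = window_bp, min_bands = as.integer(min_bands),
                 max_bands = as.integer(max_bands),
                 profile_match_threshold = profile_match_threshold,
                 neighbour_shared_fraction = neighbour_shared_fraction,
                 tol_units = as.integer(tol_units)),
            class = "qc_params")
}

#' Clip fingerprints to the band-size window and filter on band count
#'
#' Bands outside the closed window are removed; fingerprints with fewer than
#' `min_bands` or more than `max_bands` remaining bands are excluded. The
#' returned kept set keeps a full unclipped copy of each retained
#' fingerprint (attribute `"unclipped"`) so that markers below the window can
#' still be matched during anchoring.
#'
#' @param fps a [band_set]
#' @param params a [qc_params]
#' @return list with elements `kept` (clipped [band_set]), `report`
#'   (data.frame clone_id/reason for exclusions) and `counts` (exclusions per
#'   reason).
#' @export
preprocess <- function(fps, params = qc_params()) {
  stopifnot(inherits(fps, "band_set"))
  lo <- as.integer(round(params$window_bp[1] * 10))
  hi <- as.integer(round(params$window_bp[2] * 10))
  clipped <- lapply(fps$bands, function(b) b[b >= lo & b <= hi])
  nb <- lengths(clipped)
  reason <- rep(NA_character_, length(nb))
  reason[nb < params$min_bands] <- "too_few_bands"
  reason[nb > params$max_bands] <- "too_many_bands"
  keep <- is.na(reason)
  kept_ids <- names(fps$bands)[keep]
  kept <- band_set(clipped[keep],
                   heights = NULL,
                   library = fps$library[keep],
                   flags = fps$flags[keep])
  attr(kept, "unclipped") <- fps$bands[keep]
  report <- data.frame(clone_id = names(fps$bands)[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  list(kept = kept, report = report,
       counts = table(factor(report$reason,
                             levels = c("too_few_bands", "too_many_bands"))))
}

#' Flag chloroplast/artefact profiles and neighbouring-well contaminations
#'
#' A fingerprint is flagged with a reference profile's name when at least
#' `profile_match_threshold` of the profile's bands are present within the
#' matching tolerance. Two wells at Chebyshev distance 1 on the same plate
#' whose fingerprints share at least `neighbour_shared_fraction` of the
#' smaller fingerprint's bands are both flagged `contaminated`.
#'
#' @param fps a [band_set]
#' @param layout data.frame with columns clone_id, plate, well.
#' @param reference_profiles named list of integer band vectors (e.g.
#'   `chloroplast`, `artefact`).
#' @param params a [qc_params]
#' @return data.frame clone_id / flag (possibly several rows per clone)
#' @export
detect_contaminations <- function(fps, layout, reference_profiles = list(),
                                  params = qc_params()) {
  stopifnot(inherits(fps, "band_set"))
  ids <- names(fps$bands)
  miss <- setdiff(ids, layout$clone_id)
  if (length(miss)) stop("missing layout entry for clone ", miss[1L])
  out_id <- character(); out_flag <- character()
  tol <- params$tol_units
  for (pn in names(reference_profiles)) {
    prof <- sort(as.integer(reference_profiles[[pn]]))
    for (id in ids) {
      b <- fps$bands[[id]]
      if (!length(b) || !length(prof)) next
      frac <- match_count_cpp(prof, b, tol) / length(prof)
      if (frac >= params$profile_match_threshold) {
        out_id <- c(out_id, id); out_flag <- c(out_flag, pn)
      }
    }
  }
  lay <- layout[match(ids, layout$clone_id), , drop = FALSE]
  rc <- well_to_rowcol(lay$well)
  for (p in unique(lay$plate)) {
    on_p <- which(lay$plate == p)
    if (length(on_p) < 2L) next
    for (a in seq_along(on_p)) {
      for (b in seq_along(on_p)) {
        if (b <= a) next
        ia <- on_p[a]; ib <- on_p[b]
        if (max(abs(rc$row[ia] - rc$row[ib]), abs(rc$col[ia] - rc$col[ib])) != 1L)
          next
        fa <- fps$bands[[ia]]; fb <- fps$bands[[ib]]
        if (!length(fa) || !length(fb)) next
        m <- match_count_cpp(fa, fb, tol)
        if (m / min(length(fa), length(fb)) >= params$neighbour_shared_fraction) {
          out_id <- c(out_id, ids[ia], ids[ib])
          out_flag <- c(out_flag, "contaminated", "contaminated")
        }
      }
    }
  }
  unique(data.frame(clone_id = out_id, flag = out_flag,
                    stringsAsFactors = FALSE))
}
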