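#' Configuration of the synthetic diploid simulation
#'
#' The defaults emulate the statistical structure assumed by the analysis:
#' a two-haplotype genome whose restriction fragments average 3477 bp (the
#' sequence represented per fingerprint band), with a right-skewed
#' (geometric-like) length distribution; heterozygosity organised in
#' haplotype-divergence blocks such that 54% of distinct fragments/tags are
#' haplotype-specific; a partial-digest BAC library (127 kb mean clones) and
#' a sheared library (96 kb) on 384-well plates; capillary sizing noise of
#' 0.3 bp; band mobilities skewed toward the low end of the 100-650 bp
#' scoring window; chloroplast/artefact/neighbour-well contamination rates
#' of 3.8/4.7/4.4%; and repeat-fragment WGP tag dropout.
#'
#' `het_fraction` is the fraction of *distinct* fragments (equivalently,
#' WGP tags) present in exactly one haplotype. Internally the fraction of
#' genome length lying in diverged blocks is `het_fraction/(2-het_fraction)`,
#' since a diverged locus contributes two haplotype-specific fragments while
#' a shared locus contributes one.
#'
#' @param genome_length_bp haploid genome length.
#' @param n_chromosomes number of chromosomes (equal lengths).
#' @param het_fraction heterozygous fraction of distinct fragments/tags.
#' @param mean_fragment_bp mean restriction-fragment length.
#' @param clone_libraries list of library specs
#'   `list(name=, digestion_mode=, clone_size_mean_kb=, clone_size_sd_kb=,
#'   n_clones=)`; `NULL` gives a partial-digest library at `ge_partial`
#'   coverage plus a sheared library at `ge_sheared`.
#' @param ge_partial,ge_sheared default library coverages (haploid genome
#'   equivalents) used when `clone_libraries` is `NULL`.
#' @param wells_per_plate,quarter_size plate geometry (384 / 96).
#' @param sizing_noise_sd_bp capillary sizing noise (bp).
#' @param band_window_bp scoring window in bp.
#' @param band_mobility_mean_bp mean of the skewed band-mobility
#'   distribution.
#' @param repeat_fragment_fraction fraction of fragments flagged repetitive
#'   (their WGP tags fail to resolve).
#' @param contamination rates `c(chloroplast, artefact, neighbour)`.
#' @param n_markers heterozygous mapped markers to sample.
#' @param n_primer_combinations number of selective primer combinations the
#'   marker screening gels are divided over (marker gels amplify one
#'   combination at a time, which keeps their band complexity low).
#' @param het_block_bp mean haplotype-divergence block length.
#' @param rng_seed global seed; all simulation stages draw from one stream.
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(genome_length_bp = 1e7, n_chromosomes = 2L,
                              het_fraction = 0.54, mean_fragment_bp = 3477,
                              clone_libraries = NULL,
                              ge_partial = 9.6, ge_sheared = 3.3,
                              wells_per_plate = 384L, quarter_size = 96L,
                              sizing_noise_sd_bp = 0.3,
                              band_window_bp = c(100, 650),
                              band_mobility_mean_bp = 350,
                              repeat_fragment_fraction = 0.05,
                              contamination = c(chloroplast = 0.038,
                                                artefact = 0.047,
                                                neighbour = 0.044),
                              n_markers = 100L, het_block_bp = 5e5,
                              n_primer_combinations = 135L,
                              rng_seed = 1L) {
  if (is.null(clone_libraries)) {
    clone_libraries <- list(
      list(name = "RH", digestion_mode = "partial_digest",
           clone_size_mean_kb = 127, clone_size_sd_kb = 37,
           n_clones = round(ge_partial * genome_length_bp / 127e3)),
      list(name = "PL", digestion_mode = "sheared",
           clone_size_mean_kb = 96, clone_size_sd_kb = 34,
           n_clones = round(ge_sheared * genome_length_bp / 96e3)))
  }
  stopifnot(het_fraction >= 0, het_fraction <= 1,
            repeat_fragment_fraction >= 0, repeat_fragment_fraction <= 1,
            all(contamination >= 0 & contamination <= 1),
            band_window_bp[1] < band_window_bp[2],
            mean_fragment_bp > 0, genome_length_bp > 0,
            wells_per_plate == 384L, quarter_size == 96L)
  for (lib in clone_libraries) {
    stopifnot(lib$clone_size_mean_kb > 0, lib$n_clones >= 0,
              lib$digestion_mode %in% c("partial_digest", "sheared"))
  }
  structure(as.list(environment()), class = "simulation_config")
}

# skewed band mobilities in 0.1-bp units, rejection-truncated to the window
draw_mobility <- function(n, config) {
  lo <- config$band_window_bp[1] * 10
  hi <- config$band_window_bp[2] * 10
  mean_units <- (config$band_mobility_mean_bp - config$band_window_bp[1]) * 10
  p <- 1 / (mean_units + 1)
  out <- integer(0)
  while (length(out) < n) {
    u <- stats::rgeom(n - length(out), p)
    out <- c(out, u[u <= hi - lo])
  }
  as.integer(lo + out[seq_len(n)])
}

#' Simulate a diploid heterozygous genome of restriction fragments
#'
#' Fragments tile each chromosome with geometric-like (right-skewed) lengths
#' of the requested mean. Haplotype-divergence blocks (mean length
#' `het_block_bp`) cover a fraction `het_fraction/(2-het_fraction)` of the
#' genome; inside a diverged block each locus carries two allelic fragments
#' (one per haplotype) with independent band mobilities and tags, outside it
#' a single fragment shared by both haplotypes. Each fragment carries a
#' skewed-mobility AFLP band, a WGP tag id at its EcoRI end, and a
#' repetitive flag (tag dropout).
#'
#' @param config a [simulation_config]
#' @param seed optional seed; default `config$rng_seed`. Pass `NA` to
#'   continue the current RNG stream.
#' @return object of class `diploid_genome`: list with `fragments`
#'   (data.frame: frag_id, slot_id, chrom, start_bp, end_bp, shared,
#'   haplotype, repetitive, mobility, tag_id), `chrom_lengths`, `config`.
#' @export
simulate_genome <- function(config, seed = config$rng_seed) {
  if (!is.na(seed)) set.seed(seed)
  n_chr <- config$n_chromosomes
  chr_len <- rep(floor(config$genome_length_bp / n_chr), n_chr)
  min_frag <- 200
  if (config$mean_fragment_bp <= min_frag ||
      any(chr_len < 2 * config$mean_fragment_bp))
    stop("genome too short to host the requested fragment sizing")
  p <- 1 / (config$mean_fragment_bp - min_frag + 1)
  h_len <- config$het_fraction / (2 - config$het_fraction)
  rows <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    n_exp <- ceiling(chr_len[ch] / config$mean_fragment_bp * 1.4) + 10
    len <- min_frag + stats::rgeom(n_exp, p)
    ends <- cumsum(len)
    keep <- which(ends < chr_len[ch])
    len <- len[keep]; ends <- ends[keep]
    # last fragment truncated at the chromosome end
    len <- c(len, chr_len[ch] - if (length(ends)) ends[length(ends)] else 0)
    ends <- c(ends, chr_len[ch])
    starts <- ends - len
    nf <- length(len)
    # divergence blocks
    n_blk <- ceiling(chr_len[ch] / config$het_block_bp * 3) + 5
    blk_len <- stats::rexp(n_blk, 1 / config$het_block_bp)
    blk_end <- cumsum(blk_len)
    n_blk <- which(blk_end >= chr_len[ch])[1L]
    blk_end <- c(blk_end[seq_len(n_blk - 1L)], chr_len[ch])
    blk_div <- stats::runif(n_blk) < h_len
    mid <- (starts + ends) / 2
    diverged <- blk_div[findInterval(mid, c(0, blk_end),
                                     rightmost.closed = TRUE)]
    n_rows <- nf + sum(diverged)
    hap <- rep(NA_integer_, nf)
    df <- data.frame(slot_id = seq_len(nf), chrom = ch,
                     start_bp = starts, end_bp = ends,
                     shared = !diverged, haplotype = hap)
    extra <- df[diverged, , drop = FALSE]
    if (nrow(extra)) {
      df$haplotype[diverged] <- 0L
      extra$haplotype <- 1L
      df <- rbind(df, extra)
    }
    df <- df[order(df$slot_id, df$haplotype, na.last = TRUE), , drop = FALSE]
    rows[[ch]] <- df
  }
  frag <- do.call(rbind, rows)
  # chromosome-global slot ids
  frag$slot_id <- cumsum(!duplicated(paste(frag$chrom, frag$slot_id)))
  frag$frag_id <- seq_len(nrow(frag))
  frag$mobility <- draw_mobility(nrow(frag), config)
  frag$repetitive <- stats::runif(nrow(frag)) < config$repeat_fragment_fraction
  # selective primer combination of the locus (allelic fragments share it);
  # marker screening gels amplify one combination at a time
  pc_of_slot <- sample.int(config$n_primer_combinations,
                           max(frag$slot_id), replace = TRUE)
  frag$pc <- pc_of_slot[frag$slot_id]
  frag$tag_id <- seq_len(nrow(frag))
  rownames(frag) <- NULL
  structure(list(fragments = frag, chrom_lengths = chr_len, config = config),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  f <- x$fragments
  cat(sprintf(paste0("diploid_genome: %d chromosomes (%.1f Mb haploid), ",
                     "%d distinct fragments (%.1f%% haplotype-specific)\n"),
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              nrow(f), 100 * mean(!f$shared)))
  invisible(x)
}

#' Simulate BAC libraries on 384-well plates
#'
#' Clones are drawn entirely from one haplotype chosen uniformly;
#' partial-digest clone ends coincide with restriction-fragment boundaries
#' while sheared clone ends are uniform. Clones are assigned to plates and
#' wells sequentially (row-major, plates numbered from 1 per library) and
#' each well's quarter-plate pool follows the replicator parity rule of
#' [clone_to_qpp()].
#'
#' @param genome a [simulate_genome()] result
#' @param config a [simulation_config]
#' @param seed optional seed; `NA` (default) continues the stream.
#' @return object of class `bac_clones`: data.frame with clone_id, library,
#'   digestion_mode, haplotype, chromosome, start_bp, end_bp, plate, well,
#'   qpp — the simulation ground truth.
#' @export
simulate_bac_library <- function(genome, config = genome$config, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  if (!length(config$clone_libraries)) stop("at least one library spec")
  chr_len <- genome$chrom_lengths
  slots <- genome$fragments[genome$fragments$shared |
                            genome$fragments$haplotype == 0L, ]
  bounds <- split(slots$start_bp, slots$chrom)
  bounds <- lapply(seq_along(chr_len), function(ch)
    sort(unique(c(bounds[[ch]], chr_len[ch]))))
  out <- list()
  for (lib in config$clone_libraries) {
    n <- lib$n_clones
    if (n == 0L) next
    mu <- lib$clone_size_mean_kb * 1000; sd <- lib$clone_size_sd_kb * 1000
    chrom <- sample.int(length(chr_len), n, replace = TRUE,
                        prob = chr_len / sum(chr_len))
    hap <- sample(0:1, n, replace = TRUE)
    len <- round(stats::rnorm(n, mu, sd))
    for (try in 1:20) {
      bad <- which(len < 3e4 | len >= chr_len[chrom])
      if (!length(bad)) break
      len[bad] <- round(stats::rnorm(length(bad), mu, sd))
      if (try == 20) len[bad] <- pmin(pmax(len[bad], 3e4),
                                      chr_len[chrom[bad]] - 1)
    }
    start <- integer(n); end <- integer(n)
    if (lib$digestion_mode == "sheared") {
      start <- floor(stats::runif(n) * (chr_len[chrom] - len))
      end <- start + len
    } else {
      for (i in seq_len(n)) {
        b <- bounds[[chrom[i]]]
        ok <- b[b <= chr_len[chrom[i]] - len[i]]
        s <- ok[sample.int(length(ok), 1L)]
        e <- b[which.min(abs(b - (s + len[i])))]
        if (e <= s) e <- b[b > s][1L]
        start[i] <- s; end[i] <- e
      }
    }
    idx <- seq_len(n) - 1L
    plate <- idx %/% config$wells_per_plate + 1L
    well <- well_id(idx %% config$wells_per_plate)
    out[[length(out) + 1L]] <- data.frame(
      clone_id = sprintf("%s%03d%s", lib$name, plate, well),
      library = lib$name, digestion_mode = lib$digestion_mode,
      haplotype = hap, chromosome = chrom,
      start_bp = start, end_bp = end, plate = plate, well = well,
      qpp = clone_to_qpp(plate, well), stringsAsFactors = FALSE)
  }
  clones <- do.call(rbind, out)
  if (is.null(clones)) clones <- data.frame(
    clone_id = character(), library = character(),
    digestion_mode = character(), haplotype = integer(),
    chromosome = integer(), start_bp = integer(), end_bp = integer(),
    plate = integer(), well = character(), qpp = character())
  rownames(clones) <- NULL
  class(clones) <- c("bac_clones", "data.frame")
  clones
}

#' Fingerprint simulated clones
#'
#' AFLP bands are the mobilities of the fragments fully contained in a
#' clone (restricted to the clone's haplotype plus shared fragments) with
#' Gaussian sizing noise; WGP tags are the tag ids of those fragments,
#' except that repetitive fragments fail to resolve their tags and are
#' dropped entirely.
#'
#' @param clones a `bac_clones` data.frame (or a subset of rows)
#' @param genome the [simulate_genome()] result
#' @param config a [simulation_config]
#' @param seed optional seed; `NA` continues the stream.
#' @return list with `fps` (an AFLP [band_set]) and `tags` (named list of
#'   integer tag ids per clone)
#' @export
fingerprint_clones <- function(clones, genome, config = genome$config,
                               seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  frag <- genome$fragments
  by_chr <- split(frag, frag$chrom)
  sd_units <- config$sizing_noise_sd_bp * 10
  bands <- vector("list", nrow(clones))
  tags <- vector("list", nrow(clones))
  for (i in seq_len(nrow(clones))) {
    f <- by_chr[[as.character(clones$chromosome[i])]]
    inside <- f$start_bp >= clones$start_bp[i] & f$end_bp <= clones$end_bp[i] &
      (f$shared | f$haplotype == clones$haplotype[i])
    f <- f[inside, , drop = FALSE]
    noise <- if (sd_units > 0)
      as.integer(round(stats::rnorm(nrow(f), 0, sd_units))) else 0L
    bands[[i]] <- pmax(1L, f$mobility + noise)
    tags[[i]] <- f$tag_id[!f$repetitive]
  }
  names(bands) <- clones$clone_id
  names(tags) <- clones$clone_id
  list(fps = band_set(bands, library = clones$library), tags = tags)
}

#' Fingerprint of a single simulated clone
#'
#' @inheritParams fingerprint_clones
#' @param clone_id one clone id present in `clones`
#' @return list with `bands` (integer mobilities) and `tags`
#' @export
fingerprint_clone <- function(clone_id, clones, genome,
                              config = genome$config, seed = NA) {
  row <- clones[clones$clone_id == clone_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown clone id: ", clone_id)
  r <- fingerprint_clones(row, genome, config, seed)
  list(bands = r$fps$bands[[1L]], tags = r$tags[[1L]])
}

# forward shift of the radioactive->capillary mobility model used by the
# simulator: ~constant below the knot, rising linearly to about +20 bp at
# 600 bp
sim_size_shift <- function(radioactive_bp, s0 = -1, slope = 0.14,
                           knot = 450) {
  s0 + slope * pmax(0, radioactive_bp - knot)
}

sim_size_shift_inverse <- function(capillary_bp, s0 = -1, slope = 0.14,
                                   knot = 450) {
  rad <- capillary_bp - s0
  hi <- rad > knot
  rad[hi] <- (capillary_bp[hi] - s0 + knot * slope) / (1 + slope)
  rad
}

#' Sample heterozygous mapped AFLP markers from the genome
#'
#' Each marker is one allele of a haplotype-specific fragment (dominant,
#' presence/absence scoring: the opposite haplotype has no band at the
#' marker mobility), with phase equal to its haplotype, a coarse genetic bin
#' (100 bins per chromosome) and a radioactive gel size obtained by
#' inverting the piecewise-linear capillary shift model.
#'
#' @param genome the [simulate_genome()] result
#' @param config a [simulation_config]
#' @param seed optional seed; `NA` continues the stream.
#' @return data.frame: marker_id, primer_combination, radioactive_size_bp,
#'   capillary_true_bp, chromosome, bin, phase, frag_id, slot_id, mobility.
#' @export
sample_markers <- function(genome, config = genome$config, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  frag <- genome$fragments
  spec <- frag[!frag$shared, , drop = FALSE]
  spec <- spec[sample.int(nrow(spec)), , drop = FALSE]
  spec <- spec[!duplicated(spec$slot_id), , drop = FALSE]
  if (nrow(spec) < config$n_markers)
    stop("n_markers exceeds available haplotype-specific fragments")
  spec <- spec[seq_len(config$n_markers), , drop = FALSE]
  cap <- spec$mobility / 10
  rad <- round(sim_size_shift_inverse(cap), 1)
  chrlen <- genome$chrom_lengths[spec$chrom]
  bin <- pmin(100L, 1L + as.integer(floor(spec$start_bp / chrlen * 100)))
  data.frame(marker_id = sprintf("M%04d_%.1f", seq_len(nrow(spec)), cap),
             primer_combination = sprintf("PC%03d", spec$pc),
             pc = spec$pc, radioactive_size_bp = rad,
             capillary_true_bp = cap, chromosome = spec$chrom, bin = bin,
             phase = spec$haplotype, frag_id = spec$frag_id,
             slot_id = spec$slot_id, mobility = spec$mobility,
             stringsAsFactors = FALSE)
}

#' Clones whose selective marker gel pattern contains the marker band
#'
#' Emulates superpool marker screening: the marker screening gels amplify a
#' single selective primer combination, so a clone contributes the marker
#' band when it fully contains a fragment of the marker's primer
#' combination, compatible with its haplotype, whose mobility lies within
#' the scoring interval of the marker.
#'
#' @param marker one row of a [sample_markers()] table
#' @param genome the [simulate_genome()] result
#' @param clones a `bac_clones` table
#' @param interval_units scoring half-width in 0.1-bp units (default 2,
#'   i.e. a 0.4 bp wide interval)
#' @return character vector of carrier clone ids
#' @export
marker_carrier_clones <- function(marker, genome, clones,
                                  interval_units = 2L) {
  frag <- genome$fragments
  hit <- frag[frag$pc == marker$pc &
                abs(frag$mobility - marker$mobility) <= interval_units, ,
              drop = FALSE]
  if (!nrow(hit)) return(character())
  out <- character()
  for (i in seq_len(nrow(hit))) {
    ok <- clones$chromosome == hit$chrom[i] &
      clones$start_bp <= hit$start_bp[i] & clones$end_bp >= hit$end_bp[i] &
      (hit$shared[i] | clones$haplotype == hit$haplotype[i])
    out <- c(out, clones$clone_id[ok])
  }
  unique(out)
}

#' Inject contamination artifacts into fingerprints
#'
#' Chloroplast clones are replaced by a fixed reference band profile;
#' artefact clones receive a fixed extra band set on top of their own bands;
#' neighbour-mixed clones receive the union of their own and an adjacent
#' well's bands. Flags are recorded for recovery tests.
#'
#' @param fps an AFLP [band_set]
#' @param layout data.frame clone_id/plate/well
#' @param config a [simulation_config]
#' @param seed optional seed; `NA` continues the stream.
#' @return list with `fps` (contaminated [band_set]), `flags` (data.frame
#'   clone_id/flag) and `profiles` (the reference chloroplast and artefact
#'   band sets)
#' @export
inject_artifacts <- function(fps, layout, config, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  profiles <- list(chloroplast = sort(draw_mobility(45L, config)),
                   artefact = sort(draw_mobility(15L, config)))
  rates <- config$contamination
  ids <- names(fps$bands)
  n <- length(ids)
  u <- stats::runif(n)
  flag <- rep(NA_character_, n)
  flag[u < rates[[1L]]] <- "chloroplast"
  flag[u >= rates[[1L]] & u < rates[[1L]] + rates[[2L]]] <- "artefact"
  flag[u >= rates[[1L]] + rates[[2L]] &
       u < rates[[1L]] + rates[[2L]] + rates[[3L]]] <- "contaminated"
  bands <- fps$bands
  lay <- layout[match(ids, layout$clone_id), , drop = FALSE]
  rc <- well_to_rowcol(lay$well)
  for (i in which(!is.na(flag))) {
    if (flag[i] == "chloroplast") {
      bands[[i]] <- profiles$chloroplast
    } else if (flag[i] == "artefact") {
      bands[[i]] <- sort(c(bands[[i]], profiles$artefact))
    } else {
      # mix with an existing adjacent well on the same plate
      cand <- which(lay$plate == lay$plate[i] &
                    abs(rc$row - rc$row[i]) <= 1L &
                    abs(rc$col - rc$col[i]) <= 1L &
                    seq_len(n) != i)
      if (length(cand)) {
        j <- cand[1L]
        bands[[i]] <- sort(c(bands[[i]], bands[[j]]))
      } else flag[i] <- NA_character_
    }
  }
  list(fps = band_set(bands, library = fps$library),
       flags = data.frame(clone_id = ids[!is.na(flag)],
                          flag = flag[!is.na(flag)],
                          stringsAsFactors = FALSE),
       profiles = profiles)
}

#' Write a simulation to plain-text files
#'
#' Emits the extended bands file, the WGP tag table (clone id plus
#' tab-joined tags), the marker table, the plate layout and the clone truth
#' table under `dir`.
#'
#' @param sim list with components `fps`, `tags`, `clones`, `markers` (as
#'   produced by the simulation operations)
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bands_file(sim$fps, file.path(dir, "fingerprints.bands"))
  tg <- vapply(sim$tags, paste, "", collapse = "\t")
  writeLines(paste0(names(sim$tags), "\t", tg),
             file.path(dir, "wgp_tags.tsv"))
  utils::write.table(sim$markers, file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clones, file.path(dir, "clones_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clones[, c("clone_id", "plate", "well")],
                     file.path(dir, "layout.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
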