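#' Link two physical maps through shared clones and form contig groups
#'
#' Contig pairs — one from each map — sharing at least `min_shared_clones`
#' clones are linked; contigs connected by such links (directly or via a
#' chain of links) form a contig group. Per map, the group-enhanced contig
#' count takes each group as a single contig: number of groups containing at
#' least one of the map's contigs plus that map's ungrouped contigs.
#'
#' @param mapA,mapW two `physical_map`s over comparable clone ids
#' @param min_shared_clones minimum shared clones per link (default 2)
#' @return list with `links` (data.frame contig_a/contig_w/shared),
#'   `groups` (list of data.frames map/contig_id), `n_pair_groups`,
#'   `n_multi_groups`, `enhanced_count_a`, `enhanced_count_w`
#' @export
link_and_group <- function(mapA, mapW, min_shared_clones = 2L) {
  memb <- function(map, label) {
    data.frame(clone_id = unlist(lapply(map$contigs, `[[`, "members")),
               contig = rep(vapply(map$contigs, `[[`, 1L, "id"),
                            vapply(map$contigs,
                                   function(x) length(x$members), 1L)),
               map = label, stringsAsFactors = FALSE)
  }
  ma <- memb(mapA, "A"); mw <- memb(mapW, "W")
  common <- merge(ma[, c("clone_id", "contig")],
                  mw[, c("clone_id", "contig")], by = "clone_id")
  links <- data.frame(contig_a = integer(), contig_w = integer(),
                      shared = integer())
  if (nrow(common)) {
    tab <- stats::aggregate(clone_id ~ contig.x + contig.y, common, length)
    tab <- tab[tab$clone_id >= min_shared_clones, , drop = FALSE]
    links <- data.frame(contig_a = tab$contig.x, contig_w = tab$contig.y,
                        shared = tab$clone_id)
  }
  n_a <- length(mapA$contigs); n_w <- length(mapW$contigs)
  if (!nrow(links)) {
    return(list(links = links, groups = list(), n_pair_groups = 0L,
                n_multi_groups = 0L, enhanced_count_a = n_a,
                enhanced_count_w = n_w))
  }
  va <- paste0("A", links$contig_a); vw <- paste0("W", links$contig_w)
  g <- igraph::graph_from_data_frame(data.frame(va, vw), directed = FALSE)
  comp <- igraph::components(g)$membership
  groups <- lapply(split(names(comp), comp), function(vs)
    data.frame(map = substr(vs, 1L, 1L),
               contig_id = as.integer(substring(vs, 2L)),
               stringsAsFactors = FALSE))
  names(groups) <- NULL
  sizes <- vapply(groups, nrow, 1L)
  grouped_a <- length(unique(links$contig_a))
  grouped_w <- length(unique(links$contig_w))
  list(links = links, groups = groups,
       n_pair_groups = sum(sizes == 2L),
       n_multi_groups = sum(sizes >= 3L),
       enhanced_count_a = length(groups) + (n_a - grouped_a),
       enhanced_count_w = length(groups) + (n_w - grouped_w))
}

#' Expected percentage of two-haplotype contigs under free mixing
#'
#' If marker haplotypes combine independently, a contig with `n` dominant
#' markers has probability `0.5^(n-1)` of carrying a single haplotype, so
#' the expected percentage of two-haplotype contigs is
#' `100 * (1 - 0.5^(n-1))`.
#'
#' @param n markers per contig
#' @return expected percentage
#' @export
expected_pct_two_haplotypes <- function(n) 100 * (1 - 0.5^(n - 1))

#' Marker haplotype distribution across multi-marker contigs
#'
#' Classifies each anchored contig as one- or two-haplotype (two-haplotype
#' iff it carries at least one marker of each phase) and tabulates observed
#' versus expected percentages per marker-count class, with average contig
#' lengths per class.
#'
#' @param contig_phases data.frame with columns `contig_id`, `phase`
#'   (0/1; one row per anchored marker)
#' @param map optional `physical_map` supplying contig lengths (kb)
#' @return data.frame with one row per marker count n: n, one_hap_contigs,
#'   one_hap_avg_kb, two_hap_contigs, two_hap_avg_kb, observed_pct_two,
#'   expected_pct_two
#' @export
haplotype_mixing_table <- function(contig_phases, map = NULL) {
  stopifnot(all(c("contig_id", "phase") %in% names(contig_phases)))
  len_kb <- NULL
  if (!is.null(map)) {
    len_kb <- stats::setNames(
      vapply(map$contigs, `[[`, 1L, "cb_length") *
        map$params$bp_per_band / 1000,
      vapply(map$contigs, `[[`, 1L, "id"))
  }
  by_ct <- split(contig_phases$phase, contig_phases$contig_id)
  n_mark <- lengths(by_ct)
  two <- vapply(by_ct, function(p) length(unique(p)) >= 2L, TRUE)
  avg_len <- function(ids) {
    if (is.null(len_kb) || !length(ids)) return(NA_real_)
    round(mean(len_kb[ids]))
  }
  do.call(rbind, lapply(sort(unique(n_mark)), function(n) {
    sel <- n_mark == n
    one_ids <- names(by_ct)[sel & !two]
    two_ids <- names(by_ct)[sel & two]
    data.frame(n = n,
               one_hap_contigs = length(one_ids),
               one_hap_avg_kb = avg_len(one_ids),
               two_hap_contigs = length(two_ids),
               two_hap_avg_kb = avg_len(two_ids),
               observed_pct_two = round(100 * length(two_ids) /
                                          max(1L, sum(sel)), 1),
               expected_pct_two = round(expected_pct_two_haplotypes(n), 1))
  }))
}

#' Write the hybrid physical-map table
#'
#' One row per clone: its contig and offset in each map (or `singleton`),
#' its contig group, and any anchor markers with phases. Rows are sorted by
#' clone id.
#'
#' @param mapA,mapW the two `physical_map`s
#' @param groups a [link_and_group()] result
#' @param anchors optional list of `anchor_record`s with phases attached via
#'   `markers`
#' @param markers optional marker table with `marker_id` and `phase`
#' @param path output TSV path
#' @return the table, invisibly
#' @export
write_hybrid_table <- function(mapA, mapW, groups, anchors = NULL,
                               markers = NULL, path) {
  place <- function(map) {
    ids <- unlist(lapply(map$contigs, `[[`, "members"))
    data.frame(clone_id = c(ids, map$singletons),
               contig = c(rep(vapply(map$contigs, `[[`, 1L, "id"),
                              vapply(map$contigs,
                                     function(x) length(x$members), 1L)),
                          rep(NA_integer_, length(map$singletons))),
               offset = c(unlist(lapply(map$contigs, `[[`, "offsets")),
                          rep(NA_integer_, length(map$singletons))),
               stringsAsFactors = FALSE)
  }
  pa <- place(mapA); pw <- place(mapW)
  all_ids <- sort(union(pa$clone_id, pw$clone_id))
  gid_of <- rep(NA_integer_, length(all_ids))
  if (length(groups$groups)) {
    for (gi in seq_along(groups$groups)) {
      gdf <- groups$groups[[gi]]
      for (r in seq_len(nrow(gdf))) {
        map <- if (gdf$map[r] == "A") pa else pw
        gid_of[all_ids %in% map$clone_id[map$contig == gdf$contig_id[r]]] <-
          gi
      }
    }
  }
  mk <- rep(NA_character_, length(all_ids))
  if (!is.null(anchors)) {
    ph <- if (!is.null(markers))
      stats::setNames(markers$phase, markers$marker_id) else NULL
    for (a in anchors) {
      if (a$status != "anchored") next
      lab <- if (!is.null(ph)) sprintf("%s{%d}", a$marker_id,
                                       ph[[a$marker_id]]) else a$marker_id
      sel <- all_ids %in% a$positive_clones
      mk[sel] <- ifelse(is.na(mk[sel]), lab, paste(mk[sel], lab, sep = ","))
    }
  }
  fmt <- function(p) {
    i <- match(all_ids, p$clone_id)
    ifelse(is.na(i), NA,
           ifelse(is.na(p$contig[i]), "singleton",
                  paste0(p$contig[i], "@", p$offset[i])))
  }
  out <- data.frame(clone_id = all_ids, aflp = fmt(pa), wgp = fmt(pw),
                    group = gid_of, anchors = mk, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(out)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates: genome and library simulation, AFLP fingerprinting with
#' contamination injection, QC and contamination removal, AFLP map assembly
#' (build, DQ resplit, end merge), pooling design and in-silico marker
#' anchoring, WGP tag map assembly, hybrid-map integration, and the
#' heterozygosity analyses. Returns a report with Table-1-style statistics
#' of both maps plus truth-based recovery metrics.
#'
#' @param config a [simulation_config]
#' @param output_dir optional directory for the hybrid table and report JSON
#' @param quiet suppress stage messages
#' @return report list (invisibly written to JSON when `output_dir` is set)
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3L]
  stage <- function(name, expr) {
    t <- proc.time()[3L]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e)))
    say("[%s] %.1fs", name, proc.time()[3L] - t)
    r
  }
  genome <- stage("simulate_genome", simulate_genome(config))
  clones <- stage("simulate_bac_library", simulate_bac_library(genome))
  fpr <- stage("fingerprint", fingerprint_clones(clones, genome))
  markers <- stage("sample_markers", sample_markers(genome))
  art <- stage("inject_artifacts",
               inject_artifacts(fpr$fps, clones, config))
  qc <- stage("preprocess", preprocess(art$fps))
  cont <- stage("detect_contaminations",
                detect_contaminations(qc$kept, clones, list(
                  chloroplast = art$profiles$chloroplast,
                  artefact = art$profiles$artefact)))
  # the AFLP map is built from the partial-digest library only; the WGP map
  # uses both libraries
  pd_ids <- clones$clone_id[clones$digestion_mode == "partial_digest"]
  clean_ids <- setdiff(intersect(names(qc$kept$bands), pd_ids),
                       cont$clone_id)
  clean <- subset_bands(qc$kept, clean_ids)
  attr(clean, "unclipped") <- attr(qc$kept, "unclipped")[clean_ids]
  pa <- assembly_params("aflp")
  mapA <- stage("aflp_map",
                end_merge(dq_resplit(build_contigs(clean, pa))))
  # pooling + anchoring on the partial-digest library
  key <- clones[clones$digestion_mode == "partial_digest", , drop = FALSE]
  qpps <- sort(unique(key$qpp))
  design <- stage("pooling_design",
                  generate_design(n_qpp = length(qpps), v = 90L, k = 4L,
                                  seed = config$rng_seed, qpp_ids = qpps))
  clone_qpp <- stats::setNames(clones$qpp, clones$clone_id)
  clone_qpp[clones$digestion_mode != "partial_digest"] <- NA
  anchors <- stage("anchoring", {
    lapply(seq_len(nrow(markers)), function(i) {
      mk <- markers[i, ]
      # superpool screening is selective (one primer combination per gel)
      hit <- intersect(marker_carrier_clones(mk, genome, key),
                       key$clone_id)
      pos_sp <- sort(unique(as.vector(
        design$assignment[unique(clone_qpp[hit]), , drop = FALSE])))
      dec <- deconvolute(pos_sp, design)
      keymaps_anchor(mk$capillary_true_bp, dec, mapA, clone_qpp,
                     marker_id = mk$marker_id)
    })
  })
  val <- stage("validate", validate_and_summarize(anchors, markers, mapA))
  # WGP map
  universe <- stage("pseudo_ids",
                    assign_pseudo_ids(unique(unlist(fpr$tags)),
                                      seed = config$rng_seed))
  wfp_all <- stage("wgp_fps", tags_to_fingerprints(fpr$tags, universe))
  pw <- assembly_params("wgp")
  keep_w <- names(wfp_all$bands)[lengths(wfp_all$bands) >= 5L]
  wfp <- subset_bands(wfp_all, keep_w)
  mapW <- stage("wgp_map", {
    prelim <- build_contigs(wfp, pw)
    chim <- detect_chimeras(prelim)
    if (length(chim))
      prelim <- build_contigs(subset_bands(wfp, setdiff(keep_w, chim)), pw)
    end_merge(dq_resplit(prelim))
  })
  groups <- stage("integrate", link_and_group(mapA, mapW))
  # haplotype mixing among anchored contigs
  anch_df <- do.call(rbind, lapply(anchors, function(a)
    if (a$status == "anchored")
      data.frame(marker_id = a$marker_id, contig_id = a$contig_id) else NULL))
  mixing <- NULL
  if (!is.null(anch_df) && nrow(anch_df)) {
    anch_df$phase <- markers$phase[match(anch_df$marker_id,
                                         markers$marker_id)]
    mixing <- haplotype_mixing_table(anch_df, mapA)
  }
  spectrum <- tag_spectrum(fpr$tags)
  mix_fit <- if (sum(spectrum$n_tags) > 200)
    tryCatch(fit_mixture(spectrum), error = function(e) NULL) else NULL
  statsA <- map_stats(mapA)
  statsW <- map_stats(mapW)
  truth_ge <- sum(as.numeric(clones$end_bp - clones$start_bp)) /
    config$genome_length_bp
  report <- list(
    config = list(genome_mb = config$genome_length_bp / 1e6,
                  het_fraction = config$het_fraction,
                  n_clones = nrow(clones), seed = config$rng_seed),
    truth = list(coverage_ge = round(truth_ge, 1),
                 n_markers = nrow(markers)),
    qc = list(excluded = nrow(qc$report),
              contaminations_flagged = length(unique(cont$clone_id)),
              contaminations_true = nrow(art$flags)),
    aflp_map = statsA, wgp_map = statsW,
    aflp_inflation = round(statsA$total_mb /
                             (config$genome_length_bp / 1e6), 2),
    wgp_inflation = round(statsW$total_mb /
                            (config$genome_length_bp / 1e6), 2),
    anchoring = list(attempted = length(anchors),
                     status_counts = as.list(table(vapply(anchors, `[[`,
                                                          "", "status"))),
                     anchored = sum(vapply(anchors, `[[`, "",
                                           "status") == "anchored"),
                     success_rate_pct = val$success_rate_pct,
                     error_rate_pct = val$error_rate_pct),
    integration = list(n_links = nrow(groups$links),
                       n_pair_groups = groups$n_pair_groups,
                       n_multi_groups = groups$n_multi_groups,
                       enhanced_count_aflp = groups$enhanced_count_a,
                       enhanced_count_wgp = groups$enhanced_count_w),
    haplotype_mixing = mixing,
    tag_mixture_fit = if (!is.null(mix_fit))
      list(G = round(mix_fit$G, 2), w = round(mix_fit$w, 3)) else NULL,
    elapsed_s = round(proc.time()[3L] - t0, 1))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_hybrid_table(mapA, mapW, groups, anchors, markers,
                       file.path(output_dir, "hybrid_map.tsv"))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  report
}
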