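test_that("unrelated fingerprints stay singletons", {
  set.seed(4)
  # disjoint mobility blocks: no significant overlaps
  bands <- lapply(0:4, function(i) sort(seq(1000L + i * 1100L,
                                            1999L + i * 1100L, by = 50L)))
  names(bands) <- sprintf("S%d", 1:5)
  map <- build_contigs(band_set(bands), assembly_params("aflp"))
  expect_length(map$contigs, 0L)
  expect_setequal(map$singletons, names(bands))
})

test_that("three clones tiling a region form one ordered contig", {
  set.seed(9)
  # loci spaced > 2 * tolerance apart so no two loci co-migrate
  mobs <- sample(seq(1000L, 6500L, by = 12L), 60)
  fps <- tiling_fps(3, loci_per_clone = 30, step = 15, mobs = mobs)
  map <- build_contigs(fps, assembly_params("aflp"))
  expect_length(map$contigs, 1L)
  ct <- map$contigs[[1L]]
  expect_setequal(ct$members, c("T01", "T02", "T03"))
  expect_identical(ct$members[order(ct$offsets)], c("T01", "T02", "T03"))
  # consensus bands cover all 60 loci
  expect_equal(ct$cb_length, 60L)
  expect_length(identify_questionable(ct), 0L)
})

test_that("contigs and singletons partition the clones at every stage", {
  w <- tiny_world(seed = 2L)
  qc <- preprocess(w$fps)
  ids <- names(qc$kept$bands)
  for (map in list(m1 <- build_contigs(qc$kept, assembly_params("aflp")),
                   m2 <- dq_resplit(m1),
                   end_merge(m2))) {
    got <- c(unlist(lapply(map$contigs, `[[`, "members")), map$singletons)
    expect_setequal(got, ids)
    expect_equal(anyDuplicated(got), 0L)
  }
})

test_that("a forced chimeric clone is flagged questionable", {
  set.seed(21)
  mobs <- sample(1000:6500, 90)
  # two tiling groups far apart in locus space plus a low-band clone whose
  # bands are mostly chance-level vs the consensus
  g1 <- tiling_fps(4, 30, 10, mobs)
  odd <- band_set(c(g1$bands,
                    list(QX = sort(c(mobs[1:12], sample(1000:6500, 18))))))
  map <- build_contigs(odd, assembly_params("aflp",
                                            build_cutoff = 1e-6,
                                            merge_cutoffs = 1e-6,
                                            dq_cutoffs = 1e-8))
  ct <- map$contigs[[which(vapply(map$contigs, function(x)
    "QX" %in% x$members, TRUE))]]
  expect_true("QX" %in% identify_questionable(ct))
})

test_that("dq_resplit dissolves Q-rich contigs and conserves clones", {
  w <- tiny_world(seed = 8L)
  qc <- preprocess(w$fps)
  map <- build_contigs(qc$kept, assembly_params("aflp"))
  re <- dq_resplit(map)
  n_clones <- function(m) length(unlist(lapply(m$contigs, `[[`,
                                               "members"))) +
    length(m$singletons)
  expect_equal(n_clones(re), n_clones(map))
  # a map with no Q-heavy contigs is untouched
  ok <- map
  ok$contigs <- Filter(function(ct) length(ct$q_clones) <=
                         map$params$dq_max_q, ok$contigs)
  expect_equal(length(dq_resplit(ok)$contigs), length(ok$contigs))
})

test_that("end_merge joins contigs split by a coverage gap and never
           increases the contig count", {
  set.seed(31)
  mobs <- sample(1000:6500, 200)
  # two tiling runs whose junction pair overlaps more weakly (20 loci) than
  # the within-run neighbours (25 loci): pick cut-offs between the two
  # scores so the junction only closes during end merging
  left <- tiling_fps(4, 40, 15, mobs)
  right0 <- tiling_fps(4, 40, 15, mobs[66:200])
  names(right0$bands) <- sprintf("U%02d", 1:4)
  fps <- band_set(c(left$bands, right0$bands))
  p0 <- assembly_params("aflp")
  s_adj <- sulston_score(fps$bands$T01, fps$bands$T02, p0)$S
  s_bridge <- sulston_score(fps$bands$T04, fps$bands$U01, p0)$S
  expect_lt(s_adj, s_bridge)
  build <- 10^mean(log10(c(s_adj, s_bridge)))
  params <- assembly_params("aflp", build_cutoff = build,
                            dq_cutoffs = build / 100,
                            merge_cutoffs = s_bridge * 10,
                            min_merge_shared = 1L)
  map <- build_contigs(fps, params)
  expect_gte(length(map$contigs), 2L)
  merged <- end_merge(map)
  expect_lte(length(merged$contigs), length(map$contigs))
  expect_length(merged$contigs, 1L)
})

test_that("map_stats reproduces the published length arithmetic", {
  fake_map <- function(cb_lengths, n_singles = 0L) {
    contigs <- lapply(seq_along(cb_lengths), function(i)
      list(id = i, members = sprintf("C%d_%d", i, 1:3),
           offsets = c(0L, 10L, 20L),
           cb = list(), cb_length = cb_lengths[i], q_clones = character()))
    structure(list(contigs = contigs,
                   singletons = sprintf("S%d", seq_len(n_singles)),
                   fps = band_set(stats::setNames(
                     rep(list(c(1000L, 2000L)),
                         3 * length(cb_lengths) + n_singles),
                     c(sprintf("C%d_%d", rep(seq_along(cb_lengths),
                                             each = 3), 1:3),
                       if (n_singles) sprintf("S%d", seq_len(n_singles))))),
                   params = assembly_params("aflp")),
              class = "physical_map")
  }
  # 391465 aligned bands x 3477 bp -> 1361 Mb
  st <- map_stats(fake_map(c(200000L, 191465L)))
  expect_equal(st$total_mb, 1361)
  # 401465 x 3477 -> 1396 Mb and inflation 1396/850 -> 1.64
  st2 <- map_stats(fake_map(c(200000L, 201465L)))
  expect_equal(st2$total_mb, 1396)
  expect_equal(st2$inflation, 1.64)
  # N50 of equal lengths is that length
  st3 <- map_stats(fake_map(rep(2876L, 4)))  # 2876 bands = 10000 kb
  expect_equal(st3$n50_kb, 10000)
  # size-class histogram counts contigs by member count
  expect_equal(unname(st3$size_class_hist["3-9"]), 4L)
})

test_that("empty map yields zero statistics", {
  map <- structure(list(contigs = list(), singletons = character(),
                        fps = band_set(stats::setNames(list(), character())),
                        params = assembly_params("aflp")),
                   class = "physical_map")
  st <- map_stats(map)
  expect_equal(st$total_mb, 0)
  expect_equal(st$n50_kb, 0)
})
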