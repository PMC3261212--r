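test_that("simulation is deterministic under the config seed", {
  cfg <- simulation_config(genome_length_bp = 1e6, n_chromosomes = 1L,
                           n_markers = 5L, rng_seed = 99L)
  run <- function() {
    g <- simulate_genome(cfg)
    cl <- simulate_bac_library(g)
    f <- fingerprint_clones(cl, g)
    list(g$fragments, cl, f$fps$bands, f$tags)
  }
  expect_identical(run(), run())
})

test_that("homozygous limit yields byte-identical haplotypes", {
  cfg <- simulation_config(genome_length_bp = 1e6, n_chromosomes = 1L,
                           het_fraction = 0, rng_seed = 1L)
  g <- simulate_genome(cfg)
  expect_true(all(g$fragments$shared))
  expect_true(all(is.na(g$fragments$haplotype)))
})

test_that("haplotype-specific fragment and tag fractions track het_fraction", {
  # smaller divergence blocks tighten the block-level sampling variance
  cfg <- simulation_config(genome_length_bp = 2e7, n_chromosomes = 2L,
                           het_fraction = 0.54, het_block_bp = 5e4,
                           rng_seed = 12L)
  g <- simulate_genome(cfg)
  frac_specific <- mean(!g$fragments$shared)
  expect_lt(abs(frac_specific - 0.54), 0.1)
  # tags in exactly one haplotype == haplotype-specific fragments
  tag_het <- mean(!g$fragments$shared)
  expect_equal(tag_het, frac_specific)
})

test_that("fragment lengths have the stated mean and right skew", {
  cfg <- simulation_config(genome_length_bp = 4e7, n_chromosomes = 2L,
                           het_fraction = 0, rng_seed = 5L)
  g <- simulate_genome(cfg)
  len <- g$fragments$end_bp - g$fragments$start_bp
  expect_gte(length(len), 1e4)
  expect_lt(abs(mean(len) - 3477) / 3477, 0.05)
  skew <- mean((len - mean(len))^3) / stats::sd(len)^3
  expect_gt(skew, 0)
  # ~2876 fragments per haplotype on a 10 Mb genome
  g10 <- simulate_genome(simulation_config(genome_length_bp = 1e7,
                                           n_chromosomes = 1L,
                                           het_fraction = 0, rng_seed = 2L))
  expect_lt(abs(max(g10$fragments$slot_id) - 2876) / 2876, 0.05)
  expect_error(simulate_genome(simulation_config(genome_length_bp = 5000,
                                                 n_chromosomes = 1L)),
               "too short")
})

test_that("BAC libraries respect layout, coverage, and digestion mode", {
  cfg <- simulation_config(
    genome_length_bp = 1e7, n_chromosomes = 2L, rng_seed = 3L,
    clone_libraries = list(
      list(name = "RH", digestion_mode = "partial_digest",
           clone_size_mean_kb = 130, clone_size_sd_kb = 10,
           n_clones = 770L)))
  g <- simulate_genome(cfg)
  cl <- simulate_bac_library(g)
  expect_equal(nrow(cl), 770L)
  # coverage close to 10 genome equivalents
  ge <- sum(as.numeric(cl$end_bp - cl$start_bp)) / 1e7
  expect_lt(abs(ge - 10) / 10, 0.05)
  # exact coverage identity from the truth table
  expect_equal(ge, sum(as.numeric(cl$end_bp - cl$start_bp)) /
                 cfg$genome_length_bp)
  # sequential row-major plate filling: first well A01, 385th clone on
  # plate 2, clone 384 in well P24
  expect_equal(cl$well[1], "A01")
  expect_equal(cl$plate[385], 2L)
  expect_equal(cl$well[384], "P24")
  expect_equal(cl$qpp[1], "001Q1")
  # partial-digest clone ends coincide with fragment boundaries
  b <- g$fragments[g$fragments$chrom == cl$chromosome[1], ]
  expect_true(cl$start_bp[1] %in% c(0, b$start_bp))
  expect_true(cl$end_bp[1] %in% c(b$end_bp, g$chrom_lengths[1]))
  # haplotypes drawn from both
  expect_setequal(unique(cl$haplotype), 0:1)
})

test_that("empty library spec yields an empty clone table", {
  cfg <- simulation_config(genome_length_bp = 1e6, n_chromosomes = 1L,
                           clone_libraries = list(
                             list(name = "RH",
                                  digestion_mode = "sheared",
                                  clone_size_mean_kb = 90,
                                  clone_size_sd_kb = 5, n_clones = 0L)),
                           rng_seed = 1L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(simulate_bac_library(g)), 0L)
})

test_that("fingerprints contain contained fragments with sizing noise", {
  w <- tiny_world(het = 0, seed = 6L, noise = 0)
  # noise-free fingerprints over an identical interval are identical
  cl <- w$clones[1:2, ]
  cl$start_bp <- c(100000L, 100000L); cl$end_bp <- c(230000L, 230000L)
  cl$haplotype <- c(0L, 0L); cl$chromosome <- c(1L, 1L)
  f2 <- fingerprint_clones(cl, w$genome, w$cfg)
  expect_identical(f2$fps$bands[[1L]], f2$fps$bands[[2L]])
  # a clone containing no full fragment has an empty fingerprint
  cl$start_bp[1] <- 1000L; cl$end_bp[1] <- 1200L
  expect_length(fingerprint_clones(cl[1, ], w$genome, w$cfg)$fps$bands[[1L]],
                0L)
  # expected band count ~ clone_kb / 3.477 on homozygous clones
  nb <- lengths(w$fps$bands)
  len_kb <- (w$clones$end_bp - w$clones$start_bp) / 1000
  expect_lt(abs(mean(nb / (len_kb / 3.477)) - 1), 0.15)
})

test_that("markers are unique haplotype-specific dominant alleles", {
  w <- tiny_world(seed = 10L)
  mk <- sample_markers(w$genome, w$cfg, seed = 10L)
  expect_equal(nrow(mk), 20L)
  expect_equal(anyDuplicated(mk$slot_id), 0L)
  expect_true(all(mk$phase %in% 0:1))
  frag <- w$genome$fragments
  expect_true(all(!frag$shared[match(mk$frag_id, frag$frag_id)]))
  # radioactive size inverts the capillary shift model
  expect_lt(max(abs(mk$capillary_true_bp -
                    (mk$radioactive_size_bp +
                     physmapr:::sim_size_shift(mk$radioactive_size_bp)))),
            0.06)
  # hom genome cannot host heterozygous markers
  hom <- tiny_world(het = 0, seed = 1L)
  expect_error(sample_markers(hom$genome, hom$cfg), "exceeds")
})

test_that("artifact injection matches the configured rates and is exact
           at rate zero", {
  w <- tiny_world(seed = 13L)
  cfg0 <- w$cfg; cfg0$contamination <- c(0, 0, 0)
  same <- inject_artifacts(w$fps, w$clones, cfg0, seed = 1L)
  expect_identical(same$fps$bands, w$fps$bands)
  expect_equal(nrow(same$flags), 0L)
  # rates: ~3.8% chloroplast flags among ~1000 clones (binomial range)
  big <- simulation_config(genome_length_bp = 8e6, n_chromosomes = 1L,
                           rng_seed = 13L)
  gb <- simulate_genome(big); cb <- simulate_bac_library(gb)
  fb <- fingerprint_clones(cb, gb)
  art <- inject_artifacts(fb$fps, cb, big, seed = 13L)
  n <- length(fb$fps$bands)
  n_cp <- sum(art$flags$flag == "chloroplast")
  expect_lt(abs(n_cp - 0.038 * n), 3 * sqrt(n * 0.038 * 0.962) + 1)
  # neighbour-mixed fingerprints contain all of their own original bands
  mixed <- art$flags$clone_id[art$flags$flag == "contaminated"]
  for (id in utils::head(mixed, 5)) {
    expect_true(all(fb$fps$bands[[id]] %in% art$fps$bands[[id]]))
    expect_gte(length(art$fps$bands[[id]]), length(fb$fps$bands[[id]]))
  }
})

test_that("simulation files round-trip through the plain-text formats", {
  w <- tiny_world(seed = 4L)
  mk <- sample_markers(w$genome, w$cfg, seed = 4L)
  dir <- withr::local_tempdir()
  write_simulation(list(fps = w$fps, tags = w$tags, clones = w$clones,
                        markers = mk), dir)
  back <- read_bands_file(file.path(dir, "fingerprints.bands"))
  expect_identical(back$bands, w$fps$bands)
  tg <- strsplit(readLines(file.path(dir, "wgp_tags.tsv")), "\t")
  expect_equal(length(tg), length(w$tags))
  expect_identical(vapply(tg, `[`, "", 1L), names(w$tags))
})
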