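# Shared fixtures and independent oracles.

# Worked-example pooling design: three QPPs with known k-sets.
fixture_design <- function() {
  d <- generate_design(n_qpp = 3, v = 90, k = 4, seed = 1, balanced = FALSE,
                       qpp_ids = c("QPP1", "QPP25", "QPP235"))
  d$assignment["QPP1", ] <- c(1L, 2L, 3L, 4L)
  d$assignment["QPP25", ] <- c(3L, 4L, 5L, 6L)
  d$assignment["QPP235", ] <- c(5L, 6L, 7L, 90L)
  d
}

# Literal binomial-sum Sulston oracle (independent of pbinom).
sulston_oracle <- function(m, nL, nH, tol, gl) {
  p <- (2 * tol + 1) / gl
  q <- 1 - (1 - p)^nH
  j <- seq.int(m, nL)
  sum(choose(nL, j) * q^j * (1 - q)^(nL - j))
}

# Random sorted fingerprint of n bands over the AFLP window.
random_fp <- function(n, lo = 1000L, hi = 6500L) {
  sort(sample(seq.int(lo, hi), n))
}

# Small simulated world shared by several tests (2 Mb, one chromosome).
tiny_world <- function(het = 0.54, seed = 1L, noise = 0.3, ...) {
  cfg <- simulation_config(genome_length_bp = 2e6, n_chromosomes = 1L,
                           het_fraction = het, sizing_noise_sd_bp = noise,
                           n_markers = 20L, rng_seed = seed, ...)
  genome <- simulate_genome(cfg)
  clones <- simulate_bac_library(genome)
  fpr <- fingerprint_clones(clones, genome)
  list(cfg = cfg, genome = genome, clones = clones, fps = fpr$fps,
       tags = fpr$tags)
}

# Hand-built band_set of clones tiling a region: clone i carries loci
# i..i+len-1 from a shared pool of locus mobilities.
tiling_fps <- function(n_clones, loci_per_clone, step, mobs) {
  bands <- lapply(seq_len(n_clones), function(i) {
    idx <- seq.int((i - 1) * step + 1, (i - 1) * step + loci_per_clone)
    sort(mobs[idx])
  })
  names(bands) <- sprintf("T%02d", seq_len(n_clones))
  band_set(bands)
}
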