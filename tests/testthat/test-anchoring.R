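test_that("size conversion fits the piecewise shift and recovers truth", {
  # identity pairs -> zero shift
  id_pairs <- data.frame(radioactive_bp = seq(100, 600, by = 25))
  id_pairs$capillary_bp <- id_pairs$radioactive_bp
  cal <- fit_size_conversion(id_pairs)
  expect_lt(abs(cal$intercept), 1e-8)
  expect_lt(abs(cal$slope), 1e-8)
  pr <- predict(cal, c(150, 500))
  expect_equal(pr$capillary_bp, c(150, 500))
  # recovery: flat shift below 450 rising to +20 at 600, with gel noise
  set.seed(8)
  rad <- runif(80, 100, 600)
  shift <- 20 / 150 * pmax(0, rad - 450)
  pairs <- data.frame(radioactive_bp = rad,
                      capillary_bp = rad + shift + rnorm(80, 0, 0.3))
  cal2 <- fit_size_conversion(pairs)
  expect_lt(abs(predict(cal2, 600)$capillary_bp - 620), 1)
  # interval width clamped to 0.2-0.4 bp
  expect_gte(cal2$interval_width, 0.2)
  expect_lte(cal2$interval_width, 0.4)
  expect_gte(cal$interval_width, 0.2)
  # degenerate strongly decreasing data is rejected as non-monotone
  bad <- data.frame(radioactive_bp = c(100, 300, 460, 480, 500, 600))
  bad$capillary_bp <- c(100, 300, 460, 200, 150, 50)
  expect_error(fit_size_conversion(bad), "non-monotone")
  expect_error(fit_size_conversion(id_pairs[1:3, ]), "at least 4")
})

test_that("marker scoring in superpools uses closed intervals", {
  set.seed(15)
  bands <- lapply(1:90, function(i)
    sort(sample(setdiff(1000:6500, 3230:3250), 60)))
  names(bands) <- sprintf("SP%02d", 1:90)
  # plant 324.1 bp (3241 units) in 31 superpools
  planted <- sample(90, 31)
  for (i in planted) bands[[i]] <- sort(c(bands[[i]][abs(bands[[i]] - 3241)
                                                     > 5], 3241L))
  sp <- band_set(bands)
  r <- score_marker_in_superpools(sp, c(324.0, 324.3))
  expect_setequal(r$positives, planted)
  expect_equal(r$avg_size_bp, 324.1)
  expect_equal(r$status, "ok")
  # closed boundary: a band exactly at the interval end counts
  one <- band_set(list(SP1 = 3243L))
  expect_equal(score_marker_in_superpools(one, c(324.0, 324.3))$positives,
               1L)
  # no in-interval band anywhere -> failed
  expect_equal(score_marker_in_superpools(one, c(500.0, 500.4))$status,
               "failed")
  # neighbouring-band interference -> unusable
  dense <- band_set(list(SP1 = c(3240L, 3242L), SP2 = c(3240L, 3243L)))
  expect_equal(score_marker_in_superpools(dense, c(324.0, 324.3))$status,
               "unusable")
})

make_anchor_world <- function() {
  # two contigs of 4 clones; marker band 3241 planted in contig 1 clones
  set.seed(30)
  mobs <- sample(setdiff(1000:6500, 3230:3250), 200)
  c1 <- tiling_fps(4, 40, 15, mobs[1:85])
  names(c1$bands) <- sprintf("RH001A%02d", 1:4)
  c2 <- tiling_fps(4, 40, 15, mobs[86:170])
  names(c2$bands) <- sprintf("RH001B%02d", 1:4)
  bands <- c(c1$bands, c2$bands)
  for (i in 1:3) bands[[i]] <- sort(c(bands[[i]], 3241L))
  fps <- band_set(bands)
  map <- build_contigs(fps, assembly_params("aflp"))
  qpp <- stats::setNames(c(rep("001Q1", 2), rep("001Q2", 2),
                           rep("002Q1", 2), rep("002Q2", 2)),
                         names(bands))
  d <- generate_design(n_qpp = 4, v = 90, k = 4, seed = 2,
                       qpp_ids = c("001Q1", "001Q2", "002Q1", "002Q2"))
  list(map = map, qpp = qpp, design = d)
}

test_that("keymaps_anchor places markers on the supported contig", {
  w <- make_anchor_world()
  dec <- deconvolute(sort(unique(as.vector(
    w$design$assignment[c("001Q1", "001Q2"), ]))), w$design)
  a <- keymaps_anchor(324.1, dec, w$map, w$qpp, marker_id = "MK1")
  expect_s3_class(a, "anchor_record")
  expect_equal(a$status, "anchored")
  expect_setequal(a$positive_clones,
                  c("RH001A01", "RH001A02", "RH001A03"))
  expect_equal(a$n_candidate_qpps, length(dec$candidates))
  # marker band absent everywhere -> failed
  a2 <- keymaps_anchor(500.0, dec, w$map, w$qpp)
  expect_equal(a2$status, "failed")
  # single candidate QPP -> omitted
  dec1 <- deconvolute(w$design$assignment["001Q1", ], w$design)
  expect_equal(keymaps_anchor(324.1, dec1, w$map, w$qpp)$status,
               "omitted_single_qpp")
})

test_that("anchoring never uses contigs below the clone threshold", {
  w <- make_anchor_world()
  dec <- deconvolute(sort(unique(as.vector(
    w$design$assignment[c("001Q1", "001Q2"), ]))), w$design)
  a <- keymaps_anchor(324.1, dec, w$map, w$qpp, min_clones = 4L)
  expect_equal(a$status, "failed")
})

test_that("anchor validation flags conflicting anchors and rates", {
  mk <- data.frame(marker_id = sprintf("M%d", 1:5),
                   chromosome = c(1L, 1L, 2L, 1L, 1L),
                   bin = c(10L, 12L, 50L, 11L, 40L))
  rec <- function(id, contig, status = "anchored")
    structure(list(marker_id = id, contig_id = contig,
                   positive_clones = c("X1", "X2"),
                   n_candidate_qpps = 3L, n_matched_qpps = 2L,
                   status = status), class = "anchor_record")
  # contig 1 carries M1, M2 (chr1, close), M3 (chr2: invalid) and
  # M5 (chr1 but 30 bins away: invalid); M4 alone on contig 2
  anchors <- list(rec("M1", 1L), rec("M2", 1L), rec("M3", 1L),
                  rec("M4", 2L), rec("M5", 1L))
  v <- validate_and_summarize(anchors, mk, map = NULL)
  expect_setequal(v$invalid, c("M3", "M5"))
  expect_equal(v$success_rate_pct, 100)
  expect_equal(v$error_rate_pct, anchor_rate_pct(2, 5))
  # all concordant -> nothing invalid
  v2 <- validate_and_summarize(list(rec("M1", 1L), rec("M2", 1L)), mk,
                               map = NULL)
  expect_length(v2$invalid, 0L)
  expect_equal(v2$per_chromosome$markers, 2L)
})

test_that("published rate arithmetic", {
  expect_equal(anchor_rate_pct(50, 1770), 2.8)
  expect_equal(anchor_rate_pct(12781, 65919), 19.4)
  expect_equal(anchor_rate_pct(3, 0), 0)
})
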