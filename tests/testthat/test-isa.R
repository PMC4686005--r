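# Helper: similarity maps with prescribed constant values per atlas.
const_simmaps <- function(vals, d) {
  lapply(vals, function(v)
    structure(list(values = array(v, d), sigma_g = 2,
                   atlas_id = NA, condition = NA), class = "vx_simmap"))
}

test_that("within-database ranking is descending and stable", {
  d <- c(3, 3, 3)
  roi <- full_roi(d)
  rf <- rank_in_database(const_simmaps(c(0.9, 0.2, 0.5), d), roi)
  expect_equal(unique(rf$ranks[, 1]), 0L)
  expect_equal(unique(rf$ranks[, 2]), 2L)
  expect_equal(unique(rf$ranks[, 3]), 1L)

  single <- rank_in_database(const_simmaps(0.4, d), roi)
  expect_true(all(single$ranks == 0L))

  tie <- rank_in_database(const_simmaps(c(0.5, 0.5), d), roi)
  expect_true(all(tie$ranks[, 1] == 0L))
  expect_true(all(tie$ranks[, 2] == 1L))

  # undefined voxels rank among defined atlases only
  maps <- const_simmaps(c(0.9, 0.2), d)
  maps[[1]]$values[1] <- NA
  rf2 <- rank_in_database(maps, roi)
  expect_true(is.na(rf2$ranks[1, 1]))
  expect_equal(rf2$ranks[1, 2], 0L)
})

test_that("rank weights decay exponentially from one", {
  d <- c(2, 2, 2)
  rf <- rank_in_database(const_simmaps(c(0.9, 0.5, 0.1), d), full_roi(d))
  w <- ranks_to_weights(rf, beta = 0.5)
  expect_equal(unique(w[, 1]), 1)
  expect_equal(unique(w[, 3]), exp(-1), tolerance = 1e-12)
  expect_true(all(w[, 1] > w[, 2] & w[, 2] > w[, 3]))

  rf$ranks[1, 2] <- NA
  expect_equal(ranks_to_weights(rf)[1, 2], 0)
})

# Atlas volume whose ROI intensities are already standardised (mean 0,
# population sd 1), so the fusion step's internal z-scoring is the identity
# and hand-picked voxel values survive into the weighted average.
unitized_atlas <- function(first_value, n, d, roi_idx, seed) {
  set.seed(seed)
  vals <- c(first_value, stats::rnorm(n - 1))
  vals <- (vals - mean(vals)) / sqrt(mean((vals - mean(vals))^2))
  arr <- array(0, d)
  arr[roi_idx] <- vals
  vol(arr)
}

test_that("fusion reproduces the rank-weighted average exactly", {
  d <- c(10, 10, 10)
  roi_arr <- array(FALSE, d)
  roi_idx <- 1:1000
  roi_arr[roi_idx] <- TRUE
  roi <- msk(roi_arr)
  n <- length(roi_idx)

  # three atlases with ROI values standardised, first-voxel values scaled
  # from (10, 20, 30); ranks fixed to (0, 1, 2) everywhere
  a1 <- unitized_atlas(10, n, d, roi_idx, seed = 1)
  a2 <- unitized_atlas(20, n, d, roi_idx, seed = 2)
  a3 <- unitized_atlas(30, n, d, roi_idx, seed = 3)
  v1 <- a1$data[1]; v2 <- a2$data[1]; v3 <- a3$data[1]
  mapped <- lapply(list(a1, a2, a3), function(v)
    structure(list(condition = "x", id = "a", image = v,
                   mask = roi, provenance = list(backend = "identity")),
              class = "vx_mapped_atlas"))
  rf <- rank_in_database(const_simmaps(c(0.9, 0.5, 0.1), d), roi)
  w <- ranks_to_weights(rf, beta = 0.5)
  syn <- synthesize(mapped, w, roi)

  want <- (v1 + v2 * exp(-0.5) + v3 * exp(-1)) / (1 + exp(-0.5) + exp(-1))
  expect_equal(syn$values[1], want, tolerance = 1e-9)
  # direct evaluation of the fusion formula on raw values (10, 20, 30) with
  # weights (1, e^-0.5, e^-1): the frozen hand-computed oracle value
  direct <- (10 + 20 * exp(-0.5) + 30 * exp(-1)) / (1 + exp(-0.5) + exp(-1))
  expect_equal(direct, 16.7984333217, tolerance = 1e-9)

  # single atlas: fusion returns its z-scored image on the ROI
  syn1 <- synthesize(mapped[1], matrix(1, n, 1), roi)
  expect_equal(syn1$values[roi_idx], zscore(a1, roi)$data[roi_idx],
               tolerance = 1e-12)

  # equal weights: plain mean of the z-scored images
  syn2 <- synthesize(mapped, matrix(1, n, 3), roi)
  zs <- vapply(list(a1, a2, a3), function(v) zscore(v, roi)$data[roi_idx],
               numeric(n))
  expect_equal(syn2$values[roi_idx], rowMeans(zs), tolerance = 1e-12)
})

test_that("fusion output is convex in the contributing intensities", {
  d <- c(8, 8, 8)
  set.seed(50)
  roi <- full_roi(d)
  mapped <- lapply(1:4, function(i)
    structure(list(condition = "x", id = paste0("a", i),
                   image = vol(array(rnorm(prod(d)), d)),
                   mask = roi, provenance = NULL), class = "vx_mapped_atlas"))
  w <- matrix(runif(prod(d) * 4), ncol = 4)
  syn <- synthesize(mapped, w, roi)
  zs <- vapply(mapped, function(a) zscore(a$image, roi)$data[1:prod(d)],
               numeric(prod(d)))
  lo <- apply(zs, 1, min); hi <- apply(zs, 1, max)
  v <- syn$values[1:prod(d)]
  expect_true(all(v >= lo - 1e-10 & v <= hi + 1e-10))
})

test_that("ISA diagnoses a target that belongs to one database", {
  coh <- tiny_cohort()
  target <- coh[[1]]  # a normal subject
  dbs <- lapply(split(seq_along(coh),
                      vapply(coh, `[[`, character(1), "condition")),
                function(ix) lapply(coh[ix], function(s)
                  structure(list(condition = s$condition, id = s$id,
                                 image = s$image, mask = s$true_mask,
                                 provenance = NULL),
                            class = "vx_mapped_atlas")))
  roiset <- build_roi(lapply(dbs, function(db) lapply(db, `[[`, "mask")),
                      threshold = 0.8)
  rpt <- isa_diagnose(dbs, target$image, roiset$roi)
  expect_s3_class(rpt, "vx_report")
  expect_equal(rpt$diagnosis, "normal")
  expect_gt(rpt$ncc_scores$normal, rpt$ncc_scores$switch_a)

  # two identical databases tie and the tie is reported
  dbs2 <- list(a = dbs$normal, b = dbs$normal)
  rpt2 <- isa_diagnose(dbs2, target$image, roiset$roi)
  expect_equal(rpt2$diagnosis, "a")
  expect_match(paste(rpt2$warnings, collapse = " "), "tie")
  expect_equal(rpt2$ncc_scores$a, rpt2$ncc_scores$b, tolerance = 1e-10)
})
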