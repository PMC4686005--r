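# Similarity maps with one value per atlas at a single-voxel grid would
# degenerate, so fabricated maps use a small constant grid per atlas.
cond_simmaps <- function(vals_by_cond, d) {
  lapply(vals_by_cond, function(vals)
    lapply(vals, function(v)
      structure(list(values = array(v, d), sigma_g = 2,
                     atlas_id = NA, condition = NA), class = "vx_simmap")))
}

test_that("pooled ranking selects the global top-T with exact cardinality", {
  d <- c(2, 2, 2)
  roi <- full_roi(d)

  p1 <- pool_rank(cond_simmaps(list(a = 0.3, b = 0.9, c = 0.5), d), roi, T = 1)
  expect_true(all(rowSums(p1$top > 0) == 1))
  expect_true(all(p1$col_condition[p1$top[, 1]] == "b"))

  vals <- list(a = c(0.9, 0.8, 0.7), b = c(0.6, 0.5, 0.4),
               c = c(0.3, 0.2, 0.1))
  p7 <- pool_rank(cond_simmaps(vals, d), roi, T = 7)
  cc <- count_conditions(p7)
  expect_true(all(rowSums(cc$counts) == 7))
  expect_true(all(cc$counts[, "a"] == 3 & cc$counts[, "b"] == 3 &
                    cc$counts[, "c"] == 1))

  expect_warning(pool_rank(cond_simmaps(list(a = 0.1), d), roi, T = 7),
                 "T = 7")
})

test_that("condition counts match a naive tally on random pooled maps", {
  d <- c(4, 4, 2)
  set.seed(60)
  roi <- full_roi(d)
  conds <- c("a", "b", "c")
  vals <- lapply(conds, function(cn)
    lapply(1:4, function(i) {
      v <- array(runif(prod(d)), d)
      v[runif(prod(d)) < 0.15] <- NA  # scattered undefined entries
      structure(list(values = v, sigma_g = 2, atlas_id = NA, condition = NA),
                class = "vx_simmap")
    }))
  names(vals) <- conds
  p <- pool_rank(vals, roi, T = 7)
  cc <- count_conditions(p)

  V <- vapply(unlist(vals, recursive = FALSE),
              function(s) as.numeric(s$values), numeric(prod(d)))
  want <- naive_top_counts(V, rep(conds, each = 4), conds, T = 7)
  expect_equal(unname(cc$counts), unname(want))
  # conservation: total counted equals min(T, defined atlases)
  ndef <- rowSums(!is.na(V))
  expect_equal(rowSums(cc$counts), pmin(7, ndef))
})

test_that("rating rule matches the hand tally for every composition and T", {
  d <- c(1, 1, 1)
  roi <- full_roi(d)
  conds <- c("a", "b", "c")
  for (T in c(1, 3, 5, 7, 9)) {
    comps <- expand.grid(a = 0:T, b = 0:T, c = 0:T)
    comps <- comps[rowSums(comps) == T, , drop = FALSE]
    for (r in seq_len(nrow(comps))) {
      comp <- as.integer(comps[r, ])
      # engineer atlas values so the top-T composition is exactly `comp`:
      # atlases meant to be in the top get values near 1 (descending),
      # the rest distinctly lower
      vals <- list()
      hi <- seq(0.99, 0.90, length.out = T)
      k <- 0
      for (ci in 1:3) {
        vcond <- c()
        if (comp[ci] > 0) {
          vcond <- hi[(k + 1):(k + comp[ci])]
          k <- k + comp[ci]
        }
        vcond <- c(vcond, seq(0.2, 0.1, length.out = 9 - comp[ci]))
        vals[[conds[ci]]] <- vcond
      }
      p <- pool_rank(cond_simmaps(vals, d), roi, T = T)
      cc <- count_conditions(p)
      expect_equal(unname(as.integer(cc$counts[1, ])), comp)
      rm_ <- build_rating_map(cc, T)
      want <- rating_oracle(comp, T)
      expect_equal(rm_$codes[1, 1, 1], as.integer(want),
                   label = sprintf("T=%d comp=(%s)", T,
                                   paste(comp, collapse = ",")))
      # the absolute-majority guard is never violated
      if (want > 0) expect_gte(comp[want], ceiling(T / 2 + 1))
    }
  }
})

test_that("printed-threshold corner cases behave as the formula dictates", {
  expect_equal(majority_threshold(7), 5L)
  expect_equal(majority_threshold(1), 2L)  # unreachable: always UNASSIGNED
  expect_equal(majority_threshold(3), 3L)
  expect_equal(majority_threshold(9), 6L)

  d <- c(1, 1, 1)
  roi <- full_roi(d)
  # T=7, counts {a:5, b:1, c:1} -> assigned to a
  p <- pool_rank(cond_simmaps(list(a = c(0.99, 0.98, 0.97, 0.96, 0.95),
                                   b = c(0.5, 0.1), c = c(0.4, 0.1)), d),
                 roi, T = 7)
  rm1 <- build_rating_map(count_conditions(p))
  expect_equal(rm1$conditions[rm1$codes[1, 1, 1]], "a")

  # T=7, counts {a:4, b:2, c:1} -> UNASSIGNED (4 < 5)
  p2 <- pool_rank(cond_simmaps(list(a = c(0.99, 0.98, 0.97, 0.96),
                                    b = c(0.95, 0.94, 0.1),
                                    c = c(0.93, 0.1)), d), roi, T = 7)
  rm2 <- build_rating_map(count_conditions(p2))
  expect_equal(rm2$codes[1, 1, 1], 0L)

  # threshold override is honoured
  rm3 <- build_rating_map(count_conditions(p2), threshold = 4)
  expect_equal(rm3$conditions[rm3$codes[1, 1, 1]], "a")

  # T=1 with a single defined atlas: the printed threshold (2) cannot be
  # met, so the voxel stays UNASSIGNED
  p4 <- suppressWarnings(pool_rank(cond_simmaps(list(a = 0.9, b = 0.1), d),
                                   roi, T = 1))
  rm4 <- build_rating_map(count_conditions(p4))
  expect_equal(rm4$codes[1, 1, 1], 0L)
})

test_that("rating histogram percentages, separation and refusal semantics", {
  codes <- array(NA_integer_, c(5, 4, 1))
  codes[1:20] <- c(rep(1L, 6), rep(2L, 4), rep(0L, 10))
  r <- structure(list(codes = codes, conditions = c("a", "b"),
                      threshold = 5L, T = 7L), class = "vx_ratingmap")
  h <- rating_histogram(r)
  expect_equal(h$percent$a, 60)
  expect_equal(h$percent$b, 40)
  expect_equal(h$separation, 20)
  expect_equal(h$n_unassigned, 10L)
  expect_equal(sum(unlist(h$percent)), 100, tolerance = 1e-9)

  codes2 <- codes; codes2[codes2 == 2L] <- 1L
  h2 <- rating_histogram(structure(list(codes = codes2,
                                        conditions = c("a", "b"),
                                        threshold = 5L, T = 7L),
                                   class = "vx_ratingmap"))
  expect_equal(h2$percent$a, 100)

  codes3 <- codes; codes3[codes3 > 0L] <- 0L
  expect_warning(
    h3 <- rating_histogram(structure(list(codes = codes3,
                                          conditions = c("a", "b"),
                                          threshold = 5L, T = 7L),
                                     class = "vx_ratingmap")),
    "unassigned")
  expect_length(h3$percent, 0)
})

test_that("diagnosis is equivariant under condition renaming", {
  coh <- tiny_cohort()
  target <- coh[[3]]  # a switch_a subject
  mk_dbs <- function(rename = identity) {
    ix <- split(seq_along(coh), vapply(coh, `[[`, character(1), "condition"))
    ix[["switch_a"]] <- setdiff(ix[["switch_a"]], 3L)
    dbs <- lapply(ix, function(i) lapply(coh[i], function(s)
      structure(list(condition = rename(s$condition), id = s$id,
                     image = s$image, mask = s$true_mask, provenance = NULL),
                class = "vx_mapped_atlas")))
    names(dbs) <- rename(names(dbs))
    dbs
  }
  dbs <- mk_dbs()
  roiset <- build_roi(lapply(dbs, function(db) lapply(db, `[[`, "mask")), 0.8)
  r1 <- voxar_diagnose(target$image, dbs, roiset$roi, T = 3, threshold = 2)

  ren <- function(x) paste0("zz_", x)
  dbs2 <- mk_dbs(ren)
  r2 <- voxar_diagnose(target$image, dbs2, roiset$roi, T = 3, threshold = 2)
  expect_equal(r2$diagnosis, ren(r1$diagnosis))
  expect_equal(unname(unlist(r2$histogram$percent[ren(names(r1$histogram$percent))])),
               unname(unlist(r1$histogram$percent)))
})

test_that("a target duplicated inside a database dominates the histogram", {
  coh <- tiny_cohort()
  target <- coh[[1]]
  ix <- split(seq_along(coh), vapply(coh, `[[`, character(1), "condition"))
  dbs <- lapply(ix, function(i) lapply(coh[i], function(s)
    structure(list(condition = s$condition, id = s$id, image = s$image,
                   mask = s$true_mask, provenance = NULL),
              class = "vx_mapped_atlas")))
  roiset <- build_roi(lapply(dbs, function(db) lapply(db, `[[`, "mask")), 0.8)
  # T = 3 with threshold 2: the duplicated target (LNCC = 1) plus the other
  # same-condition atlas anchor the condition at most voxels
  rpt <- voxar_diagnose(target$image, dbs, roiset$roi, T = 3, threshold = 2)
  expect_equal(rpt$diagnosis, "normal")
  expect_gt(rpt$histogram$percent$normal, 50)
})
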