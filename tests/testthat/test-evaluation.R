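test_that("confusion metrics match hand-computed values on a toy matrix", {
  truth <- c(rep("aso", 4), rep("atrial", 4), rep("normal", 4))
  pred <- c("aso", "aso", "atrial", "aso",        # 3/4 correct
            "atrial", "atrial", "aso", "atrial",  # 3/4 correct
            "normal", "normal", "normal", "aso")  # 3/4 correct
  m <- confusion_metrics(truth, pred, c("aso", "atrial", "normal"), "normal")
  expect_equal(m$accuracy, 9 / 12)
  expect_equal(unname(rowSums(m$confusion)), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(m$confusion["aso", "aso"], 0.75)
  expect_equal(m$confusion["atrial", "aso"], 0.25)
  # pathological-vs-normal: TP=8 (all aso/atrial flagged pathological),
  # FN=0, TN=3, FP=1
  expect_equal(unname(m$binary["sensitivity"]), 1)
  expect_equal(unname(m$binary["specificity"]), 0.75)
  expect_equal(unname(m$binary["ppv"]), 8 / 9)
  expect_equal(unname(m$binary["npv"]), 1)

  # refusals count as wrong everywhere
  pred_na <- pred; pred_na[1] <- NA
  m2 <- confusion_metrics(truth, pred_na, c("aso", "atrial", "normal"),
                          "normal")
  expect_equal(m2$accuracy, 8 / 12)
  expect_equal(unname(m2$binary["sensitivity"]), 7 / 8)
})

test_that("LOOCV produces one diagnosis per subject, deterministically", {
  coh <- tiny_cohort()
  cache <- build_lncc_cache(coh)
  r1 <- loocv(coh, "isa", cache = cache)
  expect_equal(nrow(r1$per_target), 6)
  expect_s3_class(r1, "vx_experiment")
  r2 <- loocv(coh, "isa", cache = cache)
  expect_identical(r1$per_target, r2$per_target)

  spec <- phantom_spec(grid = c(24, 24, 24))
  single <- generate_cohort(spec, c(normal = 1, switch_a = 2), seed = 3)
  expect_error(loocv(single, "voxar"), ">= 2 subjects")
})

test_that("bit-identical subjects of one condition are always recovered", {
  spec <- phantom_spec(grid = c(24, 24, 24))
  coh_dup <- generate_cohort(spec, c(normal = 2, switch_a = 2, switch_b = 3),
                             seed = 42)
  ib <- which(vapply(coh_dup, `[[`, character(1), "condition") == "switch_b")
  for (k in ib[-1]) {
    coh_dup[[k]]$image <- coh_dup[[ib[1]]]$image
    coh_dup[[k]]$true_mask <- coh_dup[[ib[1]]]$true_mask
  }
  # after LOOCV exclusion each switch_b target keeps two bit-identical
  # atlases (LNCC = 1 everywhere); with T = 3 and threshold 2 those two
  # occupy the top ranks and the condition is certain
  r <- loocv(coh_dup, "voxar", T = 3, threshold = 2)
  got <- r$per_target[r$per_target$truth == "switch_b", "predicted"]
  expect_equal(got, rep("switch_b", 3))
})

test_that("cached diagnosis equals the direct pipeline exactly", {
  coh <- tiny_cohort()
  cache <- build_lncc_cache(coh, sigma_g = 2)
  target_ix <- 2L
  conds <- unique(cache$conditions)
  db_ix <- lapply(conds, function(cn) setdiff(which(cache$conditions == cn),
                                              target_ix))
  names(db_ix) <- conds

  cached <- voxar:::diagnose_cached(cache, target_ix, db_ix, "voxar",
                                    T = 3, threshold = 2)

  dbs <- lapply(db_ix, function(ix) lapply(coh[ix], function(s)
    structure(list(condition = s$condition, id = s$id, image = s$image,
                   mask = s$true_mask, provenance = NULL),
              class = "vx_mapped_atlas")))
  roiset <- build_roi(lapply(dbs, function(db) lapply(db, `[[`, "mask")), 0.8)
  direct <- voxar_diagnose(coh[[target_ix]]$image, dbs, roiset$roi,
                           T = 3, threshold = 2)

  expect_equal(cached$diagnosis, direct$diagnosis)
  expect_equal(cached$histogram$n_assigned, direct$histogram$n_assigned)
  expect_equal(cached$histogram$n_unassigned, direct$histogram$n_unassigned)
  expect_equal(unlist(cached$histogram$percent),
               unlist(direct$histogram$percent), tolerance = 1e-12)

  cached_isa <- voxar:::diagnose_cached(cache, target_ix, db_ix, "isa")
  direct_isa <- isa_diagnose(dbs, coh[[target_ix]]$image, roiset$roi)
  expect_equal(cached_isa$diagnosis, direct_isa$diagnosis)
  expect_equal(unlist(cached_isa$ncc_scores), unlist(direct_isa$ncc_scores),
               tolerance = 1e-9)
})

test_that("size sweep and imbalance study are deterministic and validated", {
  coh <- tiny_cohort()
  cache <- build_lncc_cache(coh)
  s1 <- size_sweep(coh, sizes = 1, repeats = 3, method = "isa", seed = 5,
                   cache = cache)
  s2 <- size_sweep(coh, sizes = 1, repeats = 3, method = "isa", seed = 5,
                   cache = cache)
  expect_identical(s1$accuracy, s2$accuracy)
  expect_equal(nrow(s1), 3)
  expect_error(size_sweep(coh, sizes = 5, repeats = 1, cache = cache),
               "exceeds")

  i1 <- imbalance_study(coh, 1, 1, repeats = 2, method = "isa", seed = 5,
                        cache = cache)
  i2 <- imbalance_study(coh, 1, 1, repeats = 2, method = "isa", seed = 5,
                        cache = cache)
  expect_identical(i1$accuracy, i2$accuracy)
  expect_error(imbalance_study(coh, 5, 1, repeats = 1, cache = cache),
               "exceeds")
})

test_that("missing-pathology probe never assigns the held-out label", {
  spec <- phantom_spec(grid = c(24, 24, 24),
                       conditions = c("normal", "switch_a", "switch_b",
                                      "fallot"))
  coh <- generate_cohort(spec, c(normal = 2, switch_a = 2, switch_b = 2,
                                 fallot = 2), seed = 77)
  res <- missing_pathology_probe(coh, "fallot", T = 3, threshold = 2)
  expect_false(any(res$held_out$diagnosis %in% "fallot", na.rm = TRUE))
  expect_equal(nrow(res$held_out), 2)
  expect_equal(nrow(res$baseline), 6)

  expect_error(missing_pathology_probe(coh, "nope"), "not present")
  spec2 <- phantom_spec(grid = c(24, 24, 24),
                        conditions = c("normal", "switch_a"))
  coh2 <- generate_cohort(spec2, c(normal = 2, switch_a = 2), seed = 1)
  expect_error(missing_pathology_probe(coh2, "normal"), "fewer than 2")
})
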