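# Experiment harnesses on common-grid phantom cohorts (identity
# registration). Because LNCC is symmetric in its two images, every
# experiment draws from a single cache of pairwise LNCC maps, which makes
# repeated-subsampling designs (size sweep, imbalance study) tractable: the
# convolutions are done once per subject pair, and each experiment only
# re-fuses masks and re-ranks cached values.

#' Pairwise LNCC cache for a common-grid cohort
#'
#' Precomputes, for every unordered subject pair, the Gaussian-windowed local
#' correlation and its denominator on the union of all subject masks. The
#' near-flat cutoff is applied at query time with the experiment's own ROI,
#' so cached queries agree exactly with the direct [lncc()] path.
#'
#' @param cohort a `vx_cohort` whose subjects share one grid.
#' @param sigma_g LNCC Gaussian window sd in voxels (default 2).
#' @return A `vx_lncc_cache`.
#' @export
build_lncc_cache <- function(cohort, sigma_g = 2) {
  stopifnot(inherits(cohort, "vx_cohort"), length(cohort) >= 2)
  d <- dim(cohort[[1]]$image$data)
  for (s in cohort) check_same_geometry(cohort[[1]]$image, s$image, "cohort images")
  n <- length(cohort)
  masks <- vapply(cohort, function(s) as.logical(s$true_mask$data),
                  logical(prod(d)))
  region <- which(rowSums(masks) > 0)
  nrm <- conv_norm(d, sigma_g)
  imgs <- vapply(cohort, function(s) as.numeric(s$image$data),
                 numeric(prod(d)))
  means <- list(); sds <- list()
  for (i in seq_len(n)) {
    a <- array(imgs[, i], dim = d)
    m <- smooth3d_raw(a, sigma_g) / nrm
    v <- pmax(smooth3d_raw(a^2, sigma_g) / nrm - m^2, 0)
    means[[i]] <- m[region]
    sds[[i]] <- sqrt(v)[region]
  }
  values <- vector("list", n * (n - 1) / 2)
  denoms <- vector("list", n * (n - 1) / 2)
  pk <- function(i, j) {
    lo <- min(i, j); hi <- max(i, j)
    (lo - 1L) * n - lo * (lo - 1L) / 2L + (hi - lo)
  }
  for (i in seq_len(n - 1)) {
    ai <- array(imgs[, i], dim = d)
    for (j in seq((i + 1), n)) {
      aj <- array(imgs[, j], dim = d)
      cv <- (smooth3d_raw(ai * aj, sigma_g) / nrm)[region] -
        means[[i]] * means[[j]]
      den <- sds[[i]] * sds[[j]]
      val <- rep(NA_real_, length(region))
      ok <- den > 0
      val[ok] <- pmin(pmax(cv[ok] / den[ok], -1), 1)
      k <- pk(i, j)
      values[[k]] <- val
      denoms[[k]] <- den
    }
  }
  structure(list(n = n, dim = d, region = region, sigma_g = sigma_g,
                 ids = vapply(cohort, `[[`, character(1), "id"),
                 conditions = vapply(cohort, `[[`, character(1), "condition"),
                 masks = masks, images = imgs,
                 values = values, denoms = denoms, pair_key = pk),
            class = "vx_lncc_cache")
}

# ROI (intersection of per-condition fused masks) as a full-grid logical
# vector, from cached masks. Returns NULL when the intersection is empty.
#' @keywords internal
cached_roi <- function(cache, db_indices, fusion_threshold = 0.8) {
  roi <- NULL
  for (cond in names(db_indices)) {
    cols <- db_indices[[cond]]
    frac <- rowMeans(cache$masks[, cols, drop = FALSE])
    fused <- frac >= fusion_threshold - 1e-12
    roi <- if (is.null(roi)) fused else roi & fused
  }
  if (!any(roi)) return(NULL)
  roi
}

# LNCC values of atlas j against target i at the given region positions,
# with the ROI-specific near-flat cutoff.
#' @keywords internal
cached_lncc_values <- function(cache, i, j, pos, tau) {
  k <- cache$pair_key(i, j)
  v <- cache$values[[k]][pos]
  v[cache$denoms[[k]][pos] <= tau] <- NA_real_
  v
}

# One cached diagnosis. db_indices: named list condition -> cohort indices
# (the target must not appear). Returns a vx_report.
#' @keywords internal
diagnose_cached <- function(cache, target, db_indices,
                            method = c("voxar", "isa"), T = 7, beta = 0.5,
                            fusion_threshold = 0.8, threshold = NULL) {
  method <- match.arg(method)
  stopifnot(!target %in% unlist(db_indices))
  roi_full <- cached_roi(cache, db_indices, fusion_threshold)
  if (is.null(roi_full))
    return(structure(list(method = toupper(method), diagnosis = NULL,
                          refused = TRUE, warnings = "empty ROI intersection"),
                     class = "vx_report"))
  pos <- which(roi_full[cache$region])
  roi_idx <- cache$region[pos]
  conds <- sort(names(db_indices))
  cols <- unlist(lapply(conds, function(cn) db_indices[[cn]]))
  col_condition <- rep(conds, times = vapply(db_indices[conds], length,
                                             integer(1)))
  sd_t <- stats::sd(cache$images[roi_idx, target])
  V <- matrix(NA_real_, length(pos), length(cols))
  for (a in seq_along(cols)) {
    sd_a <- stats::sd(cache$images[roi_idx, cols[a]])
    V[, a] <- cached_lncc_values(cache, target, cols[a], pos,
                                 tau = 1e-6 * sd_t * sd_a)
  }
  if (method == "voxar") {
    top <- row_top_indices_cpp(V, as.integer(T))
    cond_idx <- match(col_condition, conds)
    top_cond <- matrix(NA_integer_, nrow(top), ncol(top))
    nz <- top > 0L
    top_cond[nz] <- cond_idx[top[nz]]
    counts <- vapply(seq_along(conds), function(ci)
      rowSums(top_cond == ci, na.rm = TRUE), numeric(nrow(top)))
    counts <- matrix(counts, nrow = nrow(top))
    if (is.null(threshold)) threshold <- majority_threshold(T)
    maxc <- do.call(pmax, as.data.frame(counts))
    arg <- max.col(counts, ties.method = "first")
    assigned <- maxc >= threshold
    if (!any(assigned))
      return(structure(list(method = "VoxAR", diagnosis = NULL, refused = TRUE,
                            histogram = list(percent = stats::setNames(
                              list(), character(0)),
                              n_assigned = 0L,
                              n_unassigned = length(pos),
                              separation = NA_real_),
                            parameters = list(T = T, threshold = threshold),
                            warnings = "all voxels unassigned"),
                       class = "vx_report"))
    tab <- tabulate(arg[assigned], nbins = length(conds))
    pct <- 100 * tab / sum(assigned)
    names(pct) <- conds
    srt <- sort(pct, decreasing = TRUE)
    sep <- if (length(srt) >= 2) srt[1] - srt[2] else srt[1]
    structure(list(method = "VoxAR",
                   diagnosis = conds[which.max(pct)], refused = FALSE,
                   histogram = list(percent = as.list(pct),
                                    n_assigned = sum(assigned),
                                    n_unassigned = sum(!assigned),
                                    separation = unname(sep)),
                   parameters = list(T = T, sigma_g = cache$sigma_g,
                                     threshold = threshold,
                                     fusion_threshold = fusion_threshold),
                   warnings = character(0)),
              class = "vx_report")
  } else {
    tz <- cache$images[roi_idx, target]
    tz <- (tz - mean(tz)) / sqrt(mean((tz - mean(tz))^2))
    scores <- numeric(0)
    for (cn in conds) {
      sel <- which(col_condition == cn)
      Vc <- V[, sel, drop = FALSE]
      ranks <- row_ranks_desc_cpp(Vc)
      w <- exp(-beta * ranks)
      w[is.na(w)] <- 0
      J <- cache$images[roi_idx, cols[sel], drop = FALSE]
      J <- sweep(J, 2, colMeans(J))
      J <- sweep(J, 2, sqrt(colMeans(J^2)), `/`)
      wsum <- rowSums(w)
      ok <- wsum > 0
      fused <- rowSums(w * J)[ok] / wsum[ok]
      scores[cn] <- stats::cor(tz[ok], fused)
    }
    best <- max(scores)
    winners <- conds[scores >= best - 1e-12]
    structure(list(method = "ISA", diagnosis = winners[1], refused = FALSE,
                   ncc_scores = as.list(scores),
                   parameters = list(beta = beta, sigma_g = cache$sigma_g,
                                     fusion_threshold = fusion_threshold),
                   warnings = if (length(winners) > 1)
                     "NCC tie broken by condition order" else character(0)),
              class = "vx_report")
  }
}

#' Classification metrics from truth/prediction vectors
#'
#' Confusion matrix rows are normalised to sum to one. Binary
#' (pathological-vs-normal) sensitivity, specificity, PPV and NPV are
#' computed against `normal_label`; a refused diagnosis (`NA` prediction)
#' counts as wrong in every metric.
#'
#' @param truth,predicted character vectors (`NA` allowed in `predicted`).
#' @param conditions the full condition set (row/column order).
#' @param normal_label the non-pathological label, or `NA` to skip binary
#'   metrics.
#' @return List with `confusion` (row-normalised matrix), `accuracy` and
#'   `binary` (named vector or `NULL`).
#' @export
confusion_metrics <- function(truth, predicted, conditions,
                              normal_label = "normal") {
  stopifnot(length(truth) == length(predicted))
  cm <- matrix(0, length(conditions), length(conditions),
               dimnames = list(true = conditions, predicted = conditions))
  for (k in seq_along(truth)) {
    if (!is.na(predicted[k]) && predicted[k] %in% conditions)
      cm[truth[k], predicted[k]] <- cm[truth[k], predicted[k]] + 1
  }
  rs <- table(factor(truth, levels = conditions))
  cmn <- sweep(cm, 1, pmax(as.numeric(rs), 1), `/`)
  acc <- mean(!is.na(predicted) & predicted == truth)
  binary <- NULL
  if (!is.na(normal_label) && normal_label %in% conditions) {
    path_true <- truth != normal_label
    # refusals are wrong for both classes
    path_pred <- ifelse(is.na(predicted), !path_true, predicted != normal_label)
    tp <- sum(path_true & path_pred)
    tn <- sum(!path_true & !path_pred)
    fp <- sum(!path_true & path_pred)
    fn <- sum(path_true & !path_pred)
    binary <- c(sensitivity = tp / max(tp + fn, 1),
                specificity = tn / max(tn + fp, 1),
                ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  }
  list(confusion = cmn, accuracy = acc, binary = binary)
}

#' Leave-one-out cross-validated diagnosis over a cohort
#'
#' Each subject in turn is the target; its own entry is removed from its
#' database and all other databases keep full size.
#'
#' @param cohort a common-grid `vx_cohort` (>= 2 subjects per condition).
#' @param method `"voxar"` or `"isa"`.
#' @param T,beta,sigma_g,fusion_threshold,threshold method parameters; see
#'   [voxar_diagnose()] and [isa_diagnose()].
#' @param normal_label label treated as non-pathological for the binary
#'   metrics (default `"normal"`).
#' @param cache optional prebuilt [build_lncc_cache()] for the cohort.
#' @return A `vx_experiment`: list with `per_target` (data.frame: id, truth,
#'   predicted, refused, separation), `confusion`, `accuracy`, `binary`,
#'   `method`, `parameters`.
#' @export
loocv <- function(cohort, method = c("voxar", "isa"), T = 7, beta = 0.5,
                  sigma_g = 2, fusion_threshold = 0.8, threshold = NULL,
                  normal_label = "normal", cache = NULL) {
  method <- match.arg(method)
  conds <- unique(vapply(cohort, `[[`, character(1), "condition"))
  tab <- table(vapply(cohort, `[[`, character(1), "condition"))
  if (any(tab < 2)) stop("every condition needs >= 2 subjects for LOOCV")
  if (is.null(cache)) cache <- build_lncc_cache(cohort, sigma_g)
  rows <- lapply(seq_along(cohort), function(i) {
    dbs <- lapply(conds, function(cn)
      setdiff(which(cache$conditions == cn), i))
    names(dbs) <- conds
    rpt <- diagnose_cached(cache, i, dbs, method, T = T, beta = beta,
                           fusion_threshold = fusion_threshold,
                           threshold = threshold)
    data.frame(id = cache$ids[i], truth = cache$conditions[i],
               predicted = if (rpt$refused) NA_character_ else rpt$diagnosis,
               refused = rpt$refused,
               separation = if (!is.null(rpt$histogram))
                 rpt$histogram$separation else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_target <- do.call(rbind, rows)
  met <- confusion_metrics(per_target$truth, per_target$predicted,
                           sort(conds), normal_label)
  structure(list(per_target = per_target, confusion = met$confusion,
                 accuracy = met$accuracy, binary = met$binary,
                 method = method,
                 parameters = list(T = T, beta = beta, sigma_g = sigma_g,
                                   fusion_threshold = fusion_threshold)),
            class = "vx_experiment")
}

#' Balanced database-size sweep
#'
#' For every database size `s` and repeat, samples `s` atlases per condition
#' uniformly without replacement (always excluding the target), diagnoses
#' every subject, and records the accuracy. Deterministic under the master
#' seed.
#'
#' @inheritParams loocv
#' @param sizes integer vector of per-database sizes.
#' @param repeats number of random subsamplings per size (default 10).
#' @param seed master seed.
#' @return A data.frame: size, repeat_index, accuracy; with attribute
#'   `per_size` (mean and sd of accuracy by size).
#' @export
size_sweep <- function(cohort, sizes, repeats = 10,
                       method = c("voxar", "isa"), seed = 1, T = 7,
                       beta = 0.5, sigma_g = 2, fusion_threshold = 0.8,
                       threshold = NULL, cache = NULL) {
  method <- match.arg(method)
  if (is.null(cache)) cache <- build_lncc_cache(cohort, sigma_g)
  conds <- unique(cache$conditions)
  avail <- table(cache$conditions)
  if (any(max(sizes) > as.numeric(avail) - 1))
    stop("max size exceeds cohort availability (need size <= N-1 per condition)")
  out <- list()
  for (s in sizes) {
    for (l in seq_len(repeats)) {
      preds <- with_seed(seed * 10000L + s * 100L + l, {
        vapply(seq_len(cache$n), function(i) {
          dbs <- lapply(conds, function(cn) {
            pool <- setdiff(which(cache$conditions == cn), i)
            pool[sample.int(length(pool), s)]
          })
          names(dbs) <- conds
          rpt <- diagnose_cached(cache, i, dbs, method, T = T, beta = beta,
                                 fusion_threshold = fusion_threshold,
                                 threshold = threshold)
          if (rpt$refused) NA_character_ else rpt$diagnosis
        }, character(1))
      })
      acc <- mean(!is.na(preds) & preds == cache$conditions)
      out[[length(out) + 1L]] <- data.frame(size = s, repeat_index = l,
                                            accuracy = acc)
    }
  }
  df <- do.call(rbind, out)
  per_size <- stats::aggregate(accuracy ~ size, df,
                               function(x) c(mean = mean(x), sd = stats::sd(x)))
  attr(df, "per_size") <- per_size
  df
}

#' Unbalanced-database study
#'
#' For every subject, the database matching its own condition (the "correct"
#' database) is subsampled to `correct_size` and the remaining databases to
#' `other_sizes`; accuracy is averaged over repeats. `correct_size ==
#' other_sizes` reproduces the balanced design at that size.
#'
#' @inheritParams size_sweep
#' @param correct_size atlases drawn from the target's own database.
#' @param other_sizes atlases drawn from each other database (scalar or one
#'   per other database).
#' @return A data.frame: repeat_index, accuracy; attribute `mean_accuracy`.
#' @export
imbalance_study <- function(cohort, correct_size, other_sizes, repeats = 10,
                            method = c("voxar", "isa"), seed = 1, T = 7,
                            beta = 0.5, sigma_g = 2, fusion_threshold = 0.8,
                            threshold = NULL, cache = NULL) {
  method <- match.arg(method)
  if (is.null(cache)) cache <- build_lncc_cache(cohort, sigma_g)
  conds <- unique(cache$conditions)
  out <- list()
  for (l in seq_len(repeats)) {
    preds <- with_seed(seed * 10000L + l, {
      vapply(seq_len(cache$n), function(i) {
        own <- cache$conditions[i]
        others <- setdiff(conds, own)
        osz <- rep(other_sizes, length.out = length(others))
        dbs <- list()
        pool_own <- setdiff(which(cache$conditions == own), i)
        if (correct_size > length(pool_own))
          stop("correct_size exceeds available atlases for ", own)
        dbs[[own]] <- pool_own[sample.int(length(pool_own), correct_size)]
        for (k in seq_along(others)) {
          pool <- setdiff(which(cache$conditions == others[k]), i)
          if (osz[k] > length(pool))
            stop("other size exceeds available atlases for ", others[k])
          dbs[[others[k]]] <- pool[sample.int(length(pool), osz[k])]
        }
        rpt <- diagnose_cached(cache, i, dbs, method, T = T, beta = beta,
                               fusion_threshold = fusion_threshold,
                               threshold = threshold)
        if (rpt$refused) NA_character_ else rpt$diagnosis
      }, character(1))
    })
    acc <- mean(!is.na(preds) & preds == cache$conditions)
    out[[length(out) + 1L]] <- data.frame(repeat_index = l, accuracy = acc)
  }
  df <- do.call(rbind, out)
  attr(df, "mean_accuracy") <- mean(df$accuracy)
  df
}

#' Missing-pathology probe
#'
#' Diagnoses the subjects of one held-out condition against the databases of
#' the remaining conditions (which can never produce the held-out label), and
#' contrasts their rating-histogram separation with a known-condition
#' baseline (leave-one-out over the remaining subjects).
#'
#' @inheritParams loocv
#' @param held_out_condition condition whose subjects become novel targets.
#' @return List with `held_out` (data.frame: id, diagnosis, separation),
#'   `baseline` (same columns for known-condition LOOCV targets),
#'   `mean_separation_held_out`, `mean_separation_baseline`.
#' @export
missing_pathology_probe <- function(cohort, held_out_condition, T = 7,
                                    sigma_g = 2, fusion_threshold = 0.8,
                                    threshold = NULL, cache = NULL) {
  conds <- unique(vapply(cohort, `[[`, character(1), "condition"))
  if (!held_out_condition %in% conds)
    stop("held-out condition not present in the cohort")
  known <- setdiff(conds, held_out_condition)
  if (length(known) < 2)
    stop("fewer than 2 databases remain after holding out")
  if (is.null(cache)) cache <- build_lncc_cache(cohort, sigma_g)
  ho_idx <- which(cache$conditions == held_out_condition)
  kn_idx <- which(cache$conditions != held_out_condition)
  run <- function(i, exclude_self) {
    dbs <- lapply(known, function(cn) {
      pool <- which(cache$conditions == cn)
      if (exclude_self) pool <- setdiff(pool, i)
      pool
    })
    names(dbs) <- known
    rpt <- diagnose_cached(cache, i, dbs, "voxar", T = T,
                           fusion_threshold = fusion_threshold,
                           threshold = threshold)
    data.frame(id = cache$ids[i],
               diagnosis = if (rpt$refused) NA_character_ else rpt$diagnosis,
               separation = if (!is.null(rpt$histogram))
                 rpt$histogram$separation else NA_real_,
               stringsAsFactors = FALSE)
  }
  held_out <- do.call(rbind, lapply(ho_idx, run, exclude_self = FALSE))
  baseline <- do.call(rbind, lapply(kn_idx, run, exclude_self = TRUE))
  list(held_out = held_out, baseline = baseline,
       mean_separation_held_out = mean(held_out$separation, na.rm = TRUE),
       mean_separation_baseline = mean(baseline$separation, na.rm = TRUE))
}
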