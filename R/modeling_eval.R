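## Model fitting, validation regimes and metrics.
##
## Four regimes: baseline per-target QSAR (molecule bits only, one model
## per target), unified (one joint ligand+protein model, random 80/20
## split, repeated), blind (validation = all rows of held-out targets),
## and semi-blind (held-out targets chosen so each has a structurally
## similar partner remaining in training). The learner is a random-forest
## regressor with 200 trees; metrics are RMSE and RVE = 1 - SSres/SStot
## (may be negative for worse-than-mean models), aggregated across targets
## weighted by test-set size.

#' Random-forest model specification
#'
#' @param n_trees Number of trees (default 200); other hyperparameters are
#'   the learner's defaults.
#' @return A `ModelSpec` list.
#' @export
model_spec <- function(n_trees = 200L) {
  stopifnot(n_trees >= 1)
  structure(list(algorithm = "random_forest_regressor",
                 n_trees = as.integer(n_trees)), class = "ModelSpec")
}

#' Fit a random-forest regressor
#'
#' @param spec A [model_spec()].
#' @param x Numeric feature matrix.
#' @param y Numeric labels.
#' @param seed Seed controlling tree randomness; same seed and data give
#'   identical models.
#' @param num_threads Threads for the forest (default 1 for
#'   reproducibility across thread counts).
#' @return A fitted model object.
#' @export
fit_model <- function(spec, x, y, seed = 1L, num_threads = 1L) {
  stopifnot(inherits(spec, "ModelSpec"), is.matrix(x), nrow(x) == length(y),
            nrow(x) >= 1)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  # regression-forest default feature subsampling: mtry = p/3
  fit <- ranger::ranger(x = x, y = y, num.trees = spec$n_trees,
                        mtry = max(floor(ncol(x) / 3), 1),
                        seed = seed, num.threads = num_threads,
                        verbose = FALSE)
  structure(list(fit = fit, n_features = ncol(x), spec = spec),
            class = "PotencyModel")
}

#' Predict spKi for feature rows
#'
#' Raw regression outputs are returned (not clipped to \[0, 1\]); set
#' `clip = TRUE` for the clipped alternative.
#'
#' @param object A fitted `PotencyModel`.
#' @param x Feature matrix with the training feature length.
#' @param clip Clip predictions into \[0, 1\].
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.PotencyModel <- function(object, x, clip = FALSE, ...) {
  stopifnot(is.matrix(x))
  if (ncol(x) != object$n_features)
    stop("feature length ", ncol(x), " does not match model (",
         object$n_features, ")")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- stats::predict(object$fit, data = x, num.threads = 1)$predictions
  if (clip) p <- pmin(1, pmax(0, p))
  p
}

#' Root mean squared error
#' @param pred,obs Equal-length numeric vectors.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 1)
  sqrt(mean((pred - obs)^2))
}

#' Ratio of variance explained
#'
#' `1 - SSres/SStot`, the coefficient-of-determination form: 1 for perfect
#' predictions, 0 for the observed-mean predictor, negative for models
#' worse than the mean.
#'
#' @param pred,obs Equal-length numeric vectors; `obs` must have positive
#'   variance.
#' @return RVE (at most 1, possibly negative).
#' @export
rve <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) stop("RVE undefined: observed values have zero variance")
  1 - sum((pred - obs)^2) / sstot
}

#' Random 80/20 row split
#'
#' @param n Number of rows, or an `AssembledDataset`.
#' @param fraction Training fraction (default 0.8).
#' @param seed Seed; the same seed reproduces the partition.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
random_split <- function(n, fraction = 0.8, seed = 1L) {
  if (inherits(n, "AssembledDataset")) n <- nrow(n$features)
  stopifnot(n >= 5, fraction > 0, fraction < 1)
  rng <- local({set.seed(seed); sample.int(n)})
  ntr <- round(fraction * n)
  list(train = sort(rng[seq_len(ntr)]), validation = sort(rng[-seq_len(ntr)]))
}

#' Leave-target-out split
#'
#' @param ds An `AssembledDataset`.
#' @param held_out_targets Target ids whose rows form the validation set.
#' @return List with `train` and `validation` row indices.
#' @export
target_holdout_split <- function(ds, held_out_targets) {
  stopifnot(inherits(ds, "AssembledDataset"), length(held_out_targets) >= 1)
  absent <- setdiff(held_out_targets, ds$target_id)
  if (length(absent))
    stop("held-out targets not in dataset: ", paste(absent, collapse = ", "))
  val <- which(ds$target_id %in% held_out_targets)
  list(train = setdiff(seq_along(ds$target_id), val), validation = val)
}

#' Select held-out targets for semi-blind validation
#'
#' Greedily picks the `n_pairs` most similar disjoint target pairs in
#' descending Jaccard similarity; one member of each pair goes to the
#' validation set while its partner stays in training. With activity
#' counts supplied, the member with fewer activities is held out (keeping
#' more data in training); otherwise the lexicographically second member.
#'
#' @param sim Symmetric similarity matrix with target ids as dimnames.
#' @param n_pairs Number of pairs (default 15).
#' @param n_activities Optional named vector of per-target activity counts.
#' @return List with `held_out_targets` and `pairs` (data.frame:
#'   `validation_target`, `training_partner`, `similarity`).
#' @export
semi_blind_select <- function(sim, n_pairs = 15L, n_activities = NULL) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  ids <- rownames(sim)
  if (length(ids) < 2 * n_pairs)
    stop("need at least ", 2 * n_pairs, " targets for ", n_pairs, " disjoint pairs")
  avail <- ids
  pairs <- data.frame(validation_target = character(),
                      training_partner = character(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  for (p in seq_len(n_pairs)) {
    cand <- closest_pairs(sim[avail, avail, drop = FALSE], n_pairs = 1)
    a <- cand$target; b <- cand$partner
    if (!is.null(n_activities)) {
      na <- n_activities[a]; nb <- n_activities[b]
      val <- if (!is.na(na) && !is.na(nb) && na != nb)
        c(a, b)[which.min(c(na, nb))] else max(a, b)
    } else val <- max(a, b)
    partner <- setdiff(c(a, b), val)
    pairs <- rbind(pairs, data.frame(
      validation_target = val, training_partner = partner,
      similarity = cand$similarity, stringsAsFactors = FALSE))
    avail <- setdiff(avail, c(a, b))
  }
  list(held_out_targets = pairs$validation_target, pairs = pairs)
}

per_target_metrics <- function(target_id, pred, obs) {
  out <- lapply(split(seq_along(obs), target_id), function(idx) {
    r <- if (length(idx) >= 2 && stats::sd(obs[idx]) > 0)
      rve(pred[idx], obs[idx]) else NA_real_
    data.frame(rmse = rmse(pred[idx], obs[idx]), rve = r,
               n_test = length(idx))
  })
  df <- do.call(rbind, out)
  df$target_id <- names(out)
  rownames(df) <- NULL
  df[, c("target_id", "rmse", "rve", "n_test")]
}

weighted_aggregate <- function(per_target) {
  w <- per_target$n_test
  ok <- !is.na(per_target$rve)
  list(rmse = sum(w * per_target$rmse) / sum(w),
       rve = if (any(ok)) sum(w[ok] * per_target$rve[ok]) / sum(w[ok]) else NA_real_)
}

#' Evaluate a validation regime
#'
#' * `baseline_per_target`: one model per target, molecule bits only (no
#'   protein features), 80/20 split within each target; overall metrics
#'   are test-size-weighted averages over targets.
#' * `unified_random`: one joint model on the full feature rows, random
#'   80/20 split, repeated `n_repeats` times (seeds `seed + 0 ...
#'   seed + n_repeats - 1`) and averaged.
#' * `blind_random_targets`: one joint model trained with all rows of the
#'   held-out targets removed; validation is exactly those rows.
#' * `semi_blind_similar_targets`: as blind, with held-out targets chosen
#'   by [semi_blind_select()] so each has a similar partner in training.
#'
#' @param ds An `AssembledDataset`.
#' @param scheme One of the four regime names.
#' @param spec A [model_spec()].
#' @param seed Base seed.
#' @param n_repeats Repeats for the unified regime (default 10).
#' @param held_out_targets Required for blind; for semi-blind either this
#'   or `sim` must be given.
#' @param sim Similarity matrix for semi-blind selection.
#' @param n_pairs Pairs for semi-blind selection (default 15).
#' @param train_fraction Training fraction for row-wise splits.
#' @param min_target_rows Baseline regime: targets with fewer rows than
#'   this are skipped with a note (default 5).
#' @return An `EvalResult`: `scheme`, `per_target`, `overall_rmse`,
#'   `overall_rve`, `n_train`, `n_test`, `n_repeats`, and scheme
#'   provenance (`held_out_targets`, `pairs` where relevant).
#' @export
evaluate_regime <- function(ds,
                            scheme = c("baseline_per_target", "unified_random",
                                       "blind_random_targets",
                                       "semi_blind_similar_targets"),
                            spec = model_spec(), seed = 1L, n_repeats = 10L,
                            held_out_targets = NULL, sim = NULL,
                            n_pairs = 15L, train_fraction = 0.8,
                            min_target_rows = 5L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ds, "AssembledDataset"))
  mol_cols <- seq_len(ds$n_mol_bits)

  if (scheme == "baseline_per_target") {
    res <- list(); skipped <- character()
    for (tid in sort(unique(ds$target_id))) {
      idx <- which(ds$target_id == tid)
      if (length(idx) < min_target_rows) { skipped <- c(skipped, tid); next }
      sp <- random_split(length(idx), fraction = train_fraction, seed = seed)
      xtr <- ds$features[idx[sp$train], mol_cols, drop = FALSE]
      xva <- ds$features[idx[sp$validation], mol_cols, drop = FALSE]
      fit <- fit_model(spec, xtr, ds$label[idx[sp$train]], seed = seed)
      pred <- predict(fit, xva)
      obs <- ds$label[idx[sp$validation]]
      res[[tid]] <- data.frame(
        target_id = tid, rmse = rmse(pred, obs),
        rve = if (stats::sd(obs) > 0) rve(pred, obs) else NA_real_,
        n_test = length(obs), stringsAsFactors = FALSE)
    }
    if (!length(res)) stop("no target has enough rows for a baseline model")
    per_target <- do.call(rbind, res)
    rownames(per_target) <- NULL
    agg <- weighted_aggregate(per_target)
    return(structure(list(
      scheme = scheme, per_target = per_target,
      overall_rmse = agg$rmse, overall_rve = agg$rve,
      n_train = round(train_fraction * sum(per_target$n_test) /
                        (1 - train_fraction)),
      n_test = sum(per_target$n_test), n_repeats = 1L,
      skipped_targets = skipped), class = "EvalResult"))
  }

  if (scheme == "unified_random") {
    runs <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      s <- seed + r - 1L
      sp <- random_split(ds, fraction = train_fraction, seed = s)
      fit <- fit_model(spec, ds$features[sp$train, , drop = FALSE],
                       ds$label[sp$train], seed = s)
      pred <- predict(fit, ds$features[sp$validation, , drop = FALSE])
      obs <- ds$label[sp$validation]
      pt <- per_target_metrics(ds$target_id[sp$validation], pred, obs)
      runs[[r]] <- list(rmse = rmse(pred, obs), rve = rve(pred, obs),
                        per_target = pt, n_train = length(sp$train),
                        n_test = length(sp$validation))
    }
    per_target <- do.call(rbind, lapply(runs, `[[`, "per_target"))
    per_target <- do.call(rbind, lapply(
      split(per_target, per_target$target_id), function(d) data.frame(
        target_id = d$target_id[1], rmse = mean(d$rmse),
        rve = mean(d$rve, na.rm = TRUE), n_test = round(mean(d$n_test)),
        stringsAsFactors = FALSE)))
    rownames(per_target) <- NULL
    return(structure(list(
      scheme = scheme, per_target = per_target,
      overall_rmse = mean(vapply(runs, `[[`, numeric(1), "rmse")),
      overall_rve = mean(vapply(runs, `[[`, numeric(1), "rve")),
      n_train = runs[[1]]$n_train, n_test = runs[[1]]$n_test,
      n_repeats = as.integer(n_repeats), runs = runs),
      class = "EvalResult"))
  }

  # blind and semi-blind: single model, held-out-target validation
  pairs <- NULL
  if (scheme == "semi_blind_similar_targets" && is.null(held_out_targets)) {
    if (is.null(sim)) stop("semi-blind regime needs held_out_targets or sim")
    counts <- table(ds$target_id)
    sel <- semi_blind_select(sim, n_pairs = n_pairs,
                             n_activities = stats::setNames(as.integer(counts),
                                                            names(counts)))
    held_out_targets <- sel$held_out_targets
    pairs <- sel$pairs
  }
  if (is.null(held_out_targets))
    stop("blind regime needs held_out_targets")
  sp <- target_holdout_split(ds, held_out_targets)
  stopifnot(!any(ds$target_id[sp$train] %in% held_out_targets))
  fit <- fit_model(spec, ds$features[sp$train, , drop = FALSE],
                   ds$label[sp$train], seed = seed)
  pred <- predict(fit, ds$features[sp$validation, , drop = FALSE])
  obs <- ds$label[sp$validation]
  per_target <- per_target_metrics(ds$target_id[sp$validation], pred, obs)
  agg <- weighted_aggregate(per_target)
  structure(list(
    scheme = scheme, per_target = per_target,
    overall_rmse = rmse(pred, obs), overall_rve = rve(pred, obs),
    weighted_rmse = agg$rmse, weighted_rve = agg$rve,
    n_train = length(sp$train), n_test = length(sp$validation),
    n_repeats = 1L, held_out_targets = held_out_targets, pairs = pairs),
    class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("EvalResult [%s]: RMSE %.3f, RVE %.3f (train %d, test %d, repeats %d)\n",
              x$scheme, x$overall_rmse, x$overall_rve, x$n_train, x$n_test,
              x$n_repeats))
  invisible(x)
}

#' 5-fold cross-validation on a training set
#'
#' Informational model-quality check on the training portion (the
#' hyperparameters themselves stay at their defaults).
#'
#' @param ds An `AssembledDataset` (training rows).
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment and fitting.
#' @return data.frame with per-fold `rmse` and `rve`.
#' @export
cross_validate <- function(ds, spec = model_spec(), k = 5L, seed = 1L) {
  stopifnot(inherits(ds, "AssembledDataset"))
  n <- nrow(ds$features)
  stopifnot(n >= k)
  folds <- local({set.seed(seed); sample(rep_len(seq_len(k), n))})
  out <- lapply(seq_len(k), function(f) {
    tr <- which(folds != f); va <- which(folds == f)
    fit <- fit_model(spec, ds$features[tr, , drop = FALSE], ds$label[tr],
                     seed = seed + f)
    pred <- predict(fit, ds$features[va, , drop = FALSE])
    data.frame(fold = f, rmse = rmse(pred, ds$label[va]),
               rve = rve(pred, ds$label[va]))
  })
  do.call(rbind, out)
}
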