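#' Leakage-free position-based split assignment
#'
#' Assigns base positions (not variants) to train/validation/test so that
#' every feature row derived from a given position lands in one split, and
#' positions that are co-mutated in any variant always share a split
#' (grouped via union-find over the co-mutation pairs).
#'
#' @param positions integer vector of all mutated positions in the library.
#' @param co_mutation_groups list of integer vectors; the positions of each
#'   multi-mutation variant.
#' @param fractions train/validation/test fractions (sum to 1).
#' @param seed RNG seed; the assignment is deterministic given it.
#' @return object of class `split_assignment`: data.frame `position`,
#'   `split`, plus attributes `seed`, `fractions`, `groups`.
#' @export
make_position_splits <- function(positions, co_mutation_groups = list(),
                                 fractions = c(train = 0.70,
                                               validation = 0.15,
                                               test = 0.15),
                                 seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  positions <- sort(unique(as.integer(positions)))
  parent <- seq_along(positions)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (gr in co_mutation_groups) {
    gr <- match(intersect(gr, positions), positions)
    if (length(gr) > 1L)
      for (b in gr[-1]) {
        ra <- find(gr[1]); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
  }
  roots <- vapply(seq_along(positions), find, integer(1))
  groups <- split(positions, roots)

  set.seed(seed)
  ord <- sample(length(groups))
  sizes <- vapply(groups, length, integer(1))[ord]
  total <- sum(sizes)
  targets <- fractions * total
  labels <- names(fractions)
  if (is.null(labels)) labels <- c("train", "validation", "test")
  filled <- setNames(numeric(3), labels)
  assign_lab <- character(length(groups))
  for (q in seq_along(ord)) {
    deficit <- targets - filled
    lab <- labels[which.max(deficit)]
    assign_lab[q] <- lab
    filled[lab] <- filled[lab] + sizes[q]
  }
  if (any(sizes > total * max(fractions)))
    warning("a co-mutation group exceeds a split's capacity; ",
            "realized fractions are best-effort")
  df <- data.frame(position = unlist(groups[ord], use.names = FALSE),
                   split = rep(assign_lab, sizes),
                   stringsAsFactors = FALSE)
  df <- df[order(df$position), ]
  rownames(df) <- NULL
  structure(df, class = c("split_assignment", "data.frame"),
            seed = seed, fractions = fractions, groups = groups)
}

#' Map feature rows to splits
#'
#' Rows inherit the split of their mutated-base position; the WT row
#' (position 0) goes to the training split by convention.
#'
#' @param fm a `feature_matrix`.
#' @param splits a `split_assignment`.
#' @return character vector of split labels per row.
#' @export
assign_rows <- function(fm, splits) {
  lab <- splits$split[match(fm$meta$position, splits$position)]
  lab[fm$meta$position == 0L] <- "train"
  if (anyNA(lab)) stop("rows at position(s) ",
                       paste(unique(fm$meta$position[is.na(lab)]),
                             collapse = ", "),
                       " have no split assignment")
  lab
}

#' Training hyperparameters
#'
#' The documented "default parameters" block: at most 1000 boosting rounds
#' with early stopping after `patience` rounds without validation-RMSE
#' improvement; learner defaults `eta` 0.3, `max_depth` 6, `lambda` 1,
#' `min_child_weight` 1 (pinned here because library defaults drift).
#'
#' @param max_rounds,patience boosting budget and early-stopping patience.
#' @param objective `"regression"` or `"binary"`.
#' @param eta,max_depth,lambda,min_child_weight learner settings.
#' @param seed recorded in the run manifest (training itself is
#'   deterministic: exact greedy splits, no subsampling).
#' @return object of class `train_params`.
#' @export
train_params <- function(max_rounds = 1000L, patience = 10L,
                         objective = c("regression", "binary"),
                         eta = 0.3, max_depth = 6L, lambda = 1,
                         min_child_weight = 1, seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(patience >= 1L, max_rounds >= patience)
  structure(list(max_rounds = as.integer(max_rounds),
                 patience = as.integer(patience), objective = objective,
                 eta = eta, max_depth = as.integer(max_depth),
                 lambda = lambda, min_child_weight = min_child_weight,
                 seed = as.integer(seed)),
            class = "train_params")
}

#' Train gradient-boosted trees on a feature matrix
#'
#' @param fm a (masked) `feature_matrix`.
#' @param splits a `split_assignment`.
#' @param params a [train_params()].
#' @return object of class `gbt_model`: the boosted ensemble plus feature
#'   names, split labels and params.
#' @export
train_model <- function(fm, splits, params = train_params()) {
  lab <- assign_rows(fm, splits)
  tr <- which(lab == "train"); va <- which(lab == "validation")
  if (!length(tr) || !length(va))
    stop("train and validation splits must be non-empty")
  y <- if (params$objective == "binary") fm$meta$label else fm$meta$target
  if (length(unique(y[tr])) < 2L) stop("degenerate (constant) target")
  booster <- .gbt_train(fm$features, y, tr - 1L, va - 1L, params$objective,
                        params$max_rounds, params$patience, params$eta,
                        params$lambda, params$min_child_weight,
                        params$max_depth)
  structure(list(booster = booster, feature_names = colnames(fm$features),
                 params = params, split_labels = lab,
                 registry_version = attr(fm$registry, "version")),
            class = "gbt_model")
}

#' @export
print.gbt_model <- function(x, ...) {
  cat("gbt_model:", x$booster$n_rounds, "rounds,",
      length(x$feature_names), "features, objective",
      x$params$objective, "\n")
  cat("  best validation RMSE:", signif(x$booster$best_val_rmse, 4), "\n")
  invisible(x)
}

#' Predict from a trained model
#'
#' @param object a `gbt_model`.
#' @param fm a `feature_matrix` whose columns are aligned to the model's
#'   feature names (missing ones become NA).
#' @param ... unused.
#' @return numeric vector of per-row predictions (probabilities for the
#'   binary objective).
#' @export
predict.gbt_model <- function(object, fm, ...) {
  X <- align_features(fm, object$feature_names)
  as.numeric(.gbt_predict(object$booster, X, FALSE))
}

align_features <- function(fm, feature_names) {
  X <- matrix(NA_real_, nrow(fm$features), length(feature_names),
              dimnames = list(NULL, feature_names))
  shared <- intersect(feature_names, colnames(fm$features))
  if (!length(shared)) stop("zero shared features")
  X[, shared] <- fm$features[, shared]
  X
}

# variant-level aggregation: mean of a variant's per-base rows
aggregate_by_variant <- function(values, variant_id) {
  agg <- tapply(values, variant_id, mean)
  agg[unique(variant_id)]
}

#' Regression and classification metrics on held-out rows
#'
#' Per-base predictions are averaged per variant before scoring. `r2` is
#' `1 - SS_res/SS_tot` (variance explained); `mape` uses an epsilon guard
#' in the denominator; `auPR`/`auROC` treat "edited" as the positive class
#' on the binarized labels.
#'
#' @param model a `gbt_model`.
#' @param fm the `feature_matrix`.
#' @param splits a `split_assignment`.
#' @param which_split which split to score (default test).
#' @param edited_threshold binarization threshold for auPR/auROC.
#' @param mape_eps denominator guard for near-zero editing.
#' @return object of class `metrics_report` (a named list).
#' @export
evaluate <- function(model, fm, splits, which_split = "test",
                     edited_threshold = 0.01, mape_eps = 1e-3) {
  lab <- assign_rows(fm, splits)
  rows <- which(lab == which_split)
  if (!length(rows)) stop("no rows in split ", which_split)
  pred_rows <- predict(model, subset_rows(fm, rows))
  vid <- fm$meta$variant_id[rows]
  if (length(unique(vid)) < 2L) stop("need >= 2 variants in the split")
  pred <- aggregate_by_variant(pred_rows, vid)
  obs <- aggregate_by_variant(fm$meta$target[rows], vid)
  lab_bin <- as.numeric(obs > edited_threshold)
  res <- obs - pred
  r2 <- 1 - sum(res^2) / sum((obs - mean(obs))^2)
  structure(list(
    r2 = r2,
    spearman = suppressWarnings(cor(obs, pred, method = "spearman")),
    pearson = suppressWarnings(cor(obs, pred)),
    mae = mean(abs(res)),
    mape = mean(abs(res) / pmax(abs(obs), mape_eps)),
    rmse = sqrt(mean(res^2)),
    auPR = aupr(pred, lab_bin),
    auROC = auroc(pred, lab_bin),
    n_variants = length(obs), split = which_split),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics on %s split (%d variants):\n", x$split, x$n_variants))
  cat(sprintf("  R2 = %.3f  Spearman = %.3f  Pearson = %.3f\n",
              x$r2, x$spearman, x$pearson))
  cat(sprintf("  MAE = %.4f  MAPE = %.3f  RMSE = %.4f\n",
              x$mae, x$mape, x$rmse))
  cat(sprintf("  auPR = %s  auROC = %s\n",
              format(x$auPR, digits = 3), format(x$auROC, digits = 3)))
  invisible(x)
}

subset_rows <- function(fm, rows) {
  fm$features <- fm$features[rows, , drop = FALSE]
  fm$meta <- fm$meta[rows, , drop = FALSE]
  fm
}

# area under the ROC curve via the rank statistic
auroc <- function(score, label) {
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# area under the precision-recall curve (step-wise average precision)
aupr <- function(score, label) {
  n1 <- sum(label == 1)
  if (n1 == 0 || all(label == 1)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / n1
}

#' Shapley-value attribution report
#'
#' Path-dependent TreeSHAP on the rows of one split: per-row per-feature
#' attributions (raw-score scale), per-feature mean absolute attribution
#' and percent contribution (summing to 100), contributions summed over the
#' registry's nine feature groups, and the additivity baseline.
#'
#' @param model a `gbt_model`.
#' @param fm the `feature_matrix` (carries the registry for grouping).
#' @param splits a `split_assignment`.
#' @param which_split split to explain (default test).
#' @return object of class `shap_report`: list with `values` (matrix),
#'   `baseline`, `feature_importance` (data.frame name/mean_abs/percent/
#'   group), `group_contributions`.
#' @export
explain <- function(model, fm, splits, which_split = "test") {
  lab <- assign_rows(fm, splits)
  rows <- which(lab == which_split)
  X <- align_features(subset_rows(fm, rows), model$feature_names)
  sh <- .gbt_shap(model$booster, X)
  p <- length(model$feature_names)
  values <- sh[, seq_len(p), drop = FALSE]
  colnames(values) <- model$feature_names
  baseline <- sh[1, p + 1]
  mean_abs <- colMeans(abs(values))
  pct <- 100 * mean_abs / sum(mean_abs)
  grp <- fm$registry$group[match(model$feature_names, fm$registry$name)]
  fi <- data.frame(name = model$feature_names, mean_abs = mean_abs,
                   percent = pct, group = grp, stringsAsFactors = FALSE)
  fi <- fi[order(-fi$mean_abs), ]
  rownames(fi) <- NULL
  gc <- tapply(fi$percent, fi$group, sum)
  structure(list(values = values, baseline = baseline,
                 feature_importance = fi,
                 group_contributions = sort(gc, decreasing = TRUE),
                 split = which_split, rows = rows),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat("SHAP report on", x$split, "split; baseline =",
      signif(x$baseline, 4), "\n")
  cat("top features (percent contribution):\n")
  top <- head(x$feature_importance, 10)
  for (q in seq_len(nrow(top)))
    cat(sprintf("  %-28s %6.2f%%  [%s]\n", top$name[q], top$percent[q],
                top$group[q]))
  invisible(x)
}

#' Average feature ranking across substrates
#'
#' Per-feature percent contributions from several [explain()] reports are
#' averaged (features absent from a report contribute 0) to rank features
#' that matter consistently across substrates.
#'
#' @param reports list of `shap_report` objects.
#' @return data.frame `name`, `mean_percent`, sorted decreasing.
#' @export
cross_substrate_ranking <- function(reports) {
  all_names <- unique(unlist(lapply(reports, function(r)
    r$feature_importance$name)))
  m <- vapply(reports, function(r) {
    v <- setNames(rep(0, length(all_names)), all_names)
    v[r$feature_importance$name] <- r$feature_importance$percent
    v
  }, numeric(length(all_names)))
  out <- data.frame(name = all_names, mean_percent = rowMeans(m),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_percent), ]
  rownames(out) <- NULL
  out
}

#' Evaluate a model on a different substrate's matrix
#'
#' Features are aligned by registry name (features the model saw but the
#' new matrix lacks become missing); metrics are computed over all rows of
#' the unseen substrate.
#'
#' @param model a `gbt_model` trained on one (or more) substrates.
#' @param fm_other the unseen substrate's `feature_matrix`.
#' @param edited_threshold binarization threshold.
#' @return a `metrics_report`.
#' @export
cross_substrate_eval <- function(model, fm_other, edited_threshold = 0.01) {
  pred_rows <- predict(model, fm_other)
  vid <- fm_other$meta$variant_id
  pred <- aggregate_by_variant(pred_rows, vid)
  obs <- aggregate_by_variant(fm_other$meta$target, vid)
  lab_bin <- as.numeric(obs > edited_threshold)
  res <- obs - pred
  structure(list(
    r2 = 1 - sum(res^2) / sum((obs - mean(obs))^2),
    spearman = suppressWarnings(cor(obs, pred, method = "spearman")),
    pearson = suppressWarnings(cor(obs, pred)),
    mae = mean(abs(res)), mape = mean(abs(res) / pmax(abs(obs), 1e-3)),
    rmse = sqrt(mean(res^2)),
    auPR = aupr(pred, lab_bin), auROC = auroc(pred, lab_bin),
    n_variants = length(obs), split = "cross-substrate"),
    class = "metrics_report")
}

#' Assert there is no train/test position leakage
#'
#' @param fm a `feature_matrix`.
#' @param splits a `split_assignment`.
#' @return TRUE invisibly; errors on any overlap.
#' @export
assert_no_leakage <- function(fm, splits) {
  lab <- assign_rows(fm, splits)
  tr <- unique(fm$meta$position[lab == "train"])
  te <- unique(fm$meta$position[lab == "test"])
  overlap <- setdiff(intersect(tr, te), 0L)
  if (length(overlap))
    stop("position leakage between train and test: ",
         paste(overlap, collapse = ", "))
  # co-mutation groups must be split-pure
  for (gr in attr(splits, "groups")) {
    s <- unique(splits$split[splits$position %in% gr])
    if (length(s) > 1L)
      stop("co-mutation group split across assignments: ",
           paste(gr, collapse = ","))
  }
  invisible(TRUE)
}
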