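#' Incremental-learning split of one participant's windows
#'
#' Splits the held-out participant's windows into a fixed 70% test set and a
#' 30% incremental-learning pool, stratified by coarse posture label with a
#' deterministic seed-driven order. The incremental subset at level `c` is
#' the first `c / 0.30` proportion of the pool (floor rounding), so subsets
#' are nested across levels and the test set is identical for every `c`.
#'
#' @param coarse Coarse labels of the participant's windows (one per
#'   window).
#' @param c Incremental learning level, one of 0, 0.10, 0.20, 0.30.
#' @param seed Integer seed for the stratified order.
#' @param test_fraction Test fraction (default 0.70).
#' @return List with integer index vectors `test`, `pool`, `il` (the level-c
#'   subset of `pool`).
#' @export
incremental_split <- function(coarse, c = 0.3, seed = 1L,
                              test_fraction = 0.7) {
  pool_fraction <- 1 - test_fraction
  if (c < 0 || c > pool_fraction + 1e-12) {
    stop("incremental level must lie in [0, pool fraction]", call. = FALSE)
  }
  coarse <- as.character(coarse)
  test <- integer(0)
  pool_cls <- list()
  classes <- sort(unique(coarse))
  for (cls in classes) {
    idx <- which(coarse == cls)
    ord <- with_local_seed(derive_seed(seed, match(cls, classes)),
                           sample(idx))
    n_pool <- round(pool_fraction * length(ord))
    pool_cls[[cls]] <- ord[seq_len(n_pool)]
    test <- c(test, if (n_pool < length(ord))
      ord[(n_pool + 1L):length(ord)] else integer(0))
  }
  # interleave strata so any prefix of the pool is approximately stratified
  depth <- max(c(0L, lengths(pool_cls)))
  pool <- integer(0)
  for (d in seq_len(depth)) {
    for (cls in classes) {
      if (d <= length(pool_cls[[cls]])) pool <- c(pool, pool_cls[[cls]][d])
    }
  }
  n_il <- floor((c / pool_fraction) * length(pool) + 1e-9)
  list(test = sort(test), pool = pool, il = pool[seq_len(n_il)])
}

#' Train the Phase One coarse classifier
#'
#' Three-class (left / supine / right) posture model on the 12-feature
#' window representation.
#'
#' @param x Feature matrix or data.frame (the 12 feature columns are
#'   selected by name if present).
#' @param coarse Coarse labels.
#' @param spec A [classifier_spec()].
#' @return A `fitted_backend`.
#' @export
train_phase_one <- function(x, coarse, spec = classifier_spec("LGB")) {
  fit_backend(feature_matrix(x), coarse, spec)
}

#' Split Phase One output into per-side correct subsets
#'
#' Windows misclassified in Phase One are discarded; the remaining
#' correctly classified windows are grouped by their (true = predicted)
#' coarse label. The supine subset is retained for bookkeeping but is not
#' forwarded to Phase Two, whose bins only subdivide the side-lying range.
#'
#' @param predictions Predicted coarse labels.
#' @param truth True coarse labels (same length).
#' @return List of integer index vectors `left`, `supine`, `right`.
#' @export
phase_one_filter <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  ok <- as.character(predictions) == as.character(truth)
  list(left = which(ok & truth == "left"),
       supine = which(ok & truth == "supine"),
       right = which(ok & truth == "right"))
}

#' Train a Phase Two side-bin classifier
#'
#' Multiclass model over one side's angular bins at the given precision.
#' Returns `NULL` with a warning when fewer than two bins are represented
#' in the training subset.
#'
#' @param x Feature rows of one side's correctly classified windows.
#' @param bins Bin labels from [side_bin_label()].
#' @param spec A [classifier_spec()].
#' @return A `fitted_backend`, or `NULL` if the subset is degenerate.
#' @export
train_phase_two <- function(x, bins, spec = classifier_spec("LGB")) {
  if (length(unique(as.character(bins))) < 2) {
    warning("fewer than 2 bins represented; phase two model skipped",
            call. = FALSE)
    return(NULL)
  }
  fit_backend(feature_matrix(x), bins, spec)
}

# numeric matrix of the 12 features, in canonical order
feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  fn <- intersect(feature_names(), names(x))
  as.matrix(x[fn])
}

#' Leave-one-participant-out evaluation of the two-phase classifier
#'
#' For every held-out participant, backend and incremental learning level:
#' Phase One is trained on all other participants' windows (plus any
#' supplemental coarse-labelled windows and the held-out participant's
#' incremental subset) and evaluated on the held-out 70% test set. The best
#' (backend, level) configuration by mean Phase One macro F1 across
#' participants then feeds Phase Two: per fold and side, a bin classifier
#' is trained on the training windows the fold's Phase One model classifies
#' correctly and evaluated on the held-out participant's correctly
#' classified test windows, once per bin scheme.
#'
#' @param features Feature table ([extract_cohort_features()]): 12 feature
#'   columns plus `truth_tpa` and `participant_id`.
#' @param backends Character vector of backend labels (see
#'   [classifier_spec()]).
#' @param il_levels Numeric incremental learning levels (subset of
#'   0, 0.1, 0.2, 0.3).
#' @param schemes Character vector of Phase Two precisions
#'   (`"bins45"`, `"bins30"`, `"bins15"`).
#' @param seed Master seed; per-fold and per-fit seeds derive from it.
#' @param supplemental Optional extra feature table used only for Phase One
#'   training in every fold (no participant overlap with `features`).
#' @param hyperparameters Named list of per-backend hyperparameter
#'   overrides.
#' @return A `lopo_result`: list with `scores` (data.frame `participant`,
#'   `backend`, `il_level`, `phase`, `scheme`, `side`, `f1`, `accuracy`,
#'   `n_test`), `best` (chosen backend and level), `splits` (per-participant
#'   test/pool row indices), `train_rows` (per participant and level, the
#'   Phase One training rows of that fold) and `confusions` (named list of
#'   confusion tables).
#' @export
run_lopo <- function(features, backends = "LGB",
                     il_levels = c(0, 0.1, 0.2, 0.3),
                     schemes = c("bins45", "bins30", "bins15"),
                     seed = 1L, supplemental = NULL,
                     hyperparameters = list()) {
  ids <- unique(features$participant_id)
  if (length(ids) < 2) {
    stop("LOPO needs at least 2 participants", call. = FALSE)
  }
  features$.coarse <- coarse_label(features$truth_tpa)
  if (!is.null(supplemental)) {
    supplemental$.coarse <- coarse_label(supplemental$truth_tpa)
  }

  splits <- lapply(seq_along(ids), function(i) {
    rows <- which(features$participant_id == ids[i])
    sp <- incremental_split(features$.coarse[rows], c = 0.3,
                            seed = derive_seed(seed, i))
    list(rows = rows, test = rows[sp$test], pool = rows[sp$pool])
  })
  names(splits) <- ids

  scores <- list()
  confusions <- list()
  p1_cache <- list()  # per (participant, backend, il): fold model + preds
  fold_train_rows <- lapply(ids, function(p) list())
  names(fold_train_rows) <- ids

  for (i in seq_along(ids)) {
    p <- ids[i]
    sp <- splits[[p]]
    others <- setdiff(seq_len(nrow(features)), sp$rows)
    for (b in backends) {
      for (cc in il_levels) {
        il_n <- floor((cc / 0.3) * length(sp$pool) + 1e-9)
        il_rows <- sp$pool[seq_len(il_n)]
        train_rows <- c(others, il_rows)
        fold_train_rows[[p]][[sprintf("%g", cc)]] <- train_rows
        cs <- classifier_spec(b, hyperparameters = hyperparameters[[b]] %||%
                                list(),
                              seed = derive_seed(seed, 100L + i))
        xtr <- feature_matrix(features[train_rows, , drop = FALSE])
        ytr <- features$.coarse[train_rows]
        if (!is.null(supplemental)) {
          xtr <- rbind(xtr, feature_matrix(supplemental))
          ytr <- c(ytr, supplemental$.coarse)
        }
        model <- train_phase_one(xtr, ytr, cs)
        pred <- predict_backend(model,
                                feature_matrix(features[sp$test, ,
                                                        drop = FALSE]))
        truth <- features$.coarse[sp$test]
        key <- sprintf("%s|%s|%g|one", p, b, cc)
        confusions[[key]] <- table(truth = truth, pred = pred)
        scores[[key]] <- data.frame(
          participant = p, backend = b, il_level = cc, phase = "one",
          scheme = "coarse3", side = NA_character_,
          f1 = macro_f1(pred, truth),
          accuracy = mean(as.character(pred) == truth),
          n_test = length(truth))
        p1_cache[[key]] <- list(train_rows = train_rows, model = model,
                                pred = pred)
      }
    }
  }
  score_df <- do.call(rbind, scores)
  rownames(score_df) <- NULL

  # best Phase One configuration: highest mean F1 across participants
  p1 <- score_df[score_df$phase == "one", ]
  agg <- stats::aggregate(f1 ~ backend + il_level, data = p1, FUN = mean)
  best <- agg[order(-agg$f1), ][1, ]
  best_backend <- as.character(best$backend)
  best_il <- best$il_level

  for (i in seq_along(ids)) {
    p <- ids[i]
    sp <- splits[[p]]
    key <- sprintf("%s|%s|%g|one", p, best_backend, best_il)
    cache <- p1_cache[[key]]
    # training-side correct windows: fold model applied in-sample
    tr_rows <- cache$train_rows
    tr_pred <- predict_backend(cache$model,
                               feature_matrix(features[tr_rows, ,
                                                       drop = FALSE]))
    tr_ok <- phase_one_filter(tr_pred, features$.coarse[tr_rows])
    te_ok <- phase_one_filter(cache$pred, features$.coarse[sp$test])

    for (sch in schemes) {
      scheme <- scheme_edges(sch)
      for (side in c("left", "right")) {
        tr_idx <- tr_rows[tr_ok[[side]]]
        te_idx <- sp$test[te_ok[[side]]]
        tr_idx <- tr_idx[abs(features$truth_tpa[tr_idx]) <= 112.5]
        te_idx <- te_idx[abs(features$truth_tpa[te_idx]) <= 112.5]
        if (!length(te_idx)) next
        bins_tr <- side_bin_label(features$truth_tpa[tr_idx], scheme)
        bins_te <- side_bin_label(features$truth_tpa[te_idx], scheme)
        cs <- classifier_spec(best_backend,
                              hyperparameters =
                                hyperparameters[[best_backend]] %||% list(),
                              seed = derive_seed(seed, 200L + i))
        m2 <- train_phase_two(features[tr_idx, , drop = FALSE], bins_tr, cs)
        if (is.null(m2)) next
        pred2 <- predict_backend(m2,
                                 feature_matrix(features[te_idx, ,
                                                         drop = FALSE]))
        key2 <- sprintf("%s|%s|%g|two|%s|%s", p, best_backend, best_il,
                        sch, side)
        confusions[[key2]] <- table(truth = bins_te, pred = pred2)
        scores[[key2]] <- data.frame(
          participant = p, backend = best_backend, il_level = best_il,
          phase = "two", scheme = sch, side = side,
          f1 = macro_f1(pred2, bins_te),
          accuracy = mean(as.character(pred2) == as.character(bins_te)),
          n_test = length(te_idx))
      }
    }
  }

  score_df <- do.call(rbind, scores)
  rownames(score_df) <- NULL
  structure(list(scores = score_df,
                 best = list(backend = best_backend, il_level = best_il),
                 splits = lapply(splits, function(s) s[c("test", "pool")]),
                 train_rows = fold_train_rows,
                 confusions = confusions),
            class = "lopo_result")
}
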