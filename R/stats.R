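#' Macro-averaged F1 score
#'
#' Unweighted mean over the label set of the per-class F1 score
#' `2PR / (P + R)`. Classes absent from both predictions and truth are
#' excluded; a class with no true and no predicted instances among the
#' remaining labels contributes F1 = 0 only if it occurs on one side.
#'
#' @param predictions Predicted labels.
#' @param truth True labels (same length, non-empty).
#' @param label_set Optional label universe; defaults to the union of
#'   observed labels.
#' @return Macro F1 in \[0, 1\].
#' @examples
#' macro_f1(c("a", "b", "b"), c("a", "b", "a"))
#' @export
macro_f1 <- function(predictions, truth, label_set = NULL) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (!length(truth) || length(predictions) != length(truth)) {
    stop("predictions and truth must be non-empty and aligned",
         call. = FALSE)
  }
  labels <- label_set %||% sort(unique(c(predictions, truth)))
  labels <- labels[labels %in% c(predictions, truth)]
  f1 <- vapply(labels, function(l) {
    tp <- sum(predictions == l & truth == l)
    fp <- sum(predictions == l & truth != l)
    fn <- sum(predictions != l & truth == l)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Normality and homogeneity checks
#'
#' `normality_check()` is the Shapiro-Wilk test; `homogeneity_check()` is
#' Levene's test (median-centred) across groups. Both gate the choice of
#' nonparametric model comparisons.
#'
#' @param sample Numeric vector (n >= 3, non-constant).
#' @return `normality_check()`: list with `statistic` (W) and `p.value`.
#' @export
normality_check <- function(sample) {
  if (length(sample) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(sample) == 0) {
    stop("constant sample: normality is undefined", call. = FALSE)
  }
  ht <- stats::shapiro.test(sample)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' @rdname normality_check
#' @param values Numeric vector of all observations.
#' @param groups Group membership (factor), same length as `values`.
#' @return `homogeneity_check()`: list with `statistic` (F) and `p.value`.
#' @export
homogeneity_check <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  ht <- car::leveneTest(values, groups)
  list(statistic = ht[1, "F value"], p.value = ht[1, "Pr(>F)"])
}

#' Friedman's ANOVA on a participant-by-condition score matrix
#'
#' Rank-based omnibus comparison of paired conditions (models, incremental
#' learning levels, or bin schemes), chi-square statistic with
#' `k - 1` degrees of freedom.
#'
#' @param matrix Complete numeric matrix: rows = participants, columns =
#'   conditions.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
friedman_test <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) stop("score matrix must be complete", call. = FALSE)
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    stop("need at least 2 participants and 2 conditions", call. = FALSE)
  }
  ht <- stats::friedman.test(matrix)
  stat <- unname(ht$statistic)
  p <- ht$p.value
  if (is.nan(stat)) {
    # every row fully tied: no rank variation, no evidence of differences
    stat <- 0; p <- 1
  }
  list(statistic = stat, df = unname(ht$parameter), p.value = p)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank comparison of two paired score vectors. `V` is the sum of
#' the ranks of positive differences; zero differences are dropped; the
#' exact distribution is used for n <= 25 without ties, the normal
#' approximation otherwise.
#'
#' @param a,b Paired numeric vectors (same length).
#' @return List with `statistic` (V) and `p.value`.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) {
    stop("all paired differences are zero", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = length(d) <= 25, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Bonferroni-corrected pairwise comparison report
#'
#' Omnibus Friedman test over the score matrix, followed by paired
#' signed-rank tests for the requested column pairs at the Bonferroni
#' threshold `alpha / #pairs` (0.0167 for three comparisons, 0.025 for
#' two).
#'
#' @param matrix Participant-by-condition score matrix.
#' @param pairs List of length-2 column name (or index) vectors; default:
#'   all adjacent column pairs.
#' @param alpha Family-wise error rate.
#' @return A `comparison_report`: list with `omnibus`, `pairwise`
#'   (data.frame `pair`, `V`, `p.value`, `significant`) and `threshold`.
#' @export
compare_conditions <- function(matrix, pairs = NULL, alpha = 0.05) {
  matrix <- as.matrix(matrix)
  omni <- friedman_test(matrix)
  if (is.null(pairs)) {
    pairs <- lapply(seq_len(ncol(matrix) - 1L),
                    function(j) colnames(matrix)[c(j, j + 1L)] %||%
                      c(j, j + 1L))
  }
  threshold <- alpha / length(pairs)
  rows <- lapply(pairs, function(pr) {
    w <- paired_wilcoxon(matrix[, pr[1]], matrix[, pr[2]])
    data.frame(pair = paste(pr, collapse = " vs "), V = w$statistic,
               p.value = w$p.value, significant = w$p.value < threshold)
  })
  structure(list(omnibus = omni, pairwise = do.call(rbind, rows),
                 threshold = threshold),
            class = "comparison_report")
}

#' Hypothetical end-to-end F1 of the two-phase cascade
#'
#' Phase Two scores are conditional on Phase One being correct (incorrect
#' coarse classifications are removed before Phase Two), so the end-to-end
#' ceiling is the product of the two scores, reported to three decimals.
#'
#' @param phase_one_f1,phase_two_f1 F1 scores in \[0, 1\].
#' @return Their product rounded to 3 decimals.
#' @examples
#' hypothetical_max_f1(0.8343, 0.919) # 0.767
#' @export
hypothetical_max_f1 <- function(phase_one_f1, phase_two_f1) {
  if (any(c(phase_one_f1, phase_two_f1) < 0) ||
      any(c(phase_one_f1, phase_two_f1) > 1)) {
    stop("F1 scores must lie in [0, 1]", call. = FALSE)
  }
  round(phase_one_f1 * phase_two_f1, 3)
}

#' Summarise a LOPO result
#'
#' Per-participant scores aggregated to mean and standard deviation:
#' Phase Two rows per (side, scheme), Phase One rows per (backend,
#' incremental level). Single-participant groups report sd = 0 and are
#' flagged.
#'
#' @param result A `lopo_result` from [run_lopo()] (or its `scores`
#'   data.frame).
#' @return Data.frame with columns `phase`, `backend`, `il_level`,
#'   `scheme`, `side`, `mean_f1`, `sd_f1`, `mean_accuracy`, `sd_accuracy`,
#'   `n_participants`, `single_participant`.
#' @export
summarize_lopo <- function(result) {
  scores <- if (inherits(result, "lopo_result")) result$scores else result
  key <- interaction(scores$phase, scores$backend, scores$il_level,
                     scores$scheme, ifelse(is.na(scores$side), "",
                                           scores$side), drop = TRUE)
  rows <- lapply(split(scores, key), function(g) {
    data.frame(phase = g$phase[1], backend = g$backend[1],
               il_level = g$il_level[1], scheme = g$scheme[1],
               side = g$side[1],
               mean_f1 = mean(g$f1),
               sd_f1 = if (nrow(g) > 1) stats::sd(g$f1) else 0,
               mean_accuracy = mean(g$accuracy),
               sd_accuracy = if (nrow(g) > 1) stats::sd(g$accuracy) else 0,
               n_participants = nrow(g),
               single_participant = nrow(g) == 1L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$phase, out$backend, out$il_level, out$scheme,
                   out$side), , drop = FALSE]
  rownames(out) <- NULL
  out
}
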