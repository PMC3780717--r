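#' Split pairwise scores by metadata label equality
#'
#' Every unordered off-diagonal pair of experiments contributes its
#' similarity score to exactly one of two vectors: `same` if the two
#' experiments carry the same label for `factor` (e.g. run on the same
#' date, or treated with the same compound), `diff` otherwise.  These two
#' vectors feed the Wilcoxon batching test: a strong shift between them
#' means the factor batches the scores.
#'
#' @param sim A `be_sim` similarity matrix.
#' @param meta Data frame with an `experiment_id` column plus one column per
#'   factor; every experiment in `sim` must have exactly one row.
#' @param factor Name of the metadata column to split on.
#' @return A list with numeric vectors `same` and `diff` (named by pair,
#'   `"a|b"`) and the factor name.  `diff` is empty when all labels agree.
#' @examples
#' s <- matrix(c(1, .9, .1, .9, 1, .2, .1, .2, 1), 3, 3,
#'             dimnames = rep(list(c("e1", "e2", "e3")), 2))
#' meta <- data.frame(experiment_id = c("e1", "e2", "e3"),
#'                    date = c("A", "A", "B"))
#' partition_pair_scores(structure(s, method = "x", class = "be_sim"),
#'                       meta, "date")
#' @export
partition_pair_scores <- function(sim, meta, factor) {
  stopifnot(is.matrix(sim))
  ids <- colnames(sim)
  if (!is.data.frame(meta) || !"experiment_id" %in% names(meta)) {
    stop("`meta` must be a data frame with an `experiment_id` column",
         call. = FALSE)
  }
  if (!factor %in% names(meta)) {
    stop(sprintf("unknown metadata factor '%s'", factor), call. = FALSE)
  }
  missing_ids <- setdiff(ids, meta$experiment_id)
  if (length(missing_ids) > 0L) {
    stop(sprintf("experiments without metadata: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  labels <- meta[[factor]][match(ids, meta$experiment_id)]
  n <- length(ids)
  pairs <- utils::combn(n, 2)
  scores <- sim[cbind(pairs[1, ], pairs[2, ])]
  names(scores) <- paste(ids[pairs[1, ]], ids[pairs[2, ]], sep = "|")
  is_same <- labels[pairs[1, ]] == labels[pairs[2, ]]
  list(same = scores[is_same], diff = scores[!is_same], factor = factor)
}

#' Two-sided Wilcoxon rank-sum test for score batching
#'
#' Tests whether the `same`-label pair scores are shifted relative to the
#' `diff`-label pair scores.  When both vectors have at most `exact_max`
#' elements the null distribution of the rank-sum is enumerated exhaustively
#' (ties handled via midranks); otherwise a tie-corrected normal
#' approximation with continuity correction is used.  `W` is the rank sum of
#' the `same` vector in the pooled ranking.
#'
#' @param same,diff Non-empty numeric score vectors.
#' @param exact_max Size limit (per vector) for the exact branch; the
#'   default 10 keeps enumeration under `choose(20, 10)` arrangements.
#' @return An object of class `batch_test`: list with `W`, `p_value`,
#'   `n_same`, `n_diff`, `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(same, diff, exact_max = 10L) {
  same <- as.numeric(same)
  diff <- as.numeric(diff)
  if (length(same) == 0L || length(diff) == 0L) {
    stop("both score vectors must be non-empty (factor untestable)",
         call. = FALSE)
  }
  if (anyNA(same) || anyNA(diff)) stop("scores contain NA", call. = FALSE)
  n1 <- length(same)
  n2 <- length(diff)
  N <- n1 + n2
  r <- rank(c(same, diff))       # midranks under ties
  W <- sum(r[seq_len(n1)])

  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(N, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    eps <- 1e-8
    p_le <- mean(w_all <= W + eps)
    p_ge <- mean(w_all >= W - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      # every observation tied: no evidence of shift
      p <- 1
    } else {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(W = W, p_value = p, n_same = n1, n_diff = n2,
                 method = method),
            class = "batch_test")
}

#' @export
print.batch_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, p = %.4g (n = %d vs %d)\n",
              x$method, x$W, x$p_value, x$n_same, x$n_diff))
  invisible(x)
}

#' Average-linkage clustering of experiments from a similarity matrix
#'
#' Converts similarities to distances `d = 1 - sim/max(sim)` and clusters
#' with average linkage.  Experiments treated with the same compound should
#' merge early when the scoring method captures compound identity rather
#' than nuisance factors such as run date.
#'
#' @param sim Symmetric `be_sim` (or plain symmetric matrix) of at least two
#'   experiments.
#' @return An [stats::hclust] tree with experiment ids as labels.  Serialize
#'   with [write_newick()].
#' @export
cluster_experiments <- function(sim) {
  stopifnot(is.matrix(sim))
  if (ncol(sim) < 2L) stop("need at least 2 experiments", call. = FALSE)
  m <- unclass(sim)
  if (!isSymmetric(m, tol = 1e-8, check.attributes = FALSE)) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  top <- max(m, na.rm = TRUE)
  if (!is.finite(top) || top <= 0) {
    stop("similarity maximum must be positive", call. = FALSE)
  }
  d <- stats::as.dist(1 - m / top)
  stats::hclust(d, method = "average")
}

#' Write a dendrogram as a newick tree
#'
#' @param tree An [stats::hclust] result (e.g. from [cluster_experiments()]).
#' @param path Output file; experiment ids become leaf labels.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Batching report: Wilcoxon shift per method and factor
#'
#' For every similarity method and every metadata factor, computes the
#' all-pairs similarity matrix, partitions pair scores into same-label and
#' different-label vectors, and runs the two-sided Wilcoxon rank-sum test.
#' A desirable scoring method shows a strong shift for the biological
#' factor (compound) and none for nuisance factors (date).
#'
#' @param fm Numeric genes x experiments fitness matrix.
#' @param meta Metadata data frame (see [partition_pair_scores()]).
#' @param methods Character vector from `"be"`, `"pearson"`, `"spearman"`,
#'   `"kendall"`; empty gives an empty report.
#' @param factors Metadata columns to test (default all but
#'   `experiment_id`).
#' @param ... Bucket schedule arguments passed to [be_similarity()].
#' @return A data frame with one row per (method, factor): `method`,
#'   `factor`, `W`, `p_value`, `n_same`, `n_diff`, `testable`.  Untestable
#'   factors (all labels equal, or all distinct) carry `NA` statistics.
#' @export
batch_effect_report <- function(fm, meta, methods = c("be", "pearson"),
                                factors = NULL, ...) {
  if (is.null(factors)) {
    factors <- setdiff(names(meta), "experiment_id")
  }
  methods <- unique(methods)
  bad <- setdiff(methods, c("be", "pearson", "spearman", "kendall"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  rows <- list()
  for (m in methods) {
    sim <- if (m == "be") be_similarity(fm, ...) else
      correlation_similarity(fm, method = m)
    for (f in factors) {
      part <- partition_pair_scores(sim, meta, f)
      if (length(part$same) == 0L || length(part$diff) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, factor = f, W = NA_real_, p_value = NA_real_,
          n_same = length(part$same), n_diff = length(part$diff),
          testable = FALSE, stringsAsFactors = FALSE)
      } else {
        t <- wilcoxon_rank_sum(part$same, part$diff)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, factor = f, W = t$W, p_value = t$p_value,
          n_same = t$n_same, n_diff = t$n_diff, testable = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(method = character(), factor = character(),
                      W = numeric(), p_value = numeric(),
                      n_same = integer(), n_diff = integer(),
                      testable = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
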