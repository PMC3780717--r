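#' @keywords internal
#' @noRd
check_fitness_matrix <- function(fm) {
  if (!is.matrix(fm) || !is.numeric(fm)) {
    stop("fitness matrix must be a numeric matrix (genes x experiments)",
         call. = FALSE)
  }
  if (is.null(rownames(fm)) || is.null(colnames(fm))) {
    stop("fitness matrix needs gene rownames and experiment colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(fm))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(fm))) stop("duplicate experiment ids", call. = FALSE)
  if (any(is.infinite(fm))) {
    stop("fitness matrix contains non-finite values (use NA for missing)",
         call. = FALSE)
  }
  invisible(fm)
}

new_be_sim <- function(entries, method, normalized = FALSE) {
  structure(entries, method = method, normalized = normalized,
            class = c("be_sim", class(entries)))
}

#' @export
print.be_sim <- function(x, digits = 4, ...) {
  cat(sprintf("%s similarity matrix, %d experiments%s\n",
              attr(x, "method"), nrow(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized, %% of max)" else ""))
  print(signif(unclass(x), digits), ...)
  invisible(x)
}

#' All-pairs Bucket Evaluations similarity
#'
#' Computes the summed levelled-score similarity for every pair of
#' experiments in a fitness matrix.  Each profile is ranked, partitioned
#' into buckets (see [bucket_scheme()]), and every pair is scored against
#' the levelled scoring matrix ([scoring_matrix()]).  Because only rank
#' group membership enters the score, the result is invariant to any
#' strictly increasing transform of an individual profile — the property
#' that makes the score robust to scale- and batch-driven distortion.
#'
#' Missing values are handled pairwise-complete: for each pair, genes
#' missing in either profile are dropped and the bucket scheme is rebuilt on
#' the intersection size, so every comparison is a complete partition.
#'
#' @param fm Numeric matrix, genes x experiments, with rownames/colnames;
#'   `NA` marks missing scores.
#' @param initial_fraction,growth_factor,max_buckets Bucket schedule
#'   parameters, see [bucket_scheme()].  Defaults are the stringent preset.
#' @param preset Optional preset name overriding the three explicit
#'   parameters, see [bucket_preset()].
#'
#' @return A symmetric `be_sim` matrix (experiments x experiments) of raw
#'   summed scores with `method = "BE"`.  The diagonal holds each
#'   experiment's self-comparison score, the maximum attainable for its
#'   scheme.
#'
#' @examples
#' fm <- matrix(rnorm(300), 100, 3,
#'              dimnames = list(sprintf("g%03d", 1:100), c("e1", "e2", "e3")))
#' be_similarity(fm, preset = "broad")
#' @export
be_similarity <- function(fm, initial_fraction = 0.0005, growth_factor = 2,
                          max_buckets = 20L, preset = NULL) {
  check_fitness_matrix(fm)
  if (ncol(fm) < 2L) {
    stop("need at least 2 experiments to compare", call. = FALSE)
  }
  if (!is.null(preset)) {
    p <- bucket_preset(preset)
    initial_fraction <- p$initial_fraction
    growth_factor <- p$growth_factor
    max_buckets <- p$max_buckets
  }
  ne <- ncol(fm)
  ids <- colnames(fm)
  out <- matrix(NA_real_, ne, ne, dimnames = list(ids, ids))

  if (!anyNA(fm)) {
    # complete data: one scheme, one assignment per experiment
    scheme <- bucket_scheme(nrow(fm), initial_fraction, growth_factor,
                            max_buckets)
    sm <- scoring_matrix(length(scheme$sizes),
                         cap = max(max_buckets, length(scheme$sizes)))
    asg <- lapply(ids, function(e) assign_buckets(fm[, e], scheme)$bucket)
    names(asg) <- ids
    for (i in seq_len(ne)) {
      for (j in i:ne) {
        out[i, j] <- out[j, i] <- sum(sm[cbind(asg[[i]], asg[[j]])])
      }
    }
  } else {
    for (i in seq_len(ne)) {
      for (j in i:ne) {
        keep <- !is.na(fm[, i]) & !is.na(fm[, j])
        if (!any(keep)) {
          stop(sprintf("experiments '%s' and '%s' share no scored genes",
                       ids[i], ids[j]), call. = FALSE)
        }
        scheme <- bucket_scheme(sum(keep), initial_fraction, growth_factor,
                                max_buckets)
        sm <- scoring_matrix(length(scheme$sizes),
                             cap = max(max_buckets, length(scheme$sizes)))
        a <- assign_buckets(fm[keep, i], scheme)
        b <- assign_buckets(fm[keep, j], scheme)
        out[i, j] <- out[j, i] <- pair_similarity(a, b, sm)
      }
    }
  }
  new_be_sim(out, method = "BE")
}

#' Baseline correlation similarity matrices
#'
#' All-pairs Pearson, Spearman or Kendall (tau-b, tie-corrected) correlation
#' between experiment profiles, with the same pairwise-complete missing-data
#' policy as [be_similarity()].  Pairs involving a constant profile have no
#' defined correlation and are reported as `NA` with a warning.
#'
#' @param fm Numeric genes x experiments matrix, as in [be_similarity()].
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return A symmetric `be_sim` matrix of coefficients in `[-1, 1]` with
#'   unit diagonal (where defined).
#' @export
correlation_similarity <- function(fm,
                                   method = c("pearson", "spearman", "kendall")) {
  check_fitness_matrix(fm)
  method <- match.arg(method)
  if (ncol(fm) < 2L) {
    stop("need at least 2 experiments to compare", call. = FALSE)
  }
  constant <- apply(fm, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0L && diff(range(x)) == 0
  })
  if (any(constant)) {
    warning(sprintf("constant profile(s) %s: correlations undefined, set to NA",
                    paste(colnames(fm)[constant], collapse = ", ")),
            call. = FALSE)
  }
  out <- suppressWarnings(
    stats::cor(fm, use = "pairwise.complete.obs", method = method)
  )
  diag(out)[!constant] <- 1
  new_be_sim(out, method = method)
}

#' Express a similarity matrix as percent of its top score
#'
#' Divides every entry by the global maximum and multiplies by 100, so the
#' top entry becomes 100.  Raw summed scores remain the canonical output;
#' this normalization only eases cross-method comparison.
#'
#' @param sim A `be_sim` matrix with a strictly positive maximum entry.
#' @return The rescaled `be_sim` with its `normalized` flag set.  Applying
#'   it twice is a no-op.
#' @export
normalize_similarity <- function(sim) {
  stopifnot(inherits(sim, "be_sim"))
  if (length(sim) == 0L) stop("empty similarity matrix", call. = FALSE)
  top <- max(sim, na.rm = TRUE)
  if (!is.finite(top) || top <= 0) {
    stop("cannot normalize: maximum entry is not positive", call. = FALSE)
  }
  new_be_sim(unclass(sim) / top * 100, method = attr(sim, "method"),
             normalized = TRUE)
}

#' Split a signed matrix into positive and absolute-negative parts
#'
#' Rank-based scoring treats negative values as insignificant, so datasets
#' where both signs carry signal (e.g. expression log-ratios: induction and
#' repression) are analysed as two matrices: one keeping the positive
#' values, one holding the absolute values of the negatives.  Zeros replace
#' the opposite sign in each part, so `positive - negative_abs`
#' reconstructs the original.
#'
#' @param fm Numeric genes x experiments matrix; `NA` preserved in both parts.
#' @return A list with elements `positive` and `negative_abs`, both with the
#'   dimnames of `fm`.
#' @examples
#' m <- matrix(c(-2, 3, 0), 3, 1, dimnames = list(c("a", "b", "c"), "e1"))
#' split_signed_matrix(m)
#' @export
split_signed_matrix <- function(fm) {
  check_fitness_matrix(fm)
  pos <- pmax(fm, 0)
  neg <- pmax(-fm, 0)
  if (all(fm >= 0, na.rm = TRUE)) {
    warning("input has no negative values; negative_abs part is all zero",
            call. = FALSE)
  }
  list(positive = pos, negative_abs = neg)
}
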