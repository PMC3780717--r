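#' Assign ranked genes of one profile to buckets
#'
#' Sorts genes by fitness-defect score, highest first (highest defect = most
#' sensitive strain = bucket 1), and fills the buckets of `scheme` in order.
#' Ties are broken by ascending gene identifier (C-locale radix sort), so the
#' assignment is deterministic across platforms.
#'
#' @param profile Named numeric vector: one experiment's fitness-defect score
#'   per gene.  Must contain no missing values (drop them, and rebuild the
#'   scheme on the reduced gene set, before calling).
#' @param scheme A [bucket_scheme()] whose `num_genes` equals
#'   `length(profile)`.
#'
#' @return An object of class `bucket_assignment`: a list with `bucket`
#'   (integer vector of 1-based bucket indices, named by gene, in the input
#'   gene order) and `scheme`.
#'
#' @examples
#' p <- c(g1 = 9, g2 = 5, g3 = 4, g4 = 1, g5 = 0, g6 = 0, g7 = -1)
#' assign_buckets(p, bucket_scheme(7, 0.14, 2, 3))$bucket
#' # g1 -> 1; g2, g3 -> 2; g4..g7 -> 3
#' @export
assign_buckets <- function(profile, scheme) {
  stopifnot(inherits(scheme, "bucket_scheme"))
  if (is.null(names(profile)) || anyDuplicated(names(profile))) {
    stop("`profile` must be named by unique gene identifiers", call. = FALSE)
  }
  if (anyNA(profile)) {
    stop("`profile` contains missing values; drop them before assignment",
         call. = FALSE)
  }
  if (length(profile) != scheme$num_genes) {
    stop(sprintf("profile has %d genes but scheme expects %d",
                 length(profile), scheme$num_genes), call. = FALSE)
  }
  if (length(profile) > 1L && diff(range(profile)) == 0) {
    warning("all scores identical; bucket assignment is tie-break-determined",
            call. = FALSE)
  }
  ord <- order(-profile, names(profile), method = "radix")
  bucket <- integer(length(profile))
  bucket[ord] <- rep.int(seq_along(scheme$sizes), scheme$sizes)
  names(bucket) <- names(profile)
  structure(list(bucket = bucket, scheme = scheme),
            class = "bucket_assignment")
}

#' Summed levelled-score similarity between two bucket assignments
#'
#' For each shared gene `g`, looks up `S(bucket_a(g), bucket_b(g))` in the
#' levelled scoring matrix and returns the sum.  Both assignments must use
#' the same bucket scheme and cover the same gene set.  Self-comparison
#' yields the per-gene maximum, `sum(sizes * diag(S))`.
#'
#' @param a,b [assign_buckets()] results on the same scheme and gene set.
#' @param sm A [scoring_matrix()] with `n` equal to the number of buckets.
#' @return A single positive number, symmetric in `a` and `b`.
#' @export
pair_similarity <- function(a, b, sm) {
  stopifnot(inherits(a, "bucket_assignment"), inherits(b, "bucket_assignment"),
            inherits(sm, "be_scoring_matrix"))
  if (!identical(a$scheme$sizes, b$scheme$sizes)) {
    stop("assignments use different bucket schemes", call. = FALSE)
  }
  if (nrow(sm) != length(a$scheme$sizes)) {
    stop("scoring matrix size does not match the bucket scheme", call. = FALSE)
  }
  genes <- names(a$bucket)
  if (length(genes) == 0L) stop("empty shared gene set", call. = FALSE)
  if (!setequal(genes, names(b$bucket))) {
    stop("assignments cover different gene sets", call. = FALSE)
  }
  sum(sm[cbind(a$bucket, b$bucket[genes])])
}
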