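#' Levelled scoring matrix for bucket comparisons
#'
#' Builds the n x n table of scores `S(i, j)` awarded to a gene that falls in
#' bucket `i` of one experiment and bucket `j` of the other.  The matrix is
#' "levelled": hits in low (more significant) buckets outscore hits in high
#' buckets, and hits in nearby buckets outscore hits in distant buckets.
#'
#' The closed form is
#' \deqn{S(i, j) = \frac{2^{n-1}}{m! \, m^{d}}, \quad m = \max(i, j),
#'       \; d = |i - j|}
#' so the top score is `S(1, 1) = 2^(n-1)` and scores fall off factorially
#' down the diagonal and geometrically with bucket distance.  For `n = 5`
#' the scores range from `S(1,1) = 16` down to `S(1,5) ~ 2.1e-4`; for
#' `n = 11` from `1024` down to `~ 9.9e-16`.
#'
#' The matrix satisfies, for all valid indices:
#' * symmetry: `S(i, j) == S(j, i)`;
#' * level ordering: `S(i, i) > S(j, j)` whenever `i < j`;
#' * proximity ordering: `S(i, j) > S(i, k)` whenever `i < j < k`;
#' * strict positivity.
#'
#' @param n Number of buckets (positive integer).
#' @param cap Upper limit on `n`.  Defaults to 20: `20!` is still exactly
#'   representable in double precision, while larger `n` drives off-diagonal
#'   scores into underflow territory.
#'
#' @return A numeric `n` x `n` matrix of class `be_scoring_matrix` with
#'   `dimnames` `bucket1..bucketn`.
#'
#' @examples
#' sm <- scoring_matrix(5)
#' sm[1, 1]   # 16
#' sm11 <- scoring_matrix(11)
#' round(sm11[6, 6], 2)   # 1.42
#' round(sm11[5, 6], 3)   # 0.237
#' @export
scoring_matrix <- function(n, cap = 20L) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n != as.integer(n) ||
      n < 1L) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n > cap) {
    stop(sprintf(
      "`n` = %d exceeds the bucket cap (%d); factorial growth makes scores numerically extreme",
      n, cap
    ), call. = FALSE)
  }
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  m <- pmax(i, j)
  d <- abs(i - j)
  s <- 2^(n - 1) / (factorial(m) * m^d)
  dimnames(s) <- list(paste0("bucket", seq_len(n)), paste0("bucket", seq_len(n)))
  class(s) <- c("be_scoring_matrix", class(s))
  s
}

#' @export
print.be_scoring_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Levelled scoring matrix, %d buckets (top score %g)\n",
              nrow(x), x[1, 1]))
  print(signif(unclass(x), digits), ...)
  invisible(x)
}
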