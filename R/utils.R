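#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expected value for independent
#' random labelings.  Used to compare a dendrogram cut against
#' ground-truth compound labels.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number `<= 1`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
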