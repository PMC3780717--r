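# shared fixture builders and independent oracles

# strip be_sim attributes down to a plain matrix for value comparisons
as_plain <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

# random gene x experiment fitness matrix with unique dimnames
random_fm <- function(genes = 100, experiments = 3, seed = 1) {
  set.seed(seed)
  matrix(rnorm(genes * experiments), genes, experiments,
         dimnames = list(sprintf("g%04d", seq_len(genes)),
                         sprintf("e%02d", seq_len(experiments))))
}

# independent oracle for the levelled score of a single (i, j) cell
score_oracle <- function(i, j, n) {
  m <- max(i, j)
  2^(n - 1) / (prod(seq_len(m)) * m^abs(i - j))
}

# independent oracle for pair similarity: explicit per-gene loop using
# score_oracle, no scoring_matrix involved
pair_similarity_oracle <- function(bucket_a, bucket_b, n) {
  stopifnot(setequal(names(bucket_a), names(bucket_b)))
  total <- 0
  for (g in names(bucket_a)) {
    total <- total + score_oracle(bucket_a[[g]], bucket_b[[g]], n)
  }
  total
}

# brute-force two-sided rank-sum p: enumerate every assignment of pooled
# observations to group 1, re-ranking from scratch each time
wilcoxon_brute_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(length(pooled), n1)
  ws <- apply(sets, 2, function(idx) sum(rank(pooled)[idx]))
  eps <- 1e-8
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

# Figure-2-flavoured toy: three 7-gene profiles; exp1 and exp3 share the
# top-bucket gene, exp2 promotes a different gene
toy_three_experiments <- function() {
  genes <- paste0("g", 1:7)
  e1 <- c(9, 5, 4, 1, 0.5, 0.2, -1)
  e3 <- c(8, 4.5, 5, 0.8, 0.3, 0.1, -2)   # same leaders, mild reorder
  e2 <- c(0.1, 1, 0.4, 7, 6, 0.2, -0.5)   # different leaders
  fm <- cbind(e1 = e1, e2 = e2, e3 = e3)
  rownames(fm) <- genes
  fm
}
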