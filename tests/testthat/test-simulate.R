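small_cfg <- function(seed = 3, ...) {
  synthetic_config(num_genes = 800, n_compounds = 3,
                   replicates_per_compound = 4, num_dates = 3,
                   sensitive_set_size = 15, seed = seed, ...)
}

test_that("same seed reproduces the dataset bit for bit", {
  d1 <- simulate_profiles(small_cfg())
  d2 <- simulate_profiles(small_cfg())
  expect_identical(d1$fitness, d2$fitness)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_profiles(small_cfg(seed = 4))
  expect_false(identical(d1$fitness, d3$fitness))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(simulate_profiles(small_cfg()))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("layout: labels cover all experiments, sets disjoint, design stated", {
  cfg <- synthetic_config(seed = 2)
  d <- simulate_profiles(cfg)
  expect_identical(dim(d$fitness), c(6000L, 24L))
  expect_identical(colnames(d$fitness), d$metadata$experiment_id)
  expect_identical(as.integer(table(d$metadata$compound)), rep(8L, 3))
  expect_identical(as.integer(table(d$metadata$date)), rep(4L, 6))
  sens <- unlist(d$truth$sensitive_sets)
  expect_identical(anyDuplicated(sens), 0L)
  # replicates of each compound spread over several dates
  spread <- tapply(d$metadata$date, d$metadata$compound,
                   function(x) length(unique(x)))
  expect_true(all(spread >= 2))
})

test_that("each experiment's top gene belongs to its compound's sensitive set", {
  d <- simulate_profiles(small_cfg(seed = 6))
  for (e in colnames(d$fitness)) {
    cmpd <- d$truth$compound[[e]]
    top_gene <- rownames(d$fitness)[which.max(d$fitness[, e])]
    expect_true(top_gene %in% d$truth$sensitive_sets[[cmpd]])
  }
})

test_that("noise-free limit: replicates rank sensitive genes identically", {
  d <- simulate_profiles(small_cfg(seed = 9, rank_jitter_sd = 0,
                                   batch_shift_sd = 0))
  cmpd <- d$truth$compound
  for (cc in unique(cmpd)) {
    reps <- names(cmpd)[cmpd == cc]
    sens <- d$truth$sensitive_sets[[cc]]
    ranks <- sapply(reps, function(e) rank(-d$fitness[sens, e]))
    expect_true(all(ranks == ranks[, 1]))
  }
})

test_that("profiles are heavy-tailed: few genes far above background", {
  d <- simulate_profiles(small_cfg(seed = 12))
  sd_bg <- 1
  frac <- colMeans(d$fitness > 0 + 3 * sd_bg)
  expect_true(all(frac < 0.05))
})

test_that("replicate top-k overlap is high by default and falls with jitter", {
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  mean_overlap <- function(jit, seeds) {
    mean(sapply(seeds, function(s) {
      d <- simulate_profiles(small_cfg(seed = s, rank_jitter_sd = jit))
      k <- 15
      tops <- apply(d$fitness, 2, function(x)
        rownames(d$fitness)[order(-x)[1:k]], simplify = FALSE)
      cmpd <- d$truth$compound
      pairs <- combn(names(cmpd)[cmpd == cmpd[[1]]], 2)
      mean(apply(pairs, 2, function(p) jaccard(tops[[p[1]]], tops[[p[2]]])))
    }))
  }
  seeds <- 1:20
  low <- mean_overlap(0.15, seeds)
  high <- mean_overlap(2.5, seeds)
  expect_gte(low, 0.6)
  expect_lt(high, low)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(num_genes = 100, n_compounds = 3,
                                sensitive_set_size = 40),
               "exceed")
  expect_error(synthetic_config(signal_top_range = c(31, 22)), "low < high")
  expect_error(synthetic_config(background_sd = 0), "positive")
  expect_error(synthetic_config(num_genes = 0), "positive integer")
})
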