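make_sim <- function(m) {
  structure(m, method = "toy", normalized = FALSE, class = c("be_sim", "matrix"))
}

test_that("pair partition places every unordered pair exactly once", {
  ids <- c("e1", "e2", "e3")
  s <- matrix(c(1, .9, .1, .9, 1, .2, .1, .2, 1), 3, 3,
              dimnames = list(ids, ids))
  meta <- data.frame(experiment_id = ids, date = c("A", "A", "B"))
  part <- partition_pair_scores(make_sim(s), meta, "date")
  expect_identical(names(part$same), "e1|e2")
  expect_setequal(names(part$diff), c("e1|e3", "e2|e3"))
  expect_identical(unname(part$same), 0.9)

  # all labels identical: diff empty (untestable downstream)
  meta2 <- data.frame(experiment_id = ids, date = rep("A", 3))
  part2 <- partition_pair_scores(make_sim(s), meta2, "date")
  expect_length(part2$diff, 0)
  expect_length(part2$same, 3)
})

test_that("partition conservation over randomized labelings", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    ids <- sprintf("e%02d", seq_len(n))
    m <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    meta <- data.frame(experiment_id = ids,
                       lab = sample(LETTERS[1:3], n, replace = TRUE))
    part <- partition_pair_scores(make_sim(m), meta, "lab")
    expect_identical(length(part$same) + length(part$diff),
                     as.integer(choose(n, 2)))
  }
  # 4 experiments [A,A,B,B]: 2 same, 4 diff
  ids <- sprintf("e%d", 1:4)
  m <- diag(4); dimnames(m) <- list(ids, ids)
  meta <- data.frame(experiment_id = ids, lab = c("A", "A", "B", "B"))
  part <- partition_pair_scores(make_sim(m), meta, "lab")
  expect_length(part$same, 2)
  expect_length(part$diff, 4)
})

test_that("partition validates factor and metadata coverage", {
  ids <- c("e1", "e2")
  m <- diag(2); dimnames(m) <- list(ids, ids)
  meta <- data.frame(experiment_id = "e1", date = "A")
  expect_error(partition_pair_scores(make_sim(m), meta, "nope"), "unknown")
  expect_error(partition_pair_scores(make_sim(m), meta, "date"),
               "without metadata")
})

test_that("exact rank-sum test matches hand-enumerated and brute-force p", {
  t1 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$p_value, 0.1)
  expect_identical(t1$method, "exact")
  expect_identical(t1$W, 6)

  # identical multisets: no shift, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # two-sidedness: swapping the vectors preserves p
  set.seed(31)
  for (rep in 1:20) {
    x <- sample(1:8, sample(2:7, 1), replace = TRUE)  # ties likely
    y <- sample(1:8, sample(2:7, 1), replace = TRUE)
    a <- wilcoxon_rank_sum(x, y)
    b <- wilcoxon_rank_sum(y, x)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$p_value, wilcoxon_brute_p(x, y))
    expect_gt(a$p_value, 0)
    expect_lte(a$p_value, 1)
  }
})

test_that("exact branch agrees with stats::wilcox.test on tie-free data", {
  set.seed(41)
  for (rep in 1:10) {
    x <- rnorm(sample(4:9, 1))
    y <- rnorm(sample(4:9, 1))
    mine <- wilcoxon_rank_sum(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation stays close to exact at the size boundary", {
  set.seed(51)
  for (rep in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    ex <- wilcoxon_rank_sum(x, y, exact_max = 10)
    ap <- wilcoxon_rank_sum(x, y, exact_max = 5)
    expect_identical(ex$method, "exact")
    expect_identical(ap$method, "normal")
    expect_lt(abs(ap$p_value - ex$p_value) / ex$p_value, 0.10)
  }
})

test_that("empty vectors are untestable", {
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  expect_error(wilcoxon_rank_sum(1:3, numeric(0)), "non-empty")
})

test_that("identical columns merge first under average linkage", {
  fm <- random_fm(60, 3, seed = 13)
  fm[, 2] <- fm[, 1] + 1e-9
  sim <- be_similarity(fm, 0.05, 2, 4)
  tree <- cluster_experiments(sim)
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first, c("e01", "e02"))
})

test_that("asymmetric input is rejected; newick round-trips labels", {
  m <- matrix(c(1, 0.5, 0.2, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(cluster_experiments(make_sim(m)), "symmetric")

  fm <- random_fm(40, 4, seed = 14)
  tree <- cluster_experiments(be_similarity(fm, 0.05, 2, 4))
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(fm))
})

test_that("batch report covers method x factor and flags untestable rows", {
  d <- simulate_profiles(synthetic_config(
    num_genes = 400, n_compounds = 2, replicates_per_compound = 3,
    num_dates = 3, sensitive_set_size = 10, seed = 5))
  rep1 <- batch_effect_report(d$fitness, d$metadata,
                              methods = c("be", "pearson"))
  expect_identical(nrow(rep1), 4L)
  expect_setequal(rep1$factor, c("date", "compound"))
  expect_true(all(rep1$testable))
  expect_true(all(rep1$n_same + rep1$n_diff == choose(6, 2)))

  # single compound: compound factor untestable
  meta1 <- d$metadata
  meta1$compound <- "only"
  rep2 <- batch_effect_report(d$fitness, meta1, methods = "be")
  expect_false(rep2$testable[rep2$factor == "compound"])
  expect_true(is.na(rep2$p_value[rep2$factor == "compound"]))

  # empty method list: empty report, no error
  rep3 <- batch_effect_report(d$fitness, d$metadata, methods = character(0))
  expect_identical(nrow(rep3), 0L)
  expect_error(batch_effect_report(d$fitness, d$metadata, methods = "cosine"),
               "unknown method")
})
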