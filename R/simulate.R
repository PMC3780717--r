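#' Configuration for the synthetic chemogenomic-profile generator
#'
#' Bundles and validates the generator parameters.  Defaults describe a
#' typical pooled yeast deletion-collection screen: ~6000 strains, a
#' handful of compounds with a few dozen truly sensitive strains each,
#' replicate screens whose top scores land on different scales (top fitness
#' defect drawn uniformly from 22–31, i.e. a 10^6- to 10^9-fold abundance
#' drop), mild reshuffling of the top ranks between replicates, and a
#' date-linked additive nuisance shift acting on a fixed subset of
#' midrange genes.
#'
#' @param num_genes Number of genes/strains per profile.
#' @param n_compounds Number of distinct compounds.
#' @param replicates_per_compound Replicate screens per compound.
#' @param num_dates Number of run dates; experiments are laid out in
#'   duplicate pairs, two compounds per date, so replicates of one compound
#'   spread over several dates and the within-date pair composition stays
#'   close to the overall composition (date and compound unconfounded).
#' @param sensitive_set_size Truly sensitive genes per compound (disjoint
#'   across compounds).
#' @param signal_top_range Range (low, high) for the per-experiment top
#'   fitness defect; default `c(22, 31)` (log2 units).
#' @param signal_floor Relative weight of the weakest sensitive gene; the
#'   per-gene signal weights fall linearly from 1 to this value.
#' @param rank_jitter_sd SD of Gaussian jitter on the signal weights; makes
#'   replicate top lists overlap but reorder.
#' @param batch_shift_sd Scale (SD of the underlying normal) of the
#'   per-date half-normal depletion shift applied to the nuisance gene
#'   subset (log2 units).  The shift is one-sided (negative): day-specific
#'   artifacts make a subset of strains look less depleted, moving them
#'   down-rank into the large low-significance buckets rather than up into
#'   the scoring buckets.
#' @param midrange_fraction Fraction of genes (outside every sensitive set)
#'   in the date-shifted nuisance subset.
#' @param background_sd SD of the background fitness-defect noise.
#' @param seed Integer seed driving all randomness; same seed, same dataset.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(num_genes = 6000L, n_compounds = 3L,
                             replicates_per_compound = 8L, num_dates = 6L,
                             sensitive_set_size = 30L,
                             signal_top_range = c(22, 31),
                             signal_floor = 0.3,
                             rank_jitter_sd = 0.15,
                             batch_shift_sd = 1,
                             midrange_fraction = 0.2,
                             background_sd = 1,
                             seed = 1L) {
  cfg <- list(num_genes = as.integer(num_genes),
              n_compounds = as.integer(n_compounds),
              replicates_per_compound = as.integer(replicates_per_compound),
              num_dates = as.integer(num_dates),
              sensitive_set_size = as.integer(sensitive_set_size),
              signal_top_range = as.numeric(signal_top_range),
              signal_floor = as.numeric(signal_floor),
              rank_jitter_sd = as.numeric(rank_jitter_sd),
              batch_shift_sd = as.numeric(batch_shift_sd),
              midrange_fraction = as.numeric(midrange_fraction),
              background_sd = as.numeric(background_sd),
              seed = as.integer(seed))
  counts <- c("num_genes", "n_compounds", "replicates_per_compound",
              "num_dates", "sensitive_set_size")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop(sprintf("`%s` must be a positive integer", f), call. = FALSE)
    }
  }
  if (length(cfg$signal_top_range) != 2L ||
      cfg$signal_top_range[1] >= cfg$signal_top_range[2]) {
    stop("`signal_top_range` must be c(low, high) with low < high",
         call. = FALSE)
  }
  if (cfg$rank_jitter_sd < 0 || cfg$batch_shift_sd < 0 ||
      cfg$background_sd <= 0) {
    stop("noise SDs must be non-negative (background_sd positive)",
         call. = FALSE)
  }
  if (cfg$midrange_fraction < 0 || cfg$midrange_fraction >= 1) {
    stop("`midrange_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$sensitive_set_size * cfg$n_compounds +
      ceiling(cfg$midrange_fraction * cfg$num_genes) > cfg$num_genes) {
    stop("sensitive sets plus nuisance subset exceed the gene count",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic chemogenomic fitness dataset with known structure
#'
#' Emulates the qualitative features of replicate pooled-deletion screens:
#' a heavy-tailed profile where a few strains show a large fitness defect
#' and the bulk hovers around zero; replicate experiments that share their
#' top-sensitive strains but differ in score scale and in the exact order
#' of the top ranks; and a date-linked nuisance shift that perturbs a fixed
#' subset of midrange genes identically for all experiments run on the
#' same date.  The nuisance shift is a one-sided apparent-depletion
#' artifact (half-normal, negative), so affected genes sink into the large
#' low-significance buckets instead of climbing into the scoring buckets.
#' The compound signal lives in the extreme top ranks; the date
#' effect lives in the midrange — so rank-group scoring should recover
#' compounds while value-based correlation also picks up dates.
#'
#' @param config A [synthetic_config()].
#' @return A list with:
#'   * `fitness`: genes x experiments numeric matrix;
#'   * `metadata`: data frame `experiment_id`, `date`, `compound`;
#'   * `truth`: list with `compound` and `date` label vectors (named by
#'     experiment) and `sensitive_sets` (list of gene-id vectors per
#'     compound).
#' @examples
#' d <- simulate_profiles(synthetic_config(num_genes = 500, seed = 7))
#' dim(d$fitness)
#' @export
simulate_profiles <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  # localize RNG: restore the caller's state on exit
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(config$seed)

  G <- config$num_genes
  nc <- config$n_compounds
  nr <- config$replicates_per_compound
  ne <- nc * nr
  genes <- sprintf("g%05d", seq_len(G))
  compounds <- sprintf("cmpd%02d", seq_len(nc))
  dates <- sprintf("d%02d", seq_len(config$num_dates))

  # disjoint sensitive sets
  k <- config$sensitive_set_size
  sens_idx <- matrix(sample.int(G, nc * k), nrow = k)
  sensitive_sets <- lapply(seq_len(nc), function(c) genes[sens_idx[, c]])
  names(sensitive_sets) <- compounds

  # fixed nuisance subset of midrange genes (outside all sensitive sets)
  n_mid <- as.integer(round(config$midrange_fraction * G))
  pool <- setdiff(seq_len(G), as.vector(sens_idx))
  mid_idx <- if (n_mid > 0L) sample(pool, n_mid) else integer(0)
  date_shift <- lapply(dates, function(d)
    -abs(stats::rnorm(n_mid, 0, config$batch_shift_sd)))
  names(date_shift) <- dates

  # layout: duplicate pairs of one compound, chunked into dates — for the
  # default 3x8 design each date hosts 2+2 replicates of two compounds
  exp_compound <- rep(rep(compounds, each = 2L), times = nr %/% 2L)
  if (nr %% 2L == 1L) exp_compound <- c(exp_compound, compounds)
  per_date <- ceiling(ne / config$num_dates)
  exp_date <- rep(dates, each = per_date)[seq_len(ne)]
  exp_id <- sprintf("exp%02d", seq_len(ne))

  w <- seq(1, config$signal_floor, length.out = k)
  fm <- matrix(NA_real_, G, ne, dimnames = list(genes, exp_id))
  for (e in seq_len(ne)) {
    x <- stats::rnorm(G, 0, config$background_sd)
    if (n_mid > 0L) x[mid_idx] <- x[mid_idx] + date_shift[[exp_date[e]]]
    top <- stats::runif(1, config$signal_top_range[1],
                        config$signal_top_range[2])
    jit <- stats::rnorm(k, 0, config$rank_jitter_sd)
    ci <- match(exp_compound[e], compounds)
    x[sens_idx[, ci]] <- top * (w + jit)
    fm[, e] <- x
  }

  metadata <- data.frame(experiment_id = exp_id, date = exp_date,
                         compound = exp_compound, stringsAsFactors = FALSE)
  truth <- list(
    compound = stats::setNames(exp_compound, exp_id),
    date = stats::setNames(exp_date, exp_id),
    sensitive_sets = sensitive_sets
  )
  list(fitness = fm, metadata = metadata, truth = truth)
}
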