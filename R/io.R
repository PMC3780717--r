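#' Read a fitness-defect matrix from TSV
#'
#' Expected dialect: UTF-8 tab-delimited text, header row of experiment
#' ids, first column of gene ids, decimal fitness-defect scores in the
#' cells; an empty cell or `NA` marks a missing score.
#'
#' @param path File path.
#' @return Numeric genes x experiments matrix with rownames and colnames.
#' @export
read_fitness_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("fitness matrix file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) {
    stop(sprintf("%s: need a gene-id column plus at least one experiment",
                 path), call. = FALSE)
  }
  gene_ids <- as.character(df[[1]])
  dup <- which(duplicated(gene_ids))
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate gene id '%s' at data line %d",
                 path, gene_ids[dup[1]], dup[1]), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))) & !is.na(vals), arr.ind = TRUE)
    stop(sprintf("%s: non-numeric cell at data line %d, column '%s'",
                 path, bad[1, 1], colnames(vals)[bad[1, 2]]), call. = FALSE)
  }
  rownames(vals) <- gene_ids
  check_fitness_matrix(vals)
  vals
}

#' Write a fitness-defect matrix as TSV
#'
#' Inverse of [read_fitness_matrix()]; missing values are written as `NA`.
#'
#' @param fm Numeric genes x experiments matrix.
#' @param path Output file.
#' @param id_column Header of the gene-id column (default `"gene_id"`).
#' @return The path, invisibly.
#' @export
write_fitness_matrix <- function(fm, path, id_column = "gene_id") {
  check_fitness_matrix(fm)
  df <- data.frame(rownames(fm), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read experiment metadata from TSV
#'
#' Requires columns `experiment_id`, `date`, `compound`; extra factor
#' columns are kept.
#'
#' @param path File path.
#' @return Data frame with unique `experiment_id` values.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "",
                          colClasses = "character")
  required <- c("experiment_id", "date", "compound")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing metadata column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$experiment_id)) {
    stop(sprintf("%s: duplicate experiment_id", path), call. = FALSE)
  }
  df
}

#' Write experiment metadata as TSV
#' @param meta Data frame with `experiment_id` plus factor columns.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a similarity matrix as TSV
#'
#' Header and first column carry the experiment ids, in input order.
#'
#' @param sim A `be_sim` (or plain) matrix.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_similarity <- function(sim, path) {
  m <- unclass(sim)
  df <- data.frame(colnames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- "experiment_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity()]
#' @param path File path.
#' @return A symmetric numeric matrix with experiment dimnames.
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!identical(rownames(m), colnames(m))) {
    stop(sprintf("%s: row and column experiment ids differ", path),
         call. = FALSE)
  }
  m
}

#' Fitness defects from barcode count pairs
#'
#' Converts treatment/control barcode counts to per-strain fitness defects
#' `log2((control + pseudocount) / (treatment + pseudocount))`, so strains
#' depleted under treatment (sensitive) score high, matching the bucket-1
#' convention.  Set `orientation = "treatment_over_control"` for the
#' opposite sign convention.
#'
#' @param treatment,control Non-negative count vectors or matrices with
#'   matching gene names; matrices are compared column-by-column.
#' @param pseudocount Positive value added to both counts (default 1)
#'   guarding against zero counts.
#' @param orientation `"control_over_treatment"` (default; sensitivity
#'   positive) or `"treatment_over_control"`.
#' @return Numeric vector or matrix of log2-ratio fitness defects.
#' @examples
#' fitness_from_counts(treatment = c(geneA = 1), control = c(geneA = 1024))
#' # ~ 9.0
#' @export
fitness_from_counts <- function(treatment, control, pseudocount = 1,
                                orientation = c("control_over_treatment",
                                                "treatment_over_control")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  }
  if (any(treatment < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (!identical(dim(treatment), dim(control)) ||
      length(treatment) != length(control)) {
    stop("treatment and control must have identical shape", call. = FALSE)
  }
  fd <- log2((control + pseudocount) / (treatment + pseudocount))
  if (orientation == "treatment_over_control") fd <- -fd
  fd
}

#' Read a key-value run configuration file
#'
#' Minimal `key: value` (or `key = value`) format, one pair per line;
#' `#` starts a comment.  Recognized keys: `preset`, `initial_fraction`,
#' `growth_factor`, `max_buckets`, `method`, `factor`, `seed`, `normalize`.
#' Numeric-looking values are converted.
#'
#' @param path File path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.-]*)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("%s: cannot parse config line '%s'", path, ln),
           call. = FALSE)
    }
    key <- m[2]
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (val %in% c("true", "TRUE", "yes")) val <- TRUE
    else if (val %in% c("false", "FALSE", "no")) val <- FALSE
    out[[key]] <- val
  }
  out
}
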