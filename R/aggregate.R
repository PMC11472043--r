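#' Genome-wide sgRNA specificity distribution
#'
#' For a guide with on-target site and M putative off-target sites, each
#' site's predictive count distribution is sampled `n_samp` times and the
#' specificity score sample `s` is
#'
#'   y_sg[s] = log( sum_i off_draw_i[s] / max(on_draw[s], floor) )
#'
#' i.e. the log-ratio of summed off-target activity to on-target activity.
#' Lower values mean higher genome-wide specificity. The result is a full
#' distribution over `y_sg`, enabling prioritization among guides with
#' similar point aggregate scores.
#'
#' @name aggregate-score
NULL

new_aggregate_distribution <- function(samples, meta) {
  structure(list(samples = samples,
                 mean = mean(samples),
                 cv = stats::sd(samples) / abs(mean(samples)),
                 quantiles = stats::quantile(samples, c(0.05, 0.25, 0.5, 0.75, 0.95)),
                 meta = meta),
            class = "aggregate_distribution")
}

# core sample combiner: on_draws length n_samp, off_draws M x n_samp
aggregate_samples <- function(on_draws, off_draws, count_floor = 1,
                              log_base = exp(1)) {
  num <- if (is.matrix(off_draws)) colSums(off_draws) else off_draws
  y <- log(pmax(num, count_floor) / pmax(on_draws, count_floor)) / log(log_base)
  y
}

#' Aggregate score from known per-site ZINB parameters
#'
#' @param on_params List/row with `pi`, `mu`, `theta` for the on-target.
#' @param off_params Data frame of per-off-target `pi`, `mu`, `theta`
#'   (M rows).
#' @param n_samp Number of Monte-Carlo samples of the score distribution.
#' @param seed Integer seed.
#' @param count_floor Zero-count guard: draws entering the ratio are
#'   floored at this count (the on-target posterior should have
#'   `pi` near 0, making the denominator floor rare).
#' @param log_base Base of the logarithm (natural by default; the ranking
#'   of guides is base-invariant).
#' @return An `aggregate_distribution`: `samples`, `mean`, `cv`,
#'   `quantiles`.
#' @export
aggregate_from_params <- function(on_params, off_params, n_samp = 1000L,
                                  seed = 1L, count_floor = 1,
                                  log_base = exp(1)) {
  M <- nrow(as.data.frame(off_params))
  if (M < 1L) stop("at least one off-target site is required")
  if (n_samp < 1L) stop("'n_samp' must be >= 1")
  off_params <- as.data.frame(off_params)
  samples <- with_seed(seed, {
    on_draws <- zinb_sample(n_samp, on_params$pi, on_params$mu, on_params$theta)
    off_draws <- t(vapply(seq_len(M), function(i)
      zinb_sample(n_samp, off_params$pi[i], off_params$mu[i], off_params$theta[i]),
      numeric(n_samp)))
    aggregate_samples(on_draws, off_draws, count_floor, log_base)
  })
  new_aggregate_distribution(samples, meta = list(M = M, n_samp = n_samp,
                                                  count_floor = count_floor,
                                                  log_base = log_base,
                                                  seed = seed))
}

#' Aggregate specificity score of an sgRNA
#'
#' Runs the trained model on the on-target site and every off-target site,
#' then Monte-Carlo samples the log-ratio score distribution.
#'
#' @param model Trained zinb-head `ot_model`.
#' @param genome Reference genome.
#' @param on_target One-row site table for the 0-mismatch on-target.
#' @param off_targets Site table of M putative off-target sites (e.g. from
#'   [parse_offtarget_search()]).
#' @param max_mismatches Maximum allowed mismatches N for off-target sites
#'   (default 5).
#' @inheritParams aggregate_from_params
#' @export
aggregate_score <- function(model, genome, on_target, off_targets,
                            max_mismatches = 5L, n_samp = 1000L, seed = 1L,
                            count_floor = 1, log_base = exp(1)) {
  stopifnot(inherits(model, "ot_model"))
  if (model$head != "zinb") stop("aggregate_score requires a zinb-head model")
  if (nrow(off_targets) < 1L) stop("empty off-target list")
  if (mismatch_count(on_target$sgrna_seq[1], on_target$target_seq[1]) != 0L)
    stop("on-target site must have 0 mismatches")
  mm <- mismatch_count(off_targets$sgrna_seq, off_targets$target_seq)
  if (any(mm > max_mismatches))
    stop(sprintf("off-target with %d mismatches exceeds max_mismatches = %d",
                 max(mm), max_mismatches))
  all_sites <- rbind(on_target[, c("sgrna_seq", "target_seq", "chrom", "start", "strand")],
                     off_targets[, c("sgrna_seq", "target_seq", "chrom", "start", "strand")])
  xs <- encode_pairs(all_sites)
  cfg <- model$norm_stats$descriptor_config %||% descriptor_config()
  cfg$norm <- model$norm_stats$descriptor_norm
  xp <- descriptor_matrices(genome, all_sites, cfg)
  params <- model_predict(model, xs, xp)
  out <- aggregate_from_params(params[1, ], params[-1, ], n_samp = n_samp,
                               seed = seed, count_floor = count_floor,
                               log_base = log_base)
  out$meta$max_mismatches <- max_mismatches
  out
}

#' Parse a genome-search output file into a site table
#'
#' Supported dialect: tab-separated, no header, columns (sgRNA pattern
#' possibly containing N, matched target sequence, chrom, 0-based
#' position, strand, mismatch count) - the layout emitted by popular
#' putative off-target search tools. Lowercase bases (used by some tools to
#' mark mismatched positions) are uppercased. Duplicate sites (same chrom,
#' start and strand) are removed, keeping the first occurrence.
#'
#' @param path Search output file.
#' @return Site table data frame with `sgrna_seq`, `target_seq`, `chrom`,
#'   `start`, `strand`, `mismatches`; empty file gives a zero-row table.
#' @export
parse_offtarget_search <- function(path) {
  if (!file.exists(path)) stop(sprintf("search output '%s' not found", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(sgrna_seq = character(), target_seq = character(),
                      chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L)
      stop(sprintf("parse error at line %d: expected 6 tab-separated fields, got %d",
                   i, length(f)))
    start <- suppressWarnings(as.integer(f[4]))
    mm <- suppressWarnings(as.integer(f[6]))
    if (is.na(start) || is.na(mm))
      stop(sprintf("parse error at line %d: non-numeric position or mismatch count", i))
    if (!f[5] %in% c("+", "-"))
      stop(sprintf("parse error at line %d: strand must be '+' or '-'", i))
    sg <- toupper(f[1]); tg <- toupper(f[2])
    if (nchar(sg) != 23L || nchar(tg) != 23L)
      stop(sprintf("parse error at line %d: sequences must be 23 nt", i))
    data.frame(sgrna_seq = sg, target_seq = tg, chrom = f[3], start = start,
               strand = f[5], mismatches = mm, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[!duplicated(df[, c("chrom", "start", "strand")]), , drop = FALSE]
}

#' Empirical CDF of an aggregate score distribution
#'
#' @param dist An `aggregate_distribution`.
#' @param grid Numeric grid of score values.
#' @return Right-continuous empirical CDF values at `grid` (nondecreasing;
#'   1 at and beyond the sample maximum).
#' @export
aggregate_cdf <- function(dist, grid) {
  stopifnot(inherits(dist, "aggregate_distribution"))
  if (length(dist$samples) == 0L) stop("empty sample set")
  vapply(grid, function(g) mean(dist$samples <= g), numeric(1))
}
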