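#' Read a tab-separated site table
#'
#' The site-table dialect used throughout the package: a header line and the
#' columns `sgrna_seq`, `target_seq`, `chrom`, `start`, `strand` and
#' optionally `read_count`. Coordinates are 0-based half-open (a site spans
#' `[start, start + 23)` on the plus strand).
#'
#' @param path File path.
#' @param one_based If `TRUE`, input `start` values are 1-based and are
#'   shifted to the internal 0-based convention on load.
#' @return Data frame of validated site records; `read_count`, when present,
#'   is rounded to the nearest integer (pmf evaluation is discrete).
#' @export
read_site_table <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop(sprintf("site table '%s' not found", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sgrna_seq", "target_seq", "chrom", "start", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("site table '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  validate_site_table(df, path)
  if (one_based) df$start <- df$start - 1L
  if ("read_count" %in% names(df)) df$read_count <- round(df$read_count)
  df
}

validate_site_table <- function(df, path = "<site table>") {
  for (r in seq_len(nrow(df))) {
    line <- r + 1L  # header is line 1
    if (nchar(df$sgrna_seq[r]) != 23L || nchar(df$target_seq[r]) != 23L)
      stop(sprintf("%s line %d: sequences must be 23 nt", path, line))
    if (grepl("[^ACGTNUacgtnu]", df$sgrna_seq[r]) ||
        grepl("[^ACGTNUacgtnu]", df$target_seq[r]))
      stop(sprintf("%s line %d: invalid base in sequence", path, line))
    if (!df$strand[r] %in% c("+", "-"))
      stop(sprintf("%s line %d: strand must be '+' or '-'", path, line))
    if (!is.finite(df$start[r]) || df$start[r] < 0)
      stop(sprintf("%s line %d: 'start' must be a nonnegative coordinate", path, line))
    if ("read_count" %in% names(df) && !is.na(df$read_count[r]) && df$read_count[r] < 0)
      stop(sprintf("%s line %d: 'read_count' must be >= 0", path, line))
  }
  invisible(df)
}

#' Write a site table
#' @param sites Site data frame.
#' @param path Output path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize read counts across sgRNAs
#'
#' Two linear steps: (1) each sgRNA's counts are multiplied by
#' `target_total / sgrna_total`, where `target_total` is the mean of the
#' per-sgRNA read totals, so that all sgRNAs carry equal total signal;
#' (2) all counts are multiplied by `ceiling / max(count)` so the global
#' maximum equals the configured ceiling (10 000 by default). Both factors
#' are stored so the transformation can be inverted.
#'
#' @param sites Site data frame with a `read_count` column.
#' @param ceiling Target global maximum after scaling.
#' @param round Round the normalized counts to integers (done once at
#'   dataset load because pmf evaluation is discrete); set to `FALSE` to
#'   keep the exact linear transform.
#' @return The data frame with normalized `read_count` plus attributes
#'   `guide_factors` (named per-sgRNA step-1 factors), `global_factor` and
#'   `scale_ceiling`.
#' @export
normalize_read_counts <- function(sites, ceiling = 10000, round = TRUE) {
  if (!"read_count" %in% names(sites)) stop("no 'read_count' column to normalize")
  y <- sites$read_count
  if (all(y == 0)) stop("normalization error: all read counts are zero")
  totals <- tapply(y, sites$sgrna_seq, sum)
  target_total <- mean(totals)
  gf <- ifelse(totals > 0, target_total / totals, 1)
  y1 <- y * gf[sites$sgrna_seq]
  global <- ceiling / max(y1)
  out <- sites
  out$read_count <- if (round) base::round(as.numeric(y1 * global))
                    else as.numeric(y1 * global)
  attr(out, "guide_factors") <- gf
  attr(out, "global_factor") <- global
  attr(out, "scale_ceiling") <- ceiling
  out
}

#' Save a trained model checkpoint
#'
#' Single-file archive holding the network weights, architecture and
#' training configuration snapshots, descriptor normalization statistics and
#' provenance metadata, with a format version tag.
#'
#' @param model A trained model (see [train_model()]).
#' @param path Destination path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ot_model"))
  obj <- list(format = "crisprZINB-checkpoint-1", model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint path written by [save_checkpoint()].
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "crisprZINB-checkpoint-1"))
    stop(sprintf("checkpoint version mismatch in '%s' (found '%s')",
                 path, obj$format %||% "<none>"))
  obj$model
}

#' Write a per-site scores table
#'
#' Tab-separated columns: `site_id`, `pi`, `mu`, `theta`, `mean`, `cv`,
#' `ucb95`, `mismatches`.
#'
#' @param scores Data frame as produced by [score_sites()].
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
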