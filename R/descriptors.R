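#' Physical descriptors of the 147-bp sequence context
#'
#' Each of the 23 site positions gets a 147-bp window (73-bp flank on each
#' side of the position) from the reference genome; minus-strand sites use
#' the reverse complement so windows read 5'->3' along the site. Four
#' descriptors are computed per window - block-decomposition (BDM)
#' complexity, GC content, nucleosome occupancy and nucleosome affinity -
#' giving a raw 4 x 23 matrix that is min-max normalized to [0, 1] with
#' statistics frozen on the training set.
#'
#' @name physical-descriptors
NULL

DESCRIPTOR_ROWS <- c("bdm", "gc", "nupop_occupancy", "nupop_affinity")

# named character vector of contig sequences from a DNAStringSet / file path
genome_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  stop("'genome' must be a DNAStringSet, a FASTA path, or a named character vector")
}

# integer codes A=1 T=2 G=3 C=4 N/other=5 for one contig string
contig_codes <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], ENC_ALPHABET)
  v[is.na(v)] <- 5L
  v
}

COMP_CODE <- c(2L, 1L, 4L, 3L, 5L)  # A<->T, G<->C, N->N under code order

# oriented 169-base context codes around a site (0-based start), N-padded
site_context_codes <- function(codes, start, strand, contig_len) {
  pos <- (start - 73):(start + 95)          # 0-based genomic positions
  idx <- pos + 1L
  ok <- idx >= 1L & idx <= contig_len
  ctx <- rep(5L, 169L)
  ctx[ok] <- codes[idx[ok]]
  if (strand == "-") ctx <- rev(COMP_CODE[ctx])
  ctx
}

codes_to_string <- function(v) paste(c(ENC_ALPHABET, "N")[v], collapse = "")

#' Extract the 23 context windows of a site
#'
#' Window `j` (1-based) is the 147-bp genomic window centered on site base
#' `j`; on minus-strand sites the window sequence is reverse-complemented so
#' that its center base equals `target_seq[j]`.
#'
#' @param genome Reference genome (`DNAStringSet`, FASTA path, or named
#'   character vector of contigs).
#' @param site One-row site record (list/data.frame row with `chrom`,
#'   `start`, `strand`).
#' @return List of 23 windows, each a list with `chrom`, `center` (0-based
#'   plus-strand coordinate of the center base), `strand` and `seq`
#'   (147-character string, N-padded at contig edges).
#' @export
extract_windows <- function(genome, site) {
  gs <- genome_strings(genome)
  if (!site$chrom %in% names(gs))
    stop(sprintf("contig '%s' not found in genome", site$chrom))
  clen <- nchar(gs[[site$chrom]])
  if (site$start < 0 || site$start + 23 > clen)
    stop(sprintf("site %s:%d outside contig bounds (length %d)",
                 site$chrom, site$start, clen))
  ctx <- site_context_codes(contig_codes(gs[[site$chrom]]), site$start,
                            site$strand, clen)
  lapply(1:23, function(j) {
    center <- if (site$strand == "+") site$start + j - 1L else site$start + 23L - j
    list(chrom = site$chrom, center = center, strand = site$strand,
         seq = codes_to_string(ctx[j:(j + 146L)]))
  })
}

window_seq <- function(window) if (is.list(window)) window$seq else window

#' GC content of a context window
#'
#' Proportion of G and C bases over the full window length; N and other
#' ambiguous bases count toward the denominator only.
#'
#' @param window A window from [extract_windows()] or a plain DNA string.
#' @export
gc_content <- function(window) {
  s <- window_seq(window)
  if (nchar(s) == 0L) stop("empty window")
  v <- contig_codes(s)
  sum(v == 3L | v == 4L) / length(v)
}

block_entropy_complexity <- function(block_codes, block_size) {
  f <- tabulate(block_codes, 5L) / block_size
  f <- f[f > 0]
  block_size * -sum(f * log2(f))
}

#' Block-decomposition complexity of a window
#'
#' The window is partitioned into non-overlapping blocks of `block_size`
#' (remainder dropped) and the standard block-decomposition aggregation is
#' applied: the sum over distinct blocks of the block's complexity plus
#' log2 of its multiplicity. Block complexities come from a user-supplied
#' k-mer table when given; otherwise a Shannon-entropy-per-block fallback
#' (N treated as a fifth symbol) keeps the descriptor self-contained.
#'
#' @inheritParams gc_content
#' @param block_size Block length in bp (default 12).
#' @param block_table Optional named numeric vector mapping k-mer strings to
#'   complexities.
#' @param fallback Use the entropy fallback for blocks absent from the
#'   table; with `fallback = FALSE` and no usable table entries this is a
#'   configuration error.
#' @export
bdm_score <- function(window, block_size = 12L, block_table = NULL, fallback = TRUE) {
  s <- window_seq(window)
  if (block_size < 1L) stop("'block_size' must be >= 1")
  nb <- nchar(s) %/% block_size
  if (nb == 0L) stop("window shorter than one block")
  blocks <- substring(s, (0:(nb - 1L)) * block_size + 1L, (1:nb) * block_size)
  cx <- rep(NA_real_, nb)
  if (!is.null(block_table)) cx <- unname(block_table[blocks])
  need <- is.na(cx)
  if (any(need)) {
    if (!fallback)
      stop("configuration error: block(s) absent from 'block_table' and fallback disabled")
    cx[need] <- vapply(blocks[need], function(b)
      block_entropy_complexity(contig_codes(b), block_size), numeric(1))
  }
  tab <- table(blocks)
  first <- !duplicated(blocks)
  sum(cx[first]) + sum(log2(as.numeric(tab)))
}

#' Nucleosome score providers
#'
#' Two interchangeable sources of per-base nucleosome occupancy/affinity:
#' a precomputed track file (tab-separated `chrom`, 0-based `pos`,
#' `occupancy`, `affinity`) and a deterministic sequence-derived surrogate.
#' The surrogate's affinity is the amplitude of the ~10-bp periodic
#' component of AA/TT/TA dinucleotide placement within the window (the
#' classic rotational positioning signal), and occupancy is a logistic
#' transform of that amplitude. The provider identity is recorded in model
#' metadata.
#'
#' @param path Track file path (for `nucleosome_track_provider`).
#' @return A provider object for [nucleosome_scores()].
#' @export
nucleosome_track_provider <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "occupancy", "affinity")
  if (!all(need %in% names(df)))
    stop(sprintf("track file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  key <- paste(df$chrom, df$pos, sep = ":")
  structure(list(type = "track",
                 occupancy = stats::setNames(df$occupancy, key),
                 affinity = stats::setNames(df$affinity, key)),
            class = "nucleosome_provider")
}

#' @rdname nucleosome_track_provider
#' @export
nucleosome_surrogate_provider <- function() {
  structure(list(type = "surrogate"), class = "nucleosome_provider")
}

#' Write a nucleosome track file
#' @param track Data frame with `chrom`, `pos`, `occupancy`, `affinity`.
#' @param path Output path.
#' @export
write_nucleosome_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

surrogate_from_dinucs <- function(d, tpos) {
  phase <- 2 * pi * tpos / 10
  amp <- sqrt(sum(d * cos(phase))^2 + sum(d * sin(phase))^2) / (sum(d) + 1)
  c(occupancy = stats::plogis(8 * amp - 2), affinity = amp)
}

#' Nucleosome occupancy and affinity of a window
#'
#' @param provider Provider from [nucleosome_track_provider()] or
#'   [nucleosome_surrogate_provider()].
#' @param window Window from [extract_windows()] (the track provider reads
#'   the value at the window's center position; the surrogate derives it
#'   from the window sequence).
#' @return Named numeric vector `c(occupancy, affinity)`.
#' @export
nucleosome_scores <- function(provider, window) {
  stopifnot(inherits(provider, "nucleosome_provider"))
  if (provider$type == "track") {
    key <- paste(window$chrom, window$center, sep = ":")
    occ <- provider$occupancy[key]
    aff <- provider$affinity[key]
    if (is.na(occ) || is.na(aff))
      stop(sprintf("position %s absent from nucleosome track", key))
    return(c(occupancy = unname(occ), affinity = unname(aff)))
  }
  v <- contig_codes(window_seq(window))
  n <- length(v)
  a <- v[-n]; b <- v[-1]
  d <- as.numeric((a == 1L & b == 1L) | (a == 2L & b == 2L) | (a == 2L & b == 1L))
  surrogate_from_dinucs(d, seq_along(d))
}

#' Descriptor configuration
#'
#' @param block_size,block_table,fallback Passed to [bdm_score()].
#' @param provider Nucleosome score provider.
#' @param norm Optional normalization statistics from
#'   [fit_descriptor_norm()]; when present, descriptor rows are min-max
#'   scaled and clipped to [0, 1].
#' @export
descriptor_config <- function(block_size = 12L, block_table = NULL,
                              fallback = TRUE,
                              provider = nucleosome_surrogate_provider(),
                              norm = NULL) {
  structure(list(block_size = block_size, block_table = block_table,
                 fallback = fallback, provider = provider, norm = norm),
            class = "descriptor_config")
}

#' Fit min-max normalization statistics for descriptor rows
#'
#' Computed once on the training set and persisted with the model; applying
#' the model to new data reuses the stored statistics and clips to [0, 1].
#'
#' @param raw Array `(n_sites, 23, 4)` of raw descriptor values (from
#'   [descriptor_matrices()] with `config$norm = NULL`), or a list of raw
#'   4 x 23 matrices.
#' @return List with numeric vectors `min` and `max` (length 4, row order
#'   BDM, GC, occupancy, affinity).
#' @export
fit_descriptor_norm <- function(raw) {
  if (is.list(raw)) raw <- simplify2array(raw)  # 4 x 23 x n
  if (length(dim(raw)) == 3L && dim(raw)[1] == 4L && dim(raw)[2] == 23L) {
    mn <- apply(raw, 1, min); mx <- apply(raw, 1, max)
  } else {
    mn <- apply(raw, 3, min); mx <- apply(raw, 3, max)
  }
  list(min = as.numeric(mn), max = as.numeric(mx))
}

#' Apply min-max normalization to a raw 4 x 23 descriptor matrix
#'
#' Rows with a degenerate range (`max == min`) are set to 0 with a warning.
#'
#' @param raw 4 x 23 matrix.
#' @param norm Statistics from [fit_descriptor_norm()].
#' @export
apply_descriptor_norm <- function(raw, norm) {
  out <- raw
  for (r in 1:4) {
    rng <- norm$max[r] - norm$min[r]
    if (rng <= 0) {
      if (any(raw[r, ] != 0))
        warning(sprintf("degenerate normalization range for descriptor '%s'; row set to 0",
                        DESCRIPTOR_ROWS[r]))
      out[r, ] <- 0
    } else {
      out[r, ] <- pmin(pmax((raw[r, ] - norm$min[r]) / rng, 0), 1)
    }
  }
  out
}

#' Physical-descriptor matrix of one site
#'
#' Assembles the 4 x 23 matrix (rows: BDM, GC, nucleosome occupancy,
#' nucleosome affinity) by composing [bdm_score()], [gc_content()] and
#' [nucleosome_scores()] over the site's 23 windows, then normalizes with
#' `config$norm` when present.
#'
#' @inheritParams extract_windows
#' @param config A [descriptor_config()].
#' @export
descriptor_matrix <- function(genome, site, config = descriptor_config()) {
  wins <- extract_windows(genome, site)
  raw <- matrix(0, 4L, 23L, dimnames = list(DESCRIPTOR_ROWS, NULL))
  for (j in 1:23) {
    w <- wins[[j]]
    raw[1, j] <- bdm_score(w, config$block_size, config$block_table, config$fallback)
    raw[2, j] <- gc_content(w)
    ns <- nucleosome_scores(config$provider, w)
    raw[3, j] <- ns[["occupancy"]]
    raw[4, j] <- ns[["affinity"]]
  }
  if (!is.null(config$norm)) apply_descriptor_norm(raw, config$norm) else raw
}

# distinct-block BDM aggregate given per-block ids and complexities
bdm_aggregate <- function(ids, cx) {
  first <- !duplicated(ids)
  sum(cx[first]) + sum(log2(as.numeric(table(ids))))
}

#' Batch descriptor matrices for a site table
#'
#' Vectorized equivalent of [descriptor_matrix()] over all rows of a site
#' table (the two agree numerically; the batch path shares cumulative sums
#' across a site's overlapping windows). Only the entropy-fallback BDM is
#' vectorized: with a user `block_table` the per-site reference path is
#' used.
#'
#' @inheritParams descriptor_matrix
#' @param sites Site table data frame.
#' @return Array `(n_sites, 23, 4)` (site, position, descriptor row order
#'   BDM, GC, occupancy, affinity).
#' @export
descriptor_matrices <- function(genome, sites, config = descriptor_config()) {
  gs <- genome_strings(genome)
  n <- nrow(sites)
  out <- array(0, dim = c(n, 23L, 4L))
  if (!is.null(config$block_table) || config$block_size != 12L) {
    for (i in seq_len(n)) {
      m <- descriptor_matrix(gs, sites[i, ], descriptor_config(
        config$block_size, config$block_table, config$fallback,
        config$provider, NULL))
      out[i, , ] <- t(m)
    }
  } else {
    codes_by_chrom <- lapply(gs, contig_codes)
    bs <- 12L
    blk_off <- bs * (0:11)
    track <- config$provider$type == "track"
    for (i in seq_len(n)) {
      chrom <- sites$chrom[i]
      if (!chrom %in% names(gs)) stop(sprintf("contig '%s' not found in genome", chrom))
      ctx <- site_context_codes(codes_by_chrom[[chrom]], sites$start[i],
                                sites$strand[i], length(codes_by_chrom[[chrom]]))
      # GC: windowed sums of G/C indicators
      g01 <- as.numeric(ctx == 3L | ctx == 4L)
      cg <- c(0, cumsum(g01))
      out[i, , 2] <- (cg[(1:23) + 147L] - cg[1:23]) / 147
      # BDM: base-5 block ids + entropy complexities at all needed starts
      starts <- 1:156  # window j uses starts j + 12*(0:11), j = 1..23
      cnt <- sapply(1:5, function(s) {
        cs <- c(0, cumsum(ctx == s))
        cs[starts + bs] - cs[starts]
      })
      H <- -rowSums(ifelse(cnt > 0, (cnt / bs) * log2(cnt / bs), 0))
      cxs <- bs * H
      p5 <- 5^(0:11)
      idv <- as.numeric(ctx - 1L)
      ids <- sapply(0:11, function(k) idv[starts + k] * p5[k + 1])
      ids <- rowSums(ids)
      S <- outer(1:23, blk_off, "+")
      idm <- matrix(ids[S], 23L, 12L)
      cxm <- matrix(cxs[S], 23L, 12L)
      bdm <- rowSums(cxm)
      for (j in 1:23) {
        if (anyDuplicated(idm[j, ])) bdm[j] <- bdm_aggregate(idm[j, ], cxm[j, ])
      }
      out[i, , 1] <- bdm
      # nucleosome scores
      centers <- if (sites$strand[i] == "+") sites$start[i] + 0:22
                 else sites$start[i] + 22:0
      if (track) {
        keys <- paste(chrom, centers, sep = ":")
        occ <- config$provider$occupancy[keys]
        aff <- config$provider$affinity[keys]
        if (anyNA(occ) || anyNA(aff))
          stop(sprintf("position %s absent from nucleosome track",
                       keys[which(is.na(occ) | is.na(aff))[1]]))
        out[i, , 3] <- occ; out[i, , 4] <- aff
      } else {
        a <- ctx[-169L]; b <- ctx[-1L]
        d <- as.numeric((a == 1L & b == 1L) | (a == 2L & b == 2L) | (a == 2L & b == 1L))
        phase <- 2 * pi * seq_along(d) / 10
        ccs <- c(0, cumsum(d * cos(phase)))
        scs <- c(0, cumsum(d * sin(phase)))
        dcs <- c(0, cumsum(d))
        j <- 1:23
        cre <- ccs[j + 146L] - ccs[j - 1L + 1L]
        sim <- scs[j + 146L] - scs[j - 1L + 1L]
        nd <- dcs[j + 146L] - dcs[j - 1L + 1L]
        amp <- sqrt(cre^2 + sim^2) / (nd + 1)
        out[i, , 4] <- amp
        out[i, , 3] <- stats::plogis(8 * amp - 2)
      }
    }
  }
  if (!is.null(config$norm)) {
    for (r in 1:4) {
      rng <- config$norm$max[r] - config$norm$min[r]
      if (rng <= 0) {
        if (any(out[, , r] != 0))
          warning(sprintf("degenerate normalization range for descriptor '%s'; row set to 0",
                          DESCRIPTOR_ROWS[r]))
        out[, , r] <- 0
      } else {
        out[, , r] <- pmin(pmax((out[, , r] - config$norm$min[r]) / rng, 0), 1)
      }
    }
  }
  out
}
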