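#' Binary interface encoding of an sgRNA-target pair
#'
#' A 23-nt sgRNA (PAM-inclusive) and its 23-nt genomic target are encoded as
#' a 6 x 23 binary matrix: rows 1-4 are the element-wise OR of the two
#' one-hot sequences under the fixed channel order A, T, G, C (a match shows
#' one set bit per column, a mismatch two), and rows 5-6 are a two-bit
#' mismatch-direction channel that restores the orientation the OR loses.
#' For example the column `0011-10` encodes the mismatch G (sgRNA) -> C
#' (target), `0011-01` encodes C -> G, and `0100-00` the matched locus
#' T -> T.
#'
#' @name interface-encoding
NULL

ENC_ALPHABET <- c("A", "T", "G", "C")

# map base characters to channel index 1..4; N/ambiguous -> NA
base_channel <- function(x, what) {
  x <- toupper(chartr("U", "T", x))
  idx <- match(x, ENC_ALPHABET)
  bad <- is.na(idx) & x != "N"
  if (any(bad))
    stop(sprintf("invalid base '%s' in %s at position %d",
                 x[which(bad)[1]], what, which(bad)[1]))
  idx
}

#' Encode one aligned base pair as a 6-bit column
#'
#' @param sgrna_base,target_base Single characters in `A, C, G, T, N`
#'   (`U` is accepted and normalized to `T`).
#' @return Integer vector of 6 bits: channels A, T, G, C then the two
#'   direction bits. Direction bit 5 is set when the sgRNA base's channel
#'   index precedes the target base's, bit 6 otherwise; matches and any N
#'   give `00`, and N contributes an all-zero one-hot.
#' @examples
#' encode_base_pair("G", "C")  # 0 0 1 1 1 0
#' @export
encode_base_pair <- function(sgrna_base, target_base) {
  if (nchar(sgrna_base) != 1L || nchar(target_base) != 1L)
    stop("encode_base_pair takes single characters")
  i <- base_channel(sgrna_base, "sgRNA")
  j <- base_channel(target_base, "target")
  col <- integer(6)
  if (!is.na(i)) col[i] <- 1L
  if (!is.na(j)) col[j] <- 1L
  if (!is.na(i) && !is.na(j) && i != j) {
    if (i < j) col[5] <- 1L else col[6] <- 1L
  }
  col
}

split_seq <- function(s) strsplit(toupper(chartr("U", "T", s)), "", fixed = TRUE)[[1]]

check_pair_seqs <- function(sgrna_seq, target_seq) {
  if (nchar(sgrna_seq) != 23L || nchar(target_seq) != 23L)
    stop(sprintf("invalid pair: sequences must be 23 nt (got %d and %d)",
                 nchar(sgrna_seq), nchar(target_seq)))
  invisible(NULL)
}

#' Encode an sgRNA-target pair as the 6 x 23 interface matrix
#'
#' @param sgrna_seq,target_seq 23-character DNA strings (alphabet
#'   A/C/G/T/N; U normalized to T).
#' @return 6 x 23 integer 0/1 matrix; column `j` is
#'   `encode_base_pair(sgrna_seq[j], target_seq[j])`.
#' @export
encode_pair <- function(sgrna_seq, target_seq) {
  check_pair_seqs(sgrna_seq, target_seq)
  si <- base_channel(split_seq(sgrna_seq), "sgRNA")
  ti <- base_channel(split_seq(target_seq), "target")
  m <- matrix(0L, 6L, 23L)
  for (c in 1:4) m[c, ] <- as.integer((!is.na(si) & si == c) | (!is.na(ti) & ti == c))
  mm <- !is.na(si) & !is.na(ti)
  m[5, ] <- as.integer(mm & si < ti)
  m[6, ] <- as.integer(mm & si > ti)
  m
}

#' Batch-encode site pairs to a 3D array
#'
#' @param sites Data frame with columns `sgrna_seq` and `target_seq`
#'   (a site table as returned by [read_site_table()] or
#'   [simulate_sites()]).
#' @return Numeric array of dim `(n_sites, 23, 6)` (site, position,
#'   channel), the sequence input consumed by the network.
#' @export
encode_pairs <- function(sites) {
  n <- nrow(sites)
  seq_idx_mat <- function(seqs, what) {
    ch <- strsplit(toupper(chartr("U", "T", seqs)), "", fixed = TRUE)
    len <- lengths(ch)
    if (any(len != 23L))
      stop(sprintf("invalid pair at row %d: sequences must be 23 nt", which(len != 23L)[1]))
    matrix(base_channel(unlist(ch), what), nrow = n, ncol = 23L, byrow = TRUE)
  }
  si <- seq_idx_mat(sites$sgrna_seq, "sgRNA")
  ti <- seq_idx_mat(sites$target_seq, "target")
  x <- array(0, dim = c(n, 23L, 6L))
  for (c in 1:4)
    x[, , c] <- ((!is.na(si) & si == c) | (!is.na(ti) & ti == c)) * 1
  mm <- !is.na(si) & !is.na(ti)
  x[, , 5] <- (mm & si < ti) * 1
  x[, , 6] <- (mm & si > ti) * 1
  x
}

#' Count mismatched positions of a pair
#'
#' Positions where the two bases differ and neither is N. Vectorized over
#' the rows of a site table, or callable on two single sequences.
#'
#' @param sgrna_seq,target_seq Character vectors of 23-nt sequences.
#' @return Integer vector of mismatch counts.
#' @export
mismatch_count <- function(sgrna_seq, target_seq) {
  n <- length(sgrna_seq)
  out <- integer(n)
  for (r in seq_len(n)) {
    check_pair_seqs(sgrna_seq[r], target_seq[r])
    si <- base_channel(split_seq(sgrna_seq[r]), "sgRNA")
    ti <- base_channel(split_seq(target_seq[r]), "target")
    out[r] <- sum(!is.na(si) & !is.na(ti) & si != ti)
  }
  out
}
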