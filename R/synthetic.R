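#' Synthetic off-target data with known ground truth
#'
#' Generates a random genome, plants sgRNA on-targets and mutated
#' off-target sites in it, assigns each site true ZINB parameters that
#' depend on mismatch count and local GC content, and samples read counts.
#' The generator emulates the sparsity structure of genome-wide cleavage
#' assays (most sites draw zero or near-zero counts; activity decays
#' steeply with mismatch load) so the whole pipeline - encoding,
#' descriptors, network training and uncertainty outputs - can be exercised
#' and validated offline against the hidden truth.
#'
#' @name synthetic-data
NULL

#' Specification of a synthetic dataset
#'
#' Per-site truth: `pi = plogis(qlogis(zero_inflation_base) +
#' pi_mismatch_slope * m)` and `mu = mu_on * mean_decay^m *
#' 2^(gc_coef * (GC - 0.5))`, where `m` is the number of mutated positions
#' (0 for on-targets, uniform on 1..6 for off-targets) and GC is the GC
#' content of the planted site's 147-bp center window. Counts are drawn
#' from ZINB(pi, mu, theta_true). Coupling `mu` to both mismatch count and
#' context GC puts recoverable signal in the sequence branch and the
#' descriptor branch of the network.
#'
#' @param n_guides Number of sgRNAs.
#' @param sites_per_guide Off-target sites per sgRNA (each sgRNA also gets
#'   one 0-mismatch on-target).
#' @param genome_length Length of the simulated contig in bp.
#' @param zero_inflation_base Zero-inflation weight at 0 mismatches.
#' @param pi_mismatch_slope Logit-scale increase of `pi` per mismatch.
#' @param mean_decay Multiplicative decay of `mu` per mismatch, in (0, 1].
#' @param mu_on On-target NB mean.
#' @param guide_mu_sd Log-normal sd of a per-guide factor on `mu_on`.
#' @param gc_coef Log2-scale GC effect on `mu`.
#' @param theta_true NB dispersion shared by all sites.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @export
synthetic_spec <- function(n_guides = 40L, sites_per_guide = 599L,
                           genome_length = 1000000L,
                           zero_inflation_base = 0.05,
                           pi_mismatch_slope = 0.5,
                           mean_decay = 0.35, mu_on = 2000,
                           guide_mu_sd = 0.3, gc_coef = 2,
                           theta_true = 2, seed = 1L) {
  stopifnot(zero_inflation_base >= 0, zero_inflation_base <= 1,
            mean_decay > 0, mean_decay <= 1, theta_true > 0, mu_on > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Simulate a uniform random genome contig
#'
#' @param length Contig length (must fit at least one site with its 73-bp
#'   flanks, i.e. `length >= 170`).
#' @param seed Integer seed.
#' @param name Contig name.
#' @return A `Biostrings::DNAStringSet` with one contig.
#' @export
simulate_genome <- function(length, seed = 1L, name = "chrS") {
  if (length < 147 + 23) stop("'length' must be at least 170")
  s <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                             collapse = ""))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- name
  out
}

revcomp_chr <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")

#' Simulate a site table with hidden truth
#'
#' Plants each sgRNA's on-target (its own genomic sequence, 0 mismatches)
#' and `sites_per_guide` mutated off-targets at disjoint loci of the
#' genome, overwriting the contig so that every `target_seq` is literally
#' present at its coordinates (minus-strand sites are planted as the
#' reverse complement). True parameters follow [synthetic_spec()]; counts
#' are one ZINB draw per site.
#'
#' @param spec A [synthetic_spec()].
#' @param genome Optional genome to plant into; by default a fresh
#'   [simulate_genome()] of `spec$genome_length` is used.
#' @return List with `sites` (standard site table plus `site_id`), `truth`
#'   (sidecar data frame: `site_id`, `pi_true`, `mu_true`, `theta_true`,
#'   `dropped_flag`), `genome` (the planted contig) and `spec`.
#' @export
simulate_sites <- function(spec, genome = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    if (is.null(genome)) {
      gseq <- paste(sample(c("A", "C", "G", "T"), spec$genome_length,
                           replace = TRUE), collapse = "")
      chrom <- "chrS"
    } else {
      gs <- genome_strings(genome)
      gseq <- gs[[1]]
      chrom <- names(gs)[1]
    }
    L <- nchar(gseq)
    total <- spec$n_guides * (1L + spec$sites_per_guide)
    stride <- 40L
    margin <- 80L
    capacity <- (L - 2L * margin) %/% stride
    if (capacity < total)
      stop(sprintf("genome too short: %d site slots needed, %d available", total, capacity))
    slots <- margin + (sample(capacity) - 1L)[seq_len(total)] * stride
    strands <- sample(c("+", "-"), total, replace = TRUE, prob = c(0.7, 0.3))
    guide_of <- rep(seq_len(spec$n_guides), each = 1L + spec$sites_per_guide)
    is_on <- rep(c(TRUE, rep(FALSE, spec$sites_per_guide)), spec$n_guides)
    bases <- c("A", "C", "G", "T")
    chars <- strsplit(gseq, "", fixed = TRUE)[[1]]

    read_site <- function(p, strand) {
      s <- paste(chars[(p + 1):(p + 23)], collapse = "")
      if (strand == "-") revcomp_chr(s) else s
    }
    sgrna <- character(spec$n_guides)
    target <- character(total)
    mcount <- integer(total)
    for (i in seq_len(total)) {
      g <- guide_of[i]
      if (is_on[i]) {
        sgrna[g] <- read_site(slots[i], strands[i])
        target[i] <- sgrna[g]
        mcount[i] <- 0L
      } else {
        m <- sample(1:6, 1L)
        pos <- sample(23L, m)
        tg <- strsplit(sgrna[g], "", fixed = TRUE)[[1]]
        for (p in pos) tg[p] <- sample(setdiff(bases, tg[p]), 1L)
        tg <- paste(tg, collapse = "")
        planted <- if (strands[i] == "-") revcomp_chr(tg) else tg
        chars[(slots[i] + 1):(slots[i] + 23)] <- strsplit(planted, "", fixed = TRUE)[[1]]
        target[i] <- tg
        mcount[i] <- m
      }
    }
    gseq <- paste(chars, collapse = "")

    # context GC at the site center window, from the final genome
    isgc <- chars %in% c("G", "C")
    cg <- c(0, cumsum(isgc))
    centers <- slots + 11L
    lo <- pmax(centers - 73L, 0L); hi <- pmin(centers + 73L, L - 1L)
    gc_ctx <- (cg[hi + 2L] - cg[lo + 1L]) / 147

    guide_factor <- exp(stats::rnorm(spec$n_guides, 0, spec$guide_mu_sd))
    pi0 <- min(max(spec$zero_inflation_base, 1e-6), 1 - 1e-6)
    pi_true <- stats::plogis(stats::qlogis(pi0) + spec$pi_mismatch_slope * mcount)
    mu_true <- spec$mu_on * guide_factor[guide_of] * spec$mean_decay^mcount *
      2^(spec$gc_coef * (gc_ctx - 0.5))
    zero <- stats::runif(total) < pi_true
    counts <- stats::rpois(total, stats::rgamma(total, shape = spec$theta_true,
                                                rate = spec$theta_true / mu_true))
    counts[zero] <- 0L

    site_id <- sprintf("g%03d_s%05d", guide_of, seq_len(total))
    sites <- data.frame(site_id = site_id,
                        sgrna_seq = sgrna[guide_of],
                        target_seq = target,
                        chrom = chrom, start = slots, strand = strands,
                        read_count = as.numeric(counts),
                        stringsAsFactors = FALSE)
    truth <- data.frame(site_id = site_id, pi_true = pi_true,
                        mu_true = mu_true, theta_true = spec$theta_true,
                        dropped_flag = FALSE, stringsAsFactors = FALSE)
    genome_out <- Biostrings::DNAStringSet(gseq)
    names(genome_out) <- chrom
    list(sites = sites, truth = truth, genome = genome_out, spec = spec)
  })
}

#' Inject technical zeros into a simulated dataset
#'
#' Independently zeroes each positive count with probability
#' `extra_dropout`, emulating off-target sites missed by a limited-
#' sensitivity assay; zeroed rows are flagged in the truth sidecar.
#'
#' @param sim Result of [simulate_sites()].
#' @param extra_dropout Dropout probability in [0, 1).
#' @param seed Integer seed.
#' @export
corrupt_with_technical_zeros <- function(sim, extra_dropout, seed = 1L) {
  if (extra_dropout < 0 || extra_dropout >= 1)
    stop("'extra_dropout' must be in [0, 1)")
  with_seed(seed, {
    pos <- sim$sites$read_count > 0
    drop <- pos & stats::runif(nrow(sim$sites)) < extra_dropout
    sim$sites$read_count[drop] <- 0
    sim$truth$dropped_flag <- sim$truth$dropped_flag | drop
    sim
  })
}

#' Write a simulated dataset to files
#'
#' @param sim Result of [simulate_sites()].
#' @param dir Output directory (created if needed); writes `genome.fa`,
#'   `sites.tsv` and the hidden-truth sidecar `truth.tsv`.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_site_table(sim$sites, file.path(dir, "sites.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
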