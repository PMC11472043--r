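# 147-bp context windows and the four physical descriptors.

test_that("window extraction follows the 73-bp flank arithmetic", {
  genome <- simulate_genome(2000, seed = 1)
  gstr <- as.character(genome)[[1]]
  site <- list(chrom = "chrS", start = 500L, strand = "+")
  wins <- extract_windows(genome, site)
  expect_length(wins, 23)
  for (j in c(1, 10, 23)) {
    w <- wins[[j]]
    expect_equal(nchar(w$seq), 147)
    expect_equal(w$center, 500L + j - 1L)
    # window j spans [p + j - 74, p + j + 73] in 1-based string coordinates
    expect_identical(w$seq, substr(gstr, 500 + j - 73, 500 + j + 73))
    expect_identical(substr(w$seq, 74, 74), substr(gstr, 500 + j, 500 + j))
  }
})

test_that("minus-strand windows are reverse-complemented and center on target bases", {
  sim <- small_sim()
  gstr <- as.character(sim$genome)[[1]]
  for (strand in c("+", "-")) {
    i <- which(sim$sites$strand == strand)[3]
    site <- sim$sites[i, ]
    wins <- extract_windows(sim$genome, site)
    for (j in c(1, 7, 23))
      expect_identical(substr(wins[[j]]$seq, 74, 74),
                       substr(site$target_seq, j, j))
    if (strand == "-") {
      w <- wins[[5]]
      plus <- substr(gstr, w$center + 1 - 73, w$center + 1 + 73)
      expect_identical(w$seq, revcomp(plus))
    }
  }
})

test_that("contig-edge windows are N-padded and errors are informative", {
  genome <- simulate_genome(300, seed = 2)
  wins <- extract_windows(genome, list(chrom = "chrS", start = 10L, strand = "+"))
  expect_equal(nchar(wins[[1]]$seq), 147)
  expect_identical(substr(wins[[1]]$seq, 1, 63), strrep("N", 63))
  expect_error(extract_windows(genome, list(chrom = "chrX", start = 10L, strand = "+")),
               "contig 'chrX' not found")
  expect_error(extract_windows(genome, list(chrom = "chrS", start = 290L, strand = "+")),
               "outside contig bounds")
})

test_that("gc_content matches a counting loop and is reverse-complement invariant", {
  expect_equal(gc_content(strrep("G", 147)), 1)
  expect_equal(gc_content(strrep("AC", 70)), 0.5)
  set.seed(3)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 147, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    loop <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 147
    expect_equal(gc_content(s), loop)
    expect_equal(gc_content(revcomp(s)), gc_content(s))
  }
})

test_that("bdm_score implements the block-decomposition aggregate", {
  # single repeated block: table value + log2(number of blocks)
  tbl <- c(ACGTACGTACGT = 7.5)
  s <- strrep("ACGTACGTACGT", 5)
  expect_equal(bdm_score(s, 12, tbl), 7.5 + log2(5))
  # two distinct blocks with multiplicities 2 and 3
  tbl2 <- c(AAAAAAAAAAAA = 1.25, ACGTACGTACGT = 7.5)
  s2 <- paste0(strrep("AAAAAAAAAAAA", 2), strrep("ACGTACGTACGT", 3))
  expect_equal(bdm_score(s2, 12, tbl2), 1.25 + log2(2) + 7.5 + log2(3))
  # remainder shorter than one block is dropped
  expect_equal(bdm_score(paste0(s, "ACG"), 12, tbl), 7.5 + log2(5))
  # entropy fallback vs an independent dictionary-accumulation oracle
  set.seed(4)
  for (rep in 1:8) {
    w <- paste(sample(c("A", "C", "G", "T"), 147, replace = TRUE), collapse = "")
    blocks <- substring(w, seq(1, 133, 12), seq(12, 144, 12))
    dict <- new.env()
    for (b in blocks) assign(b, (mget(b, dict, ifnotfound = 0)[[1]]) + 1, dict)
    ent <- function(b) {
      f <- table(strsplit(b, "")[[1]]) / 12
      12 * -sum(f * log2(f))
    }
    oracle <- sum(vapply(ls(dict), function(b)
      ent(b) + log2(get(b, dict)), numeric(1)))
    expect_equal(bdm_score(w, 12), oracle, tolerance = 1e-10)
  }
  expect_error(bdm_score(s, 12, NULL, fallback = FALSE), "configuration error")
})

test_that("nucleosome providers: track lookup, surrogate determinism, round trip", {
  genome <- simulate_genome(1000, seed = 5)
  site <- list(chrom = "chrS", start = 300L, strand = "+")
  wins <- extract_windows(genome, site)
  track <- data.frame(chrom = "chrS", pos = 0:999, occupancy = 0.7,
                      affinity = 0.25)
  path <- tempfile(fileext = ".tsv")
  write_nucleosome_track(track, path)
  prov <- nucleosome_track_provider(path)
  for (j in c(1, 12, 23))
    expect_equal(nucleosome_scores(prov, wins[[j]]),
                 c(occupancy = 0.7, affinity = 0.25))
  # write-read round trip preserves values exactly
  track2 <- data.frame(chrom = "chrS", pos = 0:99,
                       occupancy = runif(100), affinity = runif(100))
  path2 <- tempfile(fileext = ".tsv")
  write_nucleosome_track(track2, path2)
  prov2 <- nucleosome_track_provider(path2)
  w <- list(chrom = "chrS", center = 42L, seq = wins[[1]]$seq)
  expect_equal(unname(nucleosome_scores(prov2, w)[["occupancy"]]),
               track2$occupancy[43])
  expect_error(nucleosome_scores(prov2, list(chrom = "chrS", center = 5000L)),
               "chrS:5000")
  # surrogate: deterministic, in (0, 1) for occupancy
  s1 <- nucleosome_scores(nucleosome_surrogate_provider(), wins[[4]])
  s2 <- nucleosome_scores(nucleosome_surrogate_provider(), wins[[4]])
  expect_identical(s1, s2)
  expect_gt(s1[["occupancy"]], 0)
  expect_lt(s1[["occupancy"]], 1)
})

test_that("descriptor_matrix composes the per-descriptor operations", {
  sim <- small_sim()
  cfg <- descriptor_config()
  site <- sim$sites[17, ]
  m <- descriptor_matrix(sim$genome, site, cfg)
  expect_identical(dim(m), c(4L, 23L))
  wins <- extract_windows(sim$genome, site)
  for (j in c(2, 15)) {
    expect_equal(unname(m["bdm", j]), bdm_score(wins[[j]]))
    expect_equal(unname(m["gc", j]), gc_content(wins[[j]]))
    ns <- nucleosome_scores(cfg$provider, wins[[j]])
    expect_equal(unname(m["nupop_occupancy", j]), ns[["occupancy"]])
    expect_equal(unname(m["nupop_affinity", j]), ns[["affinity"]])
  }
})

test_that("batch descriptor path agrees with the per-site reference path", {
  sim <- small_sim()
  f <- small_features()
  cfg <- descriptor_config(norm = f$norm)
  for (i in c(1, 50, 123, 300)) {
    ref <- descriptor_matrix(sim$genome, sim$sites[i, ], cfg)
    expect_equal(t(ref), f$xp[i, , ], tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("min-max normalization: endpoints, clipping, idempotence, degenerate rows", {
  raw <- matrix(runif(4 * 23, 2, 5), 4, 23)
  norm <- list(min = apply(raw, 1, min), max = apply(raw, 1, max))
  nm <- apply_descriptor_norm(raw, norm)
  expect_true(all(nm >= 0 & nm <= 1))
  for (r in 1:4) {
    expect_equal(nm[r, which.min(raw[r, ])], 0)
    expect_equal(nm[r, which.max(raw[r, ])], 1)
  }
  # idempotence: re-normalizing with the normalized row's own stats
  norm2 <- list(min = rep(0, 4), max = rep(1, 4))
  expect_equal(apply_descriptor_norm(nm, norm2), nm)
  # degenerate range: row set to 0 with a warning
  raw0 <- raw; raw0[2, ] <- 3.3
  n0 <- list(min = apply(raw0, 1, min), max = apply(raw0, 1, max))
  expect_warning(out <- apply_descriptor_norm(raw0, n0), "degenerate")
  expect_true(all(out[2, ] == 0))
  # values outside the training range are clipped into [0, 1]
  wide <- raw; wide[1, 1] <- 100
  expect_equal(apply_descriptor_norm(wide, norm)[1, 1], 1)
})

test_that("identical site sequences at different loci can differ in descriptors", {
  set.seed(12)
  gstr <- paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE), collapse = "")
  core <- rand_seq(1)
  substr(gstr, 201, 223) <- core
  substr(gstr, 601, 623) <- core
  genome <- Biostrings::DNAStringSet(gstr); names(genome) <- "chrS"
  m1 <- descriptor_matrix(genome, list(chrom = "chrS", start = 200L, strand = "+"))
  m2 <- descriptor_matrix(genome, list(chrom = "chrS", start = 600L, strand = "+"))
  expect_gt(max(abs(m1 - m2)), 0)
})
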