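# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

small_net_config <- function()
  network_config(conv1_kernels = 16L, conv2_kernels = 8L, lstm_hidden = 8L,
                 fc_seq = 32L, fc_phys = 32L, fc_joint = 32L, phys_kernels = 8L)

rand_seq <- function(n, len = 23L)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))

revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")

# a small simulated dataset (300 sites) shared by several files
small_sim <- function() memo("small_sim", {
  simulate_sites(synthetic_spec(n_guides = 6L, sites_per_guide = 49L,
                                genome_length = 30000L, seed = 42L))
})

small_features <- function() memo("small_features", {
  sim <- small_sim()
  xs <- encode_pairs(sim$sites)
  xp_raw <- descriptor_matrices(sim$genome, sim$sites)
  norm <- fit_descriptor_norm(xp_raw)
  xp <- xp_raw
  for (r in 1:4) {
    rng <- norm$max[r] - norm$min[r]
    xp[, , r] <- if (rng > 0) pmin(pmax((xp_raw[, , r] - norm$min[r]) / rng, 0), 1) else 0
  }
  list(xs = xs, xp = xp, norm = norm)
})

# a quickly trained zinb model on the small dataset
small_model <- function() memo("small_model", {
  sim <- small_sim()
  f <- small_features()
  train_model(f$xs, f$xp, sim$sites$read_count, "zinb", small_net_config(),
              train_config(lr = 2e-3, max_epochs = 10L, patience = 5L,
                           batch_size = 64L, seed = 9L),
              norm_stats = list(descriptor_norm = f$norm))
})

# the full-size study fixture used by the acceptance suite: 24 000 sites,
# 20 000 train / 2 000 validation / 2 000 test, zinb and poisson heads
acceptance_fixture <- function() memo("acceptance_fixture", {
  sim <- simulate_sites(synthetic_spec(seed = 11L))
  xs <- encode_pairs(sim$sites)
  xp <- descriptor_matrices(sim$genome, sim$sites)
  norm <- fit_descriptor_norm(xp)
  for (r in 1:4) {
    rng <- norm$max[r] - norm$min[r]
    xp[, , r] <- if (rng > 0) pmin(pmax((xp[, , r] - norm$min[r]) / rng, 0), 1) else 0
  }
  tc <- train_config(lr = 2e-3, max_epochs = 25L, patience = 8L,
                     batch_size = 256L,
                     fractions = c(20000, 2000, 2000) / 24000, seed = 7L)
  mz <- train_model(xs, xp, sim$sites$read_count, "zinb", small_net_config(),
                    tc, norm_stats = list(descriptor_norm = norm))
  mp <- train_model(xs, xp, sim$sites$read_count, "poisson",
                    small_net_config(), tc,
                    norm_stats = list(descriptor_norm = norm))
  list(sim = sim, xs = xs, xp = xp, norm = norm, mz = mz, mp = mp)
})
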