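# Shared fixtures: all generated in code at test time.

tiny_layout <- function(n_subjects = 10L) {
  dataset_layout(
    list(
      cognition = list(memory = c("m1", "m2", "rt_mean")),
      imaging = list(volume = c("v1", "v2", "v3"))
    ),
    n_subjects = n_subjects
  )
}

# A small, fully observed cohort with a strong latent signal.
tiny_cohort <- function(n = 60L, snr_db = 20, variant = "cluster",
                        link = "cluster_label", seed = 1L,
                        layout = tiny_layout(n)) {
  spec <- latent_cohort_spec(variant, n, snr_db, layout, link, seed = seed)
  generate_cohort(spec)
}

# Write a 2-submodality, 10-subject manifest fixture; returns its path.
# Punches one hole at (subject 4, feature "rt_mean").
write_tiny_manifest <- function(dir = tempfile("sgfix")) {
  ds <- tiny_cohort(n = 10L, seed = 42L)
  ds$blocks$memory[4L, "rt_mean"] <- NA
  manifest <- write_dataset(ds, dir, name = "tiny")
  list(manifest = manifest, dataset = ds, dir = dir)
}

# Rank-1 matrix with multiplicative structure plus noise at a given SNR.
rank1_block <- function(n = 60L, p = 12L, snr_db = 20, seed = 1L) {
  set.seed(seed)
  u <- rnorm(n)
  v <- rnorm(p)
  S <- outer(u, v)
  E <- matrix(rnorm(n * p), n, p)
  E <- E * sqrt(var(as.vector(S)) / (10^(snr_db / 10) * var(as.vector(E))))
  X <- S + E
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, signal = S)
}
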