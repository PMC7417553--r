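#' Specify a latent-variable cohort simulation
#'
#' Each simulated subject carries a one-dimensional latent trait driving both
#' the multimodal features and the outcome. Two restrictions on the latent
#' variable embody the competing hypotheses about treatment capability:
#' `"cluster"` (two discrete subgroups, latent in {-1, +1}) and `"spectrum"`
#' (a continuum, standard-normal latent). Features are noisy linear readouts
#' of the latent trait at a controllable dataset-level signal-to-noise ratio
#' expressed in decibels.
#'
#' @param variant `"cluster"` or `"spectrum"`.
#' @param n_subjects positive integer.
#' @param snr_db finite numeric, dB: `10 * log10(Var(signal) / Var(noise))`.
#' @param layout a [dataset_layout()] (its `n_subjects` is overridden by
#'   `n_subjects` here).
#' @param outcome_link `"cluster_label"` (label = latent > 0),
#'   `"binary_threshold"` (label = latent > median) or `"linear_response"`
#'   (continuous response = latent + noise at the same SNR).
#' @param mixing_proportion probability of the +1 subgroup (cluster variant
#'   only), in (0, 1).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return object of class `latent_cohort_spec`.
#' @export
latent_cohort_spec <- function(variant = c("cluster", "spectrum"),
                               n_subjects, snr_db, layout,
                               outcome_link = c("cluster_label",
                                                "binary_threshold",
                                                "linear_response"),
                               mixing_proportion = 0.5, seed = 1L) {
  variant <- match.arg(variant)
  outcome_link <- match.arg(outcome_link)
  stopifnot(is.finite(snr_db), inherits(layout, "dataset_layout"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects <= 0L) stop("n_subjects must be positive")
  stopifnot(mixing_proportion > 0, mixing_proportion < 1)
  layout$n_subjects <- n_subjects
  structure(
    list(variant = variant, n_subjects = n_subjects, snr_db = snr_db,
         layout = layout, outcome_link = outcome_link,
         mixing_proportion = mixing_proportion, seed = as.integer(seed)),
    class = "latent_cohort_spec"
  )
}

#' Sample the latent trait vector
#'
#' Cluster variant: two-point latent, `z in {-1, +1}` with
#' `P(+1) = mixing_proportion`. Spectrum variant: standard normal.
#'
#' @param spec a [latent_cohort_spec()].
#' @return numeric vector of length `n_subjects`; deterministic given the
#'   spec's seed.
#' @export
sample_latent <- function(spec) {
  stopifnot(inherits(spec, "latent_cohort_spec"))
  with_seed(derive_seed(spec$seed, "latent"), {
    if (spec$variant == "cluster") {
      ifelse(stats::runif(spec$n_subjects) < spec$mixing_proportion, 1, -1)
    } else {
      stats::rnorm(spec$n_subjects)
    }
  })
}

#' Random loading model for a layout
#'
#' Per-feature loadings (drawn once from a standard normal and frozen) and
#' per-feature noise scales. Loadings connect the latent trait to every
#' feature; the noise is rescaled later to realize the requested SNR.
#'
#' @param layout a [dataset_layout()].
#' @param seed integer seed.
#' @return object of class `loading_model`: named list of per-submodality
#'   lists with `w` (loadings) and `sigma` (noise scales), one entry per
#'   feature.
#' @export
random_loadings <- function(layout, seed = 1L) {
  tab <- layout_submodalities(layout)
  with_seed(derive_seed(seed, "loadings"), {
    out <- lapply(tab$submodality, function(sm) {
      feats <- layout_features(layout, sm)
      w <- stats::rnorm(length(feats))
      # guarantee at least one clearly nonzero loading per submodality
      if (max(abs(w)) < 0.1) w[which.max(abs(w))] <- 0.5
      sigma <- stats::runif(length(feats), 0.5, 1.5)
      list(w = stats::setNames(w, feats), sigma = stats::setNames(sigma, feats))
    })
    names(out) <- tab$submodality
    structure(out, class = "loading_model")
  })
}

#' Derive outcomes from a latent vector
#'
#' @param z latent vector.
#' @param link `"cluster_label"`, `"binary_threshold"` or `"linear_response"`.
#' @param seed integer seed (used only by the noisy linear response).
#' @param snr_db SNR in dB for the linear response's observation noise.
#' @return data.frame with columns `label` and `response` (the one the link
#'   does not define is `NA`).
#' @export
derive_outcomes <- function(z, link, seed = 1L, snr_db = 0) {
  if (length(z) == 0L) stop("latent vector must be non-empty")
  label <- rep(NA_real_, length(z))
  response <- rep(NA_real_, length(z))
  if (link == "cluster_label") {
    label <- as.numeric(z > 0)
  } else if (link == "binary_threshold") {
    label <- as.numeric(z > stats::median(z))
  } else if (link == "linear_response") {
    ratio <- 10^(snr_db / 10)
    eps <- with_seed(derive_seed(seed, "response_noise"),
                     stats::rnorm(length(z)))
    vz <- stats::var(z)
    if (length(z) > 1L && vz > 0 && stats::var(eps) > 0) {
      eps <- eps * sqrt(vz / (ratio * stats::var(eps)))
    }
    response <- z + eps
  } else {
    stop("unknown outcome link '", link, "'")
  }
  data.frame(label = label, response = response)
}

#' Generate a fully observed multimodal cohort
#'
#' Every feature j of every block is a linear readout of the latent trait,
#' `x_ij = w_j * z_i + eps_ij`, with Gaussian noise. The noise matrix is
#' rescaled post-hoc so the realized dataset-level variance ratio
#' `Var(signal entries) / Var(noise entries)` equals `10^(snr_db / 10)`
#' exactly (up to floating point), so the requested SNR is met within 1% by
#' construction. Outcomes are attached via the spec's link; covariates (sex,
#' age, cohort, handedness) are simulated independently of the latent trait.
#' Missingness is grafted separately by [apply_missing_pattern()].
#'
#' @param spec a [latent_cohort_spec()].
#' @param loadings a [random_loadings()] model compatible with `spec$layout`;
#'   defaults to fresh loadings drawn from the spec's seed.
#' @return a fully observed [multimodal_dataset()]; `meta` records variant,
#'   snr_db and seed.
#' @export
generate_cohort <- function(spec, loadings = NULL) {
  stopifnot(inherits(spec, "latent_cohort_spec"))
  if (is.null(loadings)) loadings <- random_loadings(spec$layout, spec$seed)
  tab <- layout_submodalities(spec$layout)
  if (!setequal(names(loadings), tab$submodality)) {
    stop("loadings do not match the layout's submodalities")
  }
  for (sm in tab$submodality) {
    if (all(loadings[[sm]]$w == 0)) {
      stop("all-zero loadings in block '", sm, "'")
    }
    if (any(loadings[[sm]]$sigma <= 0)) {
      stop("non-positive noise scale in block '", sm, "'")
    }
  }
  z <- sample_latent(spec)
  n <- spec$n_subjects
  ids <- sprintf("S%03d", seq_len(n))

  w_all <- unlist(lapply(loadings[tab$submodality], `[[`, "w"))
  sig_all <- unlist(lapply(loadings[tab$submodality], `[[`, "sigma"))
  p <- length(w_all)
  signal <- outer(z, unname(w_all))
  noise <- with_seed(derive_seed(spec$seed, "feature_noise"), {
    matrix(stats::rnorm(n * p), n, p) *
      matrix(unname(sig_all), n, p, byrow = TRUE)
  })
  ratio <- 10^(spec$snr_db / 10)
  vs <- stats::var(as.vector(signal))
  vn <- stats::var(as.vector(noise))
  if (vs <= 0) stop("degenerate latent sample: zero signal variance")
  noise <- noise * sqrt(vs / (ratio * vn))
  x <- signal + noise

  feats <- unlist(lapply(tab$submodality,
                         function(sm) layout_features(spec$layout, sm)))
  colnames(x) <- feats
  rownames(x) <- ids
  blocks <- lapply(tab$submodality, function(sm) {
    x[, layout_features(spec$layout, sm), drop = FALSE]
  })
  names(blocks) <- tab$submodality

  oc <- derive_outcomes(z, spec$outcome_link, seed = spec$seed,
                        snr_db = spec$snr_db)
  outcomes <- data.frame(subject_id = ids, oc)
  covariates <- with_seed(derive_seed(spec$seed, "covariates"), data.frame(
    subject_id = ids,
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(stats::rnorm(n, mean = 25.4, sd = 5.7), 1),
    cohort = sample(c("A", "B", "C"), n, replace = TRUE),
    handedness = sample(c("right", "left", "ambidextrous"), n,
                        replace = TRUE, prob = c(0.86, 0.11, 0.03)),
    stringsAsFactors = FALSE
  ))
  multimodal_dataset(
    spec$layout, blocks, outcomes, covariates,
    meta = list(variant = spec$variant, snr_db = spec$snr_db,
                seed = spec$seed, outcome_link = spec$outcome_link,
                latent = z)
  )
}

#' Graft a missingness pattern onto a dataset
#'
#' Applies a template mask (typically extracted from a real cohort) to a
#' simulated dataset so the simulation reproduces the real block-wise and
#' random missingness. When the subject counts differ, mask rows are
#' resampled with replacement (seeded); when they match, the mapping is the
#' identity unless `permute_subjects` asks for a seeded row permutation.
#'
#' @param dataset a fully observed (or partially observed)
#'   `multimodal_dataset`.
#' @param mask a [extract_missing_mask()] result with the same submodalities.
#' @param permute_subjects permute mask rows before applying (default FALSE).
#' @param seed integer seed for permutation/resampling.
#' @return the dataset with entries blanked where the (row-mapped) mask is
#'   TRUE.
#' @export
apply_missing_pattern <- function(dataset, mask, permute_subjects = FALSE,
                                  seed = 1L) {
  stopifnot(inherits(mask, "missing_mask"))
  if (!setequal(names(mask$masks), names(dataset$blocks))) {
    stop("mask submodalities do not match the dataset's")
  }
  n <- dataset$layout$n_subjects
  n_mask <- nrow(mask$masks[[1L]])
  row_map <- if (n_mask == n && !permute_subjects) {
    seq_len(n)
  } else if (n_mask == n) {
    with_seed(derive_seed(seed, "mask_permute"), sample.int(n))
  } else {
    with_seed(derive_seed(seed, "mask_resample"),
              sample.int(n_mask, n, replace = TRUE))
  }
  for (sm in names(dataset$blocks)) {
    m <- mask$masks[[sm]]
    if (ncol(m) != ncol(dataset$blocks[[sm]])) {
      stop("mask block '", sm, "' has ", ncol(m), " features; dataset has ",
           ncol(dataset$blocks[[sm]]))
    }
    dataset$blocks[[sm]][m[row_map, , drop = FALSE]] <- NA_real_
  }
  dataset
}

#' Specify a simulation grid
#'
#' The full factorial grid over SNR values, latent-variable variants and
#' seeds. The default grid is SNR -20 to 20 dB in steps of 5 (9 levels), both
#' variants, and ten seeds: 180 datasets.
#'
#' @param base a [latent_cohort_spec()] template (its variant, snr_db and
#'   seed are overridden cell by cell).
#' @param snr_values numeric vector of SNRs in dB.
#' @param variants character subset of `c("cluster", "spectrum")`.
#' @param seeds integer vector of seeds.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(base, snr_values = seq(-20, 20, by = 5),
                      variants = c("cluster", "spectrum"),
                      seeds = 1:10) {
  stopifnot(inherits(base, "latent_cohort_spec"),
            length(snr_values) >= 1L, length(seeds) >= 1L)
  variants <- match.arg(variants, several.ok = TRUE)
  structure(
    list(base = base, snr_values = snr_values, variants = variants,
         seeds = as.integer(seeds)),
    class = "grid_spec"
  )
}

#' Enumerate the cells of a grid
#' @param grid a [grid_spec()].
#' @return data.frame with columns `snr_db`, `variant`, `seed`, one row per
#'   dataset; `nrow` = product of the three list lengths.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- expand.grid(seed = grid$seeds, variant = grid$variants,
                       snr_db = grid$snr_values,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells[, c("snr_db", "variant", "seed")]
}

#' Build all datasets of a simulation grid
#'
#' Generates one dataset per grid cell (|snr_values| x |variants| x |seeds|),
#' each tagged with its cell in `meta`. Loadings and the missingness template
#' are shared across cells so only SNR, variant and seed vary.
#'
#' @param grid a [grid_spec()].
#' @param loadings optional shared [random_loadings()]; default drawn from
#'   the base spec's seed.
#' @param mask optional `missing_mask` grafted onto every dataset.
#' @return list of `multimodal_dataset`, in `grid_cells()` order.
#' @export
build_grid <- function(grid, loadings = NULL, mask = NULL) {
  cells <- grid_cells(grid)
  if (is.null(loadings)) {
    loadings <- random_loadings(grid$base$layout, grid$base$seed)
  }
  lapply(seq_len(nrow(cells)), function(i) {
    spec <- grid$base
    spec$snr_db <- cells$snr_db[i]
    spec$variant <- cells$variant[i]
    spec$seed <- cells$seed[i]
    ds <- generate_cohort(spec, loadings)
    if (!is.null(mask)) {
      ds <- apply_missing_pattern(ds, mask, seed = spec$seed)
    }
    ds$meta$cell <- list(snr_db = spec$snr_db, variant = spec$variant,
                         seed = spec$seed)
    ds
  })
}

#' Reference fixture: layout, missingness template and loadings
#'
#' A synthetic stand-in for the real cohort's shape: 289 subjects (138
#' patients + 151 matched controls) across five modalities — cognition, MRI,
#' electrophysiology, psychopathology, and perinatal register data — each
#' divided into named submodalities. The missingness template combines
#' block-wise absence (whole submodality missing for a subject, e.g. no MRI
#' session) with about 5% randomly missing cells elsewhere. All three pieces
#' are deterministic given the seed.
#'
#' @param seed integer seed.
#' @param n_subjects subject count (default 289).
#' @param features_per_submodality feature count per submodality (default 4;
#'   the real per-submodality counts are not public, so the fixture keeps the
#'   tree shape with configurable width).
#' @return list with `layout` ([dataset_layout()]), `mask` (`missing_mask`)
#'   and `loadings` ([random_loadings()]).
#' @export
reference_fixture <- function(seed = 1L, n_subjects = 289L,
                              features_per_submodality = 4L) {
  k <- features_per_submodality
  feat <- function(stub) paste0(stub, "_", seq_len(k))
  layout <- dataset_layout(
    list(
      cognition = list(
        BACS = feat("bacs"),
        CANTAB = feat("cantab"),
        DART = feat("dart"),
        TMT = feat("tmt")
      ),
      MRI = list(
        cortical_LH = feat("ctx_lh"),
        cortical_RH = feat("ctx_rh"),
        subcortical = feat("subctx")
      ),
      electrophysiology = list(
        MMN = feat("mmn"),
        PPI = feat("ppi"),
        SA = feat("sa")
      ),
      psychopathology = list(
        PANSS = feat("panss")
      ),
      perinatal_register = list(
        birth = feat("birth"),
        APGAR = feat("apgar")
      )
    ),
    n_subjects = n_subjects
  )
  tab <- layout_submodalities(layout)
  # block-wise missingness rates per modality: cognition nearly complete,
  # MRI/EEG sessions missing for a sizeable minority, register links patchy
  block_rate <- c(cognition = 0.05, MRI = 0.20, electrophysiology = 0.25,
                  psychopathology = 0.03, perinatal_register = 0.15)
  masks <- with_seed(derive_seed(seed, "fixture_mask"), {
    out <- lapply(seq_len(nrow(tab)), function(i) {
      p <- tab$n_features[i]
      m <- matrix(stats::runif(n_subjects * p) < 0.05, n_subjects, p)
      gone <- stats::runif(n_subjects) < block_rate[[tab$modality[i]]]
      m[gone, ] <- TRUE
      colnames(m) <- layout_features(layout, tab$submodality[i])
      m
    })
    names(out) <- tab$submodality
    out
  })
  mask <- structure(
    list(masks = masks, fractions = vapply(masks, mean, numeric(1))),
    class = "missing_mask"
  )
  list(layout = layout, mask = mask,
       loadings = random_loadings(layout, seed))
}
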