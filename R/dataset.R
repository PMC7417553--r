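#' Construct a multimodal dataset
#'
#' Bundles per-submodality feature blocks (matrices with `NA` marking missing
#' cells), outcomes, covariates and provenance metadata under a shared layout.
#' All blocks carry subjects in the same order; subject identity is the
#' `subject_id` rowname.
#'
#' @param layout a [dataset_layout()].
#' @param blocks named list of numeric matrices, one per submodality, each
#'   `n_subjects x n_features` with subject ids as rownames and the layout's
#'   feature names as colnames; `NA` entries are missing.
#' @param outcomes data.frame with columns `subject_id` and `label` (0/1 or
#'   `NA`) and/or `response` (numeric or `NA`).
#' @param covariates data.frame with `subject_id` first and the conventional
#'   covariates (sex, age, cohort, handedness); categorical columns are
#'   one-hot encoded on access via [covariate_matrix()].
#' @param meta free-form provenance list (seed, SNR, variant, ...).
#' @return object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(layout, blocks, outcomes, covariates,
                               meta = list()) {
  stopifnot(inherits(layout, "dataset_layout"))
  tab <- layout_submodalities(layout)
  if (!setequal(names(blocks), tab$submodality)) {
    stop("blocks must match layout submodalities exactly")
  }
  blocks <- blocks[tab$submodality]
  ids <- rownames(blocks[[1L]])
  if (is.null(ids)) stop("blocks must carry subject_id rownames")
  if (length(ids) != layout$n_subjects) {
    stop("block '", tab$submodality[1L], "' has ", length(ids),
         " subjects; layout declares ", layout$n_subjects)
  }
  for (sm in tab$submodality) {
    b <- blocks[[sm]]
    feats <- layout_features(layout, sm)
    if (!is.matrix(b) || !identical(colnames(b), feats)) {
      stop("block '", sm, "' columns must equal the layout's feature names")
    }
    if (!identical(rownames(b), ids)) {
      stop("block '", sm, "' subject order differs from the first block")
    }
    storage.mode(blocks[[sm]]) <- "double"
  }
  stopifnot(is.data.frame(outcomes), "subject_id" %in% names(outcomes))
  outcomes <- outcomes[match(ids, as.character(outcomes$subject_id)), ,
                       drop = FALSE]
  if (anyNA(outcomes$subject_id)) stop("outcomes missing for some subjects")
  rownames(outcomes) <- NULL
  stopifnot(is.data.frame(covariates), "subject_id" %in% names(covariates))
  covariates <- covariates[match(ids, as.character(covariates$subject_id)), ,
                           drop = FALSE]
  if (anyNA(covariates$subject_id)) stop("covariates missing for some subjects")
  rownames(covariates) <- NULL
  structure(
    list(layout = layout, blocks = blocks, outcomes = outcomes,
         covariates = covariates, meta = meta, subject_ids = ids),
    class = "multimodal_dataset"
  )
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  frac <- extract_missing_mask(x)$fractions
  cat("multimodal_dataset:", x$layout$n_subjects, "subjects,",
      length(x$blocks), "submodality blocks,",
      layout_n_features(x$layout), "features\n")
  cat("  missing fraction by block:",
      paste0(names(frac), "=", sprintf("%.2f", frac), collapse = ", "), "\n")
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1L, x$meta)
  if (length(scalars)) {
    cat("  meta:",
        paste0(names(scalars), "=", unlist(scalars), collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-hot encoded numeric covariate matrix
#'
#' Categorical covariates (sex, cohort, handedness, any character/factor
#' column) are expanded into 0/1 indicator columns with the first level
#' dropped; numeric covariates (age) pass through. Level order is the sorted
#' unique values, so the encoding is deterministic and independent of row
#' order.
#'
#' @param dataset a `multimodal_dataset`.
#' @return numeric matrix, one row per subject, rownames = subject ids.
#' @export
covariate_matrix <- function(dataset) {
  cov <- dataset$covariates
  cols <- setdiff(names(cov), "subject_id")
  pieces <- lapply(cols, function(cl) {
    v <- cov[[cl]]
    if (is.numeric(v)) {
      m <- matrix(as.numeric(v), ncol = 1L, dimnames = list(NULL, cl))
      return(m)
    }
    lev <- sort(unique(as.character(v)))
    if (length(lev) <= 1L) return(NULL)
    keep <- lev[-1L]
    m <- vapply(keep, function(l) as.numeric(as.character(v) == l),
                numeric(length(v)))
    m <- matrix(m, ncol = length(keep),
                dimnames = list(NULL, paste(cl, keep, sep = "_")))
    m
  })
  out <- do.call(cbind, Filter(Negate(is.null), pieces))
  if (is.null(out)) out <- matrix(numeric(0), nrow = nrow(cov), ncol = 0L)
  rownames(out) <- dataset$subject_ids
  out
}

#' Extract the missingness mask of a dataset
#'
#' The mask records, per submodality block, which entries are missing
#' (`TRUE` = missing) together with the per-block missing fraction. The mask
#' of a real dataset is the template grafted onto simulated cohorts by
#' [apply_missing_pattern()].
#'
#' @param dataset a `multimodal_dataset`.
#' @return object of class `missing_mask`: list with `masks` (named list of
#'   logical matrices) and `fractions` (named numeric vector in `[0, 1]`).
#' @export
extract_missing_mask <- function(dataset) {
  masks <- lapply(dataset$blocks, is.na)
  fractions <- vapply(masks, mean, numeric(1))
  structure(list(masks = masks, fractions = fractions), class = "missing_mask")
}

#' @export
print.missing_mask <- function(x, ...) {
  cat("missing_mask over", length(x$masks), "blocks; fractions:",
      paste0(sprintf("%.3f", x$fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Split a dataset into per-submodality blocks for late integration
#'
#' Returns the units at which models are fitted: one block per submodality, in
#' layout order, with the conventional covariates (one-hot encoded) appended
#' as extra columns so every submodality model is self-contained. A subject's
#' row in a block is flagged `block_missing` when every original feature of
#' that submodality is missing for them (block-wise missingness, e.g. no MRI
#' session).
#'
#' @param dataset a `multimodal_dataset`.
#' @param append_covariates append covariate columns to every block
#'   (default `TRUE`).
#' @return named list (layout order) of lists with elements `name`,
#'   `modality`, `block` (features + covariates), `mask` (logical, original
#'   features only), `block_missing` (logical per subject).
#' @export
split_into_submodalities <- function(dataset, append_covariates = TRUE) {
  tab <- layout_submodalities(dataset$layout)
  covm <- if (append_covariates) covariate_matrix(dataset) else NULL
  out <- lapply(seq_len(nrow(tab)), function(i) {
    sm <- tab$submodality[i]
    b <- dataset$blocks[[sm]]
    mask <- is.na(b)
    block_missing <- rowSums(!mask) == 0L
    block <- if (is.null(covm)) b else cbind(b, covm)
    list(name = sm, modality = tab$modality[i], block = block,
         mask = mask, block_missing = block_missing)
  })
  names(out) <- tab$submodality
  out
}

# ---- manifest I/O ----------------------------------------------------------

read_table_csv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN"))
  if (names(df)[1L] != "subject_id") {
    stop(what, " file ", path, " must have subject_id as its first column")
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in ", what, " file ", path, ": ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  }
  df
}

layout_from_list <- function(lst) {
  mods <- lapply(lst$modalities, function(mod) {
    lapply(mod, function(feats) as.character(unlist(feats)))
  })
  dataset_layout(mods, n_subjects = lst$n_subjects)
}

layout_to_list <- function(layout) {
  list(modalities = layout$modalities, n_subjects = layout$n_subjects)
}

#' Load a multimodal dataset from a JSON manifest
#'
#' The manifest declares the layout tree and points to one CSV per submodality
#' block plus an outcomes CSV and a covariates CSV. All tables are UTF-8 CSV
#' with a header row and `subject_id` as first column; empty cells and the
#' tokens `NA`/`NaN` are read as missing. Blocks are joined on `subject_id`,
#' so row order inside files carries no meaning.
#'
#' @param manifest_path path to the manifest JSON.
#' @return a [multimodal_dataset()].
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  layout <- layout_from_list(man$layout)
  tab <- layout_submodalities(layout)
  if (!setequal(names(man$blocks), tab$submodality)) {
    stop("manifest blocks do not match the declared layout submodalities")
  }
  out_df <- read_table_csv(resolve(man$outcomes), "outcomes")
  if (!"label" %in% names(out_df)) out_df$label <- NA_real_
  if (!"response" %in% names(out_df)) out_df$response <- NA_real_
  ids <- out_df$subject_id
  if (length(ids) != layout$n_subjects) {
    stop("outcomes file has ", length(ids), " subjects; layout declares ",
         layout$n_subjects)
  }
  cov_df <- read_table_csv(resolve(man$covariates), "covariates")
  blocks <- lapply(tab$submodality, function(sm) {
    df <- read_table_csv(resolve(man$blocks[[sm]]), paste0("block '", sm, "'"))
    feats <- layout_features(layout, sm)
    missing_cols <- setdiff(feats, names(df))
    if (length(missing_cols)) {
      stop("block '", sm, "' is missing declared feature column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    extra <- setdiff(names(df), c("subject_id", feats))
    if (length(extra)) {
      stop("block '", sm, "' has undeclared column(s): ",
           paste(extra, collapse = ", "))
    }
    idx <- match(ids, df$subject_id)
    if (anyNA(idx)) {
      stop("block '", sm, "' lacks rows for subject(s): ",
           paste(ids[is.na(idx)], collapse = ", "))
    }
    m <- as.matrix(df[idx, feats, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  })
  names(blocks) <- tab$submodality
  multimodal_dataset(layout, blocks, out_df, cov_df,
                     meta = man$meta %||% list())
}

#' Write a multimodal dataset as manifest + CSV files
#'
#' Inverse of [load_dataset()]: one CSV per submodality block, an outcomes
#' CSV, a covariates CSV, and a JSON manifest tying them together. Missing
#' entries are emitted as empty cells.
#'
#' @param dataset a `multimodal_dataset`.
#' @param dir output directory (created if absent).
#' @param name basename for the manifest (default `"dataset"`).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, name = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- layout_submodalities(dataset$layout)
  block_paths <- stats::setNames(
    paste0(name, "_block_", tab$submodality, ".csv"), tab$submodality)
  for (sm in tab$submodality) {
    df <- data.frame(subject_id = dataset$subject_ids,
                     dataset$blocks[[sm]], check.names = FALSE)
    utils::write.csv(df, file.path(dir, block_paths[[sm]]),
                     row.names = FALSE, na = "")
  }
  out_path <- paste0(name, "_outcomes.csv")
  utils::write.csv(dataset$outcomes, file.path(dir, out_path),
                   row.names = FALSE, na = "")
  cov_path <- paste0(name, "_covariates.csv")
  utils::write.csv(dataset$covariates, file.path(dir, cov_path),
                   row.names = FALSE, na = "")
  manifest <- list(
    layout = layout_to_list(dataset$layout),
    blocks = as.list(block_paths),
    outcomes = out_path,
    covariates = cov_path,
    meta = dataset$meta
  )
  manifest_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
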