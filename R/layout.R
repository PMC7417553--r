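#' Construct a dataset layout
#'
#' A layout is the modality -> submodality -> feature tree every dataset and
#' every simulator call must obey: an ordered list of modalities, each divided
#' into ordered submodalities, each carrying a named set of features, plus the
#' subject count. Feature names are globally unique so blocks can always be
#' re-assembled unambiguously.
#'
#' @param modalities named list; each element is itself a named list mapping a
#'   submodality name to a character vector of feature names.
#' @param n_subjects positive integer number of subjects.
#' @return an object of class `dataset_layout`.
#' @examples
#' dataset_layout(
#'   list(cognition = list(memory = c("m1", "m2"), speed = "rt_mean")),
#'   n_subjects = 10
#' )
#' @export
dataset_layout <- function(modalities, n_subjects) {
  stopifnot(is.list(modalities), length(modalities) >= 1L)
  if (is.null(names(modalities)) || anyNA(names(modalities)) ||
      any(names(modalities) == "")) {
    stop("every modality must be named")
  }
  for (mod in names(modalities)) {
    subs <- modalities[[mod]]
    if (!is.list(subs) || length(subs) == 0L || is.null(names(subs)) ||
        any(names(subs) == "")) {
      stop("modality '", mod, "' must be a named list of submodalities")
    }
    for (sm in names(subs)) {
      feats <- subs[[sm]]
      if (!is.character(feats) || length(feats) < 1L) {
        stop("submodality '", sm, "' must declare at least one feature name")
      }
    }
  }
  feats <- unlist(modalities, use.names = FALSE)
  if (anyDuplicated(feats)) {
    stop("feature names must be globally unique; duplicated: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  subnames <- unlist(lapply(modalities, names), use.names = FALSE)
  if (anyDuplicated(subnames)) {
    stop("submodality names must be unique across modalities")
  }
  n_subjects <- as.integer(n_subjects)
  stopifnot(length(n_subjects) == 1L, !is.na(n_subjects), n_subjects >= 1L)
  structure(
    list(modalities = modalities, n_subjects = n_subjects),
    class = "dataset_layout"
  )
}

#' Enumerate the submodalities of a layout
#'
#' @param layout a `dataset_layout`.
#' @return data.frame with columns `modality`, `submodality`, `n_features`,
#'   in layout order.
#' @export
layout_submodalities <- function(layout) {
  stopifnot(inherits(layout, "dataset_layout"))
  rows <- lapply(names(layout$modalities), function(mod) {
    subs <- layout$modalities[[mod]]
    data.frame(
      modality = mod,
      submodality = names(subs),
      n_features = vapply(subs, length, integer(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature names of one submodality
#' @param layout a `dataset_layout`.
#' @param submodality submodality name.
#' @return character vector of feature names.
#' @export
layout_features <- function(layout, submodality) {
  for (mod in layout$modalities) {
    if (submodality %in% names(mod)) return(mod[[submodality]])
  }
  stop("unknown submodality '", submodality, "'")
}

#' Total feature count of a layout
#' @param layout a `dataset_layout`.
#' @return integer.
#' @export
layout_n_features <- function(layout) {
  length(unlist(layout$modalities, use.names = FALSE))
}

#' @export
print.dataset_layout <- function(x, ...) {
  tab <- layout_submodalities(x)
  cat("dataset_layout:", length(x$modalities), "modalities,",
      nrow(tab), "submodalities,", layout_n_features(x), "features,",
      x$n_subjects, "subjects\n")
  for (mod in names(x$modalities)) {
    subs <- x$modalities[[mod]]
    cat("  ", mod, ": ",
        paste0(names(subs), " (", vapply(subs, length, integer(1)), ")",
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
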