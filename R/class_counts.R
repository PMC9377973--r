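#' Per-class training sample counts
#'
#' Bundle class labels with the number of training samples observed in each
#' class.  This is the sole input to both balancing schemes: the
#' effective-sample-size weights and the class priors are computed from these
#' counts once, before training, and stay fixed for a run.
#'
#' @param counts integer vector of per-class sample counts, all >= 1.
#' @param labels character vector of unique class names, same length as
#'   `counts`.  Defaults to `class1, class2, ...`.
#' @return An object of class `"class_counts"`: a list with elements
#'   `labels` and `counts`, aligned by position.
#' @examples
#' class_counts(c(838, 224, 305), c("adenoma", "cancer", "polyp"))
#' @export
class_counts <- function(counts, labels = NULL) {
  if (length(counts) < 1L)
    stop("at least one class is required")
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers")
  counts <- as.integer(round(counts))
  if (is.null(labels))
    labels <- paste0("class", seq_along(counts))
  labels <- as.character(labels)
  if (length(labels) != length(counts))
    stop("labels and counts must have the same length")
  if (anyDuplicated(labels))
    stop("labels must be unique")
  structure(list(labels = labels, counts = counts), class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  cat("Class counts (k =", length(x$counts), "classes,",
      sum(x$counts), "samples)\n")
  print(stats::setNames(x$counts, x$labels))
  invisible(x)
}

#' @export
as.data.frame.class_counts <- function(x, ...) {
  data.frame(label = x$labels, count = x$counts, stringsAsFactors = FALSE)
}

#' Read class counts from a two-column CSV
#'
#' Expects columns `label` and `count` (header required).
#'
#' @param path path to a CSV file.
#' @return A [class_counts()] object.
#' @export
read_class_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "count") %in% names(df)))
    stop("expected columns 'label' and 'count' in ", path)
  class_counts(df$count, df$label)
}

#' Reference lesion-count profiles
#'
#' Per-class image counts for the three colorectal lesion classes seen in
#' white-light endoscopy (adenoma, cancer, polyp).  The `"train"` profile
#' {adenoma = 838, cancer = 224, polyp = 305} is the canonical imbalanced
#' training profile used throughout this package as the default study
#' condition; `"full"` is the corresponding full collection before the 8:2
#' train/test split.  `"kvasir"` and `"cvc"` are two small public-style test
#' profiles with the same three classes.
#'
#' @param profile one of `"train"`, `"full"`, `"kvasir"`, `"cvc"`.
#' @return A [class_counts()] object.
#' @examples
#' sum(lesion_counts("full")$counts)   # 1709
#' sum(lesion_counts("train")$counts)  # 1367
#' @export
lesion_counts <- function(profile = c("train", "full", "kvasir", "cvc")) {
  profile <- match.arg(profile)
  labs <- c("adenoma", "cancer", "polyp")
  cnt <- switch(profile,
    train  = c(838L, 224L, 305L),
    full   = c(1048L, 280L, 381L),
    kvasir = c(180L, 73L, 175L),
    cvc    = c(40L, 19L, 36L))
  class_counts(cnt, labs)
}
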