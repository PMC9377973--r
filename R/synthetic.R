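#' Synthetic dataset specification
#'
#' Describes an imbalanced Gaussian-mixture classification dataset: class i
#' is drawn from an isotropic Gaussian at `centers[i, ]` with standard
#' deviation `spread`.  The spread controls class overlap and hence the
#' difficulty of the task; the counts control the imbalance.  The default
#' counts follow the three-class colorectal lesion training profile
#' {adenoma = 838, cancer = 224, polyp = 305} (see [lesion_counts()]), and
#' the default centers sit on a circle of radius 1.2 in the first two
#' feature dimensions, giving moderate overlap at `spread = 1`.
#'
#' @param counts a [class_counts()] object (or integer vector).
#' @param dim feature dimension (default 2).
#' @param centers optional k x dim matrix of distinct class centers.
#' @param spread positive per-class Gaussian scale (default 1).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `"dataset_spec"`.
#' @export
dataset_spec <- function(counts = lesion_counts(), dim = 2L, centers = NULL,
                         spread = 1, seed = 1L) {
  counts <- as_class_counts(counts)
  k <- length(counts$counts)
  dim <- as.integer(dim)
  if (dim < 1L) stop("dim must be >= 1")
  if (is.null(centers)) {
    centers <- matrix(0, k, dim)
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    centers[, 1L] <- 1.2 * cos(ang)
    if (dim >= 2L) centers[, 2L] <- 1.2 * sin(ang)
  }
  centers <- as.matrix(centers)
  if (nrow(centers) != k || ncol(centers) != dim)
    stop("centers must be a k x dim matrix")
  if (anyDuplicated(as.data.frame(centers)))
    stop("class centers must be distinct")
  if (!is.numeric(spread) || spread <= 0) stop("spread must be > 0")
  structure(list(counts = counts, dim = dim, centers = centers,
                 spread = spread, seed = as.integer(seed)),
            class = "dataset_spec")
}

# Run expr with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a labeled dataset
#'
#' Draws exactly `counts[i]` samples for class i from its isotropic
#' Gaussian.  Per-class tallies are exact and the result is identical for
#' identical specs; the caller's RNG state is left untouched.
#'
#' @param spec a [dataset_spec()].
#' @return An object of class `"labeled_dataset"`: list with `features`
#'   (n x dim matrix), `labels` (integer vector in `1..k`) and `spec`.
#' @examples
#' ds <- generate_dataset(dataset_spec(class_counts(c(5, 5)), seed = 7))
#' table(ds$labels)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- sum(spec$counts$counts)
  k <- length(spec$counts$counts)
  with_seed(spec$seed, {
    X <- matrix(0, n, spec$dim)
    y <- integer(n)
    at <- 0L
    for (i in seq_len(k)) {
      ni <- spec$counts$counts[i]
      rows <- at + seq_len(ni)
      X[rows, ] <- matrix(stats::rnorm(ni * spec$dim, sd = spec$spread),
                          ni, spec$dim) +
        matrix(spec$centers[i, ], ni, spec$dim, byrow = TRUE)
      y[rows] <- i
      at <- at + ni
    }
    structure(list(features = X, labels = y, spec = spec),
              class = "labeled_dataset")
  })
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset: %d samples, %d features, %d classes\n",
              nrow(x$features), ncol(x$features),
              length(x$spec$counts$counts)))
  print(stats::setNames(tabulate(x$labels, length(x$spec$counts$counts)),
                        x$spec$counts$labels))
  invisible(x)
}

#' @export
as.data.frame.labeled_dataset <- function(x, ...) {
  df <- as.data.frame(x$features)
  names(df) <- paste0("x", seq_len(ncol(x$features)))
  df$label <- x$labels
  df
}

#' Stratified train/test split
#'
#' Splits per class so the class proportions survive: class i contributes
#' `round(frac * n_i)` samples to the training set and the remainder to
#' the test set.  With the full lesion profile {adenoma = 1048, cancer =
#' 280, polyp = 381} and `frac = 0.8` this yields the training profile
#' {838, 224, 305} (1367 of 1709 images).
#'
#' @param ds a [generate_dataset()] result.
#' @param frac training fraction in `(0, 1)` (default 0.8).
#' @param seed integer seed for the within-class shuffles.
#' @return List with elements `train` and `test`, both `labeled_dataset`
#'   objects; together they partition the input.
#' @export
split_train_test <- function(ds, frac = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  k <- length(ds$spec$counts$counts)
  tallies <- tabulate(ds$labels, k)
  if (any(tallies < 2L))
    stop("every class needs at least 2 samples to stratify")
  with_seed(seed, {
    tr_idx <- integer(0)
    for (i in seq_len(k)) {
      rows <- which(ds$labels == i)
      n_tr <- round(frac * length(rows))
      tr_idx <- c(tr_idx, sample(rows, n_tr))
    }
    te_idx <- setdiff(seq_along(ds$labels), tr_idx)
    list(train = subset_dataset(ds, sort(tr_idx)),
         test  = subset_dataset(ds, sort(te_idx)))
  })
}

subset_dataset <- function(ds, idx) {
  tallies <- tabulate(ds$labels[idx], length(ds$spec$counts$counts))
  spec <- ds$spec
  spec$counts <- class_counts(pmax(tallies, 1L), spec$counts$labels)
  spec$counts$counts <- as.integer(tallies)  # allow empty classes in subsets
  structure(list(features = ds$features[idx, , drop = FALSE],
                 labels = ds$labels[idx], spec = spec),
            class = "labeled_dataset")
}

#' Write/read a labeled dataset as CSV
#'
#' Feature columns `x1..xd` plus an integer `label` column.
#'
#' @param ds a `labeled_dataset`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `labeled_dataset` with a
#'   reconstructed spec (read).
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param labels optional class names for the read dataset.
#' @export
read_dataset <- function(path, labels = NULL) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("expected a 'label' column in ", path)
  y <- as.integer(df$label)
  X <- as.matrix(df[setdiff(names(df), "label")])
  k <- max(y)
  tallies <- tabulate(y, k)
  spec <- dataset_spec(class_counts(tallies, labels), dim = ncol(X),
                       spread = 1, seed = 0L)
  structure(list(features = X, labels = y, spec = spec),
            class = "labeled_dataset")
}
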