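#' Resting-state scan container
#'
#' Holds one subject's grayordinate-by-time rest matrix together with the run
#' structure of the concatenated acquisition and a preprocessing flag.
#'
#' @param subject_id opaque subject identifier.
#' @param data numeric `n_total x t` matrix (grayordinates in rows).
#' @param run_boundaries integer frame counts per concatenated run; must sum
#'   to `ncol(data)`.
#' @param preprocessed has [preprocess_rest()] been applied?
#' @param degenerate integer count of zero-variance rows zero-filled during
#'   preprocessing.
#' @return object of class `"rest_scan"`.
#' @export
rest_scan <- function(subject_id, data, run_boundaries = ncol(data),
                      preprocessed = FALSE, degenerate = 0L) {
  data <- as.matrix(data)
  run_boundaries <- as.integer(run_boundaries)
  if (sum(run_boundaries) != ncol(data)) {
    stop("run_boundaries must sum to the number of time frames", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      data = data,
      run_boundaries = run_boundaries,
      preprocessed = isTRUE(preprocessed),
      degenerate = as.integer(degenerate)
    ),
    class = "rest_scan"
  )
}

#' @export
print.rest_scan <- function(x, ...) {
  cat(sprintf(
    "<rest_scan> subject %s: %d grayordinates x %d frames (%d run%s)%s\n",
    x$subject_id, nrow(x$data), ncol(x$data), length(x$run_boundaries),
    if (length(x$run_boundaries) == 1) "" else "s",
    if (x$preprocessed) ", preprocessed" else ", raw"
  ))
  invisible(x)
}

#' Load and concatenate rest runs
#'
#' Reads one or more run files for a subject and concatenates them along the
#' time axis. Supported formats: the portable `.rds` array container written
#' by this package, plain-text matrices (`.tsv`/`.txt`/`.csv`, grayordinates
#' in rows), and plain NIfTI (`.nii`/`.nii.gz`, read via the RNifti package
#' with the last dimension as time). Row order is never permuted.
#'
#' @param paths ordered character vector of run files.
#' @param geom a [geometry()]; every file must match its grayordinate axis.
#' @param subject_id identifier recorded on the scan.
#' @return a raw (unpreprocessed) [rest_scan()] with `run_boundaries` recording
#'   the per-run frame counts.
#' @export
load_rest_series <- function(paths, geom, subject_id = "subject") {
  if (length(paths) == 0) stop("no run files given", call. = FALSE)
  runs <- lapply(paths, read_grayordinate_matrix)
  for (i in seq_along(runs)) {
    if (nrow(runs[[i]]) != geom$n_total) {
      stop(sprintf(
        "file '%s' has %d grayordinate rows but geometry expects %d",
        paths[[i]], nrow(runs[[i]]), geom$n_total
      ), call. = FALSE)
    }
  }
  rest_scan(
    subject_id = subject_id,
    data = do.call(cbind, runs),
    run_boundaries = vapply(runs, ncol, integer(1)),
    preprocessed = FALSE
  )
}

read_grayordinate_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "rds") {
    x <- readRDS(path)
    if (is.list(x) && !is.null(x$data)) x <- x$data
    return(as.matrix(x))
  }
  if (ext %in% c("tsv", "txt", "csv")) {
    sep <- if (ext == "csv") "," else ""
    m <- as.matrix(read.table(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
    return(m)
  }
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package", call. = FALSE)
    }
    img <- RNifti::readNifti(path)
    d <- dim(img)
    return(matrix(as.numeric(img), nrow = prod(d[-length(d)]), ncol = d[length(d)]))
  }
  stop(sprintf("unrecognized rest-series format: '%s'", path), call. = FALSE)
}

#' Preprocess a rest scan
#'
#' Applies the standard contract before any feature extraction: the first
#' `n_discard` frames of each run are dropped, then every grayordinate row of
#' the concatenated series is demeaned and scaled to unit variance.
#' Zero-variance rows are set to all zeros (preserving index alignment) and
#' counted in the returned scan's `degenerate` field.
#'
#' @param scan a raw [rest_scan()].
#' @param n_discard frames discarded at the start of each run (default 5).
#' @return a preprocessed [rest_scan()].
#' @export
preprocess_rest <- function(scan, n_discard = 5) {
  stopifnot(inherits(scan, "rest_scan"))
  if (scan$preprocessed) return(scan)
  if (any(scan$run_boundaries <= n_discard)) {
    stop(sprintf(
      "every run must be longer than n_discard = %d frames", n_discard
    ), call. = FALSE)
  }
  ends <- cumsum(scan$run_boundaries)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- unlist(Map(function(s, e) (s + n_discard):e, starts, ends))
  X <- scan$data[, keep, drop = FALSE]
  mu <- rowMeans(X)
  X <- X - mu
  ## population (1/t) variance normalization; unit variance per row
  s <- sqrt(rowMeans(X^2))
  degenerate <- s < 1e-12
  s[degenerate] <- 1
  X <- X / s
  X[degenerate, ] <- 0
  rest_scan(
    subject_id = scan$subject_id,
    data = X,
    run_boundaries = scan$run_boundaries - as.integer(n_discard),
    preprocessed = TRUE,
    degenerate = sum(degenerate)
  )
}

#' Task activation map
#'
#' One subject's contrast map restricted to the cortical surface
#' (z-statistic units).
#'
#' @param subject_id subject identifier.
#' @param contrast_id contrast name from the task battery.
#' @param values numeric vector of length `n_cortex`.
#' @return object of class `"activation_map"`.
#' @export
activation_map <- function(subject_id, contrast_id, values) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) {
    stop("activation map values must be finite", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      contrast_id = as.character(contrast_id),
      values = values
    ),
    class = "activation_map"
  )
}

#' Cortical + subcortical parcellation
#'
#' Integer label per grayordinate, 0 for unassigned, 1..K for regions; every
#' region must be nonempty.
#'
#' @param labels integer vector (length `n_total`).
#' @param K number of regions; default `max(labels)`.
#' @return object of class `"parcellation"`.
#' @export
parcellation <- function(labels, K = max(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 0) || any(labels > K)) {
    stop("labels must lie in 0..K", call. = FALSE)
  }
  sizes <- tabulate(labels, nbins = K)
  if (any(sizes == 0)) {
    stop(sprintf("region(s) %s are empty", paste(which(sizes == 0), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(labels = labels, K = as.integer(K)), class = "parcellation")
}

#' Read a parcellation from a one-column TSV of integer labels
#' @param path file with one integer label per grayordinate.
#' @return a [parcellation()].
#' @export
read_parcellation <- function(path) {
  labels <- scan(path, what = integer(), quiet = TRUE)
  parcellation(labels)
}

#' Train/test cohort split
#'
#' @param train_ids,test_ids disjoint character vectors of subject ids.
#' @param seed integer seed recorded for provenance.
#' @return object of class `"cohort_split"`.
#' @export
cohort_split <- function(train_ids, test_ids, seed = NA_integer_) {
  train_ids <- as.character(train_ids)
  test_ids <- as.character(test_ids)
  if (length(intersect(train_ids, test_ids)) > 0) {
    stop("train and test ids overlap", call. = FALSE)
  }
  structure(
    list(train_ids = train_ids, test_ids = test_ids, seed = seed),
    class = "cohort_split"
  )
}

#' Read/write cohort splits as JSON
#'
#' The on-disk form is `{"train": [...], "test": [...], "seed": N}`.
#'
#' @param split a [cohort_split()].
#' @param path JSON file path.
#' @return `read_split` returns a [cohort_split()]; `write_split` returns
#'   `path` invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(train = split$train_ids, test = split$test_ids, seed = split$seed),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_split(x$train, x$test, seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

## ---- portable array store ---------------------------------------------------
## Single-file serialized store keyed by subject id. Values round-trip
## bit-identically; metadata (subject_id, feature_kind, normalized flag)
## travels with each entry.

read_store <- function(store) {
  if (file.exists(store)) readRDS(store) else structure(list(), class = "restpred_store")
}

#' Write a connectome to a store
#'
#' A store is a single-file container holding any number of connectomes (or
#' other array objects) keyed by subject id; entries round-trip bit-identically.
#'
#' @param connectome a [connectome()].
#' @param store path to the store file (created if absent).
#' @return `store`, invisibly.
#' @export
write_connectome <- function(connectome, store) {
  stopifnot(inherits(connectome, "connectome"))
  db <- read_store(store)
  db[[connectome$subject_id]] <- connectome
  saveRDS(db, store)
  invisible(store)
}

#' Read a connectome back from a store
#'
#' @param store path to a store file.
#' @param subject_id entry key.
#' @return the stored [connectome()].
#' @export
read_connectome <- function(store, subject_id) {
  if (!file.exists(store)) {
    stop(sprintf("store '%s' does not exist", store), call. = FALSE)
  }
  db <- tryCatch(readRDS(store), error = function(e) {
    stop(sprintf("store '%s' is unreadable: %s", store, conditionMessage(e)),
         call. = FALSE)
  })
  if (is.null(db[[subject_id]])) {
    stop(sprintf("no entry for subject '%s' in '%s'", subject_id, store),
         call. = FALSE)
  }
  db[[subject_id]]
}
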