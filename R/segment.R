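#' Cut a cleaned signal into fixed-length non-overlapping windows
#'
#' Windows are half-open sample ranges `[k*L, (k+1)*L)` (0-based) with
#' `L = fs * window_s`; any trailing remainder shorter than one window is
#' dropped, so a `T`-sample signal yields `floor(T / L)` segments.
#'
#' @param sig A `clean_ppg`, or a plain numeric vector (then `fs`,
#'   `subject_id` and `condition` must be supplied).
#' @param window_s Window length in seconds; `window_s * fs` must be a whole
#'   number of samples.
#' @param fs,subject_id,condition Metadata used when `sig` is a bare vector.
#' @return A list of `ppg_segment` objects, each with `samples`,
#'   `subject_id`, `condition`, `fs`, `window_s` and 0-based `offset` (first
#'   sample index).  A signal shorter than one window gives an empty list
#'   with a warning.
#' @export
segment_signal <- function(sig, window_s, fs = NULL, subject_id = NULL,
                           condition = NULL) {
  if (inherits(sig, "clean_ppg")) {
    fs <- sig$fs
    subject_id <- sig$subject_id
    condition <- sig$condition
    x <- sig$signal
  } else {
    x <- as.numeric(sig)
    if (is.null(fs)) stop("`fs` is required for a bare vector", call. = FALSE)
  }
  L <- window_s * fs
  if (abs(L - round(L)) > 1e-9) {
    stop("`window_s * fs` must be a whole number of samples", call. = FALSE)
  }
  L <- as.integer(round(L))
  n_win <- length(x) %/% L
  if (n_win == 0L) {
    warning("signal shorter than one window; returning no segments")
    return(list())
  }
  lapply(seq_len(n_win) - 1L, function(k) {
    structure(
      list(samples = x[(k * L + 1L):((k + 1L) * L)],
           subject_id = subject_id,
           condition = condition,
           fs = fs,
           window_s = window_s,
           offset = k * L),
      class = "ppg_segment"
    )
  })
}

#' Subject-disjoint train/test split
#'
#' Subjects (never individual segments) are shuffled deterministically under
#' `seed` and assigned to the training and testing groups, so no subject
#' contributes segments to both sides.
#'
#' @param subject_ids Character vector of distinct subject ids, or a list of
#'   recordings/cleaned signals from which ids are taken.
#' @param n_train,n_test Subject counts; must sum to the number of distinct
#'   subjects.
#' @param seed Integer seed for the shuffle.
#' @return A list of class `subject_split` with `train` and `test` id
#'   vectors and the `seed`.
#' @export
split_subjects <- function(subject_ids, n_train, n_test, seed = 1L) {
  if (is.list(subject_ids)) {
    subject_ids <- vapply(subject_ids, function(r) r$subject_id, character(1))
  }
  ids <- unique(subject_ids)
  if (n_train + n_test != length(ids)) {
    stop(sprintf(
      "n_train + n_test = %d does not match the %d available subjects",
      n_train + n_test, length(ids)), call. = FALSE)
  }
  shuffled <- with_seed(derive_seed(seed, "subject-split"), sample(ids))
  structure(
    list(train = sort(shuffled[seq_len(n_train)]),
         test = sort(shuffled[n_train + seq_len(n_test)]),
         seed = as.integer(seed)),
    class = "subject_split"
  )
}

#' Build a labeled, subject-disjoint segment set
#'
#' Segments every cleaned signal with [segment_signal()] and groups the
#' segments by the split: a subject set with both 180 s condition recordings
#' contributes `2 * floor(180 / window_s)` segments each, reproducing the
#' usual bookkeeping (e.g. 11 training subjects at 5 s windows give
#' `11 * 2 * 36 = 792` training segments).
#'
#' @param clean_signals List of `clean_ppg` objects (both conditions present
#'   for every subject).
#' @param window_s Window length in seconds.
#' @param split A [split_subjects()] result.
#' @return An object of class `segment_set` with `train` and `test` segment
#'   lists, `window_s` and the `split`.
#' @export
build_segment_set <- function(clean_signals, window_s, split) {
  stopifnot(inherits(split, "subject_split"))
  ids <- vapply(clean_signals, function(s) s$subject_id, character(1))
  conds <- vapply(clean_signals, function(s) s$condition, character(1))
  for (id in unique(ids)) {
    have <- sort(unique(conds[ids == id]))
    if (!identical(have, sort(condition_levels))) {
      stop(sprintf("subject %s is missing a condition recording", id),
           call. = FALSE)
    }
  }
  missing <- setdiff(c(split$train, split$test), ids)
  if (length(missing)) {
    stop("split references unknown subjects: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grab <- function(subjects) {
    segs <- list()
    for (s in clean_signals) {
      if (s$subject_id %in% subjects) {
        segs <- c(segs, segment_signal(s, window_s))
      }
    }
    segs
  }
  structure(
    list(train = grab(split$train), test = grab(split$test),
         window_s = window_s, split = split),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d train / %d test segments of %g s (%d/%d subjects)\n",
              length(x$train), length(x$test), x$window_s,
              length(x$split$train), length(x$split$test)))
  invisible(x)
}

segment_labels <- function(segments) {
  vapply(segments, function(s) as.integer(s$condition == "stressed"),
         integer(1))
}
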