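#' Subject-level k-fold split
#'
#' Subjects are shuffled by seed and dealt round-robin to folds, so every
#' examination of a subject lands in the same fold — the guard against
#' calibrating or training on the patient being scored.
#'
#' @param subject_ids character vector of subject ids, one per case
#'   (duplicates mark repeated examinations).
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return object of class `fold_split`: named integer vector mapping each
#'   unique subject to a fold, with attribute `k`.
#' @export
kfold_split <- function(subject_ids, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < k) stop("need at least k subjects")
  shuffled <- with_seed(seed, sample(subjects))
  fold <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  fold <- fold[order(names(fold))]
  structure(fold, k = as.integer(k), class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d subjects in %d folds\n", length(x), attr(x, "k")))
  invisible(x)
}

fold_of <- function(split, subject_id) {
  f <- unclass(split)[as.character(subject_id)]
  if (any(is.na(f))) stop("subject not present in fold split: ", subject_id)
  unname(f)
}
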