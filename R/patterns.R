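#' Classify a subject's efficiency-decline pattern as stepwise or not
#'
#' In the ranked deletion list, step `n -> n+1` is *stepwise* when no size-n
#' resection mixes in among the size-(n+1) resections, i.e. the minimum
#' efficiency over size-n sets strictly exceeds the maximum over size-(n+1)
#' sets (equal values count as mixed). The subject-lobe pattern is:
#' \describe{
#'   \item{`perfect`}{every step stepwise;}
#'   \item{`partial`}{steps 1->2, 2->3 and 3->4 stepwise but at least one
#'     later step not;}
#'   \item{`non-step`}{no step stepwise;}
#'   \item{`mixed`}{any other flag pattern (the three named categories do not
#'     exhaust the possibilities).}
#' }
#' When the sweep covers fewer than 4 sizes the `partial` category is
#' undefined; classification is restricted to perfect/non-step/mixed with a
#' warning.
#'
#' @param sweep a `resection_sweep`.
#' @return A `stepwise_classification`: list with `subject_id`, `lobe`,
#'   `flags` (named logical, `"1->2"`, ...) and `category`.
#' @export
classify_stepwise <- function(sweep) {
  stopifnot(inherits(sweep, "resection_sweep"))
  r <- sweep$records
  sizes <- sort(unique(r$size))
  if (length(sizes) < 2L) stop("sweep must cover at least two sizes")
  k_max <- max(sizes)
  lo <- tapply(r$ge, r$size, min)
  hi <- tapply(r$ge, r$size, max)
  steps <- sizes[-length(sizes)]
  flags <- stats::setNames(
    as.vector(lo[as.character(steps)]) > as.vector(hi[as.character(steps + 1L)]),
    paste0(steps, "->", steps + 1L)
  )
  partial_defined <- k_max >= 4L && all(c(1L, 2L, 3L, 4L) %in% sizes)
  if (!partial_defined) {
    warning("sweep covers sizes below 4; 'partial' category undefined")
  }
  category <- if (all(flags)) {
    "perfect"
  } else if (!any(flags)) {
    "non-step"
  } else if (partial_defined &&
             all(flags[c("1->2", "2->3", "3->4")]) ) {
    "partial"
  } else {
    "mixed"
  }
  structure(list(subject_id = sweep$subject_id, lobe = sweep$lobe,
                 flags = flags, category = category),
            class = "stepwise_classification")
}

#' Worst resection at each size, with nesting flags
#'
#' For each resection size present in the sweep, the set with the lowest
#' post-deletion efficiency (ties broken by the lexicographic parcel tuple).
#' The `contains` column flags whether the worst size-(n-1) set is a subset
#' of the worst size-n set — at cohort level these flags quantify how far the
#' worst large deletions are accumulations of the previous worst areas.
#'
#' @param sweep a nonempty `resection_sweep`.
#' @return A `worst_by_size` data frame with columns `size`, `parcels`, `ge`,
#'   `contains` (`NA` for the smallest size); `subject_id` and `lobe` are
#'   attached as attributes.
#' @export
worst_by_size <- function(sweep) {
  stopifnot(inherits(sweep, "resection_sweep"))
  r <- sweep$records
  if (!nrow(r)) stop("empty sweep")
  o <- order(r$size, r$ge, r$parcels, method = "radix")
  r <- r[o, , drop = FALSE]
  first <- !duplicated(r$size)
  worst <- r[first, , drop = FALSE]
  members <- strsplit(worst$parcels, ",", fixed = TRUE)
  contains <- c(NA, vapply(seq_len(nrow(worst))[-1L], function(i) {
    all(members[[i - 1L]] %in% members[[i]])
  }, logical(1L)))
  out <- data.frame(size = worst$size, parcels = worst$parcels, ge = worst$ge,
                    contains = contains, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "subject_id") <- sweep$subject_id
  attr(out, "lobe") <- sweep$lobe
  class(out) <- c("worst_by_size", "data.frame")
  out
}

#' Cohort frequency table of worst single deletions
#'
#' Tallies, over a cohort, how often each parcel is a subject's worst single
#' deletion in a lobe — the table from which lobe epicenters are read. Rows
#' are sorted by count descending (ties lexicographic); parcels below a
#' minimum count (default 5\% of the cohort) are collapsed into an
#' `"other"` row so counts still sum to the cohort size. Each row carries the
#' `"n/d; p%"` label produced by [format_percent()].
#'
#' @param cohort_worst list of [worst_by_size()] results, one per subject.
#' @param lobe lobe label (defaults to the lobe of the first element).
#' @param min_frac minimum fraction of the cohort a parcel must reach to keep
#'   its own row (default `0.05`).
#' @return A `worst_frequency_table` data frame with columns `parcel`,
#'   `count`, `n`, `percent`, `label`; `lobe` and `n_subjects` attributes.
#' @export
worst_frequency_table <- function(cohort_worst, lobe = NULL, min_frac = 0.05) {
  stopifnot(length(cohort_worst) >= 1L)
  if (is.null(lobe)) lobe <- attr(cohort_worst[[1L]], "lobe")
  worst1 <- vapply(cohort_worst, function(w) {
    stopifnot(inherits(w, "worst_by_size"))
    w$parcels[w$size == 1L][1L]
  }, "")
  n <- length(worst1)
  tab <- table(worst1)
  counts <- as.integer(tab)
  parcels <- names(tab)
  o <- order(-counts, parcels, method = "radix")
  counts <- counts[o]; parcels <- parcels[o]
  keep <- counts >= min_frac * n
  if (any(!keep)) {
    parcels <- c(parcels[keep], "other")
    counts <- c(counts[keep], sum(counts[!keep]))
  }
  out <- data.frame(
    parcel = parcels, count = counts, n = n,
    percent = vapply(counts, function(k) .percent_half_up(k, n), integer(1L)),
    label = vapply(counts, function(k) format_percent(k, n), ""),
    stringsAsFactors = FALSE
  )
  attr(out, "lobe") <- lobe
  attr(out, "n_subjects") <- n
  class(out) <- c("worst_frequency_table", "data.frame")
  out
}
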