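#' Candidate epicenters of a lobe
#'
#' The epicenter of a lobe is the parcel most frequently found as a
#' subject's worst single deletion across the cohort. Because each lobe
#' typically shows two or three such focal parcels, the top `n_candidates`
#' rows of the worst-deletion frequency table are returned (ties broken
#' lexicographically; the collapsed `"other"` row is never a candidate).
#'
#' @param freq_table a [worst_frequency_table()].
#' @param n_candidates number of candidate epicenters (default 2).
#' @return Character vector of candidate parcel IDs, most frequent first.
#' @export
lobe_epicenter <- function(freq_table, n_candidates = 2L) {
  stopifnot(inherits(freq_table, "worst_frequency_table"),
            nrow(freq_table) >= 1L, n_candidates >= 1L)
  tab <- freq_table[freq_table$parcel != "other", , drop = FALSE]
  o <- order(-tab$count, tab$parcel, method = "radix")
  utils::head(tab$parcel[o], n_candidates)
}

#' Early-arrival evidence for an epicenter candidate
#'
#' Quantifies whether a candidate parcel enters a subject's worst-deletion
#' progression earlier than its physical distance from the worst single
#' deletion predicts. `s_r` is the smallest resection size whose worst set
#' contains the candidate (`NA` if it never appears up to the sweep's
#' maximum size). Since resections are connected, a candidate at hop
#' distance `h` from the worst single deletion cannot share a resection with
#' it below size `h + 1`, so the expected minimal arrival size is
#' `s_m = h + 1`. The difference `d = s_r - s_m` is negative when the
#' candidate arrives earlier than proximity alone allows (`early = TRUE`),
#' the signature of an epicenter that matters in its own right rather than
#' through adjacency to the worst parcel.
#'
#' @param wbs a [worst_by_size()] result for one subject-lobe.
#' @param atlas the matching `atlas_topology`.
#' @param candidate a parcel ID within the lobe.
#' @return An `epicenter_evidence`: list with `subject_id`, `lobe`,
#'   `candidate`, `worst_s1`, `s_r`, `s_m`, `d`, `early`.
#' @export
epicenter_evidence <- function(wbs, atlas, candidate) {
  stopifnot(inherits(wbs, "worst_by_size"), inherits(atlas, "atlas_topology"))
  lobe <- attr(wbs, "lobe")
  if (!candidate %in% lobe_parcels(atlas, lobe)) {
    stop("candidate '", candidate, "' outside lobe '", lobe, "'")
  }
  worst_s1 <- wbs$parcels[wbs$size == 1L][1L]
  members <- strsplit(wbs$parcels, ",", fixed = TRUE)
  hit <- vapply(members, function(m) candidate %in% m, logical(1L))
  s_r <- if (any(hit)) min(wbs$size[hit]) else NA_integer_
  h <- hop_distance(atlas, lobe, worst_s1, candidate)
  s_m <- h + 1
  d <- if (is.na(s_r)) NA_real_ else s_r - s_m
  structure(list(subject_id = attr(wbs, "subject_id"), lobe = lobe,
                 candidate = candidate, worst_s1 = worst_s1,
                 s_r = s_r, s_m = s_m, d = d,
                 early = isTRUE(!is.na(s_r) && s_r < s_m)),
            class = "epicenter_evidence")
}

#' Assign each subject to a connectotype
#'
#' A connectotype groups subjects by which epicenter dominates their
#' worst-deletion progression in a lobe. Assignment precedence per subject:
#' \enumerate{
#'   \item `worst-s1-is-epicenter`: the worst single deletion is itself a
#'     candidate;
#'   \item `adjacent-collapse`: a candidate physically adjacent to the worst
#'     single deletion appears in the worst size-2 resection — small
#'     first/second-rank differences between adjacent parcels are collapsed
#'     onto the candidate rather than treated as a distinct pattern;
#'   \item `earliest-arrival`: the candidate with the most negative arrival
#'     difference `d` (ties by smaller `s_r`, then lexicographic ID).
#' }
#' Subjects in whose worst-by-size progression no candidate ever appears are
#' labeled `"unassigned"`.
#'
#' @param cohort_worst list of [worst_by_size()] results, one per subject.
#' @param atlas the matching `atlas_topology`.
#' @param candidates nonempty character vector of candidate epicenters (e.g.
#'   from [lobe_epicenter()]).
#' @return Data frame with columns `subject_id`, `lobe`, `label`, `basis`.
#' @export
assign_connectotypes <- function(cohort_worst, atlas, candidates) {
  stopifnot(length(candidates) >= 1L, inherits(atlas, "atlas_topology"))
  rows <- lapply(cohort_worst, function(wbs) {
    stopifnot(inherits(wbs, "worst_by_size"))
    lobe <- attr(wbs, "lobe")
    worst_s1 <- wbs$parcels[wbs$size == 1L][1L]
    if (worst_s1 %in% candidates) {
      return(data.frame(subject_id = attr(wbs, "subject_id"), lobe = lobe,
                        label = worst_s1, basis = "worst-s1-is-epicenter",
                        stringsAsFactors = FALSE))
    }
    if (any(wbs$size == 2L)) {
      pair <- strsplit(wbs$parcels[wbs$size == 2L][1L], ",", fixed = TRUE)[[1L]]
      adj <- adjacent_parcels(atlas, worst_s1)
      coll <- sort(intersect(intersect(candidates, adj), pair),
                   method = "radix")
      if (length(coll)) {
        return(data.frame(subject_id = attr(wbs, "subject_id"), lobe = lobe,
                          label = coll[1L], basis = "adjacent-collapse",
                          stringsAsFactors = FALSE))
      }
    }
    ev <- lapply(candidates, function(cd) epicenter_evidence(wbs, atlas, cd))
    s_r <- vapply(ev, function(e) as.numeric(if (is.na(e$s_r)) Inf else e$s_r),
                  numeric(1L))
    d <- vapply(ev, function(e) as.numeric(if (is.na(e$d)) Inf else e$d),
                numeric(1L))
    if (all(is.infinite(s_r))) {
      return(data.frame(subject_id = attr(wbs, "subject_id"), lobe = lobe,
                        label = "unassigned", basis = "earliest-arrival",
                        stringsAsFactors = FALSE))
    }
    o <- order(d, s_r, candidates, method = "radix")
    data.frame(subject_id = attr(wbs, "subject_id"), lobe = lobe,
               label = candidates[o[1L]], basis = "earliest-arrival",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
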