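#' Enumerate anatomically plausible resections of a lobe
#'
#' A plausible resection is a connected set of resectable parcels within one
#' lobe of the physical-adjacency graph, of size 1 up to `max_size` (default
#' 10, the standard limit for serial deletions). Enumeration emits each
#' connected induced vertex set exactly once, using the anchored-extension
#' (ESU) recursion: sets are grown from each anchor parcel, candidate
#' extensions are restricted to parcels ordered after the anchor, and the
#' exclusive-neighbourhood rule prevents the same set being reached along two
#' growth orders. Distinct deletion orders of the same parcel set are one
#' resection.
#'
#' @param atlas an `atlas_topology`.
#' @param lobe lobe label to enumerate within.
#' @param max_size maximum resection size `K >= 1` (default 10).
#' @param max_sets guard threshold: a warning is raised before enumeration if
#'   the subset-count upper bound `sum(choose(n, 1..K))` exceeds this cap
#'   (default `2e6`).
#' @return A data frame with columns `lobe`, `size`, and `parcels`
#'   (comma-joined, lexicographically sorted member IDs), ordered by size
#'   then parcel tuple. The split member sets are attached as the
#'   `"members"` attribute.
#' @examples
#' atlas <- generate_atlas(grid_atlas_spec(rows = 1, cols = 3))
#' enumerate_resections(atlas, "lobeA/left", max_size = 3)
#' @export
enumerate_resections <- function(atlas, lobe, max_size = 10L, max_sets = 2e6) {
  stopifnot(inherits(atlas, "atlas_topology"), max_size >= 1L)
  members <- lobe_parcels(atlas, lobe)  # errors on unknown lobe
  n <- length(members)
  k_max <- min(max_size, n)
  bound <- sum(choose(n, seq_len(k_max)))
  if (bound > max_sets) {
    warning("projected enumeration size for lobe '", lobe, "' may reach ",
            format(bound, big.mark = ","), " sets (cap ",
            format(max_sets, big.mark = ","), ")")
  }

  adj <- atlas$adjacency
  keep <- adj[, 1L] %in% members & adj[, 2L] %in% members
  ia <- match(adj[keep, 1L], members)
  ib <- match(adj[keep, 2L], members)
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- integer()
  for (e in seq_along(ia)) {
    nbr[[ia[e]]] <- c(nbr[[ia[e]]], ib[e])
    nbr[[ib[e]]] <- c(nbr[[ib[e]]], ia[e])
  }
  nbr <- lapply(nbr, function(v) sort(unique(v)))

  acc <- new.env(parent = emptyenv())
  acc$sets <- vector("list", 1024L)
  acc$n <- 0L
  emit <- function(s) {
    if (acc$n == length(acc$sets)) acc$sets <- c(acc$sets, vector("list", acc$n))
    acc$n <- acc$n + 1L
    acc$sets[[acc$n]] <- s
  }
  # ESU extension: `ext` are candidate additions, `closed` the vertices whose
  # neighbourhoods have already been offered (S's neighbourhood), both > anchor.
  extend <- function(s, ext, closed, anchor) {
    emit(s)
    if (length(s) == k_max) return(invisible())
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      fresh <- nbr[[w]]
      fresh <- fresh[fresh > anchor & !(fresh %in% closed)]
      extend(c(s, w), c(ext, fresh), c(closed, fresh), anchor)
    }
    invisible()
  }
  for (v in seq_len(n)) {
    ext0 <- nbr[[v]][nbr[[v]] > v]
    extend(v, ext0, c(v, ext0), v)
  }

  sets <- acc$sets[seq_len(acc$n)]
  sets <- lapply(sets, sort)
  size <- lengths(sets)
  ids <- lapply(sets, function(s) members[s])
  key <- vapply(ids, paste, "", collapse = ",")
  o <- order(size, key, method = "radix")
  out <- data.frame(lobe = rep(lobe, length(sets)), size = size[o],
                    parcels = key[o], stringsAsFactors = FALSE)
  attr(out, "members") <- ids[o]
  out
}

# Split the comma-joined parcel column back into member vectors, reusing the
# cached attribute when present.
resection_members <- function(sets) {
  m <- attr(sets, "members")
  if (!is.null(m) && length(m) == nrow(sets)) return(m)
  strsplit(sets$parcels, ",", fixed = TRUE)
}
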