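#' Atlas topology: parcels, lobes, and physical adjacency
#'
#' An `atlas_topology` holds the parcel set on which virtual resections are
#' defined: parcel identifiers, their hemisphere (`"left"`, `"right"` or
#' `"midline"`), a lobe label for every resectable (cortical) parcel, a
#' resectability flag (subcortical, cerebellar and brainstem nodes are present
#' in connectomes but are never resected), and the physical-adjacency graph
#' `G = (V, E)` whose edges join parcels sharing a physical border. Adjacency
#' is stored unweighted: only connectivity and hop counts in `G` are ever used.
#'
#' @section Invariants (checked by the constructor):
#' \itemize{
#'   \item parcel IDs are unique;
#'   \item adjacency is a set of unordered pairs with no self-loops;
#'   \item every resectable parcel carries exactly one lobe label, and
#'     non-resectable parcels carry none;
#'   \item each lobe's induced adjacency subgraph is connected (the resection
#'     enumerator assumes it).
#' }
#'
#' @param parcels character vector of parcel IDs.
#' @param hemisphere named character vector (parcel -> hemisphere).
#' @param lobe named character vector (parcel -> lobe label, `NA` for
#'   non-resectable parcels).
#' @param resectable named logical vector (parcel -> resectable flag).
#' @param adjacency two-column character matrix of adjacent parcel pairs;
#'   duplicates and orientation are normalized.
#' @param version schema version string.
#' @return A validated `atlas_topology` object.
#' @seealso [load_atlas()], [write_atlas()], [generate_atlas()]
#' @export
atlas_topology <- function(parcels, hemisphere, lobe, resectable, adjacency,
                           version = "1") {
  parcels <- as.character(parcels)
  if (anyDuplicated(parcels)) {
    stop("invalid atlas: duplicate parcel IDs: ",
         paste(unique(parcels[duplicated(parcels)]), collapse = ", "))
  }
  hemisphere <- .named_over(hemisphere, parcels, "hemisphere")
  lobe <- .named_over(lobe, parcels, "lobe")
  resectable <- .named_over(resectable, parcels, "resectable")
  bad_hemi <- setdiff(unique(hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi)) {
    stop("invalid atlas: unknown hemisphere value(s): ",
         paste(bad_hemi, collapse = ", "))
  }
  adjacency <- .normalize_adjacency(adjacency, parcels)

  miss <- parcels[resectable & is.na(lobe)]
  if (length(miss)) {
    stop("invalid atlas: resectable parcel(s) without a lobe label: ",
         paste(miss, collapse = ", "))
  }
  extra <- parcels[!resectable & !is.na(lobe)]
  if (length(extra)) {
    stop("invalid atlas: non-resectable parcel(s) carry a lobe label: ",
         paste(extra, collapse = ", "))
  }

  x <- structure(
    list(parcels = parcels, hemisphere = hemisphere, lobe = lobe,
         resectable = resectable, adjacency = adjacency,
         version = as.character(version)),
    class = "atlas_topology"
  )

  g <- atlas_graph(x)
  for (lb in lobes(x)) {
    members <- lobe_parcels(x, lb)
    sub <- igraph::induced_subgraph(g, members)
    if (length(members) > 1L && !igraph::is_connected(sub)) {
      stop("invalid atlas: lobe '", lb, "' not connected in adjacency")
    }
  }
  x
}

.named_over <- function(v, parcels, what) {
  if (is.null(names(v))) {
    if (length(v) != length(parcels)) {
      stop("invalid atlas: '", what, "' must be named by parcel or match length")
    }
    names(v) <- parcels
  }
  missing <- setdiff(parcels, names(v))
  if (length(missing)) {
    stop("invalid atlas: '", what, "' missing for parcel(s): ",
         paste(missing, collapse = ", "))
  }
  v[parcels]
}

.normalize_adjacency <- function(adjacency, parcels) {
  if (is.null(adjacency) || (is.matrix(adjacency) && nrow(adjacency) == 0L) ||
      length(adjacency) == 0L) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  }
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) stop("invalid atlas: adjacency must have 2 columns")
  mode(adjacency) <- "character"
  unknown <- setdiff(unique(c(adjacency)), parcels)
  if (length(unknown)) {
    stop("invalid atlas: adjacency references unknown parcel(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(adjacency[, 1L] == adjacency[, 2L])) {
    stop("invalid atlas: adjacency contains self-loop(s)")
  }
  a <- pmin(adjacency[, 1L], adjacency[, 2L])
  b <- pmax(adjacency[, 1L], adjacency[, 2L])
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  o <- order(a[keep], b[keep], method = "radix")
  out <- cbind(a = a[keep][o], b = b[keep][o])
  rownames(out) <- NULL
  out
}

#' Read an atlas topology from its JSON file
#'
#' The file format is a JSON object with keys `version`, `parcels` (an array
#' of objects with fields `id`, `hemisphere`, `lobe`, `resectable`; `lobe` is
#' `null` for non-resectable parcels) and `adjacency` (an array of two-element
#' ID arrays). Edges listed in both orientations collapse to a single
#' unordered pair. All `atlas_topology` invariants are checked; violations
#' abort with the invariant named in the message.
#'
#' @param path path to the topology JSON file.
#' @return An `atlas_topology`.
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$parcels)) stop("topology file missing 'parcels': ", path)
  p <- doc$parcels
  lobe <- if (is.null(p$lobe)) rep(NA_character_, nrow(p)) else as.character(p$lobe)
  lobe[lobe %in% c("", "NA")] <- NA_character_
  adj <- doc$adjacency
  if (is.list(adj) && !is.matrix(adj)) adj <- do.call(rbind, adj)
  atlas_topology(
    parcels = p$id,
    hemisphere = stats::setNames(as.character(p$hemisphere), p$id),
    lobe = stats::setNames(lobe, p$id),
    resectable = stats::setNames(as.logical(p$resectable), p$id),
    adjacency = adj,
    version = if (is.null(doc$version)) "1" else doc$version
  )
}

#' Write an atlas topology to JSON
#'
#' Inverse of [load_atlas()]: `load_atlas(write_atlas(x, path))` reproduces
#' `x` exactly (the stored form is already canonical).
#'
#' @param atlas an `atlas_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_topology"))
  doc <- list(
    version = atlas$version,
    parcels = data.frame(
      id = atlas$parcels,
      hemisphere = unname(atlas$hemisphere),
      lobe = unname(atlas$lobe),
      resectable = unname(atlas$resectable),
      stringsAsFactors = FALSE
    ),
    adjacency = unname(as.data.frame(atlas$adjacency))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' @export
print.atlas_topology <- function(x, ...) {
  cat("<atlas_topology> ", length(x$parcels), " parcels (",
      sum(x$resectable), " resectable), ", nrow(x$adjacency),
      " adjacency pairs, ", length(lobes(x)), " lobes\n", sep = "")
  invisible(x)
}

# igraph view of the physical-adjacency graph; isolated parcels kept.
atlas_graph <- function(atlas) {
  igraph::graph_from_data_frame(
    as.data.frame(atlas$adjacency, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = atlas$parcels, stringsAsFactors = FALSE)
  )
}

#' Lobe labels of an atlas
#'
#' @param atlas an `atlas_topology`.
#' @return Sorted character vector of the configured lobe labels.
#' @export
lobes <- function(atlas) {
  stopifnot(inherits(atlas, "atlas_topology"))
  sort(unique(atlas$lobe[!is.na(atlas$lobe)]), method = "radix")
}

#' Parcels of a lobe, in canonical order
#'
#' @param atlas an `atlas_topology`.
#' @param lobe a lobe label present in the atlas.
#' @return The lobe's resectable parcel IDs, sorted lexicographically.
#' @export
lobe_parcels <- function(atlas, lobe) {
  stopifnot(inherits(atlas, "atlas_topology"))
  if (!lobe %in% lobes(atlas)) stop("unknown lobe label: ", lobe)
  ids <- atlas$parcels[!is.na(atlas$lobe) & atlas$lobe == lobe]
  sort(ids, method = "radix")
}

#' Hop distance between two parcels within a lobe
#'
#' Minimum number of adjacency edges between `a` and `b` in the
#' lobe-restricted adjacency graph (breadth-first shortest path). Used to
#' derive the expected minimal arrival size of an epicenter candidate: a
#' parcel at hop distance `h` from a subject's worst single deletion cannot,
#' by connectedness, co-occur with it in any resection smaller than `h + 1`
#' parcels.
#'
#' @param atlas an `atlas_topology`.
#' @param lobe lobe label containing both parcels.
#' @param a,b parcel IDs within `lobe`.
#' @return Integer hop count (`0` iff `a == b`); `Inf` if unreachable within
#'   the lobe.
#' @export
hop_distance <- function(atlas, lobe, a, b) {
  members <- lobe_parcels(atlas, lobe)
  if (!a %in% members) stop("parcel '", a, "' not in lobe '", lobe, "'")
  if (!b %in% members) stop("parcel '", b, "' not in lobe '", lobe, "'")
  if (a == b) return(0)
  sub <- igraph::induced_subgraph(atlas_graph(atlas), members)
  d <- igraph::distances(sub, v = a, to = b, weights = NA)[1L, 1L]
  as.numeric(d)
}

# Parcels adjacent to p in the full atlas adjacency graph.
adjacent_parcels <- function(atlas, p) {
  stopifnot(inherits(atlas, "atlas_topology"))
  if (!p %in% atlas$parcels) stop("unknown parcel: ", p)
  adj <- atlas$adjacency
  hit <- adj[, 1L] == p | adj[, 2L] == p
  out <- setdiff(unique(c(adj[hit, , drop = FALSE])), p)
  sort(out, method = "radix")
}

# Hemisphere of a lobe label (unique over its parcels).
lobe_hemisphere <- function(atlas, lobe) {
  h <- unique(atlas$hemisphere[lobe_parcels(atlas, lobe)])
  if (length(h) == 1L) h else "mixed"
}
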