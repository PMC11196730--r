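#' Specification for a small synthetic atlas
#'
#' Describes a mirrored two-hemisphere atlas built from grid-shaped lobes:
#' each lobe is a `rows x cols` lattice of parcels (optionally truncated to
#' `count` parcels along a boustrophedon path, which keeps the lobe
#' connected). Lobes within a hemisphere are chained by a single edge between
#' the lattice-center parcels of consecutive lobes; the hemispheres are
#' bridged through the first lobe's center parcels. Attaching all external
#' edges at lobe centers keeps opposite boundary parcels exchangeable, so no
#' corner of the toy geometry becomes an artificial global hub. Optional
#' subcortical nodes are non-resectable and attach as a midline chain to
#' both hemispheres.
#'
#' @param n_lobes number of lobes per hemisphere.
#' @param rows,cols lattice dimensions of each lobe.
#' @param count parcels per lobe (default `rows * cols`; smaller values
#'   truncate the lattice along a connectivity-preserving snake path).
#' @param n_subcortical number of non-resectable midline nodes.
#' @param lobe_names optional base names for the lobes (defaults to
#'   `"lobeA"`, `"lobeB"`, ...).
#' @return A `grid_atlas_spec` list for [generate_atlas()].
#' @export
grid_atlas_spec <- function(n_lobes = 1L, rows = 3L, cols = 3L,
                            count = rows * cols, n_subcortical = 0L,
                            lobe_names = NULL) {
  stopifnot(n_lobes >= 1L, rows >= 1L, cols >= 1L,
            count >= 1L, count <= rows * cols, n_subcortical >= 0L)
  if (is.null(lobe_names)) lobe_names <- paste0("lobe", LETTERS[seq_len(n_lobes)])
  stopifnot(length(lobe_names) == n_lobes)
  structure(list(n_lobes = as.integer(n_lobes), rows = as.integer(rows),
                 cols = as.integer(cols), count = as.integer(count),
                 n_subcortical = as.integer(n_subcortical),
                 lobe_names = lobe_names),
            class = "grid_atlas_spec")
}

# Region layout of the full-scale synthetic atlas: 8 cortical regions per
# hemisphere, 180 parcels per hemisphere, plus 19 subcortical nodes = 379.
# The parcel IDs, lobe membership and lattice adjacency are synthetic
# stand-ins: the real multimodal-parcellation border graph is not published
# as data, only its node counts and region list are reproduced here.
.full_scale_layout <- function() {
  data.frame(
    lobe = c("frontal", "sensorimotor", "medial-frontal", "operculum",
             "temporal", "lateral-parietal", "medial-parietal", "occipital"),
    code = c("FRO", "SMC", "MFR", "OPR", "TMP", "LPA", "MPA", "OCC"),
    rows = c(5L, 3L, 4L, 3L, 5L, 4L, 3L, 4L),
    cols = c(6L, 5L, 5L, 6L, 7L, 6L, 5L, 7L),
    count = c(30L, 13L, 20L, 18L, 34L, 22L, 15L, 28L),
    stringsAsFactors = FALSE
  )
}

# Snake (boustrophedon) ordering of lattice cells; consecutive cells are
# lattice-adjacent, so any prefix induces a connected subgraph.
.snake_cells <- function(rows, cols) {
  cells <- list()
  for (r in seq_len(rows)) {
    cs <- if (r %% 2L == 1L) seq_len(cols) else rev(seq_len(cols))
    for (cc in cs) cells[[length(cells) + 1L]] <- c(r, cc)
  }
  cells
}

.grid_lobe <- function(ids, rows, cols) {
  count <- length(ids)
  cells <- .snake_cells(rows, cols)[seq_len(count)]
  key <- vapply(cells, function(z) paste(z, collapse = ","), "")
  at <- stats::setNames(ids, key)
  edges <- NULL
  for (i in seq_len(count)) {
    rc <- cells[[i]]
    for (dz in list(c(0L, 1L), c(1L, 0L))) {
      nb <- paste(rc + dz, collapse = ",")
      if (nb %in% names(at)) edges <- rbind(edges, c(at[[i]], at[[nb]]))
    }
  }
  edges
}

# Attachment site of a lobe: the parcel closest to the lattice center.
# External edges (inter-lobe chain, hemisphere bridge, subcortical links)
# hang off this parcel so that no boundary parcel becomes a global hub of
# the toy geometry and opposite boundary sites stay exchangeable.
.lobe_hub <- function(ids, rows, cols) {
  count <- length(ids)
  cells <- .snake_cells(rows, cols)[seq_len(count)]
  center <- c((min(vapply(cells, `[`, 0L, 1L)) +
                 max(vapply(cells, `[`, 0L, 1L))) / 2,
              (min(vapply(cells, `[`, 0L, 2L)) +
                 max(vapply(cells, `[`, 0L, 2L))) / 2)
  dd <- vapply(cells, function(rc) sum(abs(rc - center)), numeric(1L))
  ids[which.min(dd)]
}

#' Generate a synthetic atlas topology
#'
#' Builds either a small mirrored grid atlas from a [grid_atlas_spec()], or
#' the `"full-scale"` synthetic atlas: 8 named cortical regions per
#' hemisphere totalling 180 parcels each, plus 19 non-resectable subcortical
#' nodes (8 subcortical per hemisphere, one cerebellar per hemisphere, one
#' brainstem), 379 nodes in all. The full-scale parcel IDs and border graph
#' are synthetic; only the node counts and region names follow the standard
#' multimodal parcellation. Deterministic for a fixed spec; both hemispheres
#' are mirror images.
#'
#' @param spec a `grid_atlas_spec`, or the string `"full-scale"`.
#' @return An `atlas_topology`.
#' @export
generate_atlas <- function(spec = grid_atlas_spec()) {
  if (identical(spec, "full-scale")) {
    lay <- .full_scale_layout()
    spec <- grid_atlas_spec(n_lobes = nrow(lay), rows = max(lay$rows),
                            cols = max(lay$cols), n_subcortical = 19L,
                            lobe_names = lay$lobe)
    spec$layout <- lay
  }
  stopifnot(inherits(spec, "grid_atlas_spec"))
  lay <- spec$layout
  if (is.null(lay)) {
    lay <- data.frame(lobe = spec$lobe_names,
                      code = toupper(substr(spec$lobe_names,
                                            nchar(spec$lobe_names),
                                            nchar(spec$lobe_names))),
                      rows = spec$rows, cols = spec$cols, count = spec$count,
                      stringsAsFactors = FALSE)
  }

  parcels <- character(); hemi <- character(); lobe <- character()
  resectable <- logical(); edges <- NULL
  hub_of <- list()
  for (h in c("L", "R")) {
    hname <- if (h == "L") "left" else "right"
    prev_hub <- NULL
    for (i in seq_len(nrow(lay))) {
      ids <- sprintf("%s_%s%02d", h, lay$code[i], seq_len(lay$count[i]))
      parcels <- c(parcels, ids)
      hemi <- c(hemi, rep(hname, length(ids)))
      lobe <- c(lobe, rep(paste0(lay$lobe[i], "/", hname), length(ids)))
      resectable <- c(resectable, rep(TRUE, length(ids)))
      edges <- rbind(edges, .grid_lobe(ids, lay$rows[i], lay$cols[i]))
      hub <- .lobe_hub(ids, lay$rows[i], lay$cols[i])
      if (!is.null(prev_hub)) edges <- rbind(edges, c(prev_hub, hub))
      prev_hub <- hub
      if (i == 1L) hub_of[[h]] <- hub
    }
  }
  # inter-hemisphere bridge through the first lobe's hub parcels
  first_ids <- c(hub_of$L, hub_of$R)
  edges <- rbind(edges, first_ids)

  if (spec$n_subcortical > 0L) {
    nsc <- spec$n_subcortical
    sc_ids <- sprintf("SC%02d", seq_len(nsc))
    # alternate left/right, last node midline when the count is odd
    sc_hemi <- rep(c("left", "right"), length.out = nsc)
    if (nsc %% 2L == 1L) sc_hemi[nsc] <- "midline"
    parcels <- c(parcels, sc_ids)
    hemi <- c(hemi, sc_hemi)
    lobe <- c(lobe, rep(NA_character_, nsc))
    resectable <- c(resectable, rep(FALSE, nsc))
    if (nsc > 1L) {
      edges <- rbind(edges, cbind(sc_ids[-nsc], sc_ids[-1L]))
    }
    edges <- rbind(edges, c(sc_ids[1L], first_ids[1L]),
                   c(sc_ids[min(2L, nsc)], first_ids[2L]))
  }

  atlas_topology(parcels = parcels,
                 hemisphere = stats::setNames(hemi, parcels),
                 lobe = stats::setNames(lobe, parcels),
                 resectable = stats::setNames(resectable, parcels),
                 adjacency = edges)
}

#' Configuration of a synthetic connectome cohort
#'
#' Defines the generative model for a cohort of subject connectomes with
#' planted ground truth. Expected streamline weight for a parcel pair
#' `(i, j)` is `W * pi_ij` with `pi_ij` proportional to
#' `exp(-decay * hop_ij) * b_i * b_j`, where `hop_ij` is the hop distance in
#' the atlas adjacency graph (unreachable pairs are capped at one hop beyond
#' the largest finite distance so every pair keeps a small positive
#' expectation), and `b` boosts each subject's planted epicenter parcel by
#' `hub_boost` and its adjacency neighbours by `sqrt(hub_boost)`. Realized
#' weights are Poisson draws of the expectation scaled by a subject-level
#' log-normal factor `exp(N(0, noise_sd^2))`.
#'
#' The defaults encode the reference simulation conditions used throughout
#' the package's validation: 20 subjects, ~300,000 streamlines per brain,
#' distance-decay 0.5, epicenter boost 2, subject noise 0.1.
#'
#' @param atlas an `atlas_topology` (the cohort's shared parcellation).
#' @param n_subjects cohort size.
#' @param total_streamlines expected per-subject streamline total.
#' @param decay distance-decay rate `lambda >= 0`.
#' @param hub_boost multiplicative epicenter boost `beta >= 1`.
#' @param noise_sd subject-level log-normal sigma `>= 0`.
#' @param connectotype_mix named list, one entry per lobe label, each a
#'   data frame with columns `parcel` and `prop` (mixing proportions summing
#'   to 1). Default: a single epicenter per lobe at a mid-boundary site (the
#'   second parcel of the sorted lobe list) — neither the lobe's geometric
#'   center, whose natural weight dominance would make recovery trivial, nor
#'   an extremal corner, whose baseline weight no plausible boost can
#'   overcome.
#' @param seed integer RNG seed; per-subject substreams are derived from
#'   `(seed, subject index)` so cohorts are stable under `n_subjects` changes.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(atlas, n_subjects = 20L, total_streamlines = 3e5,
                          decay = 0.5, hub_boost = 2, noise_sd = 0.1,
                          connectotype_mix = NULL, seed = 1L) {
  stopifnot(inherits(atlas, "atlas_topology"), n_subjects >= 1L,
            total_streamlines > 0, decay >= 0, hub_boost >= 1, noise_sd >= 0)
  if (is.null(connectotype_mix)) {
    connectotype_mix <- lapply(lobes(atlas), function(lb) {
      mem <- lobe_parcels(atlas, lb)
      data.frame(parcel = mem[min(2L, length(mem))], prop = 1,
                 stringsAsFactors = FALSE)
    })
    names(connectotype_mix) <- lobes(atlas)
  }
  for (lb in names(connectotype_mix)) {
    mix <- connectotype_mix[[lb]]
    if (!lb %in% lobes(atlas)) stop("mix references unknown lobe: ", lb)
    if (!all(mix$parcel %in% lobe_parcels(atlas, lb))) {
      stop("mix parcel outside lobe '", lb, "'")
    }
    if (abs(sum(mix$prop) - 1) > 1e-8) {
      stop("mix proportions for lobe '", lb, "' must sum to 1")
    }
  }
  if (!setequal(names(connectotype_mix), lobes(atlas))) {
    stop("connectotype_mix must cover every lobe exactly once")
  }
  structure(list(atlas = atlas, n_subjects = as.integer(n_subjects),
                 total_streamlines = total_streamlines, decay = decay,
                 hub_boost = hub_boost, noise_sd = noise_sd,
                 connectotype_mix = connectotype_mix,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-subject RNG substream seed, kept below 2^31.
.subject_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 20771 * 100003 + i * 7919) %% 2147483629)
}

#' Generate a synthetic connectome cohort with planted ground truth
#'
#' Draws one connectome per subject under the model described in
#' [cohort_config()] and records which epicenter was planted in each lobe of
#' each subject. Fully reproducible from `config$seed`.
#'
#' @param config a `cohort_config`.
#' @return A list with elements `connectomes` (list of `connectome`) and
#'   `manifest` (data frame `subject_id`, `lobe`, `epicenter`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  atlas <- config$atlas
  n_p <- length(atlas$parcels)
  g <- atlas_graph(atlas)
  hops <- igraph::distances(g, weights = NA)
  finite_max <- max(hops[is.finite(hops)])
  hops[!is.finite(hops)] <- finite_max + 1
  decay_mat <- exp(-config$decay * hops)
  diag(decay_mat) <- 0
  nbrs <- lapply(stats::setNames(atlas$parcels, atlas$parcels),
                 function(p) adjacent_parcels(atlas, p))
  lobe_labels <- sort(names(config$connectotype_mix), method = "radix")
  upper <- upper.tri(decay_mat)

  connectomes <- vector("list", config$n_subjects)
  manifest <- NULL
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("sub%03d", s)
    set.seed(.subject_seed(config$seed, s))
    b <- stats::setNames(rep(1, n_p), atlas$parcels)
    for (lb in lobe_labels) {
      mix <- config$connectotype_mix[[lb]]
      k <- if (nrow(mix) == 1L) 1L else {
        sample.int(nrow(mix), 1L, prob = mix$prop)
      }
      e <- mix$parcel[k]
      b[e] <- max(b[e], config$hub_boost)
      nb <- nbrs[[e]]
      b[nb] <- pmax(b[nb], sqrt(config$hub_boost))
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, lobe = lb, epicenter = e,
                                   stringsAsFactors = FALSE))
    }
    pi_mat <- decay_mat * outer(b, b)
    pi_mat <- pi_mat / sum(pi_mat[upper])
    f <- exp(stats::rnorm(1L, 0, config$noise_sd))
    lam <- config$total_streamlines * pi_mat[upper] * f
    w <- matrix(0, n_p, n_p, dimnames = list(atlas$parcels, atlas$parcels))
    w[upper] <- stats::rpois(length(lam), lam)
    w <- w + t(w)
    connectomes[[s]] <- connectome(sid, atlas$parcels, w)
  }
  list(connectomes = connectomes, manifest = manifest)
}

#' Write a synthetic cohort to disk
#'
#' Writes each subject's matrix as CSV, the atlas topology as JSON, and the
#' ground-truth manifest as JSON into `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param atlas the `atlas_topology` the cohort was generated on.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(atlas, file.path(dir, "topology.json"))
  for (cn in cohort$connectomes) {
    write_connectome(cn, file.path(dir, paste0(cn$subject_id, ".csv")))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
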