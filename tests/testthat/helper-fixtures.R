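# Small programmatic fixtures shared across test files.

# Atlas with one triangle lobe {a, b, c}.
tri_atlas <- function() {
  atlas_topology(
    parcels = c("a", "b", "c"),
    hemisphere = c(a = "left", b = "left", c = "left"),
    lobe = c(a = "tri/left", b = "tri/left", c = "tri/left"),
    resectable = c(a = TRUE, b = TRUE, c = TRUE),
    adjacency = rbind(c("a", "b"), c("b", "c"), c("a", "c"))
  )
}

# Atlas with one chain lobe p1 - p2 - ... - pk.
chain_atlas <- function(k, lobe = "chain/left") {
  ids <- sprintf("p%02d", seq_len(k))
  atlas_topology(
    parcels = ids,
    hemisphere = stats::setNames(rep("left", k), ids),
    lobe = stats::setNames(rep(lobe, k), ids),
    resectable = stats::setNames(rep(TRUE, k), ids),
    adjacency = if (k > 1) cbind(ids[-k], ids[-1]) else NULL
  )
}

# Connectome from an explicit symmetric matrix.
make_connectome <- function(W, subject = "s1") {
  connectome(subject, rownames(W), W)
}

# Random symmetric integer-weight connectome on n nodes.
random_connectome <- function(n, p = 0.4, wmax = 5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  up <- upper.tri(W)
  m <- sum(up)
  W[up] <- ifelse(stats::runif(m) < p, sample.int(wmax, m, replace = TRUE), 0)
  W <- W + t(W)
  connectome(paste0("rand", seed), ids, W)
}

# Resection sweep with prescribed records (for pattern-logic tests).
fake_sweep <- function(sizes, parcels, ge, subject = "s1",
                       lobe = "lobeA/left", mode = "unweighted") {
  o <- order(-ge, sizes, parcels, method = "radix")
  structure(list(subject_id = subject, lobe = lobe, mode = mode,
                 baseline_ge = max(ge) + 1,
                 records = data.frame(size = sizes[o], parcels = parcels[o],
                                      ge = ge[o], stringsAsFactors = FALSE)),
            class = "resection_sweep")
}

# worst_by_size object with a prescribed worst set per size.
fake_wbs <- function(worst_parcels_by_size, subject = "s1",
                     lobe = "lobeA/left") {
  sizes <- seq_along(worst_parcels_by_size)
  out <- data.frame(
    size = sizes,
    parcels = vapply(worst_parcels_by_size,
                     function(m) paste(sort(m), collapse = ","), ""),
    ge = rev(seq_along(sizes)) * 1.0,
    contains = c(NA, vapply(sizes[-1], function(i) {
      all(worst_parcels_by_size[[i - 1]] %in% worst_parcels_by_size[[i]])
    }, logical(1))),
    stringsAsFactors = FALSE
  )
  attr(out, "subject_id") <- subject
  attr(out, "lobe") <- lobe
  class(out) <- c("worst_by_size", "data.frame")
  out
}

# Shared reference-simulation helpers (single- and two-epicenter cohorts on
# the 3x3 grid test atlas).
recovery_atlas <- function() generate_atlas(grid_atlas_spec())

recovery_sets <- function(atlas, lobe = "lobeA/left", K = 6L) {
  enumerate_resections(atlas, lobe, max_size = K)
}

# Default planted epicenter site of a lobe (matches cohort_config()).
planted_site <- function(atlas, lobe) {
  mem <- lobe_parcels(atlas, lobe)
  mem[min(2L, length(mem))]
}

# 60/40 mix over two exchangeable mid-boundary sites of `lobe` (the default
# site and its geometric opposite); other lobes keep their default.
two_epicenter_mix <- function(atlas, lobe = "lobeA/left") {
  mix <- lapply(lobes(atlas), function(lb) {
    data.frame(parcel = planted_site(atlas, lb), prop = 1,
               stringsAsFactors = FALSE)
  })
  names(mix) <- lobes(atlas)
  mem <- lobe_parcels(atlas, lobe)
  mix[[lobe]] <- data.frame(parcel = c(mem[2L], mem[length(mem) - 1L]),
                            prop = c(0.6, 0.4), stringsAsFactors = FALSE)
  mix
}
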