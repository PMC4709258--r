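# Triangular-lattice merging Monte Carlo.
#
# Sites live on a triangular lattice stored as an nrow x ncol matrix in
# axial (sheared) coordinates: site (r, c) is adjacent to (r, c +/- 1),
# (r +/- 1, c), (r - 1, c + 1) and (r + 1, c - 1) -- six neighbors, the
# uniform shear embedding of the triangular lattice (site (r, c) sits at
# x = c + r/2, y = r * sqrt(3)/2; neighbors are the sites at unit
# distance). Periodic boundaries wrap both indices.

# Undirected neighbor pairs as a 2-column matrix of site indices
# (column-major over the dims matrix). Three directed shifts cover all six
# neighbor relations once. Results are memoised per (dims, boundary): the
# merging Monte Carlo reuses one lattice across hundreds of replicates.
.pair_cache <- new.env(parent = emptyenv())

tri_neighbor_pairs <- function(dims, boundary = c("periodic", "open")) {
  boundary <- match.arg(boundary)
  key <- paste(dims[1], dims[2], boundary, sep = "x")
  cached <- .pair_cache[[key]]
  if (!is.null(cached)) return(cached)
  pairs <- compute_tri_pairs(dims, boundary)
  if (length(.pair_cache) > 30) rm(list = ls(.pair_cache), envir = .pair_cache)
  .pair_cache[[key]] <- pairs
  pairs
}

compute_tri_pairs <- function(dims, boundary) {
  nr <- dims[1]
  nc <- dims[2]
  idx <- matrix(seq_len(nr * nc), nr, nc)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, -1L))
  pairs <- lapply(shifts, function(s) {
    if (boundary == "periodic") {
      rs <- ((seq_len(nr) - 1L + s[1]) %% nr) + 1L
      cs <- ((seq_len(nc) - 1L + s[2]) %% nc) + 1L
      cbind(as.vector(idx), as.vector(idx[rs, cs, drop = FALSE]))
    } else {
      r0 <- seq_len(nr)
      c0 <- seq_len(nc)
      rs <- r0 + s[1]
      cs <- c0 + s[2]
      keep_r <- rs >= 1L & rs <= nr
      keep_c <- cs >= 1L & cs <= nc
      from <- idx[r0[keep_r], c0[keep_c], drop = FALSE]
      to <- idx[rs[keep_r], cs[keep_c], drop = FALSE]
      cbind(as.vector(from), as.vector(to))
    }
  })
  pairs <- do.call(rbind, pairs)
  if (boundary == "periodic" && min(nr, nc) < 3) {
    # wrap on a 1- or 2-wide lattice can duplicate or self-pair
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairs <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                          pmax(pairs[, 1], pairs[, 2])))
  }
  pairs
}

#' Randomly color a triangular lattice
#'
#' Labels every site independently: site takes color `i` with probability
#' `color_probs[i]` and stays unlabeled otherwise. This emulates high-dose
#' mosaic induction, where neighboring progenitors are frequently and
#' independently co-labeled with the same reporter color.
#'
#' @param dims Lattice dimensions `c(rows, cols)`.
#' @param color_probs Numeric vector of per-color labeling probabilities
#'   (non-negative, summing to at most 1). Names, if any, are kept.
#' @param boundary `"periodic"` (default) or `"open"`.
#' @param seed Optional integer seed.
#' @return An object of class `lattice_coloring`: a list with the integer
#'   color matrix (`0` = unlabeled), `dims`, `boundary` and `color_probs`.
#' @export
label_lattice <- function(dims, color_probs, boundary = c("periodic", "open"),
                          seed = NULL) {
  boundary <- match.arg(boundary)
  if (length(dims) != 2 || any(dims < 1)) abort("`dims` must be c(rows, cols)")
  if (any(color_probs < 0) || sum(color_probs) > 1 + 1e-12) {
    abort("color probabilities must be non-negative and sum to at most 1")
  }
  n <- prod(dims)
  color <- with_seed_or_stream(seed, {
    u <- runif(n)
    breaks <- c(0, cumsum(color_probs))
    matrix(findInterval(u, breaks, left.open = TRUE) %%
             (length(color_probs) + 1L), dims[1], dims[2])
  })
  # findInterval maps u past the last break to n_colors + 1 -> unlabeled (0)
  structure(
    list(color = color, dims = as.integer(dims), boundary = boundary,
         color_probs = color_probs),
    class = "lattice_coloring"
  )
}

#' @export
print.lattice_coloring <- function(x, ...) {
  cat(sprintf(
    "<lattice_coloring> %d x %d (%s), %d color(s), labeled fraction %.3f\n",
    x$dims[1], x$dims[2], x$boundary, length(x$color_probs),
    mean(x$color != 0)
  ))
  invisible(x)
}

#' Same-color connected clusters of a lattice coloring
#'
#' Partitions the labeled sites into connected components under the
#' 6-neighbor triangular adjacency, per color: two labeled sites belong to
#' the same cluster exactly when they share a color and are joined by a
#' path of same-color neighbors. Independently induced neighbors of one
#' color are indistinguishable from a single clone -- this merging is what
#' the Monte Carlo quantifies.
#'
#' @param coloring A `lattice_coloring` from [label_lattice()].
#' @return An object of class `cluster_set`: list with `clusters` (tibble:
#'   `cluster`, `color`, `size`) and `membership` (integer matrix mapping
#'   each site to its cluster id, `NA` for unlabeled sites).
#' @export
same_color_clusters <- function(coloring) {
  stopifnot(inherits(coloring, "lattice_coloring"))
  col <- as.vector(coloring$color)
  pairs <- tri_neighbor_pairs(coloring$dims, coloring$boundary)
  same <- col[pairs[, 1]] != 0L & col[pairs[, 1]] == col[pairs[, 2]]
  g <- igraph::make_empty_graph(n = length(col), directed = FALSE)
  if (any(same)) {
    g <- igraph::add_edges(g, t(pairs[same, , drop = FALSE]))
  }
  comp <- igraph::components(g)
  labeled <- col != 0L
  membership <- comp$membership
  membership[!labeled] <- NA_integer_
  ids <- sort(unique(membership[labeled]))
  remap <- match(membership, ids)
  first_member <- match(seq_along(ids), remap[labeled])
  clusters <- tibble(
    cluster = seq_along(ids),
    color = col[labeled][first_member],
    size = as.integer(tabulate(remap[labeled], nbins = length(ids)))
  )
  structure(
    list(
      clusters = clusters,
      membership = matrix(remap, coloring$dims[1], coloring$dims[2])
    ),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d cluster(s) over %d labeled site(s); mean size %.3f\n",
    nrow(x$clusters), sum(x$clusters$size),
    if (nrow(x$clusters) > 0) mean(x$clusters$size) else NA_real_
  ))
  invisible(x)
}

#' Merging factor of random co-labeling
#'
#' Monte Carlo estimate of how many independently labeled progenitors fuse
#' into one apparent same-color cluster. The merging factor is the
#' cell-weighted mean cluster size: the expected number of progenitors in
#' the compound containing a randomly chosen labeled progenitor,
#' `sum(size^2) / sum(size)` over same-color clusters. The plain per-cluster
#' mean size (`labeled sites / clusters`), which converts cluster counts to
#' progenitor counts, is reported alongside.
#'
#' @param color_probs Per-color labeling probabilities (see
#'   [label_lattice()]).
#' @param dims Lattice dimensions (default `c(256, 256)`, large enough for
#'   asymptotic estimates).
#' @param n_replicates Number of independent lattice replicates (>= 2);
#'   the confidence interval is a normal approximation over replicate
#'   means.
#' @param boundary Boundary condition.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `level`,
#'   `method`, `mean_cluster_size` (per-cluster mean), `n_replicates`, `n`
#'   (sites per replicate).
#' @examples
#' merging_factor(rep(0.17, 3), dims = c(64, 64), n_replicates = 10, seed = 1)
#' @export
merging_factor <- function(color_probs, dims = c(256, 256),
                           n_replicates = 200,
                           boundary = c("periodic", "open"),
                           level = 0.95, seed = NULL) {
  boundary <- match.arg(boundary)
  assert_number(n_replicates, "n_replicates", lower = 2)
  with_seed_or_stream(seed, {
    reps <- purrr::map(seq_len(n_replicates), function(i) {
      cl <- same_color_clusters(
        label_lattice(dims, color_probs, boundary)
      )$clusters
      if (nrow(cl) == 0) {
        return(tibble(weighted = NA_real_, per_cluster = NA_real_))
      }
      tibble(
        weighted = sum(cl$size^2) / sum(cl$size),
        per_cluster = mean(cl$size)
      )
    }) |>
      purrr::list_rbind()
    if (all(is.na(reps$weighted))) {
      abort("no labeled sites in any replicate; increase color_probs or dims")
    }
    w <- reps$weighted[!is.na(reps$weighted)]
    pc <- reps$per_cluster[!is.na(reps$per_cluster)]
    z <- -qnorm((1 - level) / 2)
    se <- sd(w) / sqrt(length(w))
    tibble(
      estimate = mean(w),
      conf.low = max(1, mean(w) - z * se),
      conf.high = mean(w) + z * se,
      level = level,
      method = "simulation",
      mean_cluster_size = mean(pc),
      n_replicates = length(w),
      n = prod(dims)
    )
  })
}

#' Sweep the merging factor over labeling probabilities
#'
#' Convenience wrapper running [merging_factor()] over a grid of per-color
#' probabilities with three equally likely colors, used to calibrate the
#' labeling probability against an observed compound size.
#'
#' @param p_values Grid of per-color labeling probabilities.
#' @param n_colors Number of equally likely colors (default 3).
#' @inheritParams merging_factor
#' @return A tibble with one row per grid point, columns `p_color` plus the
#'   [merging_factor()] columns.
#' @export
merging_sweep <- function(p_values, n_colors = 3, dims = c(256, 256),
                          n_replicates = 50, boundary = "periodic",
                          seed = NULL) {
  with_seed_or_stream(seed, {
    purrr::map(p_values, function(p) {
      merging_factor(rep(p, n_colors), dims = dims,
                     n_replicates = n_replicates, boundary = boundary) |>
        mutate(p_color = p, .before = 1)
    }) |>
      purrr::list_rbind()
  })
}

#' Fragmentation/merging balance
#'
#' Ratio of the fragmentation rate (fragments per clone) to the merging
#' factor (progenitors per compound). When the ratio is close to 1 the two
#' processes cancel and the raw cluster count is itself a good progenitor
#' count.
#'
#' @param frag_mean Fragments per clone (> 0).
#' @param merge_factor Progenitors per compound (> 0).
#' @param tolerance Relative tolerance for calling the processes balanced.
#' @return A one-row tibble: `ratio`, `balanced`.
#' @examples
#' fragmentation_merging_balance(2.6, 2.75)
#' @export
fragmentation_merging_balance <- function(frag_mean, merge_factor,
                                          tolerance = 0.1) {
  assert_number(frag_mean, "frag_mean", lower = 0, strict_lower = TRUE)
  assert_number(merge_factor, "merge_factor", lower = 0, strict_lower = TRUE)
  ratio <- frag_mean / merge_factor
  tibble(ratio = ratio, balanced = abs(ratio - 1) <= tolerance)
}
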