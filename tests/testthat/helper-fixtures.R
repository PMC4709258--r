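# Small in-code fixtures shared across test files.

# A hand-written valid fragment table: two organs, three clones.
make_fragment_table <- function() {
  tibble::tibble(
    heart_id = c("H1", "H1", "H1", "H1", "H1", "H2", "H2", "H2", "H2", "H2"),
    stage_induced = 6.75,
    stage_analyzed = 12.5,
    clone_id = c(rep("H1_RFP", 3), rep("H1_YFP", 2), rep("H2_CFP", 5)),
    color = c(rep("RFP", 3), rep("YFP", 2), rep("CFP", 5)),
    sa_fraction = c(0.002, 0.003, 0.0007, 0.004, 0, 0.001, 0.002,
                    0.0015, 0.0005, 0),
    touches_surface = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                        TRUE, TRUE, FALSE),
    volume_um3 = c(2150 * c(10, 12, 3, 20, 5, 4, 9, 7, 2, 1)),
    region = c("LV", "LV", "RV", "OFT", "LV", "RA", "LA", "LV", "RV", "LV")
  )
}

# Build a lattice_coloring by hand from an integer matrix (0 = unlabeled).
make_coloring <- function(mat, boundary = "open", n_colors = max(mat, 1)) {
  structure(
    list(
      color = mat,
      dims = as.integer(dim(mat)),
      boundary = boundary,
      color_probs = rep(NA_real_, n_colors)
    ),
    class = "lattice_coloring"
  )
}

# Independent flood-fill component oracle on literal triangular-lattice
# geometry: site (r, c) sits at (x, y) = (c + r/2, r * sqrt(3) / 2);
# neighbors are sites at Euclidean distance 1 (open boundary only).
geometry_components <- function(mat) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  coords <- cbind(
    x = as.vector(col(mat)) + as.vector(row(mat)) / 2,
    y = as.vector(row(mat)) * sqrt(3) / 2
  )
  n <- nr * nc
  comp <- rep(NA_integer_, n)
  labeled <- as.vector(mat) != 0
  next_id <- 0L
  for (s in seq_len(n)) {
    if (!labeled[s] || !is.na(comp[s])) next
    next_id <- next_id + 1L
    queue <- s
    comp[s] <- next_id
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      d2 <- (coords[, 1] - coords[cur, 1])^2 + (coords[, 2] - coords[cur, 2])^2
      nbr <- which(abs(d2 - 1) < 1e-9 & labeled &
                     as.vector(mat) == as.vector(mat)[cur] & is.na(comp))
      comp[nbr] <- next_id
      queue <- c(queue, nbr)
    }
  }
  sizes <- if (next_id == 0) integer() else tabulate(comp[labeled], next_id)
  list(n = next_id, sizes = sort(sizes))
}
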