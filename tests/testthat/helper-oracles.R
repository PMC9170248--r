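# Independent oracles used to cross-check package implementations.
# These stay deliberately naive: plain loops, no shared code with R/.

# flood-fill connected-component labeling (26-neighborhood) on a 3D mask
flood_fill_label <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nextlab <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (mask[i, j, k] == 0 || lab[i, j, k] != 0) next
      nextlab <- nextlab + 1L
      queue <- matrix(c(i, j, k), ncol = 3)
      lab[i, j, k] <- nextlab
      while (nrow(queue) > 0) {
        cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (o in seq_len(nrow(offs))) {
          p <- cur + offs[o, ]
          if (any(p < 1) || any(p > dims)) next
          if (mask[p[1], p[2], p[3]] != 0 && lab[p[1], p[2], p[3]] == 0L) {
            lab[p[1], p[2], p[3]] <- nextlab
            queue <- rbind(queue, p)
          }
        }
      }
    }
  lab
}

# brute-force connectivity metrics straight off an edge list
brute_metrics <- function(edges, cone_ids, rod_ids) {
  conv <- sapply(cone_ids, function(c)
    length(unique(edges$rod_id[edges$cone_id == c])))
  div <- sapply(rod_ids, function(r)
    length(unique(edges$cone_id[edges$rod_id == r])))
  shared <- outer(cone_ids, cone_ids, Vectorize(function(a, b) {
    if (a == b) return(0L)
    length(intersect(edges$rod_id[edges$cone_id == a],
                     edges$rod_id[edges$cone_id == b]))
  }))
  dimnames(shared) <- list(cone_ids, cone_ids)
  excl <- sapply(cone_ids, function(c) {
    rods <- unique(edges$rod_id[edges$cone_id == c])
    sum(sapply(rods, function(r) sum(edges$rod_id == r) == 1))
  })
  list(convergence = conv, divergence = div[div > 0], shared = shared,
       exclusive = excl, uncontacted = sum(div == 0))
}

# a small hand-wired contact table for deterministic graph tests
tiny_graph <- function() {
  edges <- data.frame(
    rod_id  = c("r1", "r2", "r2", "r3", "r4", "r4", "r4"),
    cone_id = c("c1", "c1", "c2", "c2", "c1", "c2", "c3"),
    stringsAsFactors = FALSE
  )
  contact_graph(edges, cone_ids = c("c1", "c2", "c3"),
                rod_ids = c("r1", "r2", "r3", "r4", "r5"),
                cone_field_area = c(c1 = 10, c2 = 10, c3 = 20),
                region_area = 40)
}

# axis-aligned cuboid patch of voxels (z, y, x), 0-based
slab_voxels <- function(nz, ny, nx) {
  as.matrix(expand.grid(z = 0:(nz - 1), y = 0:(ny - 1), x = 0:(nx - 1)))
}

# small, fast scene configuration for end-to-end imaging tests
mini_config <- function(seed = 1, ...) {
  scene_config(region_width = 12, region_height = 12,
               cone_density = 2 / 100, field_area_mean = 50,
               field_area_sd = 5, voxel_xy = 60, voxel_z = 150,
               noise_sd = 0.005, seed = seed, ...)
}
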