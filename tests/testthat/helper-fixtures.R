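# Shared fixtures: everything is generated in code at test time.

# Small random volume on a unit grid.
randomVolume <- function(shape = c(16L, 16L, 16L), voxelMm = 1, seed = 42,
                         modality = "other") {
  set.seed(seed)
  volume3D(array(rnorm(prod(shape)), shape),
           isotropicGrid(shape, voxelMm)@affine, modality)
}

# Default phantom used across tests: 48^3 at 4 mm.
testSpec <- function(...) phantomSpec(...)

# Coarser, faster phantom for morphology-heavy tests.
coarseSpec <- function(...) phantomSpec(grid = isotropicGrid(36L, 5), ...)

# Brute-force flood fill used as the independent connected-components
# oracle (breadth-first over an explicit neighbour list, written without
# reference to the package kernel).
floodFillLabels <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  stack <- integer(sum(mask))
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    stack[1] <- start
    top <- 1L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      vi <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        w <- vi + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        wl <- w[1] + d[1] * (w[2] - 1 + d[2] * (w[3] - 1))
        if (mask[wl] && lab[wl] == 0L) {
          lab[wl] <- cur
          top <- top + 1L
          stack[top] <- wl
        }
      }
    }
  }
  lab
}

# Canonical relabeling so two labelings can be compared as partitions.
canonicalPartition <- function(lab) {
  ord <- match(lab[lab > 0], unique(lab[lab > 0]))
  out <- lab
  out[lab > 0] <- ord
  out
}
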