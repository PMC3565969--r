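# Independent oracles and small fixture builders used across the suite.

# Classical flood-fill (BFS) connected-component labelling, the reference
# partition against which the label-equivalence implementation is checked.
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  k <- 0L
  stack <- integer(nr * nc)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- k
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (o in offs) {
        qr <- pr + o[1]; qc <- pc + o[2]
        if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
        q <- qr + (qc - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- k
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition iff the label pairing over
# foreground pixels is a bijection.
same_partition <- function(a, b) {
  fg <- a > 0L
  if (!identical(fg, b > 0L)) return(FALSE)
  pairs <- unique(cbind(a[fg], b[fg]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

disc_mask <- function(n, cx, cy, r) {
  outer(1:n, 1:n, function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# Small noiseless single-frame scene used by several reconstruction tests.
tiny_scene <- function(volumes = 90, shape = "biconcave", seed = 5,
                       grid = c(192L, 192L), aberration = 0.3, n_dirt = 3,
                       config = optical_config()) {
  pop <- lapply(volumes, function(v)
    cell_spec(shape = shape, target_volume_fl = v))
  build_scene(pop, grid, config, seed = seed,
              aberration_amplitude_rad = aberration, n_dirt = n_dirt)
}
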