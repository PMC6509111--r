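# Independent oracles used across tests. These deliberately use naive
# algorithms (enumeration, breadth-first search, per-threshold relabeling)
# so they share no code with the package implementations they check.

# number of integer lattice points with x^2 + y^2 + z^2 <= r^2
lattice_sphere_count <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  sum(g$x^2 + g$y^2 + g$z^2 <= radius^2)
}

# connected-component labels of a logical 3D array by breadth-first search
bfs_label <- function(supra, connectivity = 26) {
  dims <- dim(supra)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18)
    offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  idx <- which(supra, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    if (lab[idx[i, 1], idx[i, 2], idx[i, 3]] != 0L) next
    nxt <- nxt + 1L
    queue <- idx[i, , drop = FALSE]
    lab[queue] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (supra[nb[1], nb[2], nb[3]] &&
            lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# brute-force TFCE: explicit component labeling at every threshold
tfce_brute <- function(vol, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  v <- vol
  v[is.na(v)] <- 0
  mx <- max(v)
  if (mx <= 0) return(array(0, dim(vol)))
  if (is.null(dh)) dh <- mx / 100
  out <- array(0, dim(vol))
  n_steps <- ceiling(mx / dh)
  for (s in seq_len(n_steps)) {
    h <- (s - 0.5) * dh
    supra <- v >= h
    if (!any(supra)) next
    lab <- bfs_label(supra, connectivity)
    sizes <- tabulate(lab[lab > 0])
    out[supra] <- out[supra] + sizes[lab[supra]]^E * h^H * dh
  }
  out
}

# hand Pearson correlation straight from the covariance formula
pearson_by_hand <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# small planted-effect configuration shared by several tests
tiny_effect_config <- function(n_subjects = 6, noise_sd = 0.3, seed = 1) {
  sim_config(n_subjects = n_subjects, grid_shape = c(8, 8, 8),
             targets = c("self", "far"), n_states = 6,
             dispersion_by_target = c(self = 1.0, far = 0.2),
             baseline_dispersion = 0.2, noise_sd = noise_sd, seed = seed)
}
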