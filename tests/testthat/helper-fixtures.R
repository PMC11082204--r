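# fixtures are built in code; everything is seeded and small

# a scene spec with one centred lesion, no watery ring, no noise
lesion_scene_spec <- function(size = 64, radius = 20, severity = 1,
                              noise_sd = 0, seed = 7L, ring_width = 0) {
  scene_spec(height = size, width = size,
             fruit_semiaxes = c(size, size) * 2,
             lesions = list(list(center = c(size / 2, size / 2),
                                 radius = radius, severity = severity)),
             ring_width = ring_width, noise_sd = noise_sd, seed = seed)
}

# brute-force rasterized disc pixel count (the labeling oracle)
disc_pixel_count <- function(size, center, radius) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(rep(seq_len(size), each = size), size, size)
  sum((rr - center[1])^2 + (cc - center[2])^2 <= radius^2)
}

# straight-loop dynamic-routing reference, independent of the package path
oracle_routing <- function(u_hat, iters) {
  nc <- dim(u_hat)[1]; K <- dim(u_hat)[2]; dd <- dim(u_hat)[3]
  squash1 <- function(s) {
    n2 <- sum(s^2)
    if (n2 == 0) s * 0 else s * sqrt(n2) / (1 + n2)
  }
  b <- matrix(0, nc, K)
  v <- matrix(0, dd, K)
  for (it in seq_len(iters)) {
    cmat <- matrix(0, nc, K)
    for (i in seq_len(nc)) {
      e <- exp(b[i, ] - max(b[i, ]))
      cmat[i, ] <- e / sum(e)
    }
    for (j in seq_len(K)) {
      s <- rep(0, dd)
      for (i in seq_len(nc)) s <- s + cmat[i, j] * u_hat[i, j, ]
      v[, j] <- squash1(s)
    }
    if (it < iters)
      for (i in seq_len(nc))
        for (j in seq_len(K))
          b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[, j])
  }
  list(v = v, coupling = t(cmat))
}

# tiny class-balanced patch set at reduced spatial size (fast to train)
tiny_patch_set <- function(n_per_class = 2, size = 16, seed = 1L,
                           split = "train") {
  synthetic_patch_set(n_per_class, seed = seed, preset = "easy",
                      split = split, size = size)
}

# extract one named parameter tensor from a model's flat coefficient vector
get_param <- function(model, name) {
  tab <- parameter_table(model)
  w <- coef(model)
  off <- cumsum(c(0, tab$n))
  i <- match(name, tab$name)
  stopifnot(!is.na(i))
  matrix(w[(off[i] + 1):off[i + 1]], tab$rows[i], tab$cols[i])
}
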