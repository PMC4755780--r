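# Brute-force reference implementations used as independent oracles.

# full minimum-image distance matrix
bf_dist_matrix <- function(pos, L) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- pos[i, 1] - pos[j, 1]; dx <- dx - L * round(dx / L)
    dy <- pos[i, 2] - pos[j, 2]; dy <- dy - L * round(dy / L)
    d[i, j] <- sqrt(dx^2 + dy^2)
  }
  d
}

# neighbour sets by all-pairs sort: up to k others within lmax, by distance
# then index
bf_neighbors <- function(pos, L, lmax, k) {
  d <- bf_dist_matrix(pos, L)
  n <- nrow(pos)
  lapply(seq_len(n), function(i) {
    cand <- setdiff(which(d[i, ] <= lmax[i]), i)
    cand <- cand[order(d[i, cand], cand)]
    head(cand, k)
  })
}

# mean distance to the nn nearest others, averaged over agents
bf_mean_dist_knn <- function(pos, L, nn) {
  d <- bf_dist_matrix(pos, L)
  mean(sapply(seq_len(nrow(pos)), function(i)
    mean(sort(d[i, -i])[seq_len(nn)])))
}

# pair potential of the social interaction
pair_potential <- function(d, p) p$Cr * exp(-d / p$lr) - p$Ca * exp(-d / p$la)

# scalar radial force (positive = repulsive) by central difference of the
# potential
bf_radial_force <- function(d, p, h = 1e-5) {
  -(pair_potential(d + h, p) - pair_potential(d - h, p)) / (2 * h)
}

# direct KL summation over already-binned values
bf_kl <- function(q, p, eps = 1e-9) {
  qq <- (q + eps) / sum(q + eps)
  pp <- (p + eps) / sum(p + eps)
  sum(qq * log(qq / pp))
}

# a small seeded random configuration on a torus
random_config <- function(n, L, seed) {
  set.seed(seed)
  matrix(runif(2 * n, 0, L), ncol = 2)
}
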