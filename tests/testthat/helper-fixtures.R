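# Shared fixtures, computed lazily and cached for the whole test session.
# Descriptor-pair pools dominate runtime, so alignment-heavy tests share one
# small three-copy family and its context.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small two-domain architecture (38 residues) for fast unit tests
small_architecture <- function() {
  list(list(type = "helix", len = 10), list(type = "loop", len = 3),
       list(type = "helix", len = 10), list(type = "loop", len = 5),
       list(type = "helix", len = 10))
}

fast_params <- function(...) {
  msta_params(n_trees = 4L, pop_max = 8L, max_evals = 25L, stall = 8L,
              profile_restarts = 2L, ...)
}

small_chain <- function() cached("small_chain",
  make_chain(small_architecture(), seed = 42L, name = "tmpl"))

# rigid-transformed copy of a structure (rotation + translation)
rigid_copy <- function(s, name = paste0(s$name, "_rt"), angle = 0.9,
                       axis = c(1, 2, 3), shift = c(4, -7, 2)) {
  r <- descalign:::rot_about(axis, angle)
  s2 <- s
  s2$name <- name
  s2$ca <- sweep(s$ca %*% t(r), 2L, shift, "+")
  s2$sc <- sweep(s$sc %*% t(r), 2L, shift, "+")
  s2
}

fam3 <- function() cached("fam3", make_family(
  family_spec(architecture = small_architecture(), n_copies = 3L,
              noise_sigma = 0.2, seed = 7L)))

ctx3 <- function() cached("ctx3", {
  ctx <- alignment_context(fam3()$structures, fast_params())
  for (i in 1:2) for (j in (i + 1):3) descalign:::get_pool(ctx, i, j)
  ctx
})

# three noisy copies of the default 60-residue two-domain template
fam3big <- function() cached("fam3big", make_family(
  family_spec(n_copies = 3L, noise_sigma = 0.2, seed = 19L)))

ctx3big <- function() cached("ctx3big", {
  ctx <- alignment_context(fam3big()$structures, fast_params())
  for (i in 1:2) for (j in (i + 1):3) descalign:::get_pool(ctx, i, j)
  ctx
})

# identical-copy family (zero noise) for fixed-point tests
fam_id <- function() cached("fam_id", make_family(
  family_spec(architecture = small_architecture(), n_copies = 3L,
              noise_sigma = 0, seed = 3L)))

ctx_id <- function() cached("ctx_id", alignment_context(fam_id()$structures, fast_params()))

# deterministic random graph for clique tests
random_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- stats::runif(n * (n - 1) / 2) < p
  adj <- adj | t(adj)
  adj
}

# independent brute-force maximum-weight clique by subset enumeration
brute_force_clique <- function(adj, w) {
  n <- nrow(adj)
  best <- integer(0); best_w <- -Inf
  for (mask in 0:(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) != 0)
    if (length(v) > 1L) {
      sub <- adj[v, v]
      if (!all(sub[upper.tri(sub)])) next
    }
    cw <- sum(w[v])
    if (cw > best_w) { best <- v; best_w <- cw }
  }
  list(clique = best, weight = best_w)
}

# quaternion from rotation matrix (oracle for rotation_angle)
quat_from_rot <- function(r) {
  t <- sum(diag(r))
  q <- if (t > 0) {
    s <- sqrt(t + 1) * 2
    c((r[3,2]-r[2,3])/s, (r[1,3]-r[3,1])/s, (r[2,1]-r[1,2])/s, s/4)
  } else {
    i <- which.max(diag(r))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(r[i,i] - r[j,j] - r[k,k] + 1) * 2
    q <- numeric(4)
    q[i] <- s / 4
    q[j] <- (r[j,i] + r[i,j]) / s
    q[k] <- (r[k,i] + r[i,k]) / s
    q[4] <- (r[k,j] - r[j,k]) / s
    q
  }
  q / sqrt(sum(q^2))
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr_d <- qr(m)
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
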