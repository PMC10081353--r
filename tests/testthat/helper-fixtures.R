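# shared fixtures and independent oracles

# brute-force discrete Frechet: enumerate all monotone couplings (with exact
# minimax pruning), independent of the dynamic program under test
frechet_bruteforce <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  pd <- function(i, j) sqrt(sum((P[i, ] - Q[j, ])^2))
  best <- Inf
  rec <- function(i, j, cur) {
    cur <- max(cur, pd(i, j))
    if (cur >= best) return(invisible())
    if (i == n && j == m) { best <<- cur; return(invisible()) }
    if (i < n) rec(i + 1L, j, cur)
    if (j < m) rec(i, j + 1L, cur)
    if (i < n && j < m) rec(i + 1L, j + 1L, cur)
  }
  rec(1L, 1L, 0)
  best
}

# random rooted tree: node i > 1 attaches to a uniformly chosen earlier node
random_tree <- function(n, scale = 20) {
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  neuron_tree(data.frame(id = seq_len(n), type = 3L,
                         x = runif(n, 0, scale), y = runif(n, 0, scale),
                         z = runif(n, 0, scale),
                         radius = 1, parent = parent))
}

# random orientation-preserving affine map with moderate conditioning
random_affine <- function() {
  repeat {
    A <- diag(3) + matrix(rnorm(9, sd = 0.3), 3, 3)
    if (det(A) > 0.1) break
  }
  affine_transform(A, rnorm(3, sd = 10))
}

# random smooth diffeomorphic transform: sum of Gaussian bumps with closed-form
# derivatives; sup|Du| < 1 by construction
random_bump_transform <- function(n_bumps = 2L, amplitude = 15, sigma = 60,
                                  box = c(0, 200)) {
  centers <- matrix(runif(3 * n_bumps, box[1], box[2]), n_bumps, 3)
  dirs <- matrix(rnorm(3 * n_bumps), n_bumps, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amps <- runif(n_bumps, 0.3, 1) * amplitude
  bump_transform(centers, amps, dirs, sigma)
}

# polynomial analytic transform with symbolic derivatives, for exact checks
squash_x_transform <- function() {
  analytic_transform(
    function(p) { p <- if (is.matrix(p)) p else matrix(p, 1); cbind(p[, 1]^2, p[, 2], p[, 3]) },
    jacobian = function(x) diag(c(2 * x[1], 1, 1)),
    hessian = function(x) { H <- array(0, c(3, 3, 3)); H[1, 1, 1] <- 2; H })
}

# edges of a tree as a canonical character set "parent-child"
tree_edge_set <- function(tree) {
  nodes <- tree$nodes
  kids <- nodes[nodes$parent != -1L, ]
  sort(paste(kids$parent, kids$id, sep = "-"))
}

# edges traversed by the branches (using source_ids), as directed parent-child
branch_edge_multiset <- function(branches, tree) {
  parent_of <- setNames(tree$nodes$parent, tree$nodes$id)
  out <- character(0)
  for (br in branches) {
    ids <- br$source_ids
    for (i in seq_len(length(ids) - 1L)) {
      a <- ids[i]; b <- ids[i + 1L]
      # orient each traversed edge as parent-child
      e <- if (parent_of[[as.character(b)]] == a) paste(a, b, sep = "-")
           else paste(b, a, sep = "-")
      out <- c(out, e)
    }
  }
  sort(out)
}
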