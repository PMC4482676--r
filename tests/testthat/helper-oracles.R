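## Independent oracles and small fixtures used across the test files.

## Exhaustive linear-parsimony oracle: minimize total absolute change over
## all assignments of internal-node values drawn from the set of observed
## tip values (optimal assignments for the L1/median problem on a tree lie
## in that set). Only feasible for small trees.
brute_force_steps <- function(tree, trait) {
  ntip <- length(tree$tip.label)
  vals <- trait[tree$tip.label]
  S <- sort(unique(unname(vals)))
  nint <- tree$Nnode
  grids <- expand.grid(rep(list(S), nint))
  cost <- numeric(nrow(grids))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    pv <- grids[[p - ntip]]
    cv <- if (ch <= ntip) vals[ch] else grids[[ch - ntip]]
    cost <- cost + abs(pv - cv)
  }
  min(cost)
}

## Direct matrix-formula computation of Blomberg's K (variance ratio with
## phylogenetically corrected mean, scaled by its Brownian expectation).
direct_blomberg_k <- function(tree, trait) {
  V <- ape::vcv(tree)
  x <- trait[tree$tip.label]
  n <- length(x)
  Vi <- solve(V)
  one <- rep(1, n)
  a <- as.numeric(one %*% Vi %*% x) / as.numeric(one %*% Vi %*% one)
  d <- x - a
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(d %*% Vi %*% d) / (n - 1)
  expected <- (sum(diag(V)) - n / as.numeric(one %*% Vi %*% one)) / (n - 1)
  (mse0 / mse) / expected
}

## Numeric surface integral of a triaxial ellipsoid with semi-axes a, b, c
## (spherical parametrization, |r_theta x r_phi| integrand).
numeric_ellipsoid_area <- function(a, b, c) {
  f <- function(theta, phi) {
    sin(theta) * sqrt((b * c * sin(theta) * cos(phi))^2 +
                      (a * c * sin(theta) * sin(phi))^2 +
                      (a * b * cos(theta))^2)
  }
  pracma::integral2(f, 0, pi, 0, 2 * pi, reltol = 1e-9)$Q
}

## Multivariate-normal draws via the Cholesky root (R draws x length(mu)).
rmvn <- function(R_draws, mu, Sigma) {
  L <- t(chol(Sigma))
  Z <- matrix(rnorm(R_draws * length(mu)), nrow = length(mu))
  t(mu + L %*% Z)
}

## A wavelength grid whose visible points split evenly across the three
## visible bands (10 points each), for symmetry checks.
balanced_grid <- function() seq(305, 695, by = 10)

## Small rooted trees used in several files.
tree2 <- function(t = 1) {
  ape::read.tree(text = sprintf("(a:%g,b:%g);", t, t))
}
star3 <- function() ape::read.tree(text = "(a:1,b:1,c:1);")
balanced4 <- function() ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
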