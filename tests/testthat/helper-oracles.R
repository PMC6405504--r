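# Independent oracles used by the property tests.  These deliberately avoid
# the package's own recursions: ancestral states come from GLS matrix algebra
# on the BM covariance, the MA slope from a direct 1-D search over line
# angles.

# GLS/BM oracle: E[state at node | tip values] with the root estimated by GLS.
# V_ij = shared path length of tips i,j from the root; c_i = shared path
# length of the target node with tip i.  Pure matrix computation via ape::vcv.
gls_ancestral_oracle <- function(tree, x) {
  x <- x[tree$tip.label]
  V <- ape::vcv(tree)
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- as.numeric((t(one) %*% Vi %*% x) / (t(one) %*% Vi %*% one))
  nodes <- (n + 1L):(n + tree$Nnode)
  est <- vapply(nodes, function(k) {
    cc <- depths[M[k, seq_len(n)]]
    mu + as.numeric(t(cc) %*% Vi %*% (x - mu))
  }, numeric(1))
  names(est) <- nodes
  est
}

# Perpendicular-least-squares oracle for the MA slope: coarse grid over line
# angles followed by golden-section refinement to ~1e-8 in angle.
ma_slope_oracle <- function(x, y, through_origin = TRUE) {
  if (!through_origin) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  ss <- function(th) sum((sin(th) * x - cos(th) * y)^2)
  grid <- seq(-pi / 2, pi / 2, length.out = 2001L)
  i <- which.min(vapply(grid, ss, numeric(1)))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- ss(c1); f2 <- ss(c2)
  while (b - a > 1e-10) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- ss(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- ss(c2)
    }
  }
  tan((a + b) / 2)
}

fixture_traits_path <- function() {
  system.file("extdata", "meliponini_traits.csv", package = "phylorensch")
}

fixture_printed_path <- function() {
  system.file("extdata", "meliponini_table1_printed.csv", package = "phylorensch")
}

# deterministic synthetic stand-in chronogram over the fixture's 44 species
# (the published chronogram is an external accession and is not bundled)
fixture_stand_in_tree <- function(seed = 1L) {
  traits <- read_trait_table(fixture_traits_path())
  tr <- sim_yule_tree(nrow(traits), lambda = 1, seed = seed)
  tr$tip.label <- sort(traits$species)
  tr
}
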