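#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation: starting from two lineages at the root, each of the
#' current k lineages splits at rate `lambda`, so inter-event waits are
#' Exponential(k * lambda); after the n-th tip appears the tree is extended by
#' one final Exponential(n * lambda) epoch, i.e. it is sampled at a uniform
#' moment while carrying n tips.  The tree is ultrametric by construction and
#' its expected root height is \eqn{\sum_{k=2}^{n} 1/(k \lambda)}.
#'
#' @param n_tips number of tips (>= 2).
#' @param lambda birth rate per lineage per unit time (> 0).
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   its arguments and the seed).
#' @return an ultrametric [ape::phylo] tree with tips `t1 ... tn`.
#' @export
sim_yule_tree <- function(n_tips, lambda = 1, seed) {
  stopifnot(n_tips >= 2, lambda > 0)
  with_seed(seed, {
    # lineage bookkeeping: parent node id and birth time of each active
    # lineage; internal nodes numbered in creation order, root = 1
    node_count <- 1L
    parent <- c(1L, 1L)
    start <- c(0, 0)
    edges <- NULL; lens <- NULL
    time <- 0
    k <- 2L
    while (k < n_tips) {
      time <- time + stats::rexp(1, rate = lambda * k)
      i <- sample.int(k, 1L)
      node_count <- node_count + 1L
      # lineage i ends at `time`, becoming internal node `node_count`
      edges <- rbind(edges, c(parent[i], node_count))
      lens <- c(lens, time - start[i])
      parent <- c(parent[-i], node_count, node_count)
      start <- c(start[-i], time, time)
      k <- k + 1L
    }
    time <- time + stats::rexp(1, rate = lambda * n_tips)
    # remaining lineages become tips at `time`; renumber so tips are 1..n and
    # internal nodes n+1 .. n+node_count (root = n+1)
    edge_mat <- NULL; edge_len <- NULL
    if (!is.null(edges)) {
      edge_mat <- cbind(edges[, 1L] + n_tips, edges[, 2L] + n_tips)
      edge_len <- lens
    }
    for (i in seq_len(n_tips)) {
      edge_mat <- rbind(edge_mat, c(parent[i] + n_tips, i))
      edge_len <- c(edge_len, time - start[i])
    }
    storage.mode(edge_mat) <- "integer"
    tr <- structure(list(edge = edge_mat, edge.length = edge_len,
                         tip.label = paste0("t", seq_len(n_tips)),
                         Nnode = node_count),
                    class = "phylo", order = "cladewise")
    # canonicalize node numbering to ape's preorder convention (full-precision
    # round-trip: %.17g preserves IEEE doubles exactly)
    tr <- ape::read.tree(text = ape::write.tree(tr, digits = 17))
    validate_tree(tr)
  })
}

#' Simulate Brownian motion on a tree
#'
#' Each branch adds an independent Normal(0, sigma2 * branch length) increment
#' to the parent's value, starting from `root_state`.
#'
#' @param tree an [ape::phylo] tree.
#' @param sigma2 BM rate (variance per unit branch length, >= 0).
#' @param root_state trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
sim_bm <- function(tree, sigma2, root_state = 0, seed) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  with_seed(seed, {
    n <- length(tree$tip.label)
    val <- numeric(n + tree$Nnode)
    val[n + 1L] <- root_state
    pr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
    inc <- stats::rnorm(nrow(pr$edge), 0, sqrt(sigma2 * pr$edge.length))
    for (e in seq_len(nrow(pr$edge)))
      val[pr$edge[e, 2L]] <- val[pr$edge[e, 1L]] + inc[e]
    stats::setNames(val[seq_len(n)], tree$tip.label)
  })
}

#' Simulate correlated Brownian motion for several traits
#'
#' Joint BM: on a branch of length v the p traits gain a multivariate normal
#' increment with covariance `rate_matrix * v`.  The rate matrix must be
#' symmetric positive semi-definite; rank-deficient matrices (perfectly
#' correlated traits) are supported via an eigendecomposition square root.
#'
#' @param tree an [ape::phylo] tree.
#' @param rate_matrix p x p symmetric PSD matrix of BM rates/covariances.
#' @param root_states numeric vector of length p.
#' @param seed integer seed.
#' @return n_tips x p matrix of tip values (rows named by tip label).
#' @export
sim_bm_correlated <- function(tree, rate_matrix, root_states, seed) {
  rate_matrix <- as.matrix(rate_matrix)
  p <- nrow(rate_matrix)
  stopifnot(ncol(rate_matrix) == p, length(root_states) == p)
  if (max(abs(rate_matrix - t(rate_matrix))) > 1e-10)
    stop("rate matrix must be symmetric", call. = FALSE)
  ev <- eigen(rate_matrix, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("rate matrix must be positive semi-definite", call. = FALSE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  with_seed(seed, {
    n <- length(tree$tip.label)
    val <- matrix(0, n + tree$Nnode, p)
    val[n + 1L, ] <- root_states
    pr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(pr$edge))) {
      z <- stats::rnorm(p)
      val[pr$edge[e, 2L], ] <- val[pr$edge[e, 1L], ] +
        sqrt(pr$edge.length[e]) * as.numeric(rt %*% z)
    }
    out <- val[seq_len(n), , drop = FALSE]
    rownames(out) <- tree$tip.label
    out
  })
}

#' Configuration for the synthetic caste dataset generator
#'
#' Defaults emulate the structure of the empirical stingless-bee dataset: a
#' 44-tip pure-birth chronogram; log10 worker intertegular width evolving by
#' BM; queen and male log-sizes co-evolving with the worker deviation through
#' evolutionary allometric slopes, plus independent BM noise; a positive
#' queen-male intercept offset (female-biased dimorphism on average) that is
#' negated inside one 12-tip clade, reproducing the male-biased-clade pattern
#' seen in *Melipona*.
#'
#' @param n_tips tips in the tree.
#' @param lambda Yule birth rate.
#' @param sigma2_worker BM rate of log10 worker size.
#' @param slope_queen,slope_male evolutionary allometric slopes of queen and
#'   male log-size on worker log-size (> 0).
#' @param sigma2_noise independent BM rate added to queen and male log-sizes.
#' @param root_worker_log10 root log10 worker size (default log10 of 1.6 mm).
#' @param offset_queen,offset_male caste intercepts on the log10 scale,
#'   relative to worker size.
#' @param clade_shift logical: negate the queen-male offset difference in one
#'   clade.
#' @param clade_size target tip count of the shifted clade.
#' @param seed integer seed (mandatory).
#' @return a `"sim_config"` list.
#' @export
sim_config <- function(n_tips = 44, lambda = 1, sigma2_worker = 0.01,
                       slope_queen = 1.1, slope_male = 1.0,
                       sigma2_noise = 5e-4,
                       root_worker_log10 = log10(1.6),
                       offset_queen = 0.07, offset_male = 0,
                       clade_shift = TRUE, clade_size = 12, seed) {
  if (slope_queen <= 0 || slope_male <= 0)
    stop("allometric slopes must be > 0", call. = FALSE)
  stopifnot(n_tips >= 2, lambda > 0, sigma2_worker >= 0, sigma2_noise >= 0)
  structure(list(n_tips = n_tips, lambda = lambda,
                 sigma2_worker = sigma2_worker, slope_queen = slope_queen,
                 slope_male = slope_male, sigma2_noise = sigma2_noise,
                 root_worker_log10 = root_worker_log10,
                 offset_queen = offset_queen, offset_male = offset_male,
                 clade_shift = clade_shift, clade_size = clade_size,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic caste trait dataset on a simulated chronogram
#'
#' Implements the generative model described in [sim_config()]:
#' `log10 worker ~ BM(sigma2_worker)`;
#' `log10 queen = root + offset_queen + slope_queen * (worker deviation) + BM noise`;
#' `log10 male` likewise with its own slope and offset.  If `clade_shift` is
#' set, the internal clade whose size is closest to `clade_size` has its
#' queen-male offset difference negated, so (at low noise) exactly that clade
#' is male-biased.  Traits are exported in mm on the natural scale.
#'
#' @param config a `"sim_config"` object.
#' @return list with `tree` (ultrametric [ape::phylo]), `traits` (data.frame
#'   in [read_trait_table()] layout, with `genus` marking the shifted clade)
#'   and `clade_tips` (labels of the shifted clade, or `NULL`).
#' @examples
#' sim <- sim_caste_dataset(sim_config(n_tips = 20, seed = 42))
#' head(sim$traits)
#' @export
sim_caste_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  tree <- sim_yule_tree(cf$n_tips, cf$lambda, seed = cf$seed)
  w_log <- sim_bm(tree, cf$sigma2_worker, cf$root_worker_log10,
                  seed = cf$seed + 1L)
  dev <- w_log - cf$root_worker_log10
  q_noise <- sim_bm(tree, cf$sigma2_noise, 0, seed = cf$seed + 2L)
  m_noise <- sim_bm(tree, cf$sigma2_noise, 0, seed = cf$seed + 3L)
  q_log <- cf$root_worker_log10 + cf$offset_queen + cf$slope_queen * dev + q_noise
  m_log <- cf$root_worker_log10 + cf$offset_male + cf$slope_male * dev + m_noise

  clade_tips <- NULL
  if (isTRUE(cf$clade_shift)) {
    clade_tips <- pick_clade(tree, cf$clade_size)
    # negate the queen-male intercept difference inside the clade
    delta <- cf$offset_queen - cf$offset_male
    idx <- tree$tip.label %in% clade_tips
    q_log[idx] <- q_log[idx] - delta
    m_log[idx] <- m_log[idx] + delta
  }

  traits <- data.frame(
    species = tree$tip.label,
    worker_mm = 10^w_log,
    male_mm = 10^m_log,
    queen_mm = 10^q_log,
    genus = ifelse(tree$tip.label %in% clade_tips, "cladeA", "background"),
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  rownames(traits) <- NULL
  list(tree = tree, traits = traits, clade_tips = clade_tips)
}

# internal clade (monophyletic tip set) whose size is closest to `size`;
# ties broken toward the smaller node id (deterministic)
pick_clade <- function(tree, size) {
  n <- length(tree$tip.label)
  counts <- vapply((n + 1L):(n + tree$Nnode), function(nd)
    length(tip_descendants(tree, nd)), integer(1))
  # exclude the root (would shift everything)
  counts[1L] <- n + 1L
  nd <- (n + 1L):(n + tree$Nnode)
  best <- nd[which.min(abs(counts - size))]
  tree$tip.label[tip_descendants(tree, best)]
}

tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k) tip_descendants(tree, k)))
}
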