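#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Estimates the state of every internal node of a binary tree for a continuous
#' character evolving by Brownian motion.  Each node's estimate is obtained by
#' re-rooting the contrasts (pruning) recursion at that node: tip values are
#' propagated inward from every direction as (conditional value, variance)
#' pairs and combined by inverse-variance weighting, which yields the ML (= GLS
#' under the BM covariance) estimate at the node.  The BM rate estimated from
#' the contrasts is recorded but does not affect the point estimates, which are
#' scale-free.
#'
#' @param tree a binary [ape::phylo] tree; branch lengths >= 0 (zero allowed on
#'   resolved polytomies).
#' @param tip_values named numeric vector of tip states (or unnamed, tip
#'   order).
#' @return object of class `"anc_bm"`: list with `node_states` (named by node
#'   id), `tip_states`, `tree`, `sigma2`.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' ml_ancestral_states(tr, c(A = 1, B = 3, C = 0))   # root 8/7
#' @export
ml_ancestral_states <- function(tree, tip_values) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) stop("need >= 2 tips", call. = FALSE)
  if (!is_rooted_binary(tree))
    stop("tree has polytomies; resolve them first", call. = FALSE)
  x <- align_tip_values(tree, tip_values)
  if (anyNA(x)) stop("missing tip value(s)", call. = FALSE)

  # undirected adjacency: neighbors and connecting branch lengths per node
  m <- n + tree$Nnode
  nb <- vector("list", m)
  bl <- vector("list", m)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; len <- tree$edge.length[e]
    nb[[a]] <- c(nb[[a]], b); bl[[a]] <- c(bl[[a]], len)
    nb[[b]] <- c(nb[[b]], a); bl[[b]] <- c(bl[[b]], len)
  }

  # conditional (value, variance) of the subtree seen from `node` looking away
  # from `from`; variance includes the branch between them
  downpass <- function(node, from, len) {
    if (node <= n) return(c(x[node], len))
    vals <- c(); vars <- c()
    for (k in seq_along(nb[[node]])) {
      nxt <- nb[[node]][k]
      if (nxt == from) next
      r <- downpass(nxt, node, bl[[node]][k])
      vals <- c(vals, r[1L]); vars <- c(vars, r[2L])
    }
    r <- pool(vals, vars)
    c(r[1L], r[2L] + len)
  }

  estimate_at <- function(node) {
    vals <- c(); vars <- c()
    for (k in seq_along(nb[[node]])) {
      r <- downpass(nb[[node]][k], node, bl[[node]][k])
      vals <- c(vals, r[1L]); vars <- c(vars, r[2L])
    }
    pool(vals, vars)[1L]
  }

  internal <- (n + 1L):m
  states <- vapply(internal, estimate_at, numeric(1))
  names(states) <- internal
  pic <- compute_contrasts(tree, x)
  structure(list(node_states = states,
                 tip_states = stats::setNames(x, tree$tip.label),
                 tree = tree, sigma2 = estimate_bm_rate(pic)),
            class = "anc_bm")
}

# inverse-variance weighted combination of independent conditional estimates;
# a zero-variance component pins the result exactly
pool <- function(vals, vars) {
  if (any(vars == 0)) {
    hit <- which(vars == 0)
    v0 <- unique(vals[hit])
    if (length(v0) > 1L)
      stop("conflicting zero-variance estimates at one node", call. = FALSE)
    return(c(v0, 0))
  }
  w <- 1 / vars
  c(sum(vals * w) / sum(w), 1 / sum(w))
}

#' @export
print.anc_bm <- function(x, ...) {
  cat("ML ancestral reconstruction under Brownian motion\n")
  cat("  ", length(x$tip_states), " tips, ", length(x$node_states),
      " internal nodes, sigma2-hat = ", format(x$sigma2, digits = 4), "\n",
      sep = "")
  cat("  root state: ",
      format(x$node_states[[1L]], digits = 6), "\n", sep = "")
  invisible(x)
}

# state of any node (tip or internal) by ape node id
node_state <- function(map, id) {
  n <- length(map$tip_states)
  if (id <= n) unname(map$tip_states[id]) else unname(map$node_states[[as.character(id)]])
}

#' Interpolate a reconstructed state along a branch
#'
#' Linear interpolation between the parent and child node estimates, the
#' along-branch rule used to paint continuous characters on a tree: for
#' interior points under Brownian motion the ML state given the two endpoint
#' estimates is their branch-length-weighted average, which is exactly the
#' linear interpolant.
#'
#' @param anc_map an `"anc_bm"` object.
#' @param edge edge index (row of `tree$edge`).
#' @param t position along the branch, from 0 (parent end) to the branch
#'   length (child end).
#' @return interpolated state.
#' @export
interpolate_branch <- function(anc_map, edge, t) {
  stopifnot(inherits(anc_map, "anc_bm"))
  tr <- anc_map$tree
  len <- tr$edge.length[edge]
  if (t < 0 || t > len) stop("t outside [0, branch length]", call. = FALSE)
  sp <- node_state(anc_map, tr$edge[edge, 1L])
  sc <- node_state(anc_map, tr$edge[edge, 2L])
  if (len == 0) return(sc)
  sp + (t / len) * (sc - sp)
}

#' Paint a tree by a reconstructed continuous character
#'
#' Draws the tree with each branch colored by the interpolated state along it,
#' using a diverging color ramp centered at 0 — so, for an SSD-index map,
#' male-biased lineages sit on one side of the ramp and female-biased lineages
#' on the other.
#'
#' @param anc_map an `"anc_bm"` object.
#' @param color_ramp function mapping `[0, 1]` to colors, as from
#'   [grDevices::colorRamp()]-style palettes; default a blue-grey-red diverging
#'   ramp.
#' @param segments number of gradient segments per branch.
#' @param center value at the middle of the ramp (default 0).
#' @param ... passed to [ape::plot.phylo()].
#' @return invisibly, a `data.frame` of per-segment states and colors.
#' @export
paint_tree <- function(anc_map, color_ramp = NULL, segments = 12, center = 0,
                       ...) {
  stopifnot(inherits(anc_map, "anc_bm"))
  tr <- anc_map$tree
  states <- c(anc_map$tip_states, anc_map$node_states)
  rng <- range(states)
  if (diff(rng) <= 1e-10 * max(abs(rng), 1)) {
    warning("all states equal; painting a single color", call. = FALSE)
    rng <- rng + c(-0.5, 0.5)
  }
  if (is.null(color_ramp))
    color_ramp <- grDevices::colorRampPalette(
      c("#2166AC", "#8C9FB6", "#B2182B"))
  # symmetric range about `center` so the ramp midpoint is the center value
  half <- max(abs(rng - center))
  pal <- color_ramp(256)
  col_of <- function(s) pal[pmin(256, pmax(1, 1 + floor(
    (s - (center - half)) / (2 * half) * 255)))]

  ape::plot.phylo(tr, edge.color = "transparent", ...)
  lp <- get("last_plot.phylo", envir = ape::.PlotPhyloEnv)
  segs <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    len <- tr$edge.length[e]
    x0 <- lp$xx[p]; x1 <- lp$xx[ch]; yy <- lp$yy[ch]
    ts <- seq(0, len, length.out = segments + 1L)
    st <- vapply(ts, function(t) interpolate_branch(anc_map, e, t), numeric(1))
    mid <- (st[-1L] + st[-length(st)]) / 2
    xs <- seq(x0, x1, length.out = segments + 1L)
    graphics::segments(xs[-length(xs)], yy, xs[-1L], yy,
                       col = col_of(mid), lwd = 3)
    # vertical connector at the parent, colored by the parent state
    graphics::segments(x0, lp$yy[p], x0, yy, col = col_of(node_state(anc_map, p)),
                       lwd = 3)
    segs[[e]] <- data.frame(edge = e, state = mid, color = col_of(mid))
  }
  invisible(do.call(rbind, segs))
}
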