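#' Phylogenetic independent contrasts
#'
#' Felsenstein's contrasts by the standard pruning recursion.  At each internal
#' node with child values \eqn{x_i, x_j} on (variance-adjusted) branches
#' \eqn{v_i, v_j}:
#' contrast \eqn{(x_i - x_j)/\sqrt{v_i + v_j}}; nodal (ancestral) value
#' \eqn{(x_i/v_i + x_j/v_j)/(1/v_i + 1/v_j)}; and the node's own parent branch
#' is lengthened by \eqn{v_i v_j/(v_i + v_j)}.  Standardized contrasts are iid
#' Normal(0, sigma^2) when the trait evolves by Brownian motion with rate
#' sigma^2, which is what makes them usable as independent data points in the
#' allometric regressions.
#'
#' Child order (hence contrast sign) is fixed by the tree's internal edge
#' ordering, so two traits computed on the same tree yield aligned, co-signed
#' contrast pairs.  Zero-length branches (from resolved polytomies) are
#' handled: the nodal value collapses to the zero-branch child and the
#' parent-branch adjustment vanishes; only two zero branches meeting at one
#' node (SD 0) is an error.
#'
#' @param tree a binary [ape::phylo] tree; all branch lengths >= 0.
#' @param tip_values named numeric vector (names = tip labels), or unnamed in
#'   tip order.
#' @param log10_transform take log10 of the values first (requires > 0).
#' @return object of class `"pic_set"`: a `data.frame` with one row per
#'   internal node (`node`, `contrast`, `sd`, `nodal_value`,
#'   `adj_branch_length`), plus attributes `root_value` and `n_tips`.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' compute_contrasts(tr, c(A = 1, B = 3, C = 0))
#' @export
compute_contrasts <- function(tree, tip_values, log10_transform = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_rooted_binary(tree))
    stop("tree has polytomies; resolve them first (see resolve_polytomies())",
         call. = FALSE)
  n <- length(tree$tip.label)
  x <- align_tip_values(tree, tip_values)
  if (anyNA(x)) stop("missing tip value(s): ",
                     paste(tree$tip.label[is.na(x)], collapse = ", "), call. = FALSE)
  if (log10_transform) {
    if (any(x <= 0)) stop("log10 transform needs positive values", call. = FALSE)
    x <- log10(x)
  }

  nnode <- tree$Nnode
  val <- c(x, rep(NA_real_, nnode))
  vadj <- numeric(n + nnode)            # variance-adjusted branch above each node
  edge_len <- tree$edge.length
  po <- ape::reorder.phylo(tree, "postorder")
  # seed adjusted lengths from the original edge matrix
  vadj[tree$edge[, 2L]] <- edge_len

  rows <- list()
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  # postorder over internal nodes: order of last appearance in postorder edges
  node_order <- unique(po$edge[, 1L])
  for (nd in node_order) {
    ch <- kids[[as.character(nd)]]
    stopifnot(length(ch) == 2L)
    vi <- vadj[ch[1L]]; vj <- vadj[ch[2L]]
    vsum <- vi + vj
    if (vsum <= 0)
      stop("both child branches of node ", nd,
           " have zero adjusted length; contrast undefined", call. = FALSE)
    contrast <- (val[ch[1L]] - val[ch[2L]]) / sqrt(vsum)
    if (vi == 0) {
      nodal <- val[ch[1L]]
    } else if (vj == 0) {
      nodal <- val[ch[2L]]
    } else {
      nodal <- (val[ch[1L]] / vi + val[ch[2L]] / vj) / (1 / vi + 1 / vj)
    }
    val[nd] <- nodal
    extra <- if (vi == 0 || vj == 0) 0 else vi * vj / vsum
    vadj[nd] <- vadj[nd] + extra
    rows[[length(rows) + 1L]] <- data.frame(
      node = nd, contrast = contrast, sd = sqrt(vsum),
      nodal_value = nodal, adj_branch_length = vadj[nd])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pic_set", "data.frame"),
            root_value = val[n + 1L], n_tips = n,
            log10_transform = log10_transform)
}

align_tip_values <- function(tree, tip_values) {
  if (!is.null(names(tip_values))) {
    idx <- match(canonical_label(tree$tip.label), canonical_label(names(tip_values)))
    as.numeric(tip_values[idx])
  } else {
    if (length(tip_values) != length(tree$tip.label))
      stop("unnamed tip_values must have one value per tip", call. = FALSE)
    as.numeric(tip_values)
  }
}

#' @export
print.pic_set <- function(x, ...) {
  cat("Phylogenetic independent contrasts: ", nrow(x), " contrasts from ",
      attr(x, "n_tips"), " tips",
      if (isTRUE(attr(x, "log10_transform"))) " (log10 scale)", "\n", sep = "")
  cat("Root (GLS) value: ", format(attr(x, "root_value")), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Brownian-motion rate from standardized contrasts
#'
#' The ML estimator sigma2-hat = mean of squared standardized contrasts.
#'
#' @param contrast_set a `"pic_set"` from [compute_contrasts()], or a numeric
#'   vector of standardized contrasts.
#' @return sigma2 estimate (trait-variance units per unit branch length).
#' @export
estimate_bm_rate <- function(contrast_set) {
  cc <- if (inherits(contrast_set, "pic_set")) contrast_set$contrast else as.numeric(contrast_set)
  if (!length(cc)) stop("no contrasts", call. = FALSE)
  mean(cc^2)
}
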