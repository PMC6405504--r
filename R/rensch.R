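#' Fit phylogenetic caste-pair allometries (Rensch's rule test)
#'
#' The package's central model fit.  For each requested caste pair
#' (response, predictor) it:
#' \enumerate{
#'   \item matches tree tips to trait rows and keeps the taxa with both traits
#'     measured (missing-data pruning is per pair, not global);
#'   \item prunes the tree to those taxa and log10-transforms the sizes;
#'   \item computes Felsenstein's independent contrasts for both traits on the
#'     identical pruned tree, so the contrast pairs are node-aligned;
#'   \item fits a through-origin major-axis regression of the response
#'     contrasts on the predictor contrasts and tests the isometry null
#'     beta = b0 (default 1).
#' }
#' A slope significantly above 1 for male-on-female size is Rensch's rule;
#' significantly below 1 is its converse; otherwise isometry is not rejected.
#' Studentized perpendicular residuals beyond +/-3 are reported (never
#' removed) as an outlier screen.
#'
#' @param traits trait `data.frame` as from [read_trait_table()] (columns
#'   `species`, `worker_mm`, `male_mm`, `queen_mm`, optional `genus`).
#' @param tree an ultrametric [ape::phylo] chronogram covering the taxa.
#' @param pairs list of `c(response, predictor)` caste names drawn from
#'   `"worker"`, `"male"`, `"queen"`; default the three classic comparisons
#'   male~queen, male~worker, queen~worker.
#' @param exclude optional character vector of species to drop before
#'   fitting (e.g. a genus's members for a sensitivity re-run).
#' @param log10_transform log10 the sizes before contrasts (default TRUE).
#' @param through_origin fit MA through the origin (default TRUE, the
#'   standard for contrasts; df = n_contrasts - 1).
#' @param b0 null slope for the isometry test.
#' @param alpha significance level for the verdict labels.
#' @param convention,threshold passed to [ssdi_table()] for the SSD summary.
#' @param rel_tol ultrametricity tolerance ([check_ultrametric()]).
#' @param force proceed even if the tree fails the ultrametricity check.
#' @return an object of class `"rensch"`: list with `fits` (per pair: `ma`
#'   fit, test, contrast sets, taxa used, verdict), `ssdi` (SSD-index table),
#'   `tree`, `call`, and bookkeeping fields.
#' @examples
#' sim <- sim_caste_dataset(sim_config(n_tips = 30, seed = 7))
#' fit <- rensch(sim$traits, sim$tree)
#' fit
#' coef(fit)
#' @export
rensch <- function(traits, tree,
                   pairs = list(c("male", "queen"),
                                c("male", "worker"),
                                c("queen", "worker")),
                   exclude = NULL,
                   log10_transform = TRUE, through_origin = TRUE,
                   b0 = 1, alpha = 0.05,
                   convention = "queen_over_male", threshold = 0.06,
                   rel_tol = 1e-6, force = FALSE) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(traits))
  castes <- c("worker", "male", "queen")
  for (p in pairs)
    if (length(p) != 2L || !all(p %in% castes))
      stop("each pair must be two of: ", paste(castes, collapse = ", "),
           call. = FALSE)
  if (!is.null(exclude)) {
    drop <- canonical_label(traits$species) %in% canonical_label(exclude)
    traits <- traits[!drop, , drop = FALSE]
  }
  mt <- match_tree_traits(tree, traits)
  um <- check_ultrametric(mt$tree, rel_tol)
  if (!um$ultrametric && !force)
    stop("tree is not ultrametric (max relative tip-depth deviation ",
         format(um$max_rel_dev, digits = 3),
         "); pass force = TRUE to proceed", call. = FALSE)
  if (!is_rooted_binary(mt$tree))
    mt$tree <- resolve_polytomies(mt$tree)

  fits <- list()
  for (p in pairs) {
    yc <- p[1L]; xc <- p[2L]
    col_y <- paste0(yc, "_mm"); col_x <- paste0(xc, "_mm")
    ok <- !is.na(mt$traits[[col_y]]) & !is.na(mt$traits[[col_x]])
    if (sum(ok) < 3L)
      stop("pair ", yc, "~", xc, ": fewer than 3 taxa with both traits",
           call. = FALSE)
    taxa <- mt$tree$tip.label[ok]
    tr_p <- prune_to_taxa(mt$tree, taxa)
    tt_p <- mt$traits[match(canonical_label(tr_p$tip.label),
                            canonical_label(mt$traits$species)), ]
    pic_y <- compute_contrasts(tr_p, stats::setNames(tt_p[[col_y]], tr_p$tip.label),
                               log10_transform = log10_transform)
    pic_x <- compute_contrasts(tr_p, stats::setNames(tt_p[[col_x]], tr_p$tip.label),
                               log10_transform = log10_transform)
    fit <- ma_fit(pic_x$contrast, pic_y$contrast, through_origin = through_origin)
    tst <- ma_slope_test(fit, b0 = b0)
    verdict <- if (tst$p < alpha) {
      if (fit$slope > b0) "Rensch" else "converse-Rensch"
    } else "isometry not rejected"
    stud <- studentized_residuals(fit)
    fits[[paste0(yc, "~", xc)]] <- list(
      response = yc, predictor = xc, taxa = taxa,
      n_taxa = length(taxa), n_contrasts = fit$n,
      ma = fit, test = tst, verdict = verdict,
      pic_response = pic_y, pic_predictor = pic_x,
      outliers = which(abs(stud) > 3))
  }

  ssd <- suppressWarnings(ssdi_table(mt$traits, convention = convention,
                                     threshold = threshold))
  structure(list(fits = fits, ssdi = ssd, tree = mt$tree,
                 traits = mt$traits, b0 = b0, alpha = alpha,
                 through_origin = through_origin,
                 log10_transform = log10_transform,
                 exclude = exclude, call = match.call()),
            class = "rensch")
}

#' @export
print.rensch <- function(x, ...) {
  cat("Phylogenetic caste-pair allometry (through-origin MA on",
      if (x$log10_transform) "log10", "contrasts)\n")
  if (!is.null(x$exclude))
    cat("  excluded taxa:", length(x$exclude), "\n")
  tab <- summary(x)
  print(tab, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Summary table of a Rensch fit
#'
#' @param object a `"rensch"` object.
#' @param ... unused.
#' @return `data.frame` with one row per caste pair: n contrasts, slope, r2,
#'   F, df, p and the verdict at the fit's alpha.
#' @export
summary.rensch <- function(object, ...) {
  do.call(rbind, lapply(names(object$fits), function(nm) {
    f <- object$fits[[nm]]
    data.frame(pair = nm, n_taxa = f$n_taxa, n_contrasts = f$n_contrasts,
               slope = f$ma$slope, r2 = f$ma$r2,
               F = f$test$F, df = f$test$df, p = f$test$p,
               verdict = f$verdict, stringsAsFactors = FALSE)
  }))
}

#' @export
coef.rensch <- function(object, ...) {
  vapply(object$fits, function(f) f$ma$slope, numeric(1))
}

#' @export
plot.rensch <- function(x, positivize = TRUE, ...) {
  np <- length(x$fits)
  op <- graphics::par(mfrow = c(1, np))
  on.exit(graphics::par(op))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cx <- f$pic_predictor$contrast
    cy <- f$pic_response$contrast
    if (positivize) {
      # flip each pair so the predictor contrast is >= 0 (display only;
      # through-origin MA is invariant to joint sign flips)
      s <- ifelse(cx < 0, -1, 1)
      cx <- cx * s; cy <- cy * s
    }
    graphics::plot(cx, cy,
                   xlab = paste("IC", f$predictor), ylab = paste("IC", f$response),
                   main = nm, ...)
    graphics::abline(0, f$ma$slope)
    graphics::abline(0, x$b0, lty = 2)
  }
  invisible(x)
}

#' SSD-index ancestral reconstruction on the chronogram
#'
#' Computes the SSD index for every taxon with queen and male sizes, prunes
#' the tree accordingly, and reconstructs the index's history by ML under
#' Brownian motion ([ml_ancestral_states()]); [paint_tree()] renders the
#' result.
#'
#' @inheritParams rensch
#' @return list with `anc` (an `"anc_bm"` map), `ssdi` (the index table) and
#'   `tree` (the pruned tree).
#' @export
ssd_reconstruction <- function(traits, tree, convention = "queen_over_male",
                               threshold = 0.06, exclude = NULL,
                               rel_tol = 1e-6, force = FALSE) {
  if (!is.null(exclude)) {
    drop <- canonical_label(traits$species) %in% canonical_label(exclude)
    traits <- traits[!drop, , drop = FALSE]
  }
  mt <- match_tree_traits(tree, traits)
  um <- check_ultrametric(mt$tree, rel_tol)
  if (!um$ultrametric && !force)
    stop("tree is not ultrametric; pass force = TRUE to proceed", call. = FALSE)
  ssd <- suppressWarnings(ssdi_table(mt$traits, convention = convention,
                                     threshold = threshold))
  tr <- prune_to_taxa(mt$tree, ssd$species)
  if (!is_rooted_binary(tr)) tr <- resolve_polytomies(tr)
  anc <- ml_ancestral_states(tr, stats::setNames(ssd$ssdi, ssd$species))
  list(anc = anc, ssdi = ssd, tree = tr)
}

#' Run the full analysis from a configuration
#'
#' Orchestrates the complete pipeline: read the trait table and chronogram,
#' fit all caste-pair allometries, repeat with an exclusion set (by default
#' the genus *Melipona*, the male-biased clade), reconstruct the SSD index's
#' history, and write CSV/JSON outputs.  Outputs are a pure function of the
#' configuration, so re-running reproduces them byte-identically.
#'
#' @param config either a path to a YAML/JSON configuration file or a named
#'   list.  Recognized fields: `traits` (CSV path), `tree` (Newick/NEXUS
#'   path), `dialect`, `exclude_genus` (default `"Melipona"`), `convention`,
#'   `threshold`, `log10_transform`, `through_origin`, `b0`, `rel_tol`,
#'   `force`, `seed`, `out_dir`.  `traits`/`tree` may also be supplied as
#'   in-memory objects when `config` is a list.
#' @return invisibly, a list with `full` and `excluded` `"rensch"` fits, the
#'   `reconstruction`, and the output directory (or `NULL` if none written).
#' @export
rensch_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  get_or <- function(nm, default) if (!is.null(config[[nm]])) config[[nm]] else default

  traits <- config$traits
  if (is.character(traits)) traits <- read_trait_table(traits)
  tree <- config$tree
  if (is.character(tree))
    tree <- read_phylo_tree(tree, dialect = get_or("dialect", "auto"))

  exclude_genus <- get_or("exclude_genus", "Melipona")
  args <- list(traits = traits, tree = tree,
               log10_transform = get_or("log10_transform", TRUE),
               through_origin = get_or("through_origin", TRUE),
               b0 = get_or("b0", 1),
               convention = get_or("convention", "queen_over_male"),
               threshold = get_or("threshold", 0.06),
               rel_tol = get_or("rel_tol", 1e-6),
               force = get_or("force", FALSE))
  full <- suppressWarnings(do.call(rensch, args))
  excluded <- NULL
  if (!is.null(exclude_genus) && !is.null(traits$genus)) {
    excl_species <- traits$species[traits$genus %in% exclude_genus]
    if (length(excl_species))
      excluded <- suppressWarnings(
        do.call(rensch, c(args, list(exclude = excl_species))))
  }
  recon <- suppressWarnings(
    ssd_reconstruction(traits, tree,
                       convention = args$convention,
                       threshold = args$threshold,
                       rel_tol = args$rel_tol, force = args$force))

  out_dir <- get_or("out_dir", NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_outputs(full, excluded, recon, out_dir)
  }
  invisible(list(full = full, excluded = excluded, reconstruction = recon,
                 out_dir = out_dir))
}

write_run_outputs <- function(full, excluded, recon, out_dir) {
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(summary(full), "allometry_full.csv")
  if (!is.null(excluded)) wcsv(summary(excluded), "allometry_excluded.csv")
  wcsv(full$ssdi, "ssdi.csv")
  for (nm in names(full$fits)) {
    f <- full$fits[[nm]]
    wcsv(data.frame(node = f$pic_predictor$node,
                    contrast_x = f$pic_predictor$contrast,
                    contrast_y = f$pic_response$contrast,
                    sd = f$pic_predictor$sd),
         paste0("contrasts_", sub("~", "_on_", nm), ".csv"))
  }
  wcsv(data.frame(node = names(recon$anc$node_states),
                  state = unname(recon$anc$node_states)),
       "ancestral_states.csv")
  res <- lapply(names(full$fits), function(nm) {
    f <- full$fits[[nm]]
    list(pair = nm, n_contrasts = f$n_contrasts, slope = f$ma$slope,
         r2 = f$ma$r2, F = f$test$F, df = f$test$df, p = f$test$p,
         verdict = f$verdict)
  })
  jsonlite::write_json(
    list(results = res,
         category_counts = as.list(attr(full$ssdi, "counts"))),
    file.path(out_dir, "allometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
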