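#' Sexual size dimorphism index
#'
#' The Lovich-Gibbons index expresses dimorphism as
#' (size of larger sex / size of smaller sex) - 1, conventionally signed
#' negative when males are the larger sex.  Two conventions are offered:
#'
#' * `"queen_over_male"`: queen/male - 1.  This is the formula that reproduces
#'   the published stingless-bee table, and is the default.  Note that for
#'   male-biased species it is not numerically identical to the sign-flipped
#'   larger/smaller ratio (e.g. queen 2.158, male 2.556 gives -0.156 here but
#'   -0.184 under `"ratio_signed"`).
#' * `"ratio_signed"`: (larger/smaller - 1), negated when the male is larger —
#'   the index as originally defined.
#'
#' @param queen_mm,male_mm positive sizes (mm); vectorized.
#' @param convention `"queen_over_male"` (default) or `"ratio_signed"`.
#' @return numeric vector of SSD index values (> -1).
#' @examples
#' compute_ssdi(3.75, 2.63)                    # female-biased, 0.4259
#' compute_ssdi(2.158, 2.556)                  # male-biased, -0.1557
#' compute_ssdi(2.158, 2.556, "ratio_signed")  # -0.1844
#' @export
compute_ssdi <- function(queen_mm, male_mm,
                         convention = c("queen_over_male", "ratio_signed")) {
  convention <- match.arg(convention)
  if (any(queen_mm <= 0, na.rm = TRUE) || any(male_mm <= 0, na.rm = TRUE))
    stop("sizes must be > 0", call. = FALSE)
  if (convention == "queen_over_male") {
    queen_mm / male_mm - 1
  } else {
    ifelse(male_mm > queen_mm,
           -(male_mm / queen_mm - 1),
           queen_mm / male_mm - 1)
  }
}

#' Categorize an SSD index value
#'
#' @param ssdi SSD index value(s).
#' @param threshold non-negative half-width of the monomorphic band; values
#'   with `|ssdi| <= threshold` are called monomorphic.  The default 0.06
#'   covers the published "similar-sized" species (max |SSDi| 0.058) but is a
#'   package choice: the source analysis states no explicit cutoff.
#' @return factor with levels `male_biased`, `monomorphic`, `female_biased`.
#' @export
classify_ssd <- function(ssdi, threshold = 0.06) {
  stopifnot(threshold >= 0)
  out <- ifelse(ssdi > threshold, "female_biased",
                ifelse(ssdi < -threshold, "male_biased", "monomorphic"))
  factor(out, levels = c("male_biased", "monomorphic", "female_biased"))
}

#' Mean size of the reproductive castes
#'
#' Arithmetic mean of queen and male sizes — the "species mean thorax width
#' (reproductive individuals only)" column of the published table.
#'
#' @inheritParams compute_ssdi
#' @return numeric vector (mm).
#' @export
species_mean_size <- function(queen_mm, male_mm) {
  if (any(queen_mm <= 0, na.rm = TRUE) || any(male_mm <= 0, na.rm = TRUE))
    stop("sizes must be > 0", call. = FALSE)
  (queen_mm + male_mm) / 2
}

#' SSD index table for a caste trait table
#'
#' Applies [compute_ssdi()], [classify_ssd()] and [species_mean_size()] to every
#' row with both queen and male sizes; rows missing either are skipped with a
#' warning.
#'
#' @param traits trait `data.frame` as from [read_trait_table()].
#' @inheritParams compute_ssdi
#' @inheritParams classify_ssd
#' @return `data.frame` with columns `species`, `ssdi`, `category`,
#'   `species_mean_mm` (and `genus` when available), plus attribute `counts`
#'   (table of category counts).
#' @export
ssdi_table <- function(traits, convention = c("queen_over_male", "ratio_signed"),
                       threshold = 0.06) {
  convention <- match.arg(convention)
  ok <- !is.na(traits$queen_mm) & !is.na(traits$male_mm)
  if (!any(ok)) stop("no rows with both queen and male sizes", call. = FALSE)
  if (any(!ok))
    warning("skipping ", sum(!ok), " row(s) missing queen or male size: ",
            paste(traits$species[!ok], collapse = ", "), call. = FALSE)
  t2 <- traits[ok, , drop = FALSE]
  out <- data.frame(
    species = t2$species,
    ssdi = compute_ssdi(t2$queen_mm, t2$male_mm, convention),
    stringsAsFactors = FALSE
  )
  out$category <- classify_ssd(out$ssdi, threshold)
  out$species_mean_mm <- species_mean_size(t2$queen_mm, t2$male_mm)
  if (!is.null(t2$genus)) out$genus <- t2$genus
  attr(out, "counts") <- table(out$category)
  attr(out, "convention") <- convention
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}
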