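fixture_run <- function(...) {
  traits <- read_trait_table(fixture_traits_path())
  tree <- fixture_stand_in_tree()
  suppressWarnings(rensch(traits, tree, ...))
}

test_that("per-pair missing-data pruning gives the expected contrast counts", {
  fit <- fixture_run()
  expect_equal(fit$fits[["male~queen"]]$n_taxa, 44L)
  expect_equal(fit$fits[["male~queen"]]$n_contrasts, 43L)
  expect_equal(fit$fits[["male~queen"]]$test$df, 42L)
  # 3 taxa lack worker sizes (the two solitary Euglossini and T. extranea)
  expect_equal(fit$fits[["male~worker"]]$n_taxa, 41L)
  expect_equal(fit$fits[["male~worker"]]$n_contrasts, 40L)
  expect_equal(fit$fits[["male~worker"]]$test$df, 39L)
  expect_equal(fit$fits[["queen~worker"]]$test$df, 39L)
  # df bookkeeping for through-origin contrast fits:
  # contrasts = taxa - 1, df = contrasts - 1 = taxa - 2
  for (f in fit$fits)
    expect_equal(f$test$df, f$n_taxa - 2L)
})

test_that("excluding the male-biased genus removes exactly its 12 taxa", {
  traits <- read_trait_table(fixture_traits_path())
  excl <- traits$species[traits$genus == "Melipona"]
  fit <- fixture_run(exclude = excl)
  expect_equal(fit$fits[["male~queen"]]$n_taxa, 32L)
  expect_equal(fit$fits[["male~queen"]]$n_contrasts, 31L)
  expect_false(any(excl %in% fit$fits[["male~queen"]]$taxa))
})

test_that("rensch objects expose summaries, coefficients and plots", {
  fit <- fixture_run()
  s <- summary(fit)
  expect_equal(nrow(s), 3L)
  expect_true(all(c("pair", "slope", "r2", "F", "df", "p", "verdict") %in% names(s)))
  expect_true(all(s$p >= 0 & s$p <= 1))
  expect_named(coef(fit), c("male~queen", "male~worker", "queen~worker"))
  expect_output(print(fit), "caste-pair allometry")
  tf <- tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(tf))
})

test_that("positivization of contrast pairs does not move through-origin fits", {
  fit <- fixture_run()
  f <- fit$fits[["male~queen"]]
  cx <- f$pic_predictor$contrast; cy <- f$pic_response$contrast
  s <- ifelse(cx < 0, -1, 1)
  flipped <- ma_fit(cx * s, cy * s, through_origin = TRUE)
  expect_equal(flipped$slope, f$ma$slope, tolerance = 1e-12)
  expect_equal(flipped$r2, f$ma$r2, tolerance = 1e-12)
})

test_that("guard rails: small overlap, non-ultrametric trees, bad pairs", {
  traits <- read_trait_table(fixture_traits_path())
  tree <- fixture_stand_in_tree()
  expect_error(rensch(traits, tree, pairs = list(c("male", "wing"))),
               "each pair")
  t2 <- traits
  t2$worker_mm[!is.na(t2$worker_mm)][-(1:2)] <- NA
  expect_error(suppressWarnings(
    rensch(t2, tree, pairs = list(c("male", "worker")))), "fewer than 3")
  bumpy <- tree
  bumpy$edge.length[1] <- bumpy$edge.length[1] + 0.5
  expect_error(suppressWarnings(rensch(traits, bumpy)), "not ultrametric")
  fit <- suppressWarnings(rensch(traits, bumpy, force = TRUE))
  expect_s3_class(fit, "rensch")
})

test_that("SSD reconstruction runs full, single-clade and two-taxon cases", {
  traits <- read_trait_table(fixture_traits_path())
  tree <- fixture_stand_in_tree()
  rec <- suppressWarnings(ssd_reconstruction(traits, tree))
  expect_equal(length(rec$tree$tip.label), 44L)
  expect_equal(length(rec$anc$node_states), 43L)

  # Melipona only: every tip SSDi < 0, so every reconstructed node is < 0
  mel <- traits[traits$genus == "Melipona", ]
  rec_m <- suppressWarnings(ssd_reconstruction(mel, tree))
  expect_true(all(rec_m$anc$node_states < 0))

  # two-taxon run: root is the equal-branch mean of the two indices
  two <- traits[traits$species %in% c("Melipona beecheii",
                                      "Cephalotrigona capitata"), ]
  rec2 <- suppressWarnings(ssd_reconstruction(two, tree))
  expect_equal(unname(rec2$anc$node_states),
               mean(compute_ssdi(two$queen_mm, two$male_mm)), tolerance = 1e-12)
})

test_that("the config-driven pipeline reproduces itself byte for byte", {
  tree <- fixture_stand_in_tree()
  tree_path <- tempfile(fileext = ".nwk")
  writeLines(write_tree_text(tree), tree_path)
  cfg <- list(traits = fixture_traits_path(), tree = tree_path,
              exclude_genus = "Melipona")
  out1 <- tempfile(); out2 <- tempfile()
  cfg$out_dir <- out1
  res1 <- rensch_pipeline(cfg)
  cfg$out_dir <- out2
  res2 <- rensch_pipeline(cfg)

  files <- list.files(out1)
  expect_true(all(c("allometry_full.csv", "allometry_excluded.csv", "ssdi.csv",
                    "allometry.json", "ancestral_states.csv") %in% files))
  for (f in files)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  # excluded run drops exactly the excluded genus
  expect_equal(res1$excluded$fits[["male~queen"]]$n_taxa, 32L)
  expect_equal(sort(setdiff(res1$full$fits[["male~queen"]]$taxa,
                            res1$excluded$fits[["male~queen"]]$taxa)),
               sort(read_trait_table(fixture_traits_path())$species[
                 read_trait_table(fixture_traits_path())$genus == "Melipona"]))

  # YAML config file path works the same way
  ycfg <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(traits = fixture_traits_path(), tree = tree_path,
                        out_dir = tempfile()), ycfg)
  res3 <- rensch_pipeline(ycfg)
  expect_equal(summary(res3$full)$slope, summary(res1$full)$slope)
})
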