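small_config <- function(...) {
  study_config(n_fish_per_stratum = 12L, seed = 777L, ...)
}

test_that("the generator is deterministic for a fixed config and seed", {
  s1 <- generate_study(small_config())
  s2 <- generate_study(small_config())
  expect_identical(s1$fish, s2$fish)
  expect_identical(s1$gut, s2$gut)
  expect_identical(s1$otu_coi$counts, s2$otu_coi$counts)
  expect_identical(s1$otu_rbcl$counts, s2$otu_rbcl$counts)
  expect_identical(s1$isotopes, s2$isotopes)
  s3 <- generate_study(study_config(n_fish_per_stratum = 12L, seed = 778L))
  expect_false(identical(s1$gut, s3$gut))
})

test_that("configuration errors are caught with diagnostics", {
  expect_error(study_config(n_fish_per_stratum = 0), "positive")
  bad <- default_isotope_params()
  bad[["anchovy|GSA07"]]$cov <- matrix(c(1, 2, 2, 1), 2)  # not PD
  expect_error(study_config(isotope_params = bad), "positive-definite")
  conc <- default_concentrations()
  conc[[1]][1] <- -1
  expect_error(study_config(concentrations = conc), "strictly positive")
})

test_that("tables are consistent: ids resolve and counts are integers", {
  s <- generate_study(small_config())
  expect_true(all(rownames(s$gut) %in% s$fish$fish_id))
  expect_true(all(colnames(s$otu_coi$counts) %in% s$fish$fish_id))
  expect_true(all(s$isotopes$fish_id %in% s$fish$fish_id))
  expect_true(all(s$gut >= 0))
  expect_true(all(s$gut == round(s$gut)))
  expect_true(all(s$otu_coi$counts >= 0))
  # Dirichlet proportions are normalized per fish
  expect_equal(unname(rowSums(s$ground_truth$group_proportions)),
               rep(1, nrow(s$fish)))
  # stages are consistent with the classification rule
  expect_identical(s$fish$stage,
                   classify_stage(s$fish$species, s$fish$total_length_cm))
  # the northernmost stratum holds juveniles only
  expect_true(all(s$fish$stage[s$fish$area == "GSA07"] == "juvenile"))
})

test_that("delta15N is depressed in the north for both species", {
  s <- default_study()  # 30 fish per stratum
  iso <- merge(s$isotopes, s$fish, by = "fish_id")
  for (sp in c("anchovy", "sardine")) {
    north <- mean(iso$delta15N[iso$species == sp & iso$area == "GSA07"])
    south <- mean(iso$delta15N[iso$species == sp &
                                 iso$area == "GSA06-South"])
    expect_lt(north, south)
  }
})

test_that("southern krill enrichment shows up in directly tabulated %N", {
  s <- generate_study(study_config(
    seed = 555L, concentrations = default_concentrations(krill_south_factor = 5)))
  krill_taxa <- s$taxonomy$taxon[s$taxonomy$group %in%
                                   c("Euphausiacea", "Decapoda",
                                     "OtherMalacostraca")]
  pct_krill <- function(ar) {
    sub <- s$gut[s$fish$fish_id[s$fish$area == ar], , drop = FALSE]
    100 * sum(sub[, krill_taxa]) / sum(sub)
  }
  expect_gt(pct_krill("GSA06-South"), pct_krill("GSA07"))
})

test_that("isotope sample moments converge to the configured values", {
  cfg <- default_isotope_params()[["anchovy|GSA06-North"]]
  errs <- vapply(c(50L, 450L), function(n) {
    s <- generate_study(study_config(n_fish_per_stratum = n, seed = 31L))
    iso <- merge(s$isotopes, s$fish, by = "fish_id")
    sel <- iso$species == "anchovy" & iso$area == "GSA06-North"
    # remove the configured length effect before comparing with the mean
    d15 <- iso$delta15N[sel] -
      cfg$length_slope[["d15N"]] * (iso$total_length_cm[sel] - 12)
    abs(mean(d15) - cfg$mean[["d15N"]])
  }, numeric(1L))
  # tolerance shrinking as 1/sqrt(n): generous 4-sigma bands
  expect_lt(errs[1L], 4 * sqrt(cfg$cov[1, 1] / 50))
  expect_lt(errs[2L], 4 * sqrt(cfg$cov[1, 1] / 450))
})

test_that("injected mistag reads sit below the per-sample threshold", {
  s <- default_study()
  gt <- s$ground_truth$mistag_cells
  expect_gt(nrow(gt), 0)
  m <- s$otu_coi$counts
  stot <- colSums(m)
  fr <- vapply(seq_len(nrow(gt)), function(i)
    100 * m[gt$otu[i], gt$sample[i]] / stot[gt$sample[i]], numeric(1L))
  expect_true(all(fr < 0.01))
  # rare OTUs sit below the global threshold
  expect_true(all(100 * rowSums(m)[s$ground_truth$rare_otus] / sum(m) <
                    0.005))
})

test_that("study tables round-trip to tab-delimited text", {
  s <- generate_study(small_config())
  dir <- tempfile("study")
  files <- write_study(s, dir)
  expect_true(all(file.exists(files)))
  fish <- read.delim(file.path(dir, "fish_metadata.tsv"))
  expect_equal(nrow(fish), nrow(s$fish))
  gut <- read.delim(file.path(dir, "gut_counts.tsv"), check.names = FALSE)
  expect_equal(unname(as.matrix(gut[-1])), unname(s$gut))
  otu <- read.delim(file.path(dir, "otu_coi.tsv"), check.names = FALSE)
  expect_equal(names(otu)[length(otu)], "taxonomy")
})
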