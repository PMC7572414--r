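test_that("stage classification uses strict species-specific length cut-offs", {
  expect_equal(classify_stage("anchovy", 10.9), "juvenile")
  expect_equal(classify_stage("anchovy", 11.0), "adult")
  expect_equal(classify_stage("sardine", 12.9), "juvenile")
  expect_equal(classify_stage("sardine", 13.0), "adult")
  expect_equal(classify_stage(c("anchovy", "sardine"), c(12, 12)),
               c("adult", "juvenile"))
  expect_error(classify_stage("herring", 10), "unknown species")
  expect_error(classify_stage("anchovy", -1), "positive")
})

test_that("biomass conversion multiplies counts by resolved unit weights", {
  tax <- toy_taxonomy()
  m <- matrix(c(3L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("copepod_a", "krill_a")))
  bio <- counts_to_biomass(m, c(copepod_a = 0.005, krill_a = 5), tax)
  expect_equal(bio["f1", "copepod_a"], 0.015)
  expect_equal(unname(bio["f2", ]), c(0, 0))  # all-zero row stays zero
  prov <- attr(bio, "provenance")
  expect_equal(prov$level, c("taxon", "taxon"))
})

test_that("biomass fallback walks species -> genus -> family -> group and logs it", {
  tax <- toy_taxonomy()
  m <- matrix(2L, 1, 1, dimnames = list("f1", "copepod_b"))
  # no species-level entry; genus-level value must be used
  bio <- counts_to_biomass(m, c(Oithona = 0.01), tax)
  expect_equal(bio[1, 1], 0.02)
  expect_equal(attr(bio, "provenance")$level, "genus")
  # family level next
  bio2 <- counts_to_biomass(m, c(Oithonidae = 0.02), tax)
  expect_equal(attr(bio2, "provenance")$level, "family")
  # unresolvable taxon names the offender
  expect_error(counts_to_biomass(m, c(something_else = 1), tax),
               "copepod_b")
})

test_that("SFD is total prey weight (mg) over fish length (mm)", {
  tax <- toy_taxonomy()
  lk <- c(copepod_a = 5, krill_a = 5)
  row <- c(copepod_a = 1, krill_a = 1)      # 2 prey x 5 mg
  expect_equal(compute_sfd(row, 10, lk, tax), 0.1)  # 10 mg / 100 mm
  expect_equal(compute_sfd(c(copepod_a = 0, krill_a = 0), 10, lk, tax), 0)
  expect_error(compute_sfd(row, 0, lk, tax), "positive")
})

test_that("SFD is conserved when a taxon is split at equal unit biomass", {
  tax <- rbind(toy_taxonomy(),
               data.frame(taxon = "copepod_a2", genus = "Calanus",
                          family = "Calanidae", group = "Calanoids"))
  lk <- c(copepod_a = 0.3, copepod_a2 = 0.3, krill_a = 5)
  whole <- compute_sfd(c(copepod_a = 10, krill_a = 2), 12, lk, tax)
  split <- compute_sfd(c(copepod_a = 6, copepod_a2 = 4, krill_a = 2), 12,
                       lk, tax)
  expect_equal(split, whole)
})

test_that("single-fish composition matches hand arithmetic", {
  tax <- toy_taxonomy()
  fish <- toy_fish(1)
  gut <- matrix(c(3L, 1L), 1, 2,
                dimnames = list("f1", c("copepod_a", "krill_a")))
  pN <- composition_summary(gut, fish, "N", tax)
  expect_equal(pN$value[pN$group == "Calanoids"], 75)
  expect_equal(pN$value[pN$group == "Euphausiacea"], 25)
  pB <- composition_summary(gut, fish, "B", tax,
                            c(copepod_a = 0.005, krill_a = 5))
  expect_equal(pB$value[pB$group == "Euphausiacea"], 100 * 5 / 5.015)
  # occurrence: group present in 2 of 10 fish -> 20%
  fish10 <- toy_fish(10)
  gut10 <- matrix(0L, 10, 2,
                  dimnames = list(fish10$fish_id,
                                  c("copepod_a", "krill_a")))
  gut10[, "copepod_a"] <- 1L
  gut10[1:2, "krill_a"] <- 4L
  pFO <- composition_summary(gut10, fish10, "FO", tax)
  expect_equal(pFO$value[pFO$group == "Euphausiacea"], 20)
  expect_equal(pFO$value[pFO$group == "Calanoids"], 100)
})

test_that("percentages sum to 100 per stratum and ignore fish order", {
  study <- default_study()
  for (lev in c("N", "B")) {
    comp <- composition_summary(study$gut, study$fish, lev, study$taxonomy,
                                study$biomass_lookup)
    sums <- tapply(comp$value, paste(comp$species, comp$area), sum)
    expect_true(all(abs(sums - 100) < 1e-9))
  }
  perm <- sample(nrow(study$gut))
  comp1 <- composition_summary(study$gut, study$fish, "N", study$taxonomy)
  comp2 <- composition_summary(study$gut[perm, ], study$fish, "N",
                               study$taxonomy)
  expect_equal(comp1, comp2)
})

test_that("%FO from counts equals %FO from the presence/absence reduction", {
  study <- default_study()
  pres <- (study$gut > 0) * 1L
  a <- composition_summary(study$gut, study$fish, "FO", study$taxonomy)
  b <- composition_summary(pres, study$fish, "FO", study$taxonomy)
  expect_equal(a, b)
})

test_that("parasite-flagged taxa are rejected", {
  tax <- rbind(toy_taxonomy(),
               data.frame(taxon = "trematode", genus = NA, family = NA,
                          group = "parasite"))
  gut <- matrix(1L, 1, 1, dimnames = list("f1", "trematode"))
  expect_error(composition_summary(gut, toy_fish(1), "N", tax), "parasite")
})

test_that("adults feed more intensely than juveniles in the default study", {
  study <- default_study()
  sfd <- sfd_table(study$gut, study$fish, study$biomass_lookup,
                   study$taxonomy)
  stage <- study$fish$stage[match(sfd$fish_id, study$fish$fish_id)]
  expect_gt(mean(sfd$sfd[stage == "adult"]),
            mean(sfd$sfd[stage == "juvenile"]))
})
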