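# Fixtures are built in code. The heavier shared objects (a default synthetic
# study and a full pipeline run) are computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_study <- function() {
  fixture("study", function() generate_study(study_config()))
}

default_pipeline <- function() {
  fixture("pipeline", function() run_pipeline(seed = 1L))
}

# minimal gut-content world: two prey taxa with very different unit weights
toy_taxonomy <- function() {
  data.frame(
    taxon = c("copepod_a", "copepod_b", "krill_a"),
    genus = c("Calanus", "Oithona", "Euphausia"),
    family = c("Calanidae", "Oithonidae", "Euphausiidae"),
    group = c("Calanoids", "Cyclopoids", "Euphausiacea"),
    stringsAsFactors = FALSE)
}

toy_lookup <- function() {
  c(copepod_a = 0.005, copepod_b = 0.004, krill_a = 5)
}

toy_fish <- function(n = 1L, species = "anchovy", length_cm = 10,
                     area = "A1", site = "s1") {
  data.frame(fish_id = paste0("f", seq_len(n)), species = species,
             area = area, site_id = site, latitude = 40, depth = 50,
             total_length_cm = length_cm,
             stage = classify_stage(rep(species, n), rep(length_cm, n))[1L],
             stringsAsFactors = FALSE)
}

# Deterministic 50-OTU x 20-sample table with hand-placed cells at, above and
# strictly below both frequency thresholds (total reads exactly 100,000):
#  - OTU_R1..R3: 4 reads each (0.004% of the dataset, below the 0.005% global
#    threshold); OTU_R4: 5 reads (exactly 0.005%, retained)
#  - OTU_M1: 1 read in S01 whose total is exactly 10,000 (0.01% exactly,
#    retained) plus 10 reads in S05; OTU_M2: 1 read in S02 (total 20,000, so
#    0.005%, removed as mistagging) plus 10 reads in S06
#  - OTU_U1/U2: unassigned taxonomy (30 + 40 reads)
#  - OTU_E (Engraulis): 500 reads in anchovy sample S01 (zeroed), 300 in
#    sardine sample S11 (kept); OTU_S (Sardina): 400 in sardine S12 (zeroed),
#    200 in anchovy S02 (kept)
#  - OTU_T: 19 reads, the only content of sample S20 (dropped at the <20 rule)
#  - 20 all-zero padding OTUs (removed with the global-frequency step)
toy_filter_table <- function() {
  samples <- sprintf("S%02d", 1:20)
  hosts <- rep(c("anchovy", "sardine"), each = 10L)
  fillers <- sprintf("OTU_F%02d", 1:19)
  otus <- c(fillers, "OTU_E", "OTU_S", "OTU_M1", "OTU_M2",
            sprintf("OTU_R%d", 1:4), "OTU_U1", "OTU_U2", "OTU_T",
            sprintf("OTU_Z%02d", 1:20))
  m <- matrix(0L, length(otus), length(samples),
              dimnames = list(otus, samples))
  m["OTU_F01", "S01"] <- 9499L;  m["OTU_E", "S01"] <- 500L
  m["OTU_M1", "S01"] <- 1L                       # S01 total 10,000
  m["OTU_F02", "S02"] <- 19794L; m["OTU_S", "S02"] <- 200L
  m["OTU_R4", "S02"] <- 5L; m["OTU_M2", "S02"] <- 1L  # S02 total 20,000
  m["OTU_F03", "S03"] <- 2958L; m["OTU_U1", "S03"] <- 30L
  m[sprintf("OTU_R%d", 1:3), "S03"] <- 4L        # S03 total 3,000
  m["OTU_F04", "S04"] <- 2960L; m["OTU_U2", "S04"] <- 40L
  m["OTU_F05", "S05"] <- 4450L; m["OTU_M1", "S05"] <- 10L
  m["OTU_F06", "S06"] <- 4450L; m["OTU_M2", "S06"] <- 10L
  for (i in 7:10) m[sprintf("OTU_F%02d", i), sprintf("S%02d", i)] <- 4460L
  m["OTU_F11", "S11"] <- 2700L; m["OTU_E", "S11"] <- 300L
  m["OTU_F12", "S12"] <- 2600L; m["OTU_S", "S12"] <- 400L
  for (i in 13:18) m[sprintf("OTU_F%02d", i), sprintf("S%02d", i)] <- 4460L
  m["OTU_F19", "S19"] <- 4461L
  m["OTU_T", "S20"] <- 19L
  stopifnot(sum(m) == 100000L)
  tax <- setNames(sprintf("Calanoida;Fam;Gen;Gen sp%02d", seq_along(otus)),
                  otus)
  tax["OTU_E"] <- "Actinopterygii;Engraulidae;Engraulis;Engraulis encrasicolus"
  tax["OTU_S"] <- "Actinopterygii;Clupeidae;Sardina;Sardina pilchardus"
  tax[c("OTU_U1", "OTU_U2")] <- "unassigned"
  otu_table(m, tax, marker = "COI", host_species = hosts)
}
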