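# Synthetic multi-proxy study generator. Emulates the *downstream* tables of
# a two-species (anchovy/sardine), three-area latitudinal diet study: fish
# metadata, zero-inflated Dirichlet-multinomial gut counts with a
# north-to-south shift from copepod-dominated to krill-enriched diets, COI
# and rbcL OTU read tables with rare-OTU and mistagging noise, and
# bivariate-normal isotope values with lower delta15N in the north plus a
# fish-length effect. Ground truth (configured gradients, injected noise
# cells) is retained for recovery tests.

default_prey_taxa <- function() {
  # taxon, genus, family, group, unit wet weight (mg/individual)
  tab <- read.delim(text = "taxon\tgenus\tfamily\tgroup\tbiomass_mg
Calanus helgolandicus\tCalanus\tCalanidae\tCalanoids\t0.05
Paracalanus parvus\tParacalanus\tParacalanidae\tCalanoids\t0.02
Oithona similis\tOithona\tOithonidae\tCyclopoids\t0.01
Corycaeus sp1\tCorycaeus\tCorycaeidae\tCyclopoids\t0.012
Microsetella rosea\tMicrosetella\tEctinosomatidae\tHarpacticoids\t0.008
Euterpina acutifrons\tEuterpina\tTachidiidae\tHarpacticoids\t0.009
Euphausia krohni\tEuphausia\tEuphausiidae\tEuphausiacea\t25
Nyctiphanes couchii\tNyctiphanes\tEuphausiidae\tEuphausiacea\t12
Solenocera membranacea\tSolenocera\tSolenoceridae\tDecapoda\t15
Decapod zoea\tNA\tNA\tDecapoda\t8
Themisto sp1\tThemisto\tHyperiidae\tOtherMalacostraca\t6
Mysid juvenile\tNA\tMysidae\tOtherMalacostraca\t3
Crustacean fragments\tNA\tNA\tCrustaceanRemains\t0.5
Limacina sp1\tLimacina\tLimacinidae\tMollusca\t0.15
Bivalve larva\tNA\tNA\tMollusca\t0.4
Evadne nordmanni\tEvadne\tPodonidae\tCladocerans\t0.02
Penilia avirostris\tPenilia\tSididae\tCladocerans\t0.025
Fish egg\tNA\tNA\tActinopterygii\t1.5
Fish larva\tNA\tNA\tActinopterygii\t4
Magelona sp1\tMagelona\tMagelonidae\tOthers\t0.6
Hydrozoan fragment\tNA\tNA\tOthers\t0.8",
                    stringsAsFactors = FALSE)
  tab$genus[tab$genus == "NA"] <- NA_character_
  tab$family[tab$family == "NA"] <- NA_character_
  tab
}

prey_groups <- function() {
  c("Calanoids", "Cyclopoids", "Harpacticoids", "Euphausiacea", "Decapoda",
    "OtherMalacostraca", "CrustaceanRemains", "Mollusca", "Cladocerans",
    "Actinopterygii", "Others")
}

# Dirichlet concentrations per (species, area, stage) over the 11 prey
# groups. Copepods dominate numerically everywhere; the krill groups
# (Euphausiacea, Decapoda, OtherMalacostraca) are enriched 5x in the south
# and depleted in the north, so krill dominates the southern biomass; fish
# eggs/larvae and molluscs carry the northern biomass; the two species
# diverge in the north and converge in the south.
default_concentrations <- function(krill_south_factor = 5) {
  g <- prey_groups()
  base <- c(Calanoids = 12, Cyclopoids = 3, Harpacticoids = 2,
            Euphausiacea = 0.8, Decapoda = 0.6, OtherMalacostraca = 0.6,
            CrustaceanRemains = 1, Mollusca = 0.8, Cladocerans = 0.8,
            Actinopterygii = 0.4, Others = 0.5)[g]
  krill <- c("Euphausiacea", "Decapoda", "OtherMalacostraca")
  out <- list()
  for (sp in c("anchovy", "sardine")) for (ar in default_areas()$area)
    for (st in c("juvenile", "adult")) {
      a <- base
      mult <- switch(ar, "GSA07" = 0.1, "GSA06-North" = 1.5,
                     "GSA06-South" = krill_south_factor)
      a[krill] <- a[krill] * mult
      if (ar == "GSA07") {
        a["Actinopterygii"] <- a["Actinopterygii"] * 5
        a["Mollusca"] <- a["Mollusca"] * 1.5
        if (sp == "anchovy") {
          a["OtherMalacostraca"] <- a["OtherMalacostraca"] * 4
          a["Cladocerans"] <- a["Cladocerans"] * 0.2
        } else {
          a["Calanoids"] <- a["Calanoids"] * 1.4
          a["Actinopterygii"] <- a["Actinopterygii"] * 1.5
          a["Euphausiacea"] <- a["Euphausiacea"] * 0.2
        }
      }
      if (st == "juvenile") {
        cope <- c("Calanoids", "Cyclopoids", "Harpacticoids")
        a[cope] <- a[cope] * 1.3
        a[krill] <- a[krill] * 0.5
      }
      out[[paste(sp, ar, st, sep = "|")]] <- a
    }
  out
}

default_areas <- function() {
  data.frame(area = c("GSA07", "GSA06-North", "GSA06-South"),
             latitude = c(42.5, 40.0, 37.8),
             stringsAsFactors = FALSE)
}

# total-length ranges (cm) per species x area x stage; the northernmost area
# holds juveniles only for both species
default_length_ranges <- function() {
  rbind(
    data.frame(species = "anchovy", area = "GSA07", stage = "juvenile",
               lo = 8.5, hi = 10.9),
    data.frame(species = "anchovy", area = "GSA06-North", stage = "juvenile",
               lo = 8.9, hi = 10.9),
    data.frame(species = "anchovy", area = "GSA06-North", stage = "adult",
               lo = 11.0, hi = 14.8),
    data.frame(species = "anchovy", area = "GSA06-South", stage = "juvenile",
               lo = 9.2, hi = 10.9),
    data.frame(species = "anchovy", area = "GSA06-South", stage = "adult",
               lo = 11.0, hi = 16.2),
    data.frame(species = "sardine", area = "GSA07", stage = "juvenile",
               lo = 9.6, hi = 12.8),
    data.frame(species = "sardine", area = "GSA06-North", stage = "juvenile",
               lo = 7.8, hi = 12.9),
    data.frame(species = "sardine", area = "GSA06-North", stage = "adult",
               lo = 13.0, hi = 16.9),
    data.frame(species = "sardine", area = "GSA06-South", stage = "juvenile",
               lo = 8.5, hi = 12.9),
    data.frame(species = "sardine", area = "GSA06-South", stage = "adult",
               lo = 13.0, hi = 17.8))
}

# per-(species, area) isotope parameters: mean (d15N, d13C) in permil,
# covariance, and per-cm length slopes; d15N is depressed in the north
default_isotope_params <- function() {
  mk <- function(m15, m13) list(
    mean = c(d15N = m15, d13C = m13),
    cov = matrix(c(0.35, 0.05, 0.05, 0.25), 2L, 2L,
                 dimnames = list(c("d15N", "d13C"), c("d15N", "d13C"))),
    length_slope = c(d15N = 0.04, d13C = 0.02))
  list("anchovy|GSA07" = mk(8.2, -19.3),
       "anchovy|GSA06-North" = mk(8.9, -18.9),
       "anchovy|GSA06-South" = mk(9.5, -18.5),
       "sardine|GSA07" = mk(8.4, -19.2),
       "sardine|GSA06-North" = mk(9.2, -18.8),
       "sardine|GSA06-South" = mk(9.6, -18.4))
}

#' Configuration of a synthetic multi-proxy study
#'
#' Bundles every parameter of the generator: stratum sizes, the ordered
#' (north to south) area list with representative latitudes, the prey taxon
#' list with group labels and per-individual biomass, Dirichlet
#' concentrations per (species, area, stage) over the 11 prey groups, the
#' total-count distribution, OTU-noise settings, and per-(species, area)
#' isotope parameters. The defaults encode the study conditions the package
#' is designed around: copepod-dominated numerical diets everywhere, krill
#' (euphausiids, decapods, other malacostracans) enriched 5-fold in the
#' southern stratum so it dominates the southern biomass, northern biomass
#' carried by fish eggs/larvae, species diverging in the north and converging
#' in the south, and delta15N depressed in the northernmost area.
#'
#' @param n_fish_per_stratum fish per species-area stratum (default 30).
#' @param areas data.frame \code{area}, \code{latitude}, ordered north to
#'   south.
#' @param species character vector of predator species.
#' @param prey_taxa data.frame taxon, genus, family, group, biomass_mg.
#' @param concentrations named list (\code{"species|area|stage"}) of strictly
#'   positive Dirichlet concentration vectors over the prey groups.
#' @param total_count_meanlog,total_count_sdlog log-normal parameters of the
#'   per-fish total prey count, by stage (named vectors).
#' @param p_empty probability of an empty stomach (zero inflation).
#' @param n_sites_per_area sampling sites per area (default 3).
#' @param otu_noise list: \code{n_rare_otus}, \code{rare_max_reads},
#'   \code{mistags_per_sample}, \code{read_lambda} (Poisson mean reads per
#'   present prey taxon), \code{predator_lambda}, \code{rbcl_read_lambda}.
#' @param isotope_params named list (\code{"species|area"}) with \code{mean}
#'   (d15N, d13C), \code{cov} (2x2 SPD), \code{length_slope}.
#' @param length_ranges data.frame of total-length ranges per
#'   species/area/stage.
#' @param juvenile_fraction fraction of juveniles in strata that hold both
#'   stages (default 0.5).
#' @param seed integer seed governing every sub-generator through
#'   independent child streams.
#' @return validated object of class \code{study_config}.
#' @export
study_config <- function(n_fish_per_stratum = 30L,
                         areas = default_areas(),
                         species = c("anchovy", "sardine"),
                         prey_taxa = default_prey_taxa(),
                         concentrations = default_concentrations(),
                         total_count_meanlog = c(juvenile = log(30),
                                                 adult = log(60)),
                         total_count_sdlog = c(juvenile = 0.5, adult = 0.5),
                         p_empty = 0.08,
                         n_sites_per_area = 3L,
                         otu_noise = list(n_rare_otus = 8L,
                                          rare_max_reads = 40L,
                                          mistags_per_sample = 2L,
                                          read_lambda = 2000,
                                          predator_lambda = 4000,
                                          rbcl_read_lambda = 1500),
                         isotope_params = default_isotope_params(),
                         length_ranges = default_length_ranges(),
                         juvenile_fraction = 0.5,
                         seed = 20180501L) {
  cfg <- structure(
    list(n_fish_per_stratum = as.integer(n_fish_per_stratum), areas = areas,
         species = species, prey_taxa = prey_taxa,
         concentrations = concentrations,
         total_count_meanlog = total_count_meanlog,
         total_count_sdlog = total_count_sdlog, p_empty = p_empty,
         n_sites_per_area = as.integer(n_sites_per_area),
         otu_noise = otu_noise, isotope_params = isotope_params,
         length_ranges = length_ranges,
         juvenile_fraction = juvenile_fraction, seed = as.integer(seed)),
    class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  if (cfg$n_fish_per_stratum < 1L)
    stop("n_fish_per_stratum must be positive")
  g <- prey_groups()
  for (nm in names(cfg$concentrations)) {
    a <- cfg$concentrations[[nm]]
    if (any(!is.finite(a)) || any(a <= 0))
      stop("Dirichlet concentrations must be strictly positive (", nm, ")")
    if (!setequal(names(a), unique(cfg$prey_taxa$group)))
      stop("concentration vector ", nm,
           " does not cover the prey groups of prey_taxa")
  }
  for (nm in names(cfg$isotope_params)) {
    S <- cfg$isotope_params[[nm]]$cov
    if (!isTRUE(all.equal(S, t(S), check.attributes = FALSE)))
      stop("isotope covariance not symmetric (", nm, ")")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stop("isotope covariance not positive-definite (", nm, ")")
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic study configuration\n  %d fish per stratum; %d areas (%s); species: %s\n  %d prey taxa in %d groups; seed = %d\n",
    x$n_fish_per_stratum, nrow(x$areas),
    paste(x$areas$area, collapse = " > "),
    paste(x$species, collapse = ", "),
    nrow(x$prey_taxa), length(unique(x$prey_taxa$group)), x$seed))
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic multi-proxy study
#'
#' Draws, under independent child seed streams of \code{config$seed}:
#' fish metadata (sites, latitudes, depths, stage-specific lengths); gut
#' counts as zero-inflated multinomials with Dirichlet-drawn group
#' proportions and a log-normal total count; a COI OTU read table built from
#' true diet presence with Poisson read depths, predator-genus reads in
#' every sample, injected rare OTUs kept below the global 0.005\% frequency
#' threshold, and per-sample mistag reads kept (by construction) below the
#' per-sample 0.01\% threshold; an rbcL diatom table; and bivariate-normal
#' isotope values with area means and a linear length effect. The same
#' config and seed always reproduce identical tables.
#'
#' @param config a \code{\link{study_config}}.
#' @return object of class \code{synthetic_study}: \code{fish},
#'   \code{gut} (fish x taxon counts), \code{taxonomy},
#'   \code{biomass_lookup}, \code{otu_coi}, \code{otu_rbcl},
#'   \code{isotopes}, \code{ground_truth}.
#' @export
generate_study <- function(config = study_config()) {
  validate_study_config(config)
  seeds <- child_seeds(config$seed, 4L)
  fish <- with_seed(seeds[1L], gen_fish(config))
  gutres <- with_seed(seeds[2L], gen_gut(config, fish))
  otus <- with_seed(seeds[3L], gen_otus(config, fish, gutres$counts))
  iso <- with_seed(seeds[4L], gen_isotopes(config, fish))
  structure(list(
    fish = fish, gut = gutres$counts,
    taxonomy = config$prey_taxa[c("taxon", "genus", "family", "group")],
    biomass_lookup = setNames(config$prey_taxa$biomass_mg,
                              config$prey_taxa$taxon),
    otu_coi = otus$coi, otu_rbcl = otus$rbcl, isotopes = iso,
    ground_truth = list(config = config,
                        group_proportions = gutres$proportions,
                        mistag_cells = otus$mistag_cells,
                        rare_otus = otus$rare_otus)),
    class = "synthetic_study")
}

gen_fish <- function(cfg) {
  rows <- list()
  for (sp in cfg$species) for (ai in seq_len(nrow(cfg$areas))) {
    ar <- cfg$areas$area[ai]
    lr <- cfg$length_ranges[cfg$length_ranges$species == sp &
                              cfg$length_ranges$area == ar, , drop = FALSE]
    stages <- lr$stage
    n <- cfg$n_fish_per_stratum
    n_juv <- if (!"adult" %in% stages) n
             else if (!"juvenile" %in% stages) 0L
             else round(n * cfg$juvenile_fraction)
    stage <- c(rep("juvenile", n_juv), rep("adult", n - n_juv))
    len <- numeric(n)
    for (st in unique(stage)) {
      r <- lr[lr$stage == st, , drop = FALSE]
      len[stage == st] <- runif(sum(stage == st), r$lo, r$hi)
    }
    site <- paste0(ar, "-S", 1L + (seq_len(n) - 1L) %% cfg$n_sites_per_area)
    lat_site <- cfg$areas$latitude[ai] +
      seq(-0.2, 0.2, length.out = cfg$n_sites_per_area)
    rows[[paste(sp, ar)]] <- data.frame(
      fish_id = sprintf("%s_%s_%03d", substr(sp, 1L, 3L),
                        gsub("[^0-9A-Za-z]", "", ar), seq_len(n)),
      species = sp, area = ar, site_id = site,
      latitude = lat_site[1L + (seq_len(n) - 1L) %% cfg$n_sites_per_area],
      depth = runif(n, 30, 120),
      total_length_cm = round(len, 1),
      stringsAsFactors = FALSE)
  }
  fish <- do.call(rbind, rows)
  rownames(fish) <- NULL
  fish$stage <- classify_stage(fish$species, fish$total_length_cm)
  fish
}

gen_gut <- function(cfg, fish) {
  taxa <- cfg$prey_taxa$taxon
  grp_of <- cfg$prey_taxa$group
  groups <- prey_groups()
  counts <- matrix(0L, nrow(fish), length(taxa),
                   dimnames = list(fish$fish_id, taxa))
  props <- matrix(NA_real_, nrow(fish), length(groups),
                  dimnames = list(fish$fish_id, groups))
  for (i in seq_len(nrow(fish))) {
    key <- paste(fish$species[i], fish$area[i], fish$stage[i], sep = "|")
    alpha <- cfg$concentrations[[key]]
    if (is.null(alpha)) stop("no concentration vector for stratum ", key)
    p <- rdirichlet1(alpha[groups])
    props[i, ] <- p
    if (runif(1L) < cfg$p_empty) next  # empty stomach
    tot <- max(1L, round(rlnorm(1L, cfg$total_count_meanlog[fish$stage[i]],
                                cfg$total_count_sdlog[fish$stage[i]])))
    gcount <- as.vector(rmultinom(1L, tot, p))
    for (gi in seq_along(groups)) {
      if (gcount[gi] == 0L) next
      members <- which(grp_of == groups[gi])
      counts[i, members] <- counts[i, members] +
        as.vector(rmultinom(1L, gcount[gi], rep(1, length(members))))
    }
  }
  list(counts = counts, proportions = props)
}

gen_otus <- function(cfg, fish, gut) {
  noise <- cfg$otu_noise
  taxa <- colnames(gut)
  taxmap <- cfg$prey_taxa
  coi_tax <- vapply(taxa, function(tx) {
    r <- taxmap[taxmap$taxon == tx, ]
    paste(r$group,
          ifelse(is.na(r$family), "", r$family),
          ifelse(is.na(r$genus), "", r$genus), tx, sep = ";")
  }, character(1L))
  pred_ids <- c("OTU_pred_anchovy", "OTU_pred_sardine")
  pred_tax <- c("Actinopterygii;Engraulidae;Engraulis;Engraulis encrasicolus",
                "Actinopterygii;Clupeidae;Sardina;Sardina pilchardus")
  n_rare <- noise$n_rare_otus
  rare_ids <- sprintf("OTU_rare_%02d", seq_len(n_rare))
  rare_tax <- sprintf("Rareplankton;FamX;GenX;GenX species%02d", seq_len(n_rare))
  # a couple of unassigned OTUs exercise the taxonomy filter
  unas_ids <- c("OTU_unassigned_1", "OTU_unassigned_2")
  unas_tax <- c("unassigned", "unassigned")

  otu_ids <- c(paste0("OTU_", gsub("[^A-Za-z0-9]", "_", taxa)),
               pred_ids, rare_ids, unas_ids)
  taxonomy <- c(coi_tax, pred_tax, rare_tax, unas_tax)
  names(taxonomy) <- otu_ids
  m <- matrix(0L, length(otu_ids), nrow(fish),
              dimnames = list(otu_ids, fish$fish_id))

  # true diet reads + predator reads
  for (j in seq_len(nrow(fish))) {
    present <- which(gut[j, ] > 0)
    if (length(present))
      m[present, j] <- rpois(length(present), noise$read_lambda)
    pred <- if (fish$species[j] == "anchovy") "OTU_pred_anchovy"
            else "OTU_pred_sardine"
    m[pred, j] <- rpois(1L, noise$predator_lambda)
    m[unas_ids, j] <- rpois(2L, noise$read_lambda / 4)
  }

  # rare OTUs: total dataset reads strictly below the global 0.005% level
  total <- sum(m)
  rare_cap <- max(1L, min(noise$rare_max_reads,
                          floor(total * 0.005 / 100) - 1L))
  rare_otus <- character(0)
  for (r in rare_ids) {
    k <- sample.int(rare_cap, 1L)
    cols <- sample.int(ncol(m), min(k, ncol(m)))
    add <- as.vector(rmultinom(1L, k, rep(1, length(cols))))
    m[r, cols] <- m[r, cols] + add
    rare_otus <- c(rare_otus, r)
  }

  # mistag reads: 1-read cells injected only where the sample total keeps
  # them strictly below the per-sample 0.01% threshold, so the mistag filter
  # can remove them all
  mistag <- list()
  stot <- colSums(m)
  diet_rows <- seq_along(taxa)
  for (j in seq_len(ncol(m))) {
    if (stot[j] < 10000 + noise$mistags_per_sample) next
    absent <- diet_rows[m[diet_rows, j] == 0L]
    if (length(absent) < noise$mistags_per_sample) next
    pick <- sample(absent, noise$mistags_per_sample)
    m[pick, j] <- 1L
    mistag[[length(mistag) + 1L]] <-
      data.frame(otu = otu_ids[pick], sample = colnames(m)[j],
                 stringsAsFactors = FALSE)
  }

  coi <- otu_table(m, taxonomy, marker = "COI",
                   host_species = fish$species)

  # rbcL diatom table: per-taxon occurrence probabilities spread widely so
  # the percentile merge has both common and rare groups; three taxa lack
  # species-level names, two OTUs are non-diatom noise
  n_diat <- 14L
  fam <- rep(c("Thalassiosiraceae", "Chaetocerotaceae", "Bacillariaceae",
               "Rhizosoleniaceae"), length.out = n_diat)
  gen <- sub("aceae$", "", fam)
  diat_ids <- sprintf("dOTU_%02d", seq_len(n_diat))
  diat_tax <- sprintf("Bacillariophyta;%s;%s;%s species%02d",
                      fam, gen, gen, seq_len(n_diat))
  noname <- sample(n_diat, 3L)
  diat_tax[noname] <- sprintf("Bacillariophyta;%s;%s;", fam[noname],
                              gen[noname])
  other_ids <- c("dOTU_green_1", "dOTU_unassigned_1")
  other_tax <- c("Chlorophyta;Mamiellaceae;Micromonas;Micromonas pusilla",
                 "unassigned")
  occ_p <- seq(0.05, 0.8, length.out = n_diat)
  md <- matrix(0L, n_diat + 2L, nrow(fish),
               dimnames = list(c(diat_ids, other_ids), fish$fish_id))
  for (i in seq_len(n_diat)) {
    hit <- runif(ncol(md)) < occ_p[i]
    md[i, hit] <- rpois(sum(hit), noise$rbcl_read_lambda)
  }
  md[n_diat + 1L, ] <- rpois(ncol(md), 100)
  md[n_diat + 2L, ] <- rpois(ncol(md), 100)
  rbcl <- otu_table(md, c(diat_tax, other_tax), marker = "rbcL",
                    host_species = fish$species)

  list(coi = coi, rbcl = rbcl,
       mistag_cells = if (length(mistag)) do.call(rbind, mistag)
                      else data.frame(otu = character(),
                                      sample = character()),
       rare_otus = rare_otus)
}

gen_isotopes <- function(cfg, fish) {
  out <- data.frame(fish_id = fish$fish_id, delta13C = NA_real_,
                    delta15N = NA_real_, c_to_n = NA_real_,
                    stringsAsFactors = FALSE)
  ref_len <- 12
  for (key in unique(paste(fish$species, fish$area, sep = "|"))) {
    pars <- cfg$isotope_params[[key]]
    if (is.null(pars)) stop("no isotope parameters for stratum ", key)
    sel <- paste(fish$species, fish$area, sep = "|") == key
    n <- sum(sel)
    draws <- MASS::mvrnorm(n, mu = pars$mean, Sigma = pars$cov)
    draws <- matrix(draws, ncol = 2L,
                    dimnames = list(NULL, names(pars$mean)))
    dl <- fish$total_length_cm[sel] - ref_len
    out$delta15N[sel] <- draws[, "d15N"] + pars$length_slope[["d15N"]] * dl
    out$delta13C[sel] <- draws[, "d13C"] + pars$length_slope[["d13C"]] * dl
    out$c_to_n[sel] <- runif(n, 3.1, 4.3)
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic multi-proxy study\n  %d fish (%s), %d prey taxa\n  COI table: %d OTUs x %d samples; rbcL table: %d OTUs x %d samples\n  isotope records: %d\n",
    nrow(x$fish), paste(unique(x$fish$species), collapse = ", "),
    ncol(x$gut), nrow(x$otu_coi$counts), ncol(x$otu_coi$counts),
    nrow(x$otu_rbcl$counts), ncol(x$otu_rbcl$counts), nrow(x$isotopes)))
  invisible(x)
}

#' Write the tables of a synthetic study as tab-delimited text
#'
#' Writes fish metadata, gut counts, taxonomy/biomass lookups, both OTU
#' tables (BIOM-TSV layout: OTU rows, sample columns, trailing taxonomy
#' column) and the isotope table into a directory; the configuration is
#' stored alongside as YAML when the \pkg{yaml} package is available.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f, rn = FALSE) {
    path <- file.path(dir, f)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = rn)
    path
  }
  files <- c(
    wt(study$fish, "fish_metadata.tsv"),
    wt(cbind(fish_id = rownames(study$gut), as.data.frame(study$gut)),
       "gut_counts.tsv"),
    wt(study$taxonomy, "prey_taxonomy.tsv"),
    wt(data.frame(name = names(study$biomass_lookup),
                  biomass_mg = study$biomass_lookup), "biomass_lookup.tsv"),
    wt(cbind(as.data.frame(study$otu_coi$counts),
             taxonomy = study$otu_coi$taxonomy), "otu_coi.tsv", rn = TRUE),
    wt(cbind(as.data.frame(study$otu_rbcl$counts),
             taxonomy = study$otu_rbcl$taxonomy), "otu_rbcl.tsv", rn = TRUE),
    wt(study$isotopes, "isotopes.tsv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- study$ground_truth$config
    yaml::write_yaml(list(seed = cfg$seed,
                          n_fish_per_stratum = cfg$n_fish_per_stratum,
                          areas = cfg$areas, species = cfg$species,
                          p_empty = cfg$p_empty),
                     file.path(dir, "config.yml"))
    files <- c(files, file.path(dir, "config.yml"))
  }
  invisible(files)
}
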