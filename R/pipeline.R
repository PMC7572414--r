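#' Qualitative north-vs-south comparison of a metric
#'
#' Paired comparison between the northernmost and southernmost area values
#' of a metric. The percent difference uses the symmetric denominator
#' \eqn{100 |v_N - v_S| / \bar v}; differences strictly below
#' \code{threshold} percent are reported as \code{"NLD"} (no latitudinal
#' difference), otherwise the verdict names the larger side
#' (\code{"N > S"} / \code{"S > N"}). Set \code{denominator = "north"} for
#' the asymmetric relative-to-north variant.
#'
#' @param value_north,value_south finite metric values (not both zero).
#' @param metric optional metric label carried into the result.
#' @param species optional species label.
#' @param threshold NLD threshold in percent (default 30).
#' @param denominator \code{"mean"} (default) or \code{"north"}.
#' @return data.frame: metric, species, value_north, value_south,
#'   percent_difference, verdict.
#' @examples
#' compare_latitudinal(10, 14)  # 33.3% -> "S > N"
#' @export
compare_latitudinal <- function(value_north, value_south, metric = NA,
                                species = NA, threshold = 30,
                                denominator = c("mean", "north")) {
  denominator <- match.arg(denominator)
  if (!is.finite(value_north) || !is.finite(value_south))
    stop("both values must be finite")
  if (value_north == 0 && value_south == 0) {
    warning("both values zero; reporting NLD")
    pd <- 0
  } else {
    den <- switch(denominator, mean = mean(c(value_north, value_south)),
                  north = value_north)
    pd <- 100 * abs(value_north - value_south) / den
  }
  verdict <- if (pd < threshold) "NLD"
             else if (value_north > value_south) "N > S" else "S > N"
  data.frame(metric = metric, species = species,
             value_north = value_north, value_south = value_south,
             percent_difference = pd, verdict = verdict,
             stringsAsFactors = FALSE)
}

# pull one stratum value out of a long composition table
comp_value <- function(comp, sp, ar, grp) {
  v <- comp$value[comp$species == sp & comp$area == ar & comp$group == grp]
  if (length(v) != 1L) NA_real_ else v
}

# sum %N/%B/%FO over a set of prey groups (copepods / krill pools)
comp_pool <- function(comp, sp, ar, grps) {
  sum(vapply(grps, function(g) comp_value(comp, sp, ar, g), numeric(1L)))
}

#' Run the full multi-proxy trophic analysis
#'
#' Executes every stage of the workflow on a synthetic study (or one
#' supplied as \code{study}): gut-content metrics, OTU-table filtering and
#' occurrence summaries, richness/Shannon/beta-diversity per area and
#' method, rarefaction/extrapolation curves, pairwise Pianka overlap with
#' RA2 nulls for both data sources, isotopic standard ellipses with SEA_B
#' posteriors and directional overlaps, stepwise additive models per
#' response and species, and the qualitative north-vs-south summary matrix.
#' All randomized stages run under child streams of \code{seed}, so the
#' whole bundle is reproducible.
#'
#' @param config \code{\link{study_config}} used when no \code{study} is
#'   given.
#' @param study optionally, an existing \code{synthetic_study} (or a list
#'   with the same components built from real tables).
#' @param seed seed for the analysis stages (RA2 nulls, SEA_B, bootstraps).
#' @param ra2_iterations RA2 iterations per overlap pair (default 1000).
#' @param sea_b_draws SEA_B posterior draws (default 10000).
#' @param n_boot rarefaction bootstrap replicates (default 200).
#' @param outdir optional directory; when given, all tables are written as
#'   tab-delimited text.
#' @return object of class \code{multitroph_pipeline}; see components
#'   \code{composition}, \code{sfd}, \code{diversity_table},
#'   \code{beta_table}, \code{rarefaction}, \code{overlap},
#'   \code{isotope}, \code{models}, \code{latitudinal}.
#' @export
run_pipeline <- function(config = study_config(), study = NULL, seed = 1L,
                         ra2_iterations = 1000L, sea_b_draws = 10000L,
                         n_boot = 200L, outdir = NULL) {
  if (is.null(study)) study <- generate_study(config)
  seeds <- child_seeds(seed, 6L)
  fish <- study$fish
  areas <- unique(fish$area)
  north <- areas[1L]; south <- areas[length(areas)]
  species <- unique(fish$species)
  taxonomy <- study$taxonomy
  lookup <- study$biomass_lookup

  ## 1. gut-content metrics -------------------------------------------------
  comp <- list(
    N = composition_summary(study$gut, fish, "N", taxonomy),
    B = composition_summary(study$gut, fish, "B", taxonomy, lookup),
    FO = composition_summary(study$gut, fish, "FO", taxonomy))
  sfd <- sfd_table(study$gut, fish, lookup, taxonomy)
  sfd <- merge(sfd, fish, by = "fish_id")

  ## 2. OTU filtering and occurrence ---------------------------------------
  flt_coi <- filter_otu_table(study$otu_coi)
  flt_rbcl <- filter_otu_table(study$otu_rbcl)
  sample_meta <- data.frame(sample_id = fish$fish_id, area = fish$area,
                            site_id = fish$site_id, stringsAsFactors = FALSE)
  occ_coi <- occurrence_summary(flt_coi$table, sample_meta)
  occ_rbcl <- occurrence_summary(flt_rbcl$table, sample_meta)

  ## 3. diversity -----------------------------------------------------------
  gut_groups <- aggregate_to_groups(study$gut, taxonomy)
  div_rows <- list()
  presence_micro <- list(); presence_dna <- list()
  coi_counts <- flt_coi$table$counts
  coi_fish <- colnames(coi_counts)
  for (sp in species) for (ar in areas) {
    sel <- fish$species == sp & fish$area == ar
    sub <- study$gut[fish$fish_id[sel], , drop = FALSE]
    pooled <- colSums(sub)
    Hs <- apply(sub[rowSums(sub) > 0, , drop = FALSE], 1L, shannon)
    dna_sel <- coi_fish %in% fish$fish_id[sel]
    dna_pool <- if (any(dna_sel))
      rowSums(coi_counts[, dna_sel, drop = FALSE]) else numeric(0)
    presence_micro[[paste(sp, ar, sep = "|")]] <- names(pooled)[pooled > 0]
    presence_dna[[paste(sp, ar, sep = "|")]] <-
      names(dna_pool)[dna_pool > 0]
    div_rows[[paste(sp, ar)]] <- data.frame(
      species = sp, area = ar,
      richness_micro = richness(pooled),
      richness_dna = sum(dna_pool > 0),
      shannon_mean = mean(Hs), shannon_se = sd(Hs) / sqrt(length(Hs)),
      n_fish = sum(sel), stringsAsFactors = FALSE)
  }
  diversity_table <- do.call(rbind, div_rows)
  rownames(diversity_table) <- NULL

  beta_rows <- list()
  for (ar in areas) {
    bm <- beta_whittaker(presence_micro[[paste(species[1L], ar, sep = "|")]],
                         presence_micro[[paste(species[2L], ar, sep = "|")]])
    bd <- beta_whittaker(presence_dna[[paste(species[1L], ar, sep = "|")]],
                         presence_dna[[paste(species[2L], ar, sep = "|")]])
    beta_rows[[ar]] <- data.frame(area = ar, beta_micro = bm$beta_w,
                                  beta_dna = bd$beta_w,
                                  stringsAsFactors = FALSE)
  }
  beta_table <- do.call(rbind, beta_rows)
  rownames(beta_table) <- NULL

  rarefaction <- list()
  rare_seeds <- child_seeds(seeds[1L], 2L * length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    pooled <- colSums(study$gut[fish$fish_id[fish$species == sp], ,
                                drop = FALSE])
    rarefaction[[paste0(sp, "_micro")]] <- rarefy_extrapolate(
      pooled[pooled > 0], mode = "abundance", n_boot = n_boot,
      seed = rare_seeds[2L * i - 1L])
    dna_sel <- coi_fish %in% fish$fish_id[fish$species == sp]
    inc <- coi_counts[, dna_sel, drop = FALSE]
    rarefaction[[paste0(sp, "_dna")]] <- rarefy_extrapolate(
      inc, mode = "incidence", n_boot = n_boot, seed = rare_seeds[2L * i])
  }

  ## 4. niche overlap (both sources, presence proportions) ------------------
  strata_keys <- expand.grid(species = species, area = areas,
                             stringsAsFactors = FALSE)
  fo_vec <- function(src, sp, ar) {
    v <- vapply(sort(unique(src$group)), function(g)
      comp_value(src, sp, ar, g), numeric(1L))
    v[is.na(v)] <- 0
    v
  }
  diets_micro <- t(vapply(seq_len(nrow(strata_keys)), function(i)
    fo_vec(comp$FO, strata_keys$species[i], strata_keys$area[i]),
    numeric(length(unique(comp$FO$group)))))
  # DNA source: %FO of prey groups from the filtered COI table
  occ_grp <- occ_coi
  occ_grp$group <- vapply(strsplit(flt_coi$table$taxonomy[occ_grp$taxon],
                                   ";", fixed = TRUE),
                          `[`, character(1L), 1L)
  dna_fo <- aggregate(fo ~ species + area + group, occ_grp, mean)
  names(dna_fo)[names(dna_fo) == "fo"] <- "value"
  dna_groups <- sort(unique(dna_fo$group))
  diets_dna <- t(vapply(seq_len(nrow(strata_keys)), function(i)
    vapply(dna_groups, function(g) {
      v <- comp_value(dna_fo, strata_keys$species[i], strata_keys$area[i], g)
      if (is.na(v)) 0 else v
    }, numeric(1L)), numeric(length(dna_groups))))
  ov_seeds <- child_seeds(seeds[2L], 2L)
  overlap <- list(
    micro = pairwise_overlap_matrix(diets_micro, strata_keys, mode = "all",
                                    iterations = ra2_iterations,
                                    seed = ov_seeds[1L]),
    dna = pairwise_overlap_matrix(diets_dna, strata_keys, mode = "all",
                                  iterations = ra2_iterations,
                                  seed = ov_seeds[2L]))

  ## 5. isotopic niche -------------------------------------------------------
  iso <- lipid_correct(study$isotopes)
  iso <- merge(iso, fish, by = "fish_id")
  iso_seeds <- child_seeds(seeds[3L], nrow(strata_keys))
  ellipses <- list(); sea_rows <- list()
  for (i in seq_len(nrow(strata_keys))) {
    sp <- strata_keys$species[i]; ar <- strata_keys$area[i]
    pts <- iso[iso$species == sp & iso$area == ar,
               c("delta13C", "delta15N"), drop = FALSE]
    if (nrow(pts) < 3L) next  # SEA_C undefined below n = 3
    key <- paste(sp, ar, sep = "|")
    post <- sea_b_posterior(pts, draws = sea_b_draws, seed = iso_seeds[i])
    ellipses[[key]] <- post
    sea_rows[[key]] <- data.frame(
      species = sp, area = ar, n = post$n, SEA = post$ml$SEA,
      SEA_C = post$ml$SEA_C, SEA_B_mode = post$mode,
      SEA_B_lo = post$ci[1L], SEA_B_hi = post$ci[2L],
      mean_d15N = mean(pts$delta15N), mean_d13C = mean(pts$delta13C),
      stringsAsFactors = FALSE)
  }
  sea_table <- do.call(rbind, sea_rows)
  rownames(sea_table) <- NULL
  ov_iso <- list()
  for (sp in species) {
    ka <- paste(sp, north, sep = "|"); kb <- paste(sp, south, sep = "|")
    if (!is.null(ellipses[[ka]]) && !is.null(ellipses[[kb]]))
      ov_iso[[paste0(sp, "_N_vs_S")]] <-
        ellipse_overlap(ellipses[[ka]]$ml, ellipses[[kb]]$ml)
  }
  for (ar in areas) {
    ka <- paste(species[1L], ar, sep = "|")
    kb <- paste(species[2L], ar, sep = "|")
    if (!is.null(ellipses[[ka]]) && !is.null(ellipses[[kb]]))
      ov_iso[[paste0("species_", ar)]] <-
        ellipse_overlap(ellipses[[ka]]$ml, ellipses[[kb]]$ml)
  }

  ## 6. additive models ------------------------------------------------------
  models <- list()
  gut_H <- apply(study$gut, 1L, function(r) if (sum(r) > 0) shannon(r)
                                            else NA_real_)
  mdat <- merge(iso, data.frame(fish_id = rownames(study$gut),
                                shannon_H = gut_H, stringsAsFactors = FALSE),
                by = "fish_id")
  mdat <- merge(mdat, sfd[c("fish_id", "sfd")], by = "fish_id")
  for (sp in species) {
    d <- mdat[mdat$species == sp & mdat$sfd > 0 & is.finite(mdat$shannon_H), ]
    for (resp in c("sfd", "shannon_H", "delta15N", "delta13C")) {
      # the log/gamma decision path needs a positive response; fall back to
      # the identity-link Gaussian when the response can be non-positive
      fam <- if (resp == "sfd") "gamma-log"
             else if (any(d[[resp]] <= 0, na.rm = TRUE)) "gaussian-identity"
             else "auto"
      sel <- tryCatch(
        stepwise_select(d, resp,
                        smooth_candidates = c("latitude", "depth",
                                              "total_length_cm"),
                        family = fam),
        error = function(e) e)
      models[[paste(sp, resp, sep = "_")]] <- sel
    }
  }

  ## 7. latitudinal summary (north vs south) --------------------------------
  copepods <- c("Calanoids", "Cyclopoids", "Harpacticoids")
  krill <- c("Euphausiacea", "Decapoda", "OtherMalacostraca")
  lat_rows <- list()
  for (sp in species) {
    add <- function(metric, vn, vs)
      lat_rows[[paste(sp, metric)]] <<-
        compare_latitudinal(vn, vs, metric = metric, species = sp)
    add("SFD", mean(sfd$sfd[sfd$species == sp & sfd$area == north]),
        mean(sfd$sfd[sfd$species == sp & sfd$area == south]))
    add("%N copepods", comp_pool(comp$N, sp, north, copepods),
        comp_pool(comp$N, sp, south, copepods))
    add("%N krill", comp_pool(comp$N, sp, north, krill),
        comp_pool(comp$N, sp, south, krill))
    add("%B copepods", comp_pool(comp$B, sp, north, copepods),
        comp_pool(comp$B, sp, south, copepods))
    add("%B krill", comp_pool(comp$B, sp, north, krill),
        comp_pool(comp$B, sp, south, krill))
    add("%FO krill", comp_pool(comp$FO, sp, north, krill),
        comp_pool(comp$FO, sp, south, krill))
    dt <- diversity_table
    add("richness (microscope)",
        dt$richness_micro[dt$species == sp & dt$area == north],
        dt$richness_micro[dt$species == sp & dt$area == south])
    add("richness (DNA)",
        dt$richness_dna[dt$species == sp & dt$area == north],
        dt$richness_dna[dt$species == sp & dt$area == south])
    add("Shannon H'",
        dt$shannon_mean[dt$species == sp & dt$area == north],
        dt$shannon_mean[dt$species == sp & dt$area == south])
    if (!is.null(sea_table)) {
      sn <- sea_table[sea_table$species == sp, ]
      if (all(c(north, south) %in% sn$area)) {
        add("delta15N", sn$mean_d15N[sn$area == north],
            sn$mean_d15N[sn$area == south])
        add("SEA_B", sn$SEA_B_mode[sn$area == north],
            sn$SEA_B_mode[sn$area == south])
      }
    }
  }
  latitudinal <- do.call(rbind, lat_rows)
  rownames(latitudinal) <- NULL

  out <- structure(list(
    study = study, composition = comp, sfd = sfd,
    filter_logs = list(coi = flt_coi$log, rbcl = flt_rbcl$log),
    occurrence = list(coi = occ_coi, rbcl = occ_rbcl),
    diversity_table = diversity_table, beta_table = beta_table,
    rarefaction = rarefaction, overlap = overlap,
    isotope = list(table = sea_table, ellipses = ellipses,
                   overlaps = ov_iso),
    models = models, latitudinal = latitudinal,
    seed = seed, north = north, south = south),
    class = "multitroph_pipeline")

  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(obj, f)
    write.table(obj, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(do.call(rbind, x$composition), "diet_composition.tsv")
  wt(x$sfd[c("fish_id", "species", "area", "site_id", "stage", "sfd")],
     "sfd.tsv")
  wt(x$filter_logs$coi, "filter_log_coi.tsv")
  wt(x$filter_logs$rbcl, "filter_log_rbcl.tsv")
  wt(x$occurrence$coi, "occurrence_coi.tsv")
  wt(x$occurrence$rbcl, "occurrence_rbcl.tsv")
  wt(x$diversity_table, "diversity.tsv")
  wt(x$beta_table, "beta_diversity.tsv")
  for (nm in names(x$rarefaction))
    wt(as.data.frame(x$rarefaction[[nm]]),
       paste0("rarefaction_", nm, ".tsv"))
  wt(x$overlap$micro$pairs, "overlap_micro.tsv")
  wt(x$overlap$dna$pairs, "overlap_dna.tsv")
  if (!is.null(x$isotope$table)) wt(x$isotope$table, "isotope_niche.tsv")
  wt(x$latitudinal, "latitudinal_summary.tsv")
  invisible(outdir)
}

#' @export
print.multitroph_pipeline <- function(x, ...) {
  cat("Multi-proxy trophic analysis bundle\n")
  cat(sprintf("  %d fish, %d strata; north = %s, south = %s; seed = %d\n",
              nrow(x$study$fish),
              nrow(unique(x$study$fish[c("species", "area")])),
              x$north, x$south, x$seed))
  cat("\nLatitudinal summary (", x$north, " vs ", x$south, "):\n", sep = "")
  print(cbind(x$latitudinal[c("metric", "species")],
              round(x$latitudinal[c("value_north", "value_south",
                                    "percent_difference")], 2),
              verdict = x$latitudinal$verdict), row.names = FALSE)
  invisible(x)
}
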