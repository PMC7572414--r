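#' Classify ontogenetic stage from total length
#'
#' Anchovy shorter than 11 cm and sardine shorter than 13 cm are classified as
#' juveniles; fish at or above the species cut-off are adults (the boundary
#' length itself is adult, i.e. the comparison is strict).
#'
#' @param species character vector, each element \code{"anchovy"} or
#'   \code{"sardine"}.
#' @param total_length_cm numeric vector of total lengths in cm, all > 0.
#' @return character vector, \code{"juvenile"} or \code{"adult"}.
#' @examples
#' classify_stage("anchovy", c(10.9, 11.0))
#' @export
classify_stage <- function(species, total_length_cm) {
  if (any(!species %in% c("anchovy", "sardine")))
    stop("unknown species label: ",
         paste(unique(setdiff(species, c("anchovy", "sardine"))), collapse = ", "))
  if (any(!is.finite(total_length_cm)) || any(total_length_cm <= 0))
    stop("total_length_cm must be positive and finite")
  cutoff <- ifelse(species == "anchovy", 11, 13)
  ifelse(total_length_cm < cutoff, "juvenile", "adult")
}

# Resolve per-individual wet weight (mg) for one prey taxon through the
# taxonomic fallback chain species -> genus -> family -> group.  `lookup` is a
# named numeric vector keyed by names at any level; `taxonomy` is a data.frame
# with columns taxon, genus, family, group.
resolve_biomass <- function(taxon, lookup, taxonomy) {
  row <- taxonomy[taxonomy$taxon == taxon, , drop = FALSE]
  if (nrow(row) == 0L) stop("taxon not in taxonomy map: ", taxon)
  chain <- c(taxon = taxon, genus = row$genus[1L], family = row$family[1L],
             group = row$group[1L])
  for (lev in names(chain)) {
    key <- chain[[lev]]
    if (!is.na(key) && nzchar(key) && key %in% names(lookup)) {
      val <- lookup[[key]]
      if (!is.finite(val) || val <= 0)
        stop("non-positive unit biomass for ", key)
      return(list(value = val, level = lev, key = key))
    }
  }
  stop("unit biomass unresolvable for taxon '", taxon,
       "' at any level of the fallback chain")
}

#' Convert a gut-content count matrix to prey biomass
#'
#' Multiplies each count by the per-individual wet weight of its taxon,
#' resolving weights to the most detailed taxonomic level available: the taxon
#' itself, then its genus, family, and finally its prey group. The level used
#' for each taxon is recorded in the \code{"provenance"} attribute.
#'
#' @param gut_table numeric matrix, fish (rows) by prey taxon (columns),
#'   non-negative integer counts; column names are taxon names.
#' @param biomass_lookup named numeric vector of per-individual wet weights
#'   (mg); names may be taxa, genera, families or groups.
#' @param taxonomy data.frame with columns \code{taxon}, \code{genus},
#'   \code{family}, \code{group} covering every column of \code{gut_table}.
#' @return numeric matrix of biomass (mg) with the same dimensions, with a
#'   \code{"provenance"} attribute (data.frame taxon, level, key, unit_mg).
#' @export
counts_to_biomass <- function(gut_table, biomass_lookup, taxonomy) {
  gut_table <- as.matrix(gut_table)
  if (any(gut_table < 0)) stop("counts must be non-negative")
  taxa <- colnames(gut_table)
  if (is.null(taxa)) stop("gut_table must have taxon column names")
  res <- lapply(taxa, resolve_biomass, lookup = biomass_lookup,
                taxonomy = taxonomy)
  units <- vapply(res, `[[`, numeric(1L), "value")
  out <- sweep(gut_table, 2L, units, `*`)
  attr(out, "provenance") <- data.frame(
    taxon = taxa,
    level = vapply(res, `[[`, character(1L), "level"),
    key = vapply(res, `[[`, character(1L), "key"),
    unit_mg = units,
    stringsAsFactors = FALSE)
  out
}

#' Stomach filling degree (SFD)
#'
#' Feeding-intensity proxy: total prey wet weight in the stomach (mg) divided
#' by fish total length (mm). Dividing by length removes the trivial effect of
#' fish size on stomach capacity. An empty stomach has SFD 0.
#'
#' @param gut_row named numeric vector of prey counts for one fish.
#' @param total_length_cm fish total length in cm (> 0).
#' @param biomass_lookup,taxonomy as in \code{\link{counts_to_biomass}}.
#' @return SFD in mg per mm.
#' @export
compute_sfd <- function(gut_row, total_length_cm, biomass_lookup, taxonomy) {
  if (!is.finite(total_length_cm) || total_length_cm <= 0)
    stop("total_length_cm must be positive")
  if (any(gut_row < 0)) stop("counts must be non-negative")
  if (sum(gut_row) == 0) return(0)
  m <- matrix(gut_row, nrow = 1L, dimnames = list(NULL, names(gut_row)))
  bio <- counts_to_biomass(m, biomass_lookup, taxonomy)
  sum(bio) / (total_length_cm * 10)
}

#' Stomach filling degree for every fish in a study table
#'
#' @param gut_table fish-by-taxon count matrix with fish ids as row names.
#' @param fish data.frame with columns \code{fish_id} and
#'   \code{total_length_cm}.
#' @param biomass_lookup,taxonomy as in \code{\link{counts_to_biomass}}.
#' @return data.frame \code{fish_id}, \code{sfd} (mg/mm).
#' @export
sfd_table <- function(gut_table, fish, biomass_lookup, taxonomy) {
  gut_table <- as.matrix(gut_table)
  ids <- rownames(gut_table)
  stopifnot(!is.null(ids), all(ids %in% fish$fish_id))
  len <- fish$total_length_cm[match(ids, fish$fish_id)]
  bio <- counts_to_biomass(gut_table, biomass_lookup, taxonomy)
  data.frame(fish_id = ids, sfd = rowSums(bio) / (len * 10),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Aggregate a fish x taxon matrix to fish x prey-group using the taxonomy map.
# Taxa flagged as parasites are rejected: bench protocol excludes them before
# diet analysis, so their presence signals a malformed input table.
aggregate_to_groups <- function(mat, taxonomy) {
  taxa <- colnames(mat)
  grp <- taxonomy$group[match(taxa, taxonomy$taxon)]
  if (anyNA(grp)) stop("taxa missing from taxonomy map: ",
                       paste(taxa[is.na(grp)], collapse = ", "))
  if (any(tolower(grp) == "parasite"))
    stop("parasite-flagged taxa present in gut table: ",
         paste(taxa[tolower(grp) == "parasite"], collapse = ", "))
  t(rowsum(t(mat), group = grp))
}

#' Diet composition summary (\%N, \%B, \%FO)
#'
#' Per-stratum prey-group composition from gut-content counts. Percentages are
#' computed per sampling site first and then averaged (unweighted) across the
#' sites of a stratum, so that sites with many fish do not dominate the
#' stratum mean; set \code{site_average = FALSE} to pool fish instead. For
#' \%B, group biomass is divided by the number of fish of the stratum before
#' percentage formation (a sample-size normalization; it leaves within-site
#' percentages unchanged but is applied as stated for transparency).
#'
#' @param gut_table fish-by-taxon count matrix, fish ids as row names.
#' @param fish data.frame with columns \code{fish_id}, \code{species},
#'   \code{area}, \code{site_id} and (if \code{by_stage}) \code{stage}.
#' @param level \code{"N"} (numerical percentage), \code{"B"} (biomass
#'   percentage) or \code{"FO"} (percent frequency of occurrence).
#' @param taxonomy taxonomy map (taxon, genus, family, group).
#' @param biomass_lookup named unit-biomass vector; required for
#'   \code{level = "B"}.
#' @param by_stage also stratify by ontogenetic stage.
#' @param site_average average percentages across sites (default) or pool all
#'   fish of the stratum.
#' @return long data.frame: species, area (stage), group, metric, value,
#'   n_fish, n_sites. \%N and \%B sum to 100 within each stratum.
#' @export
composition_summary <- function(gut_table, fish,
                                level = c("N", "B", "FO"),
                                taxonomy, biomass_lookup = NULL,
                                by_stage = FALSE, site_average = TRUE) {
  level <- match.arg(level)
  gut_table <- as.matrix(gut_table)
  ids <- rownames(gut_table)
  stopifnot(!is.null(ids), all(ids %in% fish$fish_id))
  meta <- fish[match(ids, fish$fish_id), , drop = FALSE]

  gmat <- aggregate_to_groups(gut_table, taxonomy)
  if (level == "B") {
    if (is.null(biomass_lookup)) stop("biomass_lookup required for level 'B'")
    bio <- counts_to_biomass(gut_table, biomass_lookup, taxonomy)
    gmat <- aggregate_to_groups(bio, taxonomy)
  }
  groups <- colnames(gmat)

  keyvars <- c("species", "area", if (by_stage) "stage")
  key <- interaction(meta[keyvars], drop = TRUE, sep = "|")
  out <- list()
  for (k in levels(key)) {
    sel <- key == k
    sub <- gmat[sel, , drop = FALSE]
    sites <- meta$site_id[sel]
    nonempty <- rowSums(sub) > 0
    if (level != "FO" && !any(nonempty)) {
      warning("stratum '", k, "' has no non-empty stomachs; omitted")
      next
    }
    n_fish <- sum(sel)
    if (level == "B") sub <- sub / n_fish  # per-fish weighting, see Details
    per_site <- function(s) {
      ssub <- sub[sites == s, , drop = FALSE]
      if (level == "FO") return(100 * colMeans(ssub > 0))
      tot <- sum(ssub)
      if (tot == 0) return(NULL)  # site with only empty stomachs
      100 * colSums(ssub) / tot
    }
    if (site_average) {
      rows <- Filter(Negate(is.null), lapply(unique(sites), per_site))
      vals <- colMeans(do.call(rbind, rows))
    } else {
      if (level == "FO") vals <- 100 * colMeans(sub > 0)
      else vals <- 100 * colSums(sub) / sum(sub)
    }
    keyparts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    rec <- data.frame(species = keyparts[1L], area = keyparts[2L],
                      stringsAsFactors = FALSE)
    if (by_stage) rec$stage <- keyparts[3L]
    out[[k]] <- cbind(rec[rep(1L, length(groups)), , drop = FALSE],
                      data.frame(group = groups, metric = paste0("%", level),
                                 value = unname(vals), n_fish = n_fish,
                                 n_sites = length(unique(sites)),
                                 stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
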