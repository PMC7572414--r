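#' Construct an OTU table
#'
#' Container for a post-clustering OTU read-count table: OTU-by-sample
#' integer counts, one ranked taxonomy string per OTU, the marker the table
#' was amplified with (COI for zooplankton prey, rbcL for diatoms), and the
#' host (predator) species of every sample.
#'
#' @param counts integer matrix, OTUs as rows, samples as columns, with
#'   dimnames.
#' @param taxonomy character vector, one semicolon-ranked taxonomy string per
#'   OTU (possibly \code{"unassigned"}).
#' @param marker \code{"COI"} or \code{"rbcL"}.
#' @param host_species character vector, one of \code{"anchovy"} /
#'   \code{"sardine"} per sample.
#' @return object of class \code{otu_table}.
#' @export
otu_table <- function(counts, taxonomy, marker = c("COI", "rbcL"),
                      host_species) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("read counts must be non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and sample column names")
  if (length(taxonomy) != nrow(counts))
    stop("one taxonomy string per OTU required")
  if (length(host_species) != ncol(counts))
    stop("one host species per sample required")
  if (any(!host_species %in% c("anchovy", "sardine")))
    stop("host species must be 'anchovy' or 'sardine'")
  structure(list(counts = counts,
                 taxonomy = setNames(as.character(taxonomy), rownames(counts)),
                 marker = marker,
                 host_species = setNames(host_species, colnames(counts))),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table (%s marker): %d OTUs x %d samples, %d reads\n",
              x$marker, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

new_filter_log <- function() {
  data.frame(step = character(), otus_removed = integer(),
             samples_removed = integer(), reads_removed = numeric(),
             stringsAsFactors = FALSE)
}

log_step <- function(log, step, before, after) {
  rbind(log, data.frame(
    step = step,
    otus_removed = nrow(before) - nrow(after),
    samples_removed = ncol(before) - ncol(after),
    reads_removed = sum(before) - sum(after),
    stringsAsFactors = FALSE))
}

#' OTU-table hygiene filter cascade
#'
#' Applies, in order, the post-clustering filters used for diet
#' metabarcoding tables; all threshold comparisons are strict
#' ("below X" removes, ties are retained):
#' \enumerate{
#'   \item drop OTUs whose read fraction over the whole dataset is strictly
#'     below \code{global_min_frac} (rare-noise removal);
#'   \item zero out cells whose within-sample read fraction is strictly below
#'     \code{sample_min_frac} (mistagging correction; sample totals are taken
#'     after step 1);
#'   \item taxonomic cleanup: for the COI (zooplankton) marker, drop OTUs
#'     with unassigned taxonomy; for the rbcL marker, keep only diatom OTUs;
#'   \item zero OTUs of the predator genus in samples of that host species
#'     (anchovy OTUs in anchovy guts, sardine OTUs in sardine guts);
#'   \item for the COI marker only, drop samples left with fewer than
#'     \code{min_sample_reads} reads.
#' }
#' OTUs or samples whose counts become all-zero along the way are dropped and
#' attributed to the responsible step. An empty result is returned (with its
#' log), not raised as an error.
#'
#' @param x an \code{\link{otu_table}}.
#' @param global_min_frac global frequency threshold, in percent
#'   (default 0.005, i.e. 0.005\%).
#' @param sample_min_frac within-sample frequency threshold, in percent
#'   (default 0.01).
#' @param min_sample_reads minimum surviving reads per COI sample
#'   (default 20).
#' @param predator_patterns named character vector mapping host species to a
#'   regex matched against OTU taxonomy.
#' @param diatom_pattern regex identifying diatom taxonomy (rbcL step 3).
#' @param unassigned_pattern regex identifying unassigned taxonomy (COI
#'   step 3).
#' @return list with the filtered \code{table} and the \code{log}
#'   (data.frame: step, otus_removed, samples_removed, reads_removed).
#' @export
filter_otu_table <- function(x,
                             global_min_frac = 0.005,
                             sample_min_frac = 0.01,
                             min_sample_reads = 20,
                             predator_patterns = c(anchovy = "Engraulis",
                                                   sardine = "Sardina"),
                             diatom_pattern = "Bacillariophyta",
                             unassigned_pattern = "^unassigned$") {
  stopifnot(inherits(x, "otu_table"))
  if (global_min_frac < 0 || sample_min_frac < 0 || min_sample_reads < 0)
    stop("thresholds must be non-negative")
  log <- new_filter_log()
  m <- x$counts
  tax <- x$taxonomy
  host <- x$host_species

  drop_empty <- function(m, otus = TRUE, samples = FALSE) {
    if (otus) m <- m[rowSums(m) > 0, , drop = FALSE]
    if (samples) m <- m[, colSums(m) > 0, drop = FALSE]
    m
  }

  # 1. global rare-OTU removal
  before <- m
  total <- sum(m)
  if (total > 0) {
    frac <- 100 * rowSums(m) / total
    m <- m[frac >= global_min_frac, , drop = FALSE]
  }
  log <- log_step(log, "global_frequency", before, m)

  # 2. per-sample mistagging correction
  before <- m
  if (ncol(m) > 0 && nrow(m) > 0) {
    stot <- colSums(m)
    frac <- 100 * sweep(m, 2L, pmax(stot, 1L), `/`)
    m[frac < sample_min_frac & stot[col(m)] > 0] <- 0L
    m <- drop_empty(m)
  }
  log <- log_step(log, "sample_frequency_mistag", before, m)

  # 3. taxonomy cleanup
  before <- m
  if (nrow(m) > 0) {
    keep <- if (x$marker == "COI") !grepl(unassigned_pattern, tax[rownames(m)])
            else grepl(diatom_pattern, tax[rownames(m)])
    m <- m[keep, , drop = FALSE]
  }
  log <- log_step(log, "taxonomic_assignment", before, m)

  # 4. predator removal, per host species
  before <- m
  if (nrow(m) > 0) for (sp in names(predator_patterns)) {
    hit_otu <- grepl(predator_patterns[[sp]], tax[rownames(m)])
    hit_sample <- host[colnames(m)] == sp
    if (any(hit_otu) && any(hit_sample))
      m[hit_otu, hit_sample] <- 0L
  }
  m <- drop_empty(m)
  log <- log_step(log, "predator_removal", before, m)

  # 5. low-read sample removal (zooplankton marker only)
  before <- m
  if (x$marker == "COI" && ncol(m) > 0) {
    m <- m[, colSums(m) >= min_sample_reads, drop = FALSE]
    m <- drop_empty(m)
  }
  log <- log_step(log, "low_read_samples", before, m)

  out <- x
  out$counts <- m
  out$taxonomy <- tax[rownames(m)]
  out$host_species <- host[colnames(m)]
  list(table = out, log = log)
}

# species-level information present? convention: ranked taxonomy separated by
# ";" whose last field is the (non-empty) species epithet
has_species_level <- function(taxonomy) {
  open_ended <- grepl(";\\s*$", taxonomy)  # trailing rank left empty
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    p <- trimws(p)
    length(p) >= 1L && nzchar(p[length(p)]) &&
      !grepl("unclassified|unassigned|_sp\\.?$", p[length(p)],
             ignore.case = TRUE)
  }, logical(1L))
  ok & !open_ended
}

#' Occurrence summary of a filtered OTU table
#'
#' Percent frequency of occurrence (\%FO) of each taxon per stratum
#' (host species x area), from presence/absence of the filtered reads.
#' Percentages are computed per sampling site and averaged across the sites
#' of an area, as for the microscope composition summaries. For the rbcL
#' (diatom) marker, taxa without species-level taxonomy are pooled as
#' \code{"Diatom remains"}, and taxa whose overall occurrence falls strictly
#' below the chosen percentile of the nonzero occurrence-frequency
#' distribution are pooled as \code{"Other diatom groups"}; pooled rows use
#' the union of their members' presences.
#'
#' @param x a filtered \code{\link{otu_table}}.
#' @param samples data.frame with columns \code{sample_id}, \code{area},
#'   \code{site_id} covering every sample column.
#' @param diatom_percentile percentile (0-100) below which rbcL taxa are
#'   merged (default 70); computed with linear interpolation over the nonzero
#'   overall occurrence frequencies.
#' @param merge_diatoms apply the rbcL merge rules (default TRUE for rbcL).
#' @return long data.frame: species, area, taxon, fo (percent), n_samples,
#'   n_sites.
#' @export
occurrence_summary <- function(x, samples, diatom_percentile = 70,
                               merge_diatoms = x$marker == "rbcL") {
  stopifnot(inherits(x, "otu_table"))
  m <- x$counts
  if (ncol(m) == 0L) stop("no samples in table")
  meta <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  if (anyNA(meta$area)) stop("sample metadata missing for some samples")
  pres <- m > 0

  if (merge_diatoms) {
    tax <- x$taxonomy[rownames(m)]
    named <- has_species_level(tax)
    # overall occurrence (percent of all samples), zero rows excluded from
    # the percentile computation
    occ <- 100 * rowMeans(pres)
    occ_named <- occ[named & occ > 0]
    thr <- if (length(occ_named)) {
      quantile(occ_named, probs = diatom_percentile / 100, type = 7)
    } else Inf
    rare <- named & occ < thr & occ > 0
    keep <- named & !rare
    merged <- list()
    if (any(!named))
      merged[["Diatom remains"]] <- colSums(pres[!named, , drop = FALSE]) > 0
    if (any(rare))
      merged[["Other diatom groups"]] <- colSums(pres[rare, , drop = FALSE]) > 0
    pres <- rbind(pres[keep, , drop = FALSE], do.call(rbind, merged))
  }

  host <- x$host_species[colnames(m)]
  key <- interaction(host, meta$area, drop = TRUE, sep = "|")
  out <- list()
  for (k in levels(key)) {
    sel <- key == k
    sub <- pres[, sel, drop = FALSE]
    sites <- meta$site_id[sel]
    per_site <- vapply(unique(sites), function(s)
      100 * rowMeans(sub[, sites == s, drop = FALSE]),
      numeric(nrow(sub)))
    fo <- if (is.null(dim(per_site))) per_site else rowMeans(per_site)
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    out[[k]] <- data.frame(species = parts[1L], area = parts[2L],
                           taxon = rownames(sub), fo = unname(fo),
                           n_samples = sum(sel),
                           n_sites = length(unique(sites)),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
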