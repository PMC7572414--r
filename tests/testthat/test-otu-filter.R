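test_that("global and per-sample thresholds are strict (ties retained)", {
  x <- toy_filter_table()
  res <- filter_otu_table(x)
  m <- res$table$counts
  # 4 reads of 100,000 = 0.004% -> removed; 5 reads = 0.005% -> retained
  expect_false("OTU_R1" %in% rownames(m))
  expect_false("OTU_R2" %in% rownames(m))
  expect_true("OTU_R4" %in% rownames(m))
  expect_equal(m["OTU_R4", "S02"], 5L)
  # cell of exactly 0.01% of its sample is retained, strictly-below removed
  expect_equal(m["OTU_M1", "S01"], 1L)
  expect_equal(m["OTU_M2", "S02"], 0L)
  expect_equal(m["OTU_M2", "S06"], 10L)
})

test_that("predator OTUs are zeroed only in samples of their own host", {
  res <- filter_otu_table(toy_filter_table())
  m <- res$table$counts
  expect_equal(m["OTU_E", "S01"], 0L)    # anchovy host: Engraulis removed
  expect_equal(m["OTU_E", "S11"], 300L)  # sardine host: untouched
  expect_equal(m["OTU_S", "S12"], 0L)    # sardine host: Sardina removed
  expect_equal(m["OTU_S", "S02"], 200L)  # anchovy host: untouched
})

test_that("the filter log records the constructed cascade exactly", {
  res <- filter_otu_table(toy_filter_table())
  log <- res$log
  expect_equal(log$step,
               c("global_frequency", "sample_frequency_mistag",
                 "taxonomic_assignment", "predator_removal",
                 "low_read_samples"))
  # 3 rare OTUs (4 reads each) + 20 all-zero padding OTUs
  expect_equal(log$otus_removed, c(23L, 0L, 2L, 0L, 1L))
  expect_equal(log$samples_removed, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(log$reads_removed, c(12, 1, 70, 900, 19))
  expect_equal(dim(res$table$counts), c(24L, 19L))
  expect_false("S20" %in% colnames(res$table$counts))
  expect_false("OTU_T" %in% rownames(res$table$counts))
})

test_that("the low-read sample drop applies to the COI marker only", {
  x <- toy_filter_table()
  x$marker <- "rbcL"
  # rbcL keeps only diatom OTUs; relabel everything diatom to isolate step 5
  x$taxonomy[] <- sub("^Calanoida", "Bacillariophyta", x$taxonomy)
  x$taxonomy[c("OTU_U1", "OTU_U2")] <- "unassigned"
  res <- filter_otu_table(x)
  expect_true("S20" %in% colnames(res$table$counts))
  expect_equal(res$log$samples_removed[res$log$step == "low_read_samples"], 0L)
})

test_that("the cascade is idempotent and read totals are non-increasing", {
  study <- default_study()
  r1 <- filter_otu_table(study$otu_coi)
  r2 <- filter_otu_table(r1$table)
  expect_equal(r2$table$counts, r1$table$counts)
  expect_true(all(r1$log$reads_removed >= 0))
  # toy table too
  t1 <- filter_otu_table(toy_filter_table())
  t2 <- filter_otu_table(t1$table)
  expect_equal(t2$table$counts, t1$table$counts)
})

test_that("filtering commutes with sample and OTU reordering", {
  x <- toy_filter_table()
  ro <- sample(nrow(x$counts)); co <- sample(ncol(x$counts))
  y <- otu_table(x$counts[ro, co], x$taxonomy[ro], marker = "COI",
                 host_species = x$host_species[co])
  a <- filter_otu_table(x)$table$counts
  b <- filter_otu_table(y)$table$counts
  expect_equal(sort(rownames(a)), sort(rownames(b)))
  expect_equal(a[sort(rownames(a)), sort(colnames(a))],
               b[sort(rownames(a)), sort(colnames(a))])
})

test_that("ground-truth mistags are removed and true diet cells survive", {
  study <- default_study()
  res <- filter_otu_table(study$otu_coi)
  m <- res$table$counts
  gt <- study$ground_truth$mistag_cells
  surviving <- vapply(seq_len(nrow(gt)), function(i) {
    o <- gt$otu[i]; s <- gt$sample[i]
    o %in% rownames(m) && s %in% colnames(m) && m[o, s] > 0
  }, logical(1L))
  expect_gte(mean(!surviving), 0.95)
  # true diet presences: diet OTUs with reads before filtering
  raw <- study$otu_coi$counts
  diet_otus <- setdiff(rownames(raw),
                       c(study$ground_truth$rare_otus,
                         grep("pred|unassigned", rownames(raw),
                              value = TRUE)))
  mist_key <- paste(gt$otu, gt$sample)
  truth <- which(raw[diet_otus, , drop = FALSE] > 0, arr.ind = TRUE)
  keys <- paste(diet_otus[truth[, 1L]], colnames(raw)[truth[, 2L]])
  true_cells <- keys[!keys %in% mist_key]
  kept <- vapply(strsplit(true_cells, " "), function(k) {
    k[1] %in% rownames(m) && k[2] %in% colnames(m) && m[k[1], k[2]] > 0
  }, logical(1L))
  expect_lte(mean(!kept), 0.05)
})

test_that("occurrence percentile merge matches a brute-force union oracle", {
  # five diatom taxa with overall occurrences 50, 30, 10, 5, 2 percent
  samples <- sprintf("d%02d", 1:50)
  occ <- c(25, 15, 5, 3, 1)  # samples present, of 50
  m <- matrix(0L, 5, 50, dimnames = list(sprintf("D%d", 1:5), samples))
  set.seed(42)
  present <- lapply(occ, function(k) sample(50, k))
  for (i in 1:5) m[i, present[[i]]] <- 100L
  tax <- sprintf("Bacillariophyta;Fam;Gen;Gen sp%d", 1:5)
  x <- otu_table(m, tax, marker = "rbcL",
                 host_species = rep("anchovy", 50))
  meta <- data.frame(sample_id = samples, area = "A1", site_id = "s1",
                     stringsAsFactors = FALSE)
  res <- occurrence_summary(x, meta, diatom_percentile = 70)
  # brute force: threshold = 70th percentile of {50,30,10,6,2}
  ov <- 100 * rowMeans(m > 0)
  thr <- quantile(ov[ov > 0], 0.7, type = 7)
  rare <- names(ov)[ov < thr & ov > 0]
  union_occ <- 100 * mean(colSums(m[rare, , drop = FALSE] > 0) > 0)
  merged <- res$fo[res$taxon == "Other diatom groups"]
  expect_equal(merged, union_occ)
  expect_setequal(res$taxon,
                  c(setdiff(rownames(m), rare), "Other diatom groups"))
})

test_that("no-species diatoms become 'Diatom remains'; zero taxa report 0%", {
  m <- matrix(c(10L, 10L, 0L, 0L,
                5L, 0L, 0L, 0L,
                0L, 0L, 0L, 0L), 3, 4, byrow = TRUE,
              dimnames = list(c("D1", "D2", "D3"), sprintf("s%d", 1:4)))
  tax <- c("Bacillariophyta;Fam;Gen;Gen sp1",
           "Bacillariophyta;Fam;Gen;",       # no species epithet
           "Bacillariophyta;Fam;Gen;Gen sp3")
  x <- otu_table(m, tax, marker = "rbcL", host_species = rep("sardine", 4))
  meta <- data.frame(sample_id = sprintf("s%d", 1:4), area = "A1",
                     site_id = "s1", stringsAsFactors = FALSE)
  res <- occurrence_summary(x, meta, diatom_percentile = 0)
  expect_true("Diatom remains" %in% res$taxon)
  expect_equal(res$fo[res$taxon == "Diatom remains"], 25)
  expect_equal(res$fo[res$taxon == "D3"], 0)  # all-zero taxon reported at 0
})

test_that("occurrence %FO is percent of stratum samples with presence", {
  m <- matrix(0L, 1, 10, dimnames = list("D1", sprintf("s%d", 1:10)))
  m[1, 1:2] <- 50L
  x <- otu_table(m, "Calanoida;F;G;G sp1", marker = "COI",
                 host_species = rep("anchovy", 10))
  meta <- data.frame(sample_id = sprintf("s%d", 1:10), area = "A1",
                     site_id = "s1", stringsAsFactors = FALSE)
  res <- occurrence_summary(x, meta)
  expect_equal(res$fo, 20)
})
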