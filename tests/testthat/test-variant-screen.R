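test_that("the prevalence filter keeps truncating variants seen in >= 2 individuals", {
  tab <- data.frame(
    gene = c("G1", "G2", "G3", "G4", "G5"),
    hgvs_p = c("Q100*", "L7Qfs*21", "V5M", "A9V", "K3R"),
    source = "DB",
    het = c(3, 1, 10, 10, 10), hom = 0)
  out <- civa_filter(tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene, "G1")
  expect_equal(out$n_individuals, 3L)
  expect_false(out$homozygous_observed)
})

test_that("a high-frequency frameshift with homozygous carriers is flagged", {
  tab <- data.frame(gene = "SKA3", hgvs_p = "Q70Kfs*7", source = "GH",
                    het = 1906, hom = 2)
  out <- civa_filter(tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_individuals, 1908L)
  expect_true(out$homozygous_observed)

  # single carrier excluded at the default threshold
  one <- data.frame(gene = "G", hgvs_p = "Q10*", source = "DB",
                    het = 1, hom = 0)
  expect_equal(nrow(civa_filter(one)), 0L)
  expect_equal(nrow(civa_filter(one, min_individuals = 1)), 1L)
})

test_that("filter equals the brute-force oracle on random tables", {
  for (seed in 1:25) {
    tab <- random_variant_table(n = sample(20:200, 1), seed = seed)
    for (ss in c(FALSE, TRUE)) {
      got <- civa_filter(tab, sum_sources = ss)
      expect_equal(sort(paste(got$gene, got$hgvs_p, sep = "|")),
                   brute_civa(tab, sum_sources = ss),
                   info = paste("seed", seed, "sum", ss))
    }
  }
})

test_that("filter and merge are invariant under row permutation", {
  tab <- random_variant_table(80, seed = 42)
  tab <- tab[!duplicated(paste(tab$gene, tab$hgvs_p, tab$source)), ]
  set.seed(1)
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(civa_filter(tab), civa_filter(perm))
  expect_equal(merge_databases(tab), merge_databases(perm))
})

test_that("candidates satisfy their own invariants", {
  tab <- random_variant_table(150, seed = 7)
  out <- civa_filter(tab)
  expect_true(all(out$n_individuals >= 2))
  expect_true(all(out$class %in% c("stop_gain", "frameshift")))
  hom_by_key <- tapply(tab$hom, paste(tab$gene, normalize_hgvs_p(tab$hgvs_p),
                                      sep = "|"), sum)
  expect_equal(out$homozygous_observed,
               as.vector(hom_by_key[paste(out$gene, out$hgvs_p, sep = "|")] >= 1))
})

test_that("cross-database merging keeps one count entry per source", {
  gh <- data.frame(gene = "SPAG5", hgvs_p = "L7Qfs*21", source = "GH",
                   het = 134, hom = 1)
  gn <- data.frame(gene = "SPAG5", hgvs_p = "p.(L7Qfs*21)", source = "gnomAD",
                   het = 320, hom = 6)
  m <- merge_databases(list(gh, gn))
  expect_equal(nrow(m), 2L)
  expect_equal(sort(m$source), c("GH", "gnomAD"))
  expect_equal(m$het[m$source == "GH"], 134)
  expect_equal(m$hom[m$source == "gnomAD"], 6)
  expect_equal(unique(m$hgvs_p), "L7Qfs*21")   # normalized key

  # disjoint variants concatenate
  other <- data.frame(gene = "SKA3", hgvs_p = "R27*", source = "COSMIC",
                      het = 5, hom = 0)
  expect_equal(nrow(merge_databases(list(gh, other))), 2L)

  # the same (gene, variant, source) row twice is an error
  expect_error(merge_databases(list(gh, gh)), "duplicate")
})

test_that("allele frequency is the diploid carrier formula and is monotone", {
  expect_equal(allele_frequency(0, 0, 500), 0)
  expect_equal(allele_frequency(2, 1, 100), 0.02)
  expect_equal(allele_frequency(0, 250, 250), 1)
  expect_error(allele_frequency(1, 0, 0), "positive")
  expect_error(allele_frequency(80, 30, 100), "exceed")
  set.seed(3)
  for (i in 1:20) {
    het <- sample(0:50, 1); hom <- sample(0:20, 1); n <- 200
    f0 <- allele_frequency(het, hom, n)
    expect_gte(allele_frequency(het + 1, hom, n), f0)
    expect_gte(allele_frequency(het, hom + 1, n), f0)
    expect_equal(f0 == 0, het == 0 && hom == 0)
  }
})

test_that("lollipop export tabulates positions by category", {
  expect_equal(nrow(lollipop_export("G", data.frame(
    gene = character(), hgvs_p = character(), source = character(),
    het = integer(), hom = integer()))), 0L)
  rec <- data.frame(gene = "SPAG5",
                    hgvs_p = c("Q1012*", "Q1012*", "V5M"),
                    source = c("A", "B", "A"),
                    het = c(1, 1, 3), hom = 0)
  out <- lollipop_export("SPAG5", rec)
  expect_equal(out$position, c(5L, 1012L))
  expect_equal(out$category, c("missense", "truncating"))
  expect_equal(out$n_occurrences, c(3L, 2L))
  expect_equal(out$n_homozygous, c(0L, 0L))

  hom <- data.frame(gene = "G", hgvs_p = "Q9*", source = "A", het = 0, hom = 1)
  expect_equal(lollipop_export("G", hom)$n_homozygous, 1L)
  expect_error(lollipop_export("OTHER", rec), "different gene")
})

test_that("the CIVa database round-trips and resolves both query keys", {
  rec <- data.frame(gene = "SPAG5", uniprot = "Q96R06",
                    hgvs_p = c("Q1012*", "L7Qfs*21"),
                    source = "GH", het = c(2, 134), hom = c(0, 1))
  doc <- civa_db_export(rec)
  expect_identical(civa_db_query(doc, "SPAG5"), civa_db_query(doc, "Q96R06"))
  expect_equal(civa_db_query(doc, "SPAG5")$variants[[2]]$sources$GH$het, 134L)
  expect_null(civa_db_query(doc, "NOPE"))

  # export -> import round trip through a file
  sim <- sim_variant_table(variant_sim_config(n_genes = 10, seed = 5))
  rec10 <- sim$records
  rec10$uniprot <- paste0("U", rec10$gene)
  f <- tempfile(fileext = ".json")
  civa_db_export(rec10, f)
  back <- civa_db_import(f)
  expect_equal(length(back$genes), 10L)
  orig <- civa_db_export(rec10)
  expect_equal(jsonlite::toJSON(back, auto_unbox = TRUE),
               jsonlite::toJSON(orig, auto_unbox = TRUE))

  # scale: one entry per gene on a 135-gene table
  sim135 <- sim_variant_table(variant_sim_config(n_genes = 135, seed = 2))
  expect_equal(length(civa_db_export(sim135$records)$genes), 135L)

  dup <- rbind(rec, transform(rec, uniprot = "OTHER"))
  expect_error(civa_db_export(dup), "multiple UniProt")
})

test_that("variant tables read back from TSV and CSV", {
  rec <- data.frame(gene = "SPAG5", hgvs_p = "Q1012*", source = "GH",
                    het = 2, hom = 0)
  tsv <- tempfile(fileext = ".tsv")
  write.table(rec, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_variant_table(tsv)$hgvs_p, "Q1012*")
  csv <- tempfile(fileext = ".csv")
  write.csv(rec, csv, row.names = FALSE)
  expect_equal(read_variant_table(csv)$het, 2)
})
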