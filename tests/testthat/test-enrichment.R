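# Hand-built one-genome fixture: 1000 genes, 100 labeled "X"; one
# rearranged block of 10 genes containing 3 of the X genes.
enrichment_fixture <- function() {
  n <- 1000
  cat <- rep("", n)
  cat[1:97] <- "X"           # 97 X outside the block
  cat[101:190] <- "K"        # 90 K outside the block
  # block spans genes 201..210 by coordinates: 3 X + 7 K, so genome-wide
  # totals are exactly 100 X and 900 non-X
  cat[201:210] <- c("X", "X", "X", rep("K", 7))
  starts <- (seq_len(n) - 1) * 100 + 1
  g <- genome_record(
    "q1", "sp", TRUE, n * 100,
    data.frame(gene_id = sprintf("g%04d", seq_len(n)), family_id = "",
               strand = "+", start = starts, end = starts + 50,
               cog_id = ifelse(nzchar(cat), paste0("COG_", cat), ""),
               cog_category = cat, is_transposase = cat == "X",
               stringsAsFactors = FALSE))
  blocks <- data.frame(
    families = c("+f1,+f2", "+f3,+f4"), n_core = c(50, 2),
    n_total_genes = c(900, 10), orientation = c("forward", "forward"),
    frac_sign_flipped = 0, midpoint_bp = c(NA, 20500),
    query_start = c(80026, 20026), query_end = c(99926, 20926),
    ref_start_index = c(1, 5), identity_key = c("k1", "k2"),
    is_backbone = c(TRUE, FALSE),
    classification = c("backbone", "translocation"),
    stringsAsFactors = FALSE)
  part <- structure(list(ref_id = "ref", query_id = "q1", blocks = blocks,
                         n_blocks = 2, n_singletons_discarded = 0,
                         n_shared = 52, flipped = FALSE),
                    class = "block_partition")
  list(genome = g, partition = part)
}

test_that("contingency tables count block genes against whole genomes", {
  fx <- enrichment_fixture()
  tabs <- count_cogs(list(fx$partition), list(fx$genome),
                     scope = "all", level = "category")
  x <- tabs[tabs$cog == "X", ]
  expect_equal(c(x$a, x$b, x$c, x$d), c(3, 7, 100, 900))
  k <- tabs[tabs$cog == "K", ]
  expect_equal(c(k$a, k$b), c(7, 3))
  # the genome-wide side includes the block genes unless disjoint
  tabs_d <- count_cogs(list(fx$partition), list(fx$genome),
                       scope = "all", level = "category", disjoint = TRUE)
  xd <- tabs_d[tabs_d$cog == "X", ]
  expect_equal(c(xd$a, xd$c), c(3, 97))
  expect_equal(xd$d, 900 - 7)
  # scope filtering: no inversions in the fixture
  expect_warning(
    inv <- count_cogs(list(fx$partition), list(fx$genome),
                      scope = "inversion"), "no non-backbone")
  expect_equal(nrow(inv), 0)
})

test_that("single-block genomes are excluded from the block side", {
  fx <- enrichment_fixture()
  single <- fx$partition
  single$n_blocks <- 1
  single$blocks <- single$blocks[1, ]
  expect_warning(tabs <- count_cogs(list(single), list(fx$genome)),
                 "no non-backbone")
  expect_equal(nrow(tabs), 0)
})

test_that("chi-square enrichment flags direction and corrects with BH", {
  fx <- enrichment_fixture()
  tabs <- count_cogs(list(fx$partition), list(fx$genome),
                     scope = "all", level = "category")
  res <- chi2_enrichment(tabs)
  expect_true(all(res$q >= res$p))
  x <- res[res$cog == "X", ]
  # 30% in the block vs 10% genome-wide on 10 block genes: directional but
  # weak; enrichment requires q < 0.05 AND excess frequency
  expect_equal(x$enriched, x$q < 0.05)
  # equal-proportion table gives chi2 = 0, p = 1, not enriched
  flat <- data.frame(cog = "Z", a = 10, b = 90, c = 100, d = 900,
                     scope = "all", gene_class = "both")
  rflat <- chi2_enrichment(flat)
  expect_equal(rflat$chi2, 0)
  expect_false(rflat$enriched)
})

test_that("functional composition columns are frequency distributions", {
  fx <- enrichment_fixture()
  comp <- functional_composition(list(fx$partition), list(fx$genome))
  for (col in setdiff(names(comp), "category"))
    expect_equal(sum(comp[[col]]), 1)
  expect_true("unannotated" %in% comp$category)
  # block column reflects the planted 3/10 X fraction
  expect_equal(comp$translocation[comp$category == "X"], 0.3)
})

test_that("planted mobilome excess in rearranged spans is recovered", {
  pars <- synth_params(n_genomes = 10, C = 150, accessory_per_interval = 1,
                       genome_length_bp = 6e5, gene_length_bp = 500,
                       rearr_per_branch = 1, transposase_boost = 5,
                       seed = 2024)
  bundle <- make_species(pars)
  core <- call_core_families(bundle$species, freq = 0.90)
  orders <- lapply(bundle$species$genomes, project_core_order, core = core)
  ref_id <- as.character(select_reference(orders))
  parts <- lapply(orders[setdiff(names(orders), ref_id)], function(q)
    suppressWarnings(find_blocks(orders[[ref_id]], q)))
  tabs <- count_cogs(parts, bundle$species, scope = "all",
                     level = "category")
  res <- chi2_enrichment(tabs)
  planted <- bundle$truth$enriched_category
  expect_true(res$enriched[res$cog == planted])
  decoys <- res[res$cog != planted, ]
  expect_gte(mean(!decoys$enriched), 0.9)
})

test_that("transposase correlation requires 3+ species and finds monotone links", {
  df <- data.frame(mean_blocks = c(1, 3, 5, 9),
                   transposase_density = c(0.5, 1.2, 2.0, 4.1))
  r <- transposase_correlation(df)
  expect_equal(r$statistic, 1)
  expect_error(transposase_correlation(df[1:2, ]), "at least 3")
  flat <- data.frame(mean_blocks = c(1, 2, 3),
                     transposase_density = c(1, 1, 1))
  expect_true(grepl("zero rank variance", transposase_correlation(flat)$note))
})
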