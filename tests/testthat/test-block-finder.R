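test_that("single events split an identity genome into the expected blocks", {
  ref <- core_order(1:6)
  expect_equal(find_blocks(ref, core_order(1:6))$n_blocks, 1)

  # internal inversion of [3,4]: backbone {5,6,1,2} + reverted {3,4}
  inv <- core_order(c(1, 2, 4, 3, 5, 6), signs = c(1, 1, -1, -1, 1, 1))
  p <- find_blocks(ref, inv)
  expect_equal(p$n_blocks, 2)
  expect_equal(sort(p$blocks$classification), c("backbone", "inversion"))
  expect_equal(p$blocks$orientation[p$blocks$classification == "inversion"],
               "reverted")

  # translocation of [3,4] between 6 and 7: three forward blocks
  ref8 <- core_order(1:8)
  tr <- core_order(c(1, 2, 5, 6, 3, 4, 7, 8))
  p8 <- find_blocks(ref8, tr)
  expect_equal(p8$n_blocks, 3)
  expect_equal(sort(p8$blocks$classification),
               c("backbone", "translocation", "translocation"))

  # translocation that leaves a stranded singleton {5}
  ps <- find_blocks(ref, core_order(c(1, 2, 5, 3, 4, 6)))
  expect_equal(ps$n_blocks, 2)
  expect_equal(ps$n_singletons_discarded, 1)

  # a whole-genome reverse complement is one block, zero events
  rc <- core_order(6:1, signs = rep(-1L, 6))
  prc <- find_blocks(ref, rc)
  expect_equal(prc$n_blocks, 1)
  expect_equal(nrow(rearranged_blocks(prc)), 0)
})

test_that("find_blocks matches the brute-force adjacency oracle", {
  set.seed(101)
  for (rep in 1:300) {
    C <- sample(4:12, 1)
    ref <- random_core_order(C, "ref")
    qry <- random_core_order(C, "qry")
    oracle <- brute_force_blocks(ref$families, qry$families)
    p <- suppressWarnings(find_blocks(ref, qry))
    expect_equal(p$n_blocks, oracle$retained,
                 info = paste("retained, rep", rep))
    expect_equal(p$n_singletons_discarded, oracle$singletons,
                 info = paste("singletons, rep", rep))
    # partition conservation: cores in blocks + singletons == shared size
    expect_equal(sum(p$blocks$n_core) + p$n_singletons_discarded, C)
    # counting is symmetric in the pair
    expect_equal(suppressWarnings(find_blocks(qry, ref))$n_blocks,
                 p$n_blocks)
  }
})

test_that("exactly one backbone exists and ties break deterministically", {
  ref <- core_order(1:8)
  p <- find_blocks(ref, core_order(c(1, 2, 5, 6, 3, 4, 7, 8)))
  expect_equal(sum(p$blocks$is_backbone), 1)
  # backbone is the largest block (4 cores vs 2 and 2)
  expect_equal(p$blocks$n_core[p$blocks$is_backbone], 4)

  # two blocks tied at max core size: smallest reference start wins
  ref4 <- core_order(1:4)
  q <- core_order(c(2, 1, 3, 4))  # blocks {3,4,...} arrangement varies
  p4 <- suppressWarnings(find_blocks(ref4, q))
  expect_equal(sum(p4$blocks$is_backbone), 1)
  if (sum(p4$blocks$n_core == max(p4$blocks$n_core)) > 1) {
    bb <- p4$blocks[p4$blocks$is_backbone, ]
    tied <- p4$blocks[p4$blocks$n_core == max(p4$blocks$n_core), ]
    expect_equal(bb$ref_start_index, min(tied$ref_start_index))
  }

  expect_error(classify_block(p$blocks[p$blocks$is_backbone, ]),
               "backbone")
})

test_that("reference selection minimizes the average block count", {
  # g2 is the unrearranged ancestor; g1 and g3 are independently rearranged
  g2 <- core_order(1:10, genome_id = "g2")
  g1 <- plant_rearrangements(
    core_order(1:10, genome_id = "g1"),
    list(list(type = "inversion", start = 3, len = 2)))$order
  g3 <- plant_rearrangements(
    core_order(1:10, genome_id = "g3"),
    list(list(type = "translocation", start = 6, len = 2, dest = 2)))$order
  orders <- list(g1, g2, g3)
  ref <- select_reference(orders)
  # independent check: enumerate candidate averages directly
  ids <- c("g1", "g2", "g3")
  avg <- sapply(seq_along(orders), function(i)
    mean(sapply(setdiff(seq_along(orders), i), function(j)
      find_blocks(orders[[i]], orders[[j]])$n_blocks)))
  expect_equal(as.character(ref), ids[which.min(avg)])
  expect_equal(as.character(ref), "g2")

  # identical genomes: lexicographically smallest id wins the tie
  same <- list(core_order(1:5, genome_id = "b"),
               core_order(1:5, genome_id = "a"))
  expect_equal(as.character(select_reference(same)), "a")
})

test_that("block deduplication removes identities seen more than twice", {
  ref <- core_order(1:8, genome_id = "ref")
  inv_q <- function(id) plant_rearrangements(
    core_order(1:8, genome_id = id),
    list(list(type = "inversion", start = 3, len = 2)))$order
  # different families than the inversion: identity keys are
  # orientation-normalized, so the same segment would share a key
  tr_q <- function(id) plant_rearrangements(
    core_order(1:8, genome_id = id),
    list(list(type = "translocation", start = 5, len = 2, dest = 3)))$order
  # the same inversion in three genomes, the same translocation in two
  parts <- c(lapply(paste0("i", 1:3), function(id)
    find_blocks(ref, inv_q(id))),
    lapply(paste0("t", 1:2), function(id) find_blocks(ref, tr_q(id))))
  kept <- dedup_blocks(parts)
  expect_false(any(kept$classification == "inversion"))
  expect_true(any(kept$classification == "translocation"))
  expect_equal(attr(kept, "n_removed"), 3)
})

test_that("a block and its reverted listing share one identity key", {
  k1 <- synbreak:::block_identity_key(c(1, 1), c("f3", "f4"))
  k2 <- synbreak:::block_identity_key(c(-1, -1), c("f4", "f3"))
  expect_equal(k1, k2)
  k3 <- synbreak:::block_identity_key(c(1, -1), c("f3", "f4"))
  expect_false(k1 == k3)
})

test_that("species summaries count events and exclude the reference", {
  ref <- core_order(1:10, genome_id = "gref")
  clean <- core_order(1:10, genome_id = "gclean")
  inv <- plant_rearrangements(
    core_order(1:10, genome_id = "ginv"),
    list(list(type = "inversion", start = 4, len = 3)))$order
  parts <- list(find_blocks(ref, clean), find_blocks(ref, inv),
                find_blocks(ref, core_order(1:10, genome_id = "gref")))
  s <- summarize_species(parts)
  expect_equal(nrow(s$per_genome), 2)  # self-comparison dropped
  expect_equal(s$per_genome$n_blocks[s$per_genome$genome_id == "gclean"], 1)
  expect_equal(s$per_genome$n_blocks[s$per_genome$genome_id == "ginv"], 2)
  expect_equal(s$per_genome$n_inversions[s$per_genome$genome_id == "ginv"],
               1)
  expect_equal(s$mean_blocks, 1.5)
})

test_that("extra random events never lower the expected block count", {
  set.seed(77)
  C <- 60
  idp <- core_order(seq_len(C))
  pars <- sim_params(C, seg_len_dist = list(kind = "uniform", min = 2,
                                            max = 6))
  mean_blocks <- sapply(c(1, 3, 6), function(k)
    mean(replicate(100, {
      sim <- simulate_rearrangements(idp, k, pars)
      suppressWarnings(find_blocks(idp, sim$order)$n_blocks)
    })))
  expect_true(all(diff(mean_blocks) > 0))
})
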