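# Shared fixtures and independent oracles.

# Independent brute-force block counter: a query adjacency is conserved iff
# its unordered family pair is adjacent on the reference circle; blocks are
# the runs between broken adjacencies. Deliberately set-based, a different
# route than the run-scan in find_blocks.
brute_force_blocks <- function(ref_families, qry_families) {
  n <- length(ref_families)
  ref_pairs <- vapply(seq_len(n), function(i) {
    j <- i %% n + 1
    paste(sort(c(ref_families[i], ref_families[j])), collapse = "|")
  }, character(1))
  broken <- vapply(seq_len(n), function(i) {
    j <- i %% n + 1
    !(paste(sort(c(qry_families[i], qry_families[j])), collapse = "|") %in%
        ref_pairs)
  }, logical(1))
  n_bp <- sum(broken)
  if (n_bp == 0) return(list(retained = 1L, singletons = 0L))
  # run lengths between breakpoints, walking the circle
  starts <- which(broken) %% n + 1
  lens <- diff(c(sort(starts), sort(starts)[1] + n))
  list(retained = sum(lens >= 2), singletons = sum(lens == 1))
}

random_core_order <- function(C, genome_id = "rand") {
  core_order(sample(sprintf("f%02d", seq_len(C))),
             signs = sample(c(1L, -1L), C, replace = TRUE),
             genome_id = genome_id)
}

# A minimal two-genome species with hand-placed genes, used by io and
# core-calling tests.
tiny_species <- function() {
  mk_genes <- function(fams, strands, start0 = 1, cog = "") {
    n <- length(fams)
    starts <- start0 + (seq_len(n) - 1) * 1000
    data.frame(gene_id = paste0(fams, "_g"), family_id = fams,
               strand = strands, start = starts, end = starts + 800,
               cog_id = ifelse(nzchar(cog), paste0("COG", seq_len(n)), ""),
               cog_category = rep(cog, n),
               is_transposase = rep(FALSE, n), stringsAsFactors = FALSE)
  }
  g1 <- genome_record("gA", "sp1", TRUE, 10000,
                      mk_genes(c("f1", "f2", "f3"), c("+", "+", "-")))
  g2 <- genome_record("gB", "sp1", TRUE, 10000,
                      mk_genes(c("f1", "f3", "f2"), c("+", "-", "+")))
  species_set(list(g1, g2))
}
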