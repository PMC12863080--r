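# Synthetic species with planted ground truth: clonal genomes sharing a
# single-copy core, interleaved accessory genes, planted inversions and
# translocations, substitutions on a core alignment, GC-skewed replichores
# and COG labels with a mobilome excess inside rearranged segments.

# One-letter COG functional classes with rough base frequencies; "X" is the
# mobilome class carrying transposases, "" is unannotated.
default_cog_frequencies <- function(p_mobilome = 0.02) {
  base <- c(J = 0.06, K = 0.07, L = 0.05, D = 0.02, V = 0.02, T = 0.04,
            M = 0.06, N = 0.01, U = 0.02, O = 0.04, C = 0.06, G = 0.07,
            E = 0.08, F = 0.02, H = 0.04, I = 0.03, P = 0.05, Q = 0.02,
            S = 0.14)
  base <- base / sum(base) * (1 - p_mobilome - 0.10)
  c(base, X = p_mobilome, `NA` = 0.10)  # "NA" slot becomes the empty label
}

#' Parameters of the synthetic-species generator
#'
#' Defaults emulate a well-sampled bacterial species at desk scale: ten
#' clonal genomes (the study design required more than five per species), a
#' single-copy core of 100 families with accessory genes interleaved, about
#' one rearrangement per genome, a clear replication-associated GC skew and
#' a mobilome excess inside rearranged segments.
#'
#' @param n_genomes Number of genomes (star genealogy from one ancestor).
#' @param C Core families (single copy, present in all genomes).
#' @param accessory_per_interval Poisson mean of accessory genes between
#'   consecutive core genes.
#' @param genome_length_bp Chromosome length.
#' @param gene_length_bp Gene length (uniform; must fit between gene slots).
#' @param sub_rate Substitutions per alignment site per branch.
#' @param rearr_per_branch Poisson mean of rearrangement events per genome.
#' @param p_inversion Probability an event is an inversion.
#' @param seg_len_dist Segment-length law (see [sim_params()]).
#' @param skew_delta Leading-strand G excess in (0, 1).
#' @param transposase_boost Multiplier on the mobilome labeling rate for
#'   genes inside rearranged segments.
#' @param p_mobilome_base Baseline mobilome-class frequency.
#' @param ori_frac,ter_frac Planted Ori/Ter as fractions of genome length.
#' @param seed Integer seed; the bundle is byte-identical under a fixed
#'   seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_genomes = 10, C = 100,
                         accessory_per_interval = 0.5,
                         genome_length_bp = 5e5, gene_length_bp = 900,
                         sub_rate = 0.002, rearr_per_branch = 1,
                         p_inversion = 0.5,
                         seg_len_dist = list(kind = "uniform", min = 2,
                                             max = max(2, C %/% 10)),
                         skew_delta = 0.5, transposase_boost = 5,
                         p_mobilome_base = 0.02,
                         ori_frac = 0.25, ter_frac = 0.75, seed = 1) {
  if (C < 10) stop("C must be at least 10")
  if (skew_delta <= 0 || skew_delta >= 1) stop("skew_delta must be in (0, 1)")
  if (n_genomes < 2) stop("need at least 2 genomes")
  structure(as.list(environment()), class = "synth_params")
}

#' Generate a GC-skewed circular sequence with planted Ori and Ter
#'
#' Emulates replication-associated strand mutation bias: on the leading
#' replichore (the Ori-to-Ter arc in ascending coordinates) a G/C position
#' is G with probability (1 + delta)/2, on the other replichore with
#' probability (1 - delta)/2; half of all positions are A/T filler. The
#' cumulative GC skew of such a sequence falls to a minimum at Ori and
#' rises to a maximum at Ter.
#'
#' @param length_bp Sequence length.
#' @param ori_bp,ter_bp Planted switch points (1-based, distinct).
#' @param delta Leading-strand G excess in (0, 1).
#' @param seed Optional integer seed.
#' @return A nucleotide string.
#' @export
make_skewed_sequence <- function(length_bp, ori_bp, ter_bp, delta,
                                 seed = NULL) {
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  if (ori_bp == ter_bp) stop("ori and ter must differ")
  if (!is.null(seed)) set.seed(seed)
  pos <- seq_len(length_bp)
  arc1 <- (ter_bp - ori_bp) %% length_bp
  leading <- ((pos - ori_bp) %% length_bp) < arc1
  is_gc <- stats::runif(length_bp) < 0.5
  p_g <- ifelse(leading, (1 + delta) / 2, (1 - delta) / 2)
  g_draw <- stats::runif(length_bp) < p_g
  at_draw <- stats::runif(length_bp) < 0.5
  chars <- ifelse(is_gc, ifelse(g_draw, "G", "C"),
                  ifelse(at_draw, "A", "T"))
  paste(chars, collapse = "")
}

#' Generate a synthetic species bundle with planted ground truth
#'
#' Builds one ancestral genome (core families in identity order, accessory
#' genes interleaved, COG labels drawn from base frequencies) and derives
#' `n_genomes` descendants along a star genealogy. Per branch, a Poisson
#' number of rearrangement events is applied via the same event model the
#' rate calibration uses, and Poisson substitutions are placed (without
#' replacement) on a generated core alignment. Each genome receives a
#' GC-skewed sequence with the planted Ori/Ter. Genes inside rearranged
#' segments are relabeled to the mobilome class at `transposase_boost`
#' times the base rate, planting a recoverable enrichment signal. The truth
#' log records every event, substitution site, and label.
#'
#' @param params A [synth_params()].
#' @return Object of class `species_bundle`: `species` ([species_set()]
#'   with sequences attached), `alignment`, `params`, `truth` (per-genome
#'   `events` and `k`, `moved_families`, `sub_sites`, `pairwise_S` matrix,
#'   `ori_bp`, `ter_bp`, `enriched_category`, `core_families`).
#' @export
make_species <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  C <- params$C
  fams <- sprintf("F%04d", seq_len(C))
  anc_signs <- sample(c(1L, -1L), C, replace = TRUE)
  anc <- core_order(fams, anc_signs, genome_id = "ancestor",
                    genome_length = params$genome_length_bp)

  # accessory genes attached to the core family they follow
  n_acc <- stats::rpois(C, params$accessory_per_interval)
  acc_ids <- lapply(seq_len(C), function(i)
    if (n_acc[i] > 0) sprintf("A%04d_%02d", i, seq_len(n_acc[i]))
    else character(0))
  acc_strands <- lapply(n_acc, function(k) sample(c("+", "-"), k,
                                                  replace = TRUE))

  cog_freq <- default_cog_frequencies(params$p_mobilome_base)
  draw_cogs <- function(n) {
    cat <- sample(names(cog_freq), n, replace = TRUE, prob = cog_freq)
    cat[cat == "NA"] <- ""
    id <- ifelse(nzchar(cat),
                 paste0("COG", match(cat, names(cog_freq)), "00",
                        sample(0:9, n, replace = TRUE)),
                 "")
    data.frame(cog_category = cat, cog_id = id,
               is_transposase = cat == "X", stringsAsFactors = FALSE)
  }
  core_cogs <- draw_cogs(C); rownames(core_cogs) <- fams
  acc_cogs <- draw_cogs(sum(n_acc))
  rownames(acc_cogs) <- unlist(acc_ids)

  # core alignment: ancestor sequence + per-branch substitutions
  L <- C * params$gene_length_bp
  anc_aln <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  sim_par <- sim_params(C, p_inversion = params$p_inversion,
                        seg_len_dist = params$seg_len_dist,
                        seed = params$seed)

  genome_ids <- sprintf("g%02d", seq_len(params$n_genomes))
  ori_bp <- round(params$ori_frac * params$genome_length_bp)
  ter_bp <- round(params$ter_frac * params$genome_length_bp)
  p_boost <- min(1, params$p_mobilome_base * params$transposase_boost)

  truth <- list(ori_bp = ori_bp, ter_bp = ter_bp,
                enriched_category = "X", core_families = fams,
                genomes = list())
  sub_maps <- list()
  genomes <- list()

  # first pass: rearrangement histories and substitutions per branch
  sims <- list()
  for (gid in genome_ids) {
    k <- stats::rpois(1, params$rearr_per_branch)
    sim <- simulate_rearrangements(anc, k, sim_par)
    # replay events to collect the families that were ever inside an arc
    moved <- character(0)
    f <- anc$families; s <- anc$signs
    for (ev in sim$truth) {
      idx <- ((ev$start:(ev$start + ev$len - 1)) - 1L) %% C + 1L
      moved <- union(moved, f[idx])
      r <- apply_event(f, s, ev$type, ev$start, ev$len,
                       dest = if (!is.null(ev$dest)) ev$dest else NA)
      f <- r$fams; s <- r$signs
    }
    sims[[gid]] <- list(k = k, sim = sim, moved = moved)

    m <- stats::rpois(1, params$sub_rate * L)
    sites <- sample.int(L, min(m, L))
    new_base <- vapply(sites, function(s)
      sample(setdiff(c("A", "C", "G", "T"), anc_aln[s]), 1), character(1))
    sub_maps[[gid]] <- stats::setNames(new_base, sites)
  }

  # second pass: gene tables and sequences; mobilome planting marks genes
  # of segments that moved on this genome's own branch
  for (gid in genome_ids) {
    k <- sims[[gid]]$k
    sim <- sims[[gid]]$sim
    perm <- sim$order$families
    signs <- sim$order$signs
    gene_id <- character(0); family_id <- character(0)
    strand <- character(0)
    for (j in seq_len(C)) {
      fam <- perm[j]
      i <- match(fam, fams)
      flip <- signs[j] != anc_signs[i]
      gene_id <- c(gene_id, fam, acc_ids[[i]])
      family_id <- c(family_id, fam, rep("", n_acc[i]))
      core_strand <- if (signs[j] > 0) "+" else "-"
      acc_str <- acc_strands[[i]]
      if (flip) acc_str <- chartr("+-", "-+", acc_str)
      strand <- c(strand, core_strand, acc_str)
    }
    n_tot <- length(gene_id)
    slot <- params$genome_length_bp %/% n_tot
    if (params$gene_length_bp >= slot)
      stop("gene_length_bp too large for ", n_tot, " genes on ",
           params$genome_length_bp, " bp")
    start <- (seq_len(n_tot) - 1) * slot + 1
    end <- start + params$gene_length_bp - 1

    base_cog <- rbind(core_cogs, acc_cogs)[gene_id, , drop = FALSE]
    cog_category <- base_cog$cog_category
    cog_id <- base_cog$cog_id
    is_tn <- base_cog$is_transposase
    # rearranged spans of this genome relative to the ancestor: the
    # non-backbone blocks of its partition; genes inside them get the
    # mobilome label at transposase_boost times the base rate
    part <- suppressWarnings(find_blocks(anc, sim$order))
    span_fams <- unlist(lapply(
      strsplit(rearranged_blocks(part)$families, ","),
      function(v) sub("^[+-]", "", v)))
    fam_of_gene <- rep(perm, vapply(match(perm, fams), function(i)
      1L + n_acc[i], integer(1)))
    hit <- fam_of_gene %in% span_fams & stats::runif(n_tot) < p_boost
    cog_category[hit] <- "X"
    cog_id[hit] <- "COGX001"
    is_tn[hit] <- TRUE
    sims[[gid]]$boosted_families <- unique(span_fams)

    seqc <- make_skewed_sequence(params$genome_length_bp, ori_bp, ter_bp,
                                 params$skew_delta)
    genomes[[gid]] <- genome_record(
      genome_id = gid, species_id = "synthetic_sp", circular = TRUE,
      length_bp = params$genome_length_bp,
      genes = data.frame(gene_id = gene_id, family_id = family_id,
                         strand = strand, start = start, end = end,
                         cog_id = cog_id, cog_category = cog_category,
                         is_transposase = is_tn, stringsAsFactors = FALSE),
      sequence = seqc)

    truth$genomes[[gid]] <- list(k = k, events = sim$truth,
                                 moved_families = sims[[gid]]$moved,
                                 boosted_families = sims[[gid]]$boosted_families,
                                 n_substitutions = length(sub_maps[[gid]]))
  }

  # alignment rows and exact pairwise substitution counts from the maps
  aln <- vapply(genome_ids, function(gid) {
    row <- anc_aln
    mp <- sub_maps[[gid]]
    if (length(mp) > 0) row[as.integer(names(mp))] <- mp
    paste(row, collapse = "")
  }, character(1))
  S <- matrix(0L, params$n_genomes, params$n_genomes,
              dimnames = list(genome_ids, genome_ids))
  for (i in seq_along(genome_ids)) for (j in seq_along(genome_ids)) {
    if (j <= i) next
    m1 <- sub_maps[[genome_ids[i]]]; m2 <- sub_maps[[genome_ids[j]]]
    shared <- intersect(names(m1), names(m2))
    s <- length(m1) + length(m2) - 2 * length(shared) +
      sum(m1[shared] != m2[shared])
    S[i, j] <- S[j, i] <- s
  }
  truth$pairwise_S <- S
  truth$sub_sites <- lapply(sub_maps, function(m) as.integer(names(m)))

  structure(list(species = species_set(genomes,
                                       alignment = as_alignment(aln)),
                 alignment = as_alignment(aln),
                 params = params, truth = truth),
            class = "species_bundle")
}

#' @export
print.species_bundle <- function(x, ...) {
  ks <- vapply(x$truth$genomes, function(g) g$k, numeric(1))
  cat("<species_bundle> ", length(x$species$genomes), " genomes, C = ",
      x$params$C, ", planted events per genome: ",
      paste(ks, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write a species bundle to plain-text files
#'
#' Emits `gene_table.tsv`, `genomes.fasta`, `core_aln.fasta` and
#' `truth.json` under `dir`.
#'
#' @param bundle A `species_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_species_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_table(bundle$species$genomes, file.path(dir, "gene_table.tsv"))
  seqs <- vapply(bundle$species$genomes, function(g) g$sequence,
                 character(1))
  write_fasta(seqs, file.path(dir, "genomes.fasta"))
  write_fasta(unclass(bundle$alignment)[seq_along(bundle$alignment)],
              file.path(dir, "core_aln.fasta"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
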