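# COG functional enrichment of rearranged blocks.

# Genes of a genome falling inside a block's chromosomal arc (by midpoint),
# honoring circular wrap-around.
genes_in_span <- function(genome, q_start, q_end) {
  g <- genome$genes
  mid <- (g$start + g$end) / 2
  G <- genome$length_bp
  arc <- (q_end - q_start) %% G
  off <- (mid - q_start) %% G
  g[off <= arc, , drop = FALSE]
}

gene_labels <- function(genes, level) {
  if (level == "category") genes$cog_category else genes$cog_id
}

filter_gene_class <- function(genes, gene_class, core) {
  if (gene_class == "both") return(genes)
  if (is.null(core))
    stop("gene_class filtering needs the core_genome object")
  is_core <- genes$family_id %in% core$core_families
  if (gene_class == "core") genes[is_core, , drop = FALSE]
  else genes[!is_core, , drop = FALSE]
}

#' Build per-COG contingency tables for rearranged blocks vs whole genomes
#'
#' For every COG (id or one-letter category) seen inside rearranged blocks,
#' a 2x2 table is built: `a` = genes with this COG inside rearranged
#' blocks, `b` = other genes inside rearranged blocks, `c` = genes with
#' this COG across all genomes, `d` = other genes across all genomes. Block
#' gene content includes the accessory genes lying between the core genes
#' of a block. Single-block genomes (no rearrangement) and backbone blocks
#' are excluded from the block side; the genome-wide side counts every
#' gene, including those inside blocks (set `disjoint = TRUE` to subtract
#' block genes from the genome-wide side instead). Unannotated genes count
#' toward the `b`/`d` totals but are not tested themselves.
#'
#' @param partitions List of `block_partition` (queries vs the species
#'   reference, with bp coordinates).
#' @param genomes A [species_set()] (or list of [genome_record()]).
#' @param scope Which rearranged blocks to count: `"all"`, `"inversion"`,
#'   or `"translocation"`.
#' @param gene_class `"both"`, `"core"` or `"accessory"` (the latter two
#'   need `core`).
#' @param level `"category"` (one-letter class) or `"cog"` (COG id).
#' @param core Optional `core_genome`, required for `gene_class != "both"`.
#' @param disjoint Subtract block counts from the genome-wide column.
#' @return Data frame: `cog`, `a`, `b`, `c`, `d`, `scope`, `gene_class`;
#'   zero rows (with a warning) when no genome shows a rearrangement.
#' @export
count_cogs <- function(partitions, genomes,
                       scope = c("all", "inversion", "translocation"),
                       gene_class = c("both", "core", "accessory"),
                       level = c("category", "cog"), core = NULL,
                       disjoint = FALSE) {
  scope <- match.arg(scope)
  gene_class <- match.arg(gene_class)
  level <- match.arg(level)
  glist <- if (inherits(genomes, "species_set")) genomes$genomes else genomes
  names(glist) <- vapply(glist, function(g) g$genome_id, character(1))

  block_genes <- list()
  for (p in partitions) {
    if (p$query_id == p$ref_id || p$n_blocks < 2) next  # single-block: skip
    qg <- glist[[p$query_id]]
    if (is.null(qg)) stop("query genome ", p$query_id, " not supplied")
    b <- rearranged_blocks(p)
    if (scope != "all") b <- b[b$classification == scope, , drop = FALSE]
    for (i in seq_len(nrow(b)))
      block_genes[[length(block_genes) + 1]] <-
        genes_in_span(qg, b$query_start[i], b$query_end[i])
  }
  empty <- data.frame(cog = character(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), d = numeric(0), scope = character(0),
                      gene_class = character(0), stringsAsFactors = FALSE)
  if (length(block_genes) == 0) {
    warning("no non-backbone blocks in scope '", scope, "'")
    return(empty)
  }
  bg <- filter_gene_class(do.call(rbind, block_genes), gene_class, core)
  all_genes <- filter_gene_class(
    do.call(rbind, lapply(glist, function(g) g$genes)), gene_class, core)
  blab <- gene_labels(bg, level)
  alab <- gene_labels(all_genes, level)
  n_block <- nrow(bg)
  n_all <- nrow(all_genes)
  labels <- sort(unique(blab[nzchar(blab)]))
  if (length(labels) == 0) {
    warning("no annotated genes inside rearranged blocks")
    return(empty)
  }
  rows <- lapply(labels, function(lb) {
    a <- sum(blab == lb)
    cc <- sum(alab == lb)
    dd <- n_all - cc
    if (disjoint) { cc <- cc - a; dd <- dd - (n_block - a) }
    data.frame(cog = lb, a = a, b = n_block - a, c = cc, d = dd,
               scope = scope, gene_class = gene_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chi-square enrichment tests with Benjamini-Hochberg correction
#'
#' Runs a Pearson chi-square (df = 1, no continuity correction) on each
#' contingency table, adjusts the p-values within the scope by BH, and
#' calls a COG enriched when q < `alpha` and its frequency inside blocks
#' exceeds its genome-wide frequency. Tables with a zero margin get p = 1
#' with a note; tables with an expected cell below 5 are flagged
#' `low_count` (no Fisher fallback).
#'
#' @param tables Output of [count_cogs()].
#' @param alpha Significance threshold on q (default 0.05).
#' @return Data frame: `cog`, `chi2`, `p`, `q`, `enriched`, `low_count`,
#'   `note`.
#' @export
chi2_enrichment <- function(tables, alpha = 0.05) {
  if (nrow(tables) == 0)
    return(data.frame(cog = character(0), chi2 = numeric(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0),
                      low_count = logical(0), note = character(0),
                      stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(tables)), function(i) {
    t <- tables[i, ]
    r <- chi2_2x2(t$a, t$b, t$c, t$d)
    data.frame(cog = t$cog, chi2 = r$statistic, p = r$p_value,
               low_count = grepl("expected count", r$note),
               note = r$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  freq_block <- tables$a / (tables$a + tables$b)
  freq_genome <- tables$c / (tables$c + tables$d)
  out$enriched <- out$q < alpha & freq_block > freq_genome
  out[, c("cog", "chi2", "p", "q", "enriched", "low_count", "note")]
}

#' Functional composition of rearranged vs non-rearranged gene content
#'
#' Per-category gene frequencies for translocated blocks, inverted blocks,
#' non-rearranged regions, and all genomes pooled. Columns sum to 1;
#' unannotated genes are reported as their own `"unannotated"` category.
#' Columns with no genes are omitted.
#'
#' @param partitions List of `block_partition`.
#' @param genomes A [species_set()] or list of [genome_record()].
#' @return Data frame of frequencies, one row per category.
#' @export
functional_composition <- function(partitions, genomes) {
  glist <- if (inherits(genomes, "species_set")) genomes$genomes else genomes
  names(glist) <- vapply(glist, function(g) g$genome_id, character(1))
  pick <- function(scope) {
    out <- list()
    for (p in partitions) {
      if (p$query_id == p$ref_id || p$n_blocks < 2) next
      qg <- glist[[p$query_id]]
      b <- rearranged_blocks(p)
      b <- b[b$classification == scope, , drop = FALSE]
      for (i in seq_len(nrow(b)))
        out[[length(out) + 1]] <- genes_in_span(qg, b$query_start[i],
                                                b$query_end[i])
    }
    if (length(out) == 0) NULL else do.call(rbind, out)
  }
  trans <- pick("translocation")
  inv <- pick("inversion")
  all_genes <- do.call(rbind, lapply(glist, function(g) g$genes))
  # non-rearranged: genes of rearranged genomes outside any rearranged block
  nonr <- list()
  for (p in partitions) {
    if (p$query_id == p$ref_id || p$n_blocks < 2) next
    qg <- glist[[p$query_id]]
    b <- rearranged_blocks(p)
    g <- qg$genes
    mid <- (g$start + g$end) / 2
    inside <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(b))) {
      arc <- (b$query_end[i] - b$query_start[i]) %% qg$length_bp
      off <- (mid - b$query_start[i]) %% qg$length_bp
      inside <- inside | off <= arc
    }
    nonr[[length(nonr) + 1]] <- g[!inside, , drop = FALSE]
  }
  nonr <- if (length(nonr) == 0) NULL else do.call(rbind, nonr)
  cols <- list(translocation = trans, inversion = inv,
               non_rearranged = nonr, all_genomes = all_genes)
  cols <- Filter(Negate(is.null), cols)
  cats <- sort(unique(unlist(lapply(cols, function(g)
    ifelse(nzchar(g$cog_category), g$cog_category, "unannotated")))))
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    lab <- ifelse(nzchar(cols[[nm]]$cog_category), cols[[nm]]$cog_category,
                  "unannotated")
    tab <- table(factor(lab, levels = cats))
    out[[nm]] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' Correlation between transposase load and rearranged-block counts
#'
#' Species-level Spearman correlation between the mean number of blocks per
#' genome and the mean transposase count per genome normalized by genome
#' length (Mb).
#'
#' @param species_stats Data frame with columns `mean_blocks` and
#'   `transposase_density` (transposases per Mb), one row per species.
#' @return List as from [spearman_cor()].
#' @export
transposase_correlation <- function(species_stats) {
  if (nrow(species_stats) < 3)
    stop("need at least 3 species for a correlation")
  spearman_cor(species_stats$transposase_density, species_stats$mean_blocks)
}

#' Transposase density of a genome
#'
#' @param genome A [genome_record()].
#' @return Transposase genes per Mb.
#' @export
transposase_density <- function(genome) {
  sum(genome$genes$is_transposase) / (genome$length_bp / 1e6)
}
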