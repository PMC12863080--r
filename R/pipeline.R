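# End-to-end orchestration: core calling -> block finding -> classification
# -> Ori/Ter and positional bias -> rate estimation -> COG enrichment, with
# exclusion bookkeeping and TSV reports.

#' Run the full rearrangement analysis on one species
#'
#' Executes the stages in order and writes one TSV per stage plus a summary
#' to `out_dir`. Exclusion bookkeeping (singleton blocks, over-represented
#' block identities, ambiguous skew profiles, single-block genomes) is
#' first-class output because those filters materially shape the results.
#'
#' @param species A [species_set()] with sequences attached (or a
#'   `species_bundle`, whose species and alignment are used), or a path to
#'   a YAML config file with entries `gene_table`, `fasta`, `alignment`
#'   and optional stage parameters.
#' @param out_dir Output directory for TSV reports; `NULL` writes nothing.
#' @param freq Core-calling presence threshold.
#' @param window_bp GC-skew window size.
#' @param reference `"auto"` (parsimony selection) or a genome id.
#' @param calibration Optional [sim_params()]; defaults to the species'
#'   core size with `k_grid = 0:20`.
#' @param seed Seed for the calibration simulations.
#' @param stages Character vector of stages to run, any of `"blocks"`,
#'   `"replichore"`, `"rates"`, `"enrichment"` (core calling always runs).
#' @return A list of stage results: `core`, `reference_id`, `partitions`,
#'   `summary`, `dedup`, `skew`, `positional`, `model`, `rates`,
#'   `enrichment`, `composition`, `exclusions`.
#' @export
run_pipeline <- function(species, out_dir = NULL, freq = 0.90,
                         window_bp = 1000, reference = "auto",
                         calibration = NULL, seed = 1,
                         stages = c("blocks", "replichore", "rates",
                                    "enrichment")) {
  alignment <- NULL
  if (is.character(species) && length(species) == 1) {
    cfg <- yaml::read_yaml(species)
    for (p in c("gene_table", "fasta")) if (!is.null(cfg[[p]]) &&
                                            !file.exists(cfg[[p]]))
      stop("config path does not exist: ", cfg[[p]])
    recs <- read_gene_table(cfg$gene_table)
    if (!is.null(cfg$fasta)) {
      seqs <- read_fasta(cfg$fasta)
      for (i in seq_along(recs))
        recs[[i]]$sequence <- unname(seqs[recs[[i]]$genome_id])
    }
    if (!is.null(cfg$alignment)) alignment <- read_alignment(cfg$alignment)
    species <- species_set(recs, alignment = alignment)
    if (!is.null(cfg$freq)) freq <- cfg$freq
    if (!is.null(cfg$window_bp)) window_bp <- cfg$window_bp
    if (!is.null(cfg$reference)) reference <- cfg$reference
    if (!is.null(cfg$seed)) seed <- cfg$seed
  }
  if (inherits(species, "species_bundle")) {
    alignment <- species$alignment
    species <- species$species
  }
  if (is.null(alignment)) alignment <- species$alignment
  stopifnot(inherits(species, "species_set"))

  res <- list(exclusions = list())
  message("[core] calling core families at freq >= ", freq)
  res$core <- call_core_families(species, freq = freq)
  orders <- lapply(species$genomes, project_core_order, core = res$core)

  if ("blocks" %in% stages) {
    message("[blocks] selecting reference and partitioning ",
            length(orders), " genomes")
    ref_id <- if (identical(reference, "auto"))
      as.character(select_reference(orders)) else reference
    if (!ref_id %in% names(orders)) stop("unknown reference: ", ref_id)
    res$reference_id <- ref_id
    res$partitions <- lapply(orders[setdiff(names(orders), ref_id)],
                             function(q) find_blocks(orders[[ref_id]], q))
    res$summary <- summarize_species(res$partitions)
    res$dedup <- dedup_blocks(res$partitions)
    res$exclusions$singleton_blocks <-
      sum(vapply(res$partitions, function(p) p$n_singletons_discarded,
                 numeric(1)))
    res$exclusions$overrepresented_blocks <-
      if (is.null(res$dedup)) 0 else attr(res$dedup, "n_removed")
    res$exclusions$single_block_genomes <-
      sum(vapply(res$partitions, function(p) p$n_blocks == 1, logical(1)))
  }

  if ("replichore" %in% stages && "blocks" %in% stages) {
    message("[replichore] GC-skew profiles at ", window_bp, " bp windows")
    with_seq <- Filter(function(g) !is.null(g$sequence), species$genomes)
    res$skew <- lapply(with_seq, function(g)
      gc_skew_profile(g$sequence, window_bp, genome_id = g$genome_id))
    ambiguous <- vapply(res$skew, function(s) s$ambiguous, logical(1))
    res$exclusions$ambiguous_genomes <- sum(ambiguous)
    dd <- res$dedup
    if (!is.null(dd) && nrow(dd) > 0) {
      rows <- lapply(seq_len(nrow(dd)), function(i) {
        prof <- res$skew[[dd$query_id[i]]]
        if (is.null(prof) || prof$ambiguous) return(NULL)
        data.frame(query_id = dd$query_id[i],
                   classification = dd$classification[i],
                   d = relative_position(dd$midpoint_bp[i], prof),
                   stringsAsFactors = FALSE)
      })
      dist_tab <- do.call(rbind, rows)
      res$positional <- list(distances = dist_tab)
      if (!is.null(dist_tab) && nrow(dist_tab) > 0) {
        res$positional$all <- test_positional_bias(dist_tab$d)
        for (cl in c("inversion", "translocation")) {
          d <- dist_tab$d[dist_tab$classification == cl]
          if (length(d) > 0)
            res$positional[[cl]] <- test_positional_bias(d)
        }
      }
    }
  }

  if ("rates" %in% stages && "blocks" %in% stages && !is.null(alignment)) {
    message("[rates] calibrating blocks-to-events model (C = ",
            res$core$C, ")")
    if (is.null(calibration))
      calibration <- sim_params(res$core$C, k_grid = 0:20,
                                replicates = 50, seed = seed)
    res$model <- calibrate_blocks_to_events(calibration)
    res$rates <- estimate_rates(res$partitions, alignment, res$model,
                                C = res$core$C)
  }

  if ("enrichment" %in% stages && "blocks" %in% stages) {
    message("[enrichment] COG contingency tables and chi-square tests")
    res$enrichment <- lapply(
      stats::setNames(nm = c("all", "inversion", "translocation")),
      function(sc) {
        tab <- suppressWarnings(count_cogs(res$partitions, species,
                                           scope = sc))
        chi2_enrichment(tab)
      })
    res$composition <- tryCatch(
      functional_composition(res$partitions, species),
      error = function(e) NULL)
  }

  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  invisible(res)
}

write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$summary)) {
    write_tsv_report(res$summary$per_genome,
                     file.path(out_dir, "blocks_per_genome.tsv"))
    write_tsv_report(
      data.frame(reference_id = res$summary$reference_id,
                 mean_blocks = res$summary$mean_blocks),
      file.path(out_dir, "species_summary.tsv"))
  }
  if (!is.null(res$dedup) && nrow(res$dedup) > 0)
    write_tsv_report(res$dedup, file.path(out_dir, "blocks.tsv"))
  if (!is.null(res$skew)) {
    st <- do.call(rbind, lapply(res$skew, function(s)
      data.frame(genome_id = s$genome_id, ori_bp = s$ori_bp,
                 ter_bp = s$ter_bp, ambiguous = s$ambiguous,
                 reason = s$ambiguity_reason, stringsAsFactors = FALSE)))
    write_tsv_report(st, file.path(out_dir, "oriter.tsv"))
  }
  if (!is.null(res$positional$distances))
    write_tsv_report(res$positional$distances,
                     file.path(out_dir, "distances.tsv"))
  if (!is.null(res$rates))
    write_tsv_report(res$rates, file.path(out_dir, "rates.tsv"))
  if (!is.null(res$enrichment))
    for (sc in names(res$enrichment))
      if (nrow(res$enrichment[[sc]]) > 0)
        write_tsv_report(res$enrichment[[sc]],
                         file.path(out_dir,
                                   paste0("enrichment_", sc, ".tsv")))
  if (!is.null(res$composition))
    write_tsv_report(res$composition,
                     file.path(out_dir, "functional_composition.tsv"))
  excl <- data.frame(rule = names(res$exclusions),
                     n = unlist(res$exclusions), row.names = NULL)
  if (nrow(excl) > 0)
    write_tsv_report(excl, file.path(out_dir, "exclusions.tsv"))
  invisible(out_dir)
}
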