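# Syntenic blocks between signed circular core-gene permutations.
#
# A block is a maximal run of core families consecutive in both genomes; a
# run that is consecutive in reversed reference order counts as one reverted
# block. Adjacency is circular on both genomes unless flagged linear.

# Internal: given query families as signed reference positions (sign = query
# strand relative to the reference strand of that family), return the number
# of broken circular adjacencies. A query adjacency (i, i+1) is conserved
# when the two reference positions are circularly consecutive in either
# direction. With distinct positions a maximal unbroken run cannot change
# direction, so pair adjacency fully determines the run structure.
breakpoint_flags <- function(pos, circular = TRUE) {
  n <- length(pos)
  nxt <- c(pos[-1], pos[1])
  diff <- (nxt - pos) %% n
  conserved <- diff == 1 | diff == n - 1
  bp <- !conserved
  if (!circular) bp[n] <- TRUE  # no wrap adjacency on a linear chromosome
  bp
}

#' Find syntenic core-gene blocks between a reference and a query genome
#'
#' Both genomes are reduced to the core families they share. Blocks are
#' maximal runs of shared families consecutive in both genomes (same or
#' fully reversed order); the first and last permutation elements are
#' adjacent on circular chromosomes. Runs of a single core gene are
#' discarded (possible orthology misassignments) but counted. Before block
#' finding the query orientation is canonicalized: if reversing the query
#' and flipping all signs strictly reduces the breakpoint count, the
#' reversed representation is used, so that a genome deposited on the
#' opposite strand is not read as one giant inversion.
#'
#' @param ref,qry [core_order()] objects.
#' @param canonicalize Logical; apply whole-genome orientation
#'   canonicalization (default TRUE).
#' @return Object of class `block_partition`: `ref_id`, `query_id`,
#'   `blocks` (data frame: one row per retained block with `families`
#'   (signed, comma-joined, query order), `n_core`, `n_total_genes`,
#'   `orientation` (`forward`/`reverted`), `is_backbone`, `classification`
#'   (`backbone`/`inversion`/`translocation`), `midpoint_bp`,
#'   `query_start`, `query_end`, `ref_start_index`, `identity_key`),
#'   `n_blocks`, `n_singletons_discarded`, `n_shared`, `flipped` (whether
#'   canonicalization reversed the query).
#' @export
find_blocks <- function(ref, qry, canonicalize = TRUE) {
  stopifnot(inherits(ref, "core_order"), inherits(qry, "core_order"))
  shared <- intersect(ref$families, qry$families)
  if (length(shared) < 2)
    stop("genomes ", ref$genome_id, " and ", qry$genome_id, " share ",
         length(shared), " core families; need at least 2")
  circular <- ref$circular && qry$circular

  rkeep <- ref$families %in% shared
  ref_fam <- ref$families[rkeep]
  ref_sign <- ref$signs[rkeep]
  ref_pos_of <- stats::setNames(seq_along(ref_fam), ref_fam)

  qkeep <- which(qry$families %in% shared)
  qry_fam <- qry$families[qkeep]
  qry_sign <- qry$signs[qkeep]
  n <- length(qry_fam)

  # genes (non-shared core + accessory) spanned between consecutive shared
  # core genes in the query, used for block gene-content tallies
  extra <- integer(n)
  if (length(qry$interval_extra) == length(qry$families)) {
    nq <- length(qry$families)
    for (i in seq_len(n)) {
      lo <- qkeep[i]
      hi <- if (i < n) qkeep[i + 1] else qkeep[1] + nq
      span <- if (hi - lo >= 1) ((lo:(hi - 1)) - 1L) %% nq + 1L else integer(0)
      extra[i] <- sum(qry$interval_extra[span]) + (hi - lo - 1L)
    }
  }

  pos <- unname(ref_pos_of[qry_fam])
  rel <- qry_sign * ref_sign[pos]

  flipped <- FALSE
  if (canonicalize && n >= 3) {
    fwd_bp <- sum(breakpoint_flags(pos, circular))
    rev_bp <- sum(breakpoint_flags(rev(pos), circular))
    if (rev_bp < fwd_bp) {
      flipped <- TRUE
      ord <- rev(seq_len(n))
      pos <- pos[ord]; rel <- -rel[ord]
      qry_fam <- qry_fam[ord]
      # interval i in reversed coordinates is interval i-1 of the original
      extra <- extra[c(n, seq_len(n - 1))][ord]
    }
  }

  bp <- breakpoint_flags(pos, circular)
  n_bp <- sum(bp)
  if (n_bp == 0) {
    runs <- list(seq_len(n))
  } else {
    starts <- (which(bp) %% n) + 1L
    starts <- sort(starts)
    runs <- vector("list", length(starts))
    for (j in seq_along(starts)) {
      s <- starts[j]
      e_excl <- if (j < length(starts)) starts[j + 1] else starts[1] + n
      runs[[j]] <- ((s:(e_excl - 1L)) - 1L) %% n + 1L
    }
  }

  qpos <- if (!is.null(qry$positions)) qry$positions[qkeep] else NULL
  if (flipped && !is.null(qpos)) qpos <- qpos[rev(seq_len(n))]
  glen <- qry$genome_length

  rows <- lapply(runs, function(idx) {
    k <- length(idx)
    if (k >= 2) {
      d <- (pos[idx[2]] - pos[idx[1]]) %% n
      orientation <- if (d == 1) "forward" else "reverted"
    } else orientation <- NA_character_
    n_total <- k + if (k >= 2) sum(extra[idx[-k]]) else 0L
    signed <- paste0(ifelse(rel[idx] > 0, "+", "-"), qry_fam[idx])
    mid <- q_start <- q_end <- NA_real_
    if (!is.null(qpos)) {
      q_start <- qpos[idx[1]]; q_end <- qpos[idx[k]]
      # in a flipped (canonicalized) query the permutation runs against the
      # chromosome coordinate direction, so the block arc is q_end -> q_start
      if (flipped) { tmp <- q_start; q_start <- q_end; q_end <- tmp }
      if (!is.null(glen)) {
        arc <- (q_end - q_start) %% glen
        mid <- (q_start + arc / 2) %% glen
      } else mid <- (q_start + q_end) / 2
    }
    frac_flipped <- mean(rel[idx] < 0)
    data.frame(families = paste(signed, collapse = ","),
               n_core = k, n_total_genes = n_total,
               orientation = orientation,
               frac_sign_flipped = frac_flipped,
               midpoint_bp = mid, query_start = q_start, query_end = q_end,
               ref_start_index = min(pos[idx]),
               identity_key = block_identity_key(rel[idx] , qry_fam[idx]),
               stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, rows)
  singles <- blocks$n_core < 2
  n_singletons <- sum(singles)
  blocks <- blocks[!singles, , drop = FALSE]
  rownames(blocks) <- NULL

  if (nrow(blocks) > 0) {
    ord <- order(-blocks$n_core, -blocks$n_total_genes,
                 blocks$ref_start_index)
    blocks$is_backbone <- FALSE
    blocks$is_backbone[ord[1]] <- TRUE
    blocks$classification <- ifelse(
      blocks$is_backbone, "backbone",
      ifelse(blocks$orientation == "reverted", "inversion", "translocation"))
    odd <- !blocks$is_backbone & blocks$orientation == "reverted" &
      blocks$frac_sign_flipped < 0.5
    if (any(odd))
      warning("order-reverted block(s) with <50% strand flips in ",
              qry$genome_id, " vs ", ref$genome_id,
              "; classified as inversion (order is primary)")
  } else {
    blocks$is_backbone <- logical(0)
    blocks$classification <- character(0)
  }

  structure(list(ref_id = ref$genome_id, query_id = qry$genome_id,
                 blocks = blocks, n_blocks = nrow(blocks),
                 n_singletons_discarded = n_singletons,
                 n_shared = n, flipped = flipped),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("<block_partition> ", x$query_id, " vs ", x$ref_id, ": ",
      x$n_blocks, " block(s), ", x$n_singletons_discarded,
      " singleton(s) discarded\n", sep = "")
  invisible(x)
}

# Canonical identity of a block: the lexicographically smaller of the signed
# family tuple and its reversed, sign-flipped counterpart, so the same
# rearranged segment seen from either side maps to one key.
block_identity_key <- function(rel_signs, families) {
  fwd <- paste0(ifelse(rel_signs > 0, "+", "-"), families)
  rev_ <- paste0(ifelse(rev(rel_signs) > 0, "-", "+"), rev(families))
  a <- paste(fwd, collapse = ",")
  b <- paste(rev_, collapse = ",")
  if (a <= b) a else b
}

#' Classify a non-backbone block as inversion or translocation
#'
#' An inversion reverses the gene order of a contiguous block relative to
#' the reference (and normally flips its strands); a translocation relocates
#' the block with order and orientation preserved.
#'
#' @param block One row of a `block_partition$blocks` data frame.
#' @return `"inversion"` or `"translocation"`.
#' @export
classify_block <- function(block) {
  if (isTRUE(block$is_backbone))
    stop("the backbone block is the unrearranged frame; it has no event class")
  if (block$orientation == "reverted") "inversion" else "translocation"
}

#' Extract the rearranged (non-backbone) blocks of a partition
#'
#' The largest block (most core genes; ties by total genes, then smallest
#' reference start) is the backbone — the unrearranged frame. The remaining
#' n-1 blocks are the rearranged ones. A single-block partition means the
#' pair shows no rearrangement.
#'
#' @param partition A `block_partition`.
#' @return Data frame of rearranged block rows (possibly 0 rows).
#' @export
rearranged_blocks <- function(partition) {
  stopifnot(inherits(partition, "block_partition"))
  partition$blocks[!partition$blocks$is_backbone, , drop = FALSE]
}

#' Select the species reference genome
#'
#' The reference is the genome that minimizes the average number of blocks
#' against all other genomes of the species (parsimony: the layout closest
#' to every other layout). Ties break to the lexicographically smallest id.
#'
#' @param orders List of [core_order()] objects (>= 2).
#' @return The selected `genome_id` (with attribute `mean_blocks`, the
#'   per-candidate averages).
#' @export
select_reference <- function(orders) {
  if (length(orders) < 2) stop("reference selection needs >= 2 genomes")
  ids <- vapply(orders, function(o) o$genome_id, character(1))
  names(orders) <- ids
  means <- vapply(ids, function(r) {
    others <- setdiff(ids, r)
    mean(vapply(others, function(q)
      find_blocks(orders[[r]], orders[[q]])$n_blocks, numeric(1)))
  }, numeric(1))
  best <- sort(ids[means == min(means)])[1]
  structure(best, mean_blocks = means)
}

#' Remove over-represented blocks across a species
#'
#' The same rearranged segment seen in many genome pairs would otherwise be
#' counted as many independent events. Blocks whose canonical identity key
#' occurs more than twice across the supplied partitions are removed
#' entirely.
#'
#' @param partitions List of `block_partition` objects (one species).
#' @param max_occurrences Keep keys seen at most this often (default 2).
#' @return Data frame of retained rearranged blocks with `ref_id` and
#'   `query_id` columns prepended.
#' @export
dedup_blocks <- function(partitions, max_occurrences = 2) {
  rows <- lapply(partitions, function(p) {
    b <- rearranged_blocks(p)
    if (nrow(b) == 0) return(NULL)
    cbind(data.frame(ref_id = p$ref_id, query_id = p$query_id,
                     stringsAsFactors = FALSE), b)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0) return(all)
  counts <- table(all$identity_key)
  keep <- all$identity_key %in% names(counts)[counts <= max_occurrences]
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Summarize block partitions of a species
#'
#' @param partitions List of `block_partition` objects, all against the
#'   selected reference; a reference self-comparison (one block by
#'   definition) is excluded from the species mean.
#' @return Object of class `species_block_summary`: `per_genome` data frame
#'   (`genome_id`, `n_blocks`, `n_inversions`, `n_translocations`),
#'   `mean_blocks`, `block_lengths_genes` (core+accessory gene counts of all
#'   rearranged blocks), `reference_id`.
#' @export
summarize_species <- function(partitions) {
  partitions <- Filter(function(p) p$query_id != p$ref_id, partitions)
  if (length(partitions) == 0) stop("no non-self partitions to summarize")
  per <- do.call(rbind, lapply(partitions, function(p) {
    b <- p$blocks
    data.frame(genome_id = p$query_id, n_blocks = p$n_blocks,
               n_inversions = sum(b$classification == "inversion"),
               n_translocations = sum(b$classification == "translocation"),
               stringsAsFactors = FALSE)
  }))
  lens <- unlist(lapply(partitions, function(p)
    rearranged_blocks(p)$n_total_genes))
  structure(list(reference_id = partitions[[1]]$ref_id,
                 per_genome = per,
                 mean_blocks = mean(per$n_blocks),
                 block_lengths_genes = if (is.null(lens)) numeric(0) else lens),
            class = "species_block_summary")
}

#' @export
print.species_block_summary <- function(x, ...) {
  cat("<species_block_summary> reference ", x$reference_id, ": ",
      nrow(x$per_genome), " genomes, mean ", round(x$mean_blocks, 2),
      " blocks\n", sep = "")
  invisible(x)
}
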