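# Pangenome construction: per-genomospecies protein dereplication (70%
# identity), cross-unit ortholog families (30% identity over 75% of the
# shorter sequence, single linkage), and core/accessory partitioning.

#' Dereplicate proteins of one genomospecies into a pangenome
#'
#' Pools the proteomes of the member genomes and clusters them greedily in
#' length-descending order at `identity` percent over at least `coverage`
#' of the shorter sequence; one representative (the longest member) is kept
#' per cluster. Following the usual SAG practice, a genomospecies is only
#' dereplicated when it has at least `min_genomes` members, because fewer
#' partial genomes do not approximate the gene pool.
#'
#' @param proteins Tibble with columns `genome_id`, `protein_id`,
#'   `sequence`.
#' @param identity Clustering identity threshold (percent).
#' @param coverage Minimum aligned fraction of the shorter sequence.
#' @param min_genomes Minimum member genomes required.
#' @param force Proceed below `min_genomes` (for toy data).
#' @return Tibble of representatives: `protein_id`, `genome_id`,
#'   `sequence`, `cluster_id`, `n_members`.
#' @export
dereplicate_proteins <- function(proteins, identity = 70, coverage = 0.75,
                                 min_genomes = 5, force = FALSE) {
  proteins <- tibble::as_tibble(proteins)
  need <- c("genome_id", "protein_id", "sequence")
  if (!all(need %in% names(proteins))) {
    abort("dereplicate_proteins: need genome_id, protein_id, sequence columns")
  }
  ng <- length(unique(proteins$genome_id))
  if (ng < min_genomes && !force) {
    abort(paste0("dereplicate_proteins: genomospecies has ", ng,
                 " genome(s); at least ", min_genomes,
                 " are required (use force = TRUE to override)"))
  }
  o <- order(-nchar(proteins$sequence), proteins$protein_id)
  p <- proteins[o, ]
  cl <- .cpp_cluster_greedy(toupper(p$sequence), identity, coverage, 3L, 16L)
  p$cluster_id <- cl
  reps <- p %>%
    group_by(.data$cluster_id) %>%
    summarise(protein_id = first(.data$protein_id),
              genome_id = first(.data$genome_id),
              sequence = first(.data$sequence),
              n_members = n(), .groups = "drop")
  reps[, c("protein_id", "genome_id", "sequence", "cluster_id", "n_members")]
}

#' Build ortholog families across units
#'
#' Units are genomospecies pangenomes (representative protein sets) or, for
#' small studies, plain genomes. Families are single-linkage components of
#' the graph of protein pairs aligning at >= `identity` percent over
#' >= `coverage` of the shorter sequence.
#'
#' @param units Named list of protein sets: each a named character vector of
#'   protein sequences, or a tibble with `protein_id` and `sequence`.
#' @param identity Identity threshold (percent).
#' @param coverage Minimum aligned fraction of the shorter sequence.
#' @return Object of class `ortholog_families`: list with `families`
#'   (tibble: `family_id`, `unit`, `protein_id`), `pa` (0/1 matrix family x
#'   unit), `parameters`.
#' @export
build_families <- function(units, identity = 30, coverage = 0.75) {
  if (length(units) < 2) abort("build_families: need >= 2 units")
  if (is.null(names(units)) || any(!nzchar(names(units)))) {
    abort("build_families: units must be named")
  }
  tabs <- imap(units, function(u, nm) {
    v <- protein_vec(u)
    if (!length(v)) abort(paste0("build_families: unit ", nm, " is empty"))
    tibble(unit = nm, protein_id = names(v), sequence = toupper(unname(v)))
  })
  all <- dplyr::bind_rows(tabs)
  hits <- .cpp_all_hits(all$sequence, identity, coverage, 3L, 16L)
  # union-find over proteins
  parent <- seq_len(nrow(all))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(hits)) {
    for (r in seq_len(nrow(hits))) {
      a <- find(hits$i[r]); b <- find(hits$j[r])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  comp <- vapply(seq_len(nrow(all)), find, integer(1))
  fam_ids <- match(comp, sort(unique(comp)))
  all$family_id <- sprintf("fam%05d", fam_ids)
  pa_tbl <- all %>%
    distinct(.data$family_id, .data$unit) %>%
    mutate(present = 1L) %>%
    pivot_wider(names_from = "unit", values_from = "present",
                values_fill = 0L) %>%
    arrange(.data$family_id)
  pa <- as.matrix(pa_tbl[, -1, drop = FALSE])
  rownames(pa) <- pa_tbl$family_id
  pa <- pa[, names(units), drop = FALSE]
  structure(list(
    families = all[, c("family_id", "unit", "protein_id")] %>%
      arrange(.data$family_id, .data$unit, .data$protein_id),
    pa = pa,
    parameters = list(identity = identity, coverage = coverage)
  ), class = "ortholog_families")
}

#' @export
print.ortholog_families <- function(x, ...) {
  cat(sprintf("<ortholog_families: %d families x %d units (%g%% id, %g cov)>\n",
              nrow(x$pa), ncol(x$pa), x$parameters$identity,
              x$parameters$coverage))
  invisible(x)
}

#' Core / accessory partition of a presence-absence matrix
#'
#' Core families are those present in every unit; the core fraction is the
#' core count divided by the mean per-unit family count (i.e. the fraction
#' of an average genome that is core).
#'
#' @param pa Binary matrix (family x unit) or an `ortholog_families`
#'   object.
#' @return One-row tibble: `n_units`, `n_families_total`, `n_core`,
#'   `mean_unit_families`, `core_fraction_of_avg_genome`.
#' @export
core_accessory <- function(pa) {
  if (inherits(pa, "ortholog_families")) pa <- pa$pa
  if (!is.matrix(pa)) abort("core_accessory: need a binary matrix")
  pa <- (pa > 0) + 0L
  n_core <- sum(rowSums(pa) == ncol(pa))
  per_unit <- colSums(pa)
  tibble(n_units = ncol(pa), n_families_total = nrow(pa),
         n_core = as.integer(n_core), mean_unit_families = mean(per_unit),
         core_fraction_of_avg_genome = n_core / mean(per_unit))
}

#' Gene-to-family map for whole genomes
#'
#' Convenience wrapper: builds ortholog families with genomes as units and
#' returns the per-gene family assignment needed by the island detector and
#' the gene-content distances.
#'
#' @param genomes Named list of `genome_record` objects.
#' @inheritParams build_families
#' @return List with `families` object and `gene_map` tibble (`genome_id`,
#'   `gene_id`, `family_id`).
#' @export
genome_families <- function(genomes, identity = 30, coverage = 0.75) {
  units <- lapply(genomes, genome_proteins)
  fam <- build_families(units, identity = identity, coverage = coverage)
  gene_map <- fam$families %>%
    rename(genome_id = "unit", gene_id = "protein_id")
  list(families = fam, gene_map = gene_map)
}
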