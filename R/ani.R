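# Fragment-based ANI (ANIb convention: 1,020-bp fragments, fragments kept
# at >= 30 percent identity over >= 70 percent of their length, two-way
# mean) and average-linkage rank clustering at genus / genomospecies /
# species ANI thresholds.

genome_cat <- function(g) {
  if (inherits(g, "genome_record")) paste(g$replicons$sequence, collapse = "")
  else toupper(as.character(g))
}

genome_id_of <- function(g, fallback) {
  if (inherits(g, "genome_record")) g$genome_id else fallback
}

ani_one_direction <- function(qseq, tseq, fragment, min_id, min_cov, k, band) {
  n <- nchar(qseq)
  starts <- seq(1, n, by = fragment)
  frags <- substring(qseq, starts, pmin(starts + fragment - 1, n))
  frags <- frags[nchar(frags) >= 100]
  if (!length(frags)) return(list(ani = NA_real_, kept = 0L, bases = 0L,
                                  total = n))
  min_len <- ceiling(min_cov * nchar(frags))
  df <- .cpp_map_reads(frags, tseq, k, band, 0L, 0, TRUE, 4L)
  keep <- df$found & df$columns >= min_len & df$identity >= min_id
  if (!any(keep)) return(list(ani = NA_real_, kept = 0L, bases = 0L,
                              total = n))
  list(ani = mean(df$identity[keep]), kept = sum(keep),
       bases = sum(df$columns[keep]), total = n)
}

#' Fragment-based ANI between two genomes
#'
#' Each genome is chopped into `fragment`-bp pieces aligned against the
#' other; fragments aligning at >= `min_fragment_identity` percent over
#' >= `min_fragment_coverage` of their length are kept, and ANI is the
#' two-way mean of kept-fragment identities. Genome pairs below the
#' alignable range come back with `defined = FALSE`.
#'
#' @param a,b `genome_record` objects (or plain sequences; >= 2 kb each).
#' @param fragment Fragment size in bp.
#' @param min_fragment_identity Identity floor for keeping a fragment (%).
#' @param min_fragment_coverage Fraction of the fragment that must align.
#' @param k,band Seeding parameters for the aligner.
#' @return One-row tibble: `genome_a`, `genome_b`, `ani_pct`,
#'   `aligned_fraction`, `n_fragments_used`, `defined`.
#' @export
ani_pair <- function(a, b, fragment = 1020, min_fragment_identity = 30,
                     min_fragment_coverage = 0.70, k = 13, band = 16) {
  ida <- genome_id_of(a, "genome_a"); idb <- genome_id_of(b, "genome_b")
  sa <- genome_cat(a); sb <- genome_cat(b)
  if (nchar(sa) < 2000 || nchar(sb) < 2000) {
    abort("ani_pair: both genomes must be >= 2 kb")
  }
  d1 <- ani_one_direction(sa, sb, fragment, min_fragment_identity,
                          min_fragment_coverage, k, band)
  d2 <- ani_one_direction(sb, sa, fragment, min_fragment_identity,
                          min_fragment_coverage, k, band)
  anis <- c(d1$ani, d2$ani)
  defined <- any(!is.na(anis))
  tibble(genome_a = ida, genome_b = idb,
         ani_pct = if (defined) mean(anis, na.rm = TRUE) else NA_real_,
         aligned_fraction = (d1$bases + d2$bases) / (d1$total + d2$total),
         n_fragments_used = d1$kept + d2$kept,
         defined = defined)
}

#' All-pairs ANI table for a set of genomes
#'
#' @param genomes Named list of `genome_record` objects.
#' @inheritParams ani_pair
#' @return Tibble of all unordered pairs (see [ani_pair()]).
#' @export
ani_matrix <- function(genomes, fragment = 1020, min_fragment_identity = 30,
                       min_fragment_coverage = 0.70, k = 13, band = 16) {
  ids <- vapply(genomes, function(g) genome_id_of(g, ""), character(1))
  if (is.null(names(genomes))) names(genomes) <- ids
  n <- length(genomes)
  if (n < 2) abort("ani_matrix: need >= 2 genomes")
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[[length(out) + 1]] <-
        ani_pair(genomes[[i]], genomes[[j]], fragment = fragment,
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 k = k, band = band)
    }
  }
  dplyr::bind_rows(out)
}

#' Convert a tidy ANI table to a symmetric matrix
#'
#' Undefined pairs become 0 (below the alignable range); the diagonal is
#' 100.
#'
#' @param ani Tibble from [ani_matrix()] (or a matrix, returned as-is).
#' @return Symmetric numeric matrix with genome ids as dimnames.
#' @export
ani_to_matrix <- function(ani) {
  if (is.matrix(ani)) return(ani)
  ids <- sort(unique(c(ani$genome_a, ani$genome_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(nrow(ani))) {
    v <- if (isTRUE(ani$defined[i])) ani$ani_pct[i] else 0
    if (is.na(v)) v <- 0
    m[ani$genome_a[i], ani$genome_b[i]] <- v
    m[ani$genome_b[i], ani$genome_a[i]] <- v
  }
  m
}

#' Cluster genomes into genera, genomospecies and species by ANI
#'
#' Average-linkage hierarchical clustering on 100 - ANI distances, cut at
#' each rank threshold. Cuts on the same dendrogram are nested, so genomes
#' sharing a genomospecies always share a genus. Labels are assigned in the
#' lexicographic order of each cluster's smallest genome id, which makes
#' them independent of input order.
#'
#' @param ani Tidy ANI table or symmetric ANI matrix. Undefined pairs are
#'   treated as ANI 0.
#' @param genus_thr,genomospecies_thr,species_thr Rank thresholds (% ANI).
#' @return Tibble: `genome_id`, `genus`, `genomospecies`, `species`.
#' @export
cluster_ranks <- function(ani, genus_thr = 70, genomospecies_thr = 90,
                          species_thr = 95) {
  m <- ani_to_matrix(ani)
  if (!isSymmetric(unname(m))) abort("cluster_ranks: matrix must be symmetric")
  if (nrow(m) < 2) abort("cluster_ranks: need >= 2 genomes")
  d <- as.dist(100 - m)
  hc <- hclust(d, method = "average")
  cut_label <- function(thr, prefix, parent = NULL) {
    cl <- cutree(hc, h = 100 - thr)
    relabel_clusters(cl, prefix, parent)
  }
  ids <- rownames(m)
  genus <- cut_label(genus_thr, "G")
  gs_cl <- cutree(hc, h = 100 - genomospecies_thr)
  sp_cl <- cutree(hc, h = 100 - species_thr)
  gs <- nested_labels(genus, gs_cl)
  sp <- nested_labels(gs, sp_cl)
  tibble(genome_id = ids, genus = unname(genus),
         genomospecies = unname(gs), species = unname(sp))
}

# deterministic labels: clusters ordered by their smallest member id
relabel_clusters <- function(cl, prefix, parent = NULL) {
  ids <- names(cl)
  firsts <- vapply(split(ids, cl), min, character(1))
  ord <- rank(firsts)
  lab <- paste0(prefix, ord[as.character(cl)])
  setNames(lab, ids)
}

# child labels nested inside parent labels: parent.1, parent.2, ...
nested_labels <- function(parent, child_cl) {
  ids <- names(parent)
  out <- setNames(character(length(ids)), ids)
  for (p in unique(parent)) {
    sub <- ids[parent == p]
    sub_cl <- child_cl[sub]
    firsts <- vapply(split(sub, sub_cl), min, character(1))
    ord <- rank(firsts)
    out[sub] <- paste0(p, ".", ord[as.character(sub_cl)])
  }
  out
}
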