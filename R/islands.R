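# Flexible genomic island detection from core-anchor synteny, and tRNA
# 3'-fragment direct-repeat integration hallmarks.

#' Detect flexible genomic islands between core anchors
#'
#' Universal single-copy families act as synteny anchors. For every anchor
#' adjacency shared by all genomes (consecutive anchors with no anchor in
#' between, in every genome), the genes between the two anchors form the
#' candidate cargo. The interval is called an island when the cargo family
#' sets overlap poorly across genomes: minimum pairwise Jaccard <=
#' `max_jaccard` (boundary inclusive), with cargo present in at least one
#' genome.
#'
#' @param genomes Named list of `genome_record` objects (>= 2).
#' @param gene_map Tibble (`genome_id`, `gene_id`, `family_id`) from
#'   [genome_families()]; computed if missing.
#' @param max_jaccard Cargo-overlap threshold for calling an island.
#' @return Tibble with one row per genome x island: `island_id`,
#'   `genome_id`, `left_anchor_family`, `right_anchor_family`, `start`,
#'   `end`, `n_cargo`, `cargo_gene_ids` (list), `cargo_families` (list),
#'   `gc_pct`, `min_jaccard`.
#' @export
find_variable_regions <- function(genomes, gene_map = NULL,
                                  max_jaccard = 0.5) {
  if (length(genomes) < 2) abort("find_variable_regions: need >= 2 genomes")
  ids <- names(genomes)
  if (is.null(gene_map)) gene_map <- genome_families(genomes)$gene_map
  counts <- gene_map %>%
    count(.data$family_id, .data$genome_id) %>%
    group_by(.data$family_id) %>%
    summarise(n_genomes = n(), single = all(.data$n == 1), .groups = "drop")
  anchors <- counts$family_id[counts$n_genomes == length(ids) & counts$single]
  if (!length(anchors)) abort("find_variable_regions: no anchor families")

  # per genome: genes ordered by position with family labels
  ordered <- lapply(ids, function(g) {
    gn <- genomes[[g]]$genes
    gn <- gn[order(gn$replicon_id, gn$start), ]
    fam <- gene_map$family_id[match(paste(g, gn$gene_id),
                                    paste(gene_map$genome_id,
                                          gene_map$gene_id))]
    tibble(genome_id = g, gene_id = gn$gene_id,
           replicon_id = gn$replicon_id, start = gn$start, end = gn$end,
           family = fam, is_anchor = fam %in% anchors)
  })
  names(ordered) <- ids

  # anchor adjacencies per genome (unordered anchor pairs)
  adj <- lapply(ordered, function(d) {
    a <- d[d$is_anchor & !is.na(d$family), ]
    a <- a[order(a$replicon_id, a$start), ]
    res <- list()
    for (rep_id in unique(a$replicon_id)) {
      ar <- a[a$replicon_id == rep_id, ]
      if (nrow(ar) < 2) next
      for (i in seq_len(nrow(ar) - 1)) {
        key <- paste(sort(c(ar$family[i], ar$family[i + 1])), collapse = "|")
        res[[length(res) + 1]] <- tibble(
          key = key, left = ar$family[i], right = ar$family[i + 1],
          replicon_id = rep_id,
          lo = ar$end[i], hi = ar$start[i + 1])
      }
    }
    dplyr::bind_rows(res)
  })
  shared <- Reduce(intersect, lapply(adj, function(d) d$key))
  out <- list(); isl <- 0
  for (key in shared) {
    per <- lapply(ids, function(g) {
      row <- adj[[g]][adj[[g]]$key == key, ][1, ]
      d <- ordered[[g]]
      cargo <- d[d$replicon_id == row$replicon_id &
                   d$start > row$lo & d$end < row$hi, ]
      list(row = row, cargo = cargo)
    })
    names(per) <- ids
    famsets <- lapply(per, function(x) unique(stats::na.omit(x$cargo$family)))
    if (all(lengths(famsets) == 0)) next
    jac <- c()
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        u <- union(famsets[[i]], famsets[[j]])
        jac <- c(jac, if (!length(u)) 1 else
          length(intersect(famsets[[i]], famsets[[j]])) / length(u))
      }
    }
    if (min(jac) > max_jaccard) next
    isl <- isl + 1
    for (g in ids) {
      row <- per[[g]]$row; cargo <- per[[g]]$cargo
      span_start <- row$lo + 1; span_end <- row$hi - 1
      gc <- if (span_end > span_start) {
        gc_content(substr(replicon_seq(genomes[[g]], row$replicon_id),
                          span_start, span_end))
      } else NA_real_
      out[[length(out) + 1]] <- tibble(
        island_id = sprintf("fgi%02d", isl), genome_id = g,
        left_anchor_family = row$left, right_anchor_family = row$right,
        start = span_start, end = span_end, n_cargo = nrow(cargo),
        cargo_gene_ids = list(cargo$gene_id),
        cargo_families = list(famsets[[g]]),
        gc_pct = gc, min_jaccard = min(jac))
    }
  }
  if (!length(out)) {
    return(tibble(island_id = character(), genome_id = character(),
                  left_anchor_family = character(),
                  right_anchor_family = character(), start = integer(),
                  end = integer(), n_cargo = integer(),
                  cargo_gene_ids = list(), cargo_families = list(),
                  gc_pct = double(), min_jaccard = double()))
  }
  dplyr::bind_rows(out)
}

#' tRNA direct-repeat integration hallmarks
#'
#' For each annotated tRNA, exact occurrences of its 3'-terminal
#' `min_repeat` bases on the same strand, within `window` bp downstream
#' (3' of the tRNA on its coding strand) and excluding the tRNA itself,
#' are reported as hallmarks of site-specific cassette integration.
#'
#' @param genome A `genome_record` with tRNA annotations.
#' @param min_repeat Repeat length to search for (bp); tRNAs shorter than
#'   this yield no hallmark.
#' @param window Search window downstream of the tRNA (bp).
#' @return Tibble: `trna_id`, `strand`, `repeat_len`, `repeat_seq`,
#'   `trna_end3`, `repeat_start`, `repeat_end` (1-based genome
#'   coordinates).
#' @export
trna_hallmarks <- function(genome, min_repeat = 15, window = 100000) {
  stopifnot(inherits(genome, "genome_record"))
  tr <- genome$genes[genome$genes$kind == "tRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tr))) {
    tlen <- tr$end[i] - tr$start[i] + 1
    if (min_repeat > tlen || min_repeat < 1) next
    seq <- replicon_seq(genome, tr$replicon_id[i])
    L <- nchar(seq)
    if (tr$strand[i] == "+") {
      rep_fwd <- substr(seq, tr$end[i] - min_repeat + 1, tr$end[i])
      lo <- tr$end[i] + 1; hi <- min(L, tr$end[i] + window)
      if (hi - lo + 1 < min_repeat) next
      region <- substr(seq, lo, hi)
      m <- Biostrings::matchPattern(rep_fwd, Biostrings::DNAString(region))
      if (length(m)) {
        st <- Biostrings::start(m) + lo - 1
        out[[length(out) + 1]] <- tibble(
          trna_id = tr$gene_id[i], strand = "+",
          repeat_len = min_repeat, repeat_seq = rep_fwd,
          trna_end3 = tr$end[i], repeat_start = st,
          repeat_end = st + min_repeat - 1)
      }
    } else {
      # 3' end of a '-' tRNA is at its lowest coordinate; downstream is
      # towards lower coordinates, and the repeat lies on the '-' strand,
      # i.e. its forward-strand image equals the tRNA's first bases.
      rep_fwd <- substr(seq, tr$start[i], tr$start[i] + min_repeat - 1)
      hi <- tr$start[i] - 1; lo <- max(1, tr$start[i] - window)
      if (hi - lo + 1 < min_repeat) next
      region <- substr(seq, lo, hi)
      m <- Biostrings::matchPattern(rep_fwd, Biostrings::DNAString(region))
      if (length(m)) {
        st <- Biostrings::start(m) + lo - 1
        out[[length(out) + 1]] <- tibble(
          trna_id = tr$gene_id[i], strand = "-",
          repeat_len = min_repeat, repeat_seq = rep_fwd,
          trna_end3 = tr$start[i], repeat_start = st,
          repeat_end = st + min_repeat - 1)
      }
    }
  }
  if (!length(out)) {
    return(tibble(trna_id = character(), strand = character(),
                  repeat_len = integer(), repeat_seq = character(),
                  trna_end3 = integer(), repeat_start = integer(),
                  repeat_end = integer()))
  }
  dplyr::bind_rows(out)
}
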