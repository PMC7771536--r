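# Genome-streamlining statistics: GC content, coding stats, intergenic
# spacers, paralog counts by iterative identity clustering, an operon
# heuristic, and the cumulative GC-skew origin/terminus signal.

#' GC content of a sequence
#'
#' 100 (G+C) / (A+C+G+T); N bases are excluded from numerator and
#' denominator.
#'
#' @param sequence A single nucleotide string, or a `genome_record` (all
#'   replicons pooled).
#' @return Percent GC.
#' @export
#' @examples
#' gc_content("GCGC")
gc_content <- function(sequence) {
  if (inherits(sequence, "genome_record")) {
    sequence <- paste(sequence$replicons$sequence, collapse = "")
  }
  sequence <- check_seq(sequence)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) abort("gc_content undefined: sequence has no A/C/G/T bases")
  100 * (f[["C"]] + f[["G"]]) / tot
}

#' Coding statistics of an annotated genome
#'
#' Coding density is the fraction of genome positions covered by at least
#' one CDS (union over strands); average gene size is the mean CDS length.
#'
#' @param genome A `genome_record`.
#' @return One-row tibble: `genome_id`, `n_proteins`, `proteins_per_mb`,
#'   `avg_gene_size`, `coding_density_pct` (CDS only) and
#'   `gene_density_pct` (all annotated genes, including RNA genes).
#' @export
coding_stats <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  cds <- genome$genes[genome$genes$kind == "CDS", , drop = FALSE]
  glen <- genome_length(genome)
  if (!nrow(cds)) {
    return(tibble(genome_id = genome$genome_id, n_proteins = 0L,
                  proteins_per_mb = 0, avg_gene_size = 0,
                  coding_density_pct = 0, gene_density_pct = 0))
  }
  dens <- function(d) {
    sum(vapply(split(d, d$replicon_id), function(x) {
      interval_union_len(x$start, x$end)
    }, double(1)))
  }
  tibble(genome_id = genome$genome_id,
         n_proteins = nrow(cds),
         proteins_per_mb = nrow(cds) / (glen / 1e6),
         avg_gene_size = mean(cds$end - cds$start + 1),
         coding_density_pct = 100 * dens(cds) / glen,
         gene_density_pct = 100 * dens(genome$genes) / glen)
}

# total length of the union of 1-based inclusive intervals
interval_union_len <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce + 1) ce <- max(ce, end[i])
    else { tot <- tot + ce - cs + 1; cs <- start[i]; ce <- end[i] }
  }
  tot + ce - cs + 1
}

# merged union intervals as a tibble
interval_union <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  cs <- start[1]; ce <- end[1]; out <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce + 1) ce <- max(ce, end[i])
    else { out[[length(out) + 1]] <- c(cs, ce); cs <- start[i]; ce <- end[i] }
  }
  out[[length(out) + 1]] <- c(cs, ce)
  m <- do.call(rbind, out)
  tibble(start = m[, 1], end = m[, 2])
}

#' Median intergenic spacer
#'
#' For consecutive genes per replicon, sorted by start and strand-agnostic,
#' the spacer is `next.start - prev.end - 1` (1-based inclusive
#' coordinates). Overlapping genes give negative spacers, which are kept.
#'
#' @param genome A `genome_record` (needs >= 2 genes on some replicon).
#' @return Median spacer in bp (possibly negative).
#' @export
median_intergenic_spacer <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  sp <- unlist(lapply(split(genome$genes, genome$genes$replicon_id),
                      function(d) {
    if (nrow(d) < 2) return(numeric())
    d <- d[order(d$start, d$end), ]
    d$start[-1] - d$end[-nrow(d)] - 1
  }))
  if (!length(sp)) abort("median_intergenic_spacer undefined: < 2 genes")
  median(sp)
}

#' Count paralogs by iterative identity clustering
#'
#' Greedy length-descending clustering of the proteome at each identity
#' threshold (identity over at least `coverage` of the shorter sequence);
#' the paralog count at a threshold is the number of proteins falling in
#' clusters of size >= 2. Counts are non-decreasing as the threshold drops.
#'
#' @param proteins Named character vector of protein sequences, or a tibble
#'   with columns `protein_id`, `sequence`.
#' @param thresholds Identity thresholds (percent), default 90/70/50/30.
#' @param coverage Minimum aligned fraction of the shorter sequence.
#' @return Tibble with columns `threshold`, `n_paralogs`.
#' @export
count_paralogs <- function(proteins, thresholds = c(90, 70, 50, 30),
                           coverage = 0.75) {
  seqs <- protein_vec(proteins)
  if (!length(seqs)) abort("count_paralogs: need at least one protein")
  o <- order(-nchar(seqs))
  sorted <- toupper(seqs[o])
  out <- lapply(sort(thresholds, decreasing = TRUE), function(thr) {
    cl <- .cpp_cluster_greedy(sorted, thr, coverage, 3L, 16L)
    sizes <- table(cl)
    tibble(threshold = thr,
           n_paralogs = as.integer(sum(sizes[sizes >= 2])))
  })
  dplyr::bind_rows(out)
}

protein_vec <- function(proteins) {
  if (is.data.frame(proteins)) {
    setNames(proteins$sequence, proteins$protein_id)
  } else {
    if (is.null(names(proteins))) {
      names(proteins) <- paste0("p", seq_along(proteins))
    }
    proteins
  }
}

#' Operon prediction heuristic
#'
#' Maximal runs of same-strand consecutive CDS separated by at most
#' `max_gap` bp form one operon; singletons count as operons of size 1.
#'
#' @param genome A `genome_record`.
#' @param max_gap Maximum intergenic gap within an operon (bp).
#' @return List with `operons` (tibble: `operon_id`, `replicon_id`,
#'   `strand`, `start`, `end`, `n_genes`) and `avg_genes_per_operon`.
#' @export
predict_operons <- function(genome, max_gap = 30) {
  stopifnot(inherits(genome, "genome_record"))
  cds <- genome$genes[genome$genes$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) {
    return(list(operons = tibble(), avg_genes_per_operon = NA_real_))
  }
  res <- lapply(split(cds, cds$replicon_id), function(d) {
    d <- d[order(d$start, d$end), ]
    if (nrow(d) == 1) {
      brk <- logical(0)
    } else {
      gap <- d$start[-1] - d$end[-nrow(d)] - 1
      brk <- gap > max_gap | d$strand[-1] != d$strand[-nrow(d)]
    }
    grp <- cumsum(c(TRUE, brk))
    d %>%
      mutate(grp = grp) %>%
      group_by(.data$grp) %>%
      summarise(replicon_id = first(.data$replicon_id),
                strand = first(.data$strand), start = min(.data$start),
                end = max(.data$end), n_genes = n(), .groups = "drop") %>%
      select(-"grp")
  })
  op <- dplyr::bind_rows(res)
  op$operon_id <- sprintf("op%04d", seq_len(nrow(op)))
  list(operons = op[, c("operon_id", "replicon_id", "strand", "start",
                        "end", "n_genes")],
       avg_genes_per_operon = mean(op$n_genes))
}

#' GC-skew origin/terminus signal
#'
#' Per non-overlapping window skew (G-C)/(G+C), cumulative sum scanned from
#' coordinate 0 of the (circular) sequence; the global minimum of the
#' cumulative profile marks the replication origin and the global maximum
#' the terminus.
#'
#' @param sequence A single nucleotide string or `genome_record` (largest
#'   replicon used).
#' @param window Window size in bp (sequence must be >= 2 windows).
#' @return List with `origin_pos`, `terminus_pos` (1-based window-start
#'   positions) and `profile` (tibble: `window_start`, `skew`, `cum_skew`).
#' @export
gc_skew_extrema <- function(sequence, window = 1000) {
  if (inherits(sequence, "genome_record")) {
    sequence <- sequence$replicons$sequence[
      which.max(sequence$replicons$length)]
  }
  sequence <- check_seq(sequence)
  n <- nchar(sequence)
  if (n < 2 * window) abort("gc_skew_extrema: sequence shorter than 2 windows")
  nwin <- n %/% window
  starts <- (seq_len(nwin) - 1) * window + 1
  wins <- substring(sequence, starts, starts + window - 1)
  g <- nchar(gsub("[^G]", "", wins))
  c_ <- nchar(gsub("[^C]", "", wins))
  skew <- ifelse(g + c_ == 0, 0, (g - c_) / (g + c_))
  cum <- cumsum(skew)
  list(origin_pos = starts[which.min(cum)],
       terminus_pos = starts[which.max(cum)],
       profile = tibble(window_start = starts, skew = skew, cum_skew = cum))
}

#' Streamlining report (one genome)
#'
#' Bundles the genome-reduction statistics commonly tabulated for
#' streamlined marine genomes: size, GC, protein counts and density,
#' spacers, paralogs (headline at the 30 percent threshold), operon sizes,
#' and GC-skew extrema.
#'
#' @param genome A `genome_record`.
#' @param proteins Optional protein set (defaults to the genome's CDS
#'   translations).
#' @param config An [analysis_config()].
#' @return One-row tibble.
#' @export
streamline_report <- function(genome, proteins = NULL,
                              config = analysis_config()) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(proteins)) proteins <- genome_proteins(genome)
  cs <- coding_stats(genome)
  par <- if (length(proteins)) {
    count_paralogs(proteins, thresholds = config$paralog_thresholds,
                   coverage = config$paralog_coverage)
  } else tibble(threshold = config$paralog_thresholds, n_paralogs = 0L)
  ops <- predict_operons(genome, max_gap = config$operon_max_gap)
  glen <- genome_length(genome)
  skew <- if (glen >= 2000) gc_skew_extrema(genome) else
    list(origin_pos = NA_integer_, terminus_pos = NA_integer_)
  spacer <- tryCatch(median_intergenic_spacer(genome),
                     error = function(e) NA_real_)
  tibble(
    genome_id = genome$genome_id,
    genome_size = glen,
    gc_pct = gc_content(genome),
    n_proteins = cs$n_proteins,
    proteins_per_mb = cs$proteins_per_mb,
    avg_gene_size = cs$avg_gene_size,
    coding_density_pct = cs$coding_density_pct,
    median_intergenic_spacer = spacer,
    n_paralogs = par$n_paralogs[par$threshold == min(par$threshold)],
    paralog_counts = list(par),
    avg_genes_per_operon = ops$avg_genes_per_operon,
    skew_origin = skew$origin_pos,
    skew_terminus = skew$terminus_pos
  )
}
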