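# Metagenomic read recruitment: read QC, best-hit recruitment with rRNA
# operon masking, RPKG / coverage presence calls, read-based ANI (ANIr),
# identity histograms, and genomospecies-level distribution summaries.

#' Quality-control metagenomic reads
#'
#' Keeps reads with mean Phred >= `min_phred`, length >= `min_len` and no
#' ambiguous bases. FASTA-style input (no `quality` column, or NA quality)
#' skips the Phred test.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`
#'   (Phred+33 string).
#' @param min_phred Minimum mean Phred score.
#' @param min_len Minimum read length (bp).
#' @return Filtered tibble.
#' @export
qc_reads <- function(reads, min_phred = 30, min_len = 50) {
  reads <- tibble::as_tibble(reads)
  if (!all(c("read_id", "sequence") %in% names(reads))) {
    abort("qc_reads: reads need read_id and sequence columns")
  }
  keep <- nchar(reads$sequence) >= min_len &
    !grepl("N", reads$sequence, fixed = TRUE) &
    !grepl("n", reads$sequence, fixed = TRUE)
  if ("quality" %in% names(reads)) {
    q <- reads$quality
    has_q <- !is.na(q)
    if (any(has_q & nchar(q) != nchar(reads$sequence))) {
      bad <- which(has_q & nchar(q) != nchar(reads$sequence))[1]
      abort(paste0("qc_reads: quality/sequence length mismatch at record ",
                   bad))
    }
    mean_q <- rep(Inf, nrow(reads))
    mean_q[has_q] <- vapply(q[has_q], function(s) {
      mean(utf8ToInt(s)) - 33
    }, double(1))
    keep <- keep & mean_q >= min_phred
  }
  reads[keep, , drop = FALSE]
}

#' Read a FASTA/FASTQ read set into a tibble
#'
#' @param path File path; format guessed from the extension unless given.
#' @param format "auto", "fasta" or "fastq".
#' @return Tibble with `read_id`, `sequence` and (FASTQ) `quality`.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    tibble(read_id = sub("\\s.*", "", names(x)),
           sequence = as.character(x), quality = qual)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    tibble(read_id = sub("\\s.*", "", names(x)), sequence = as.character(x),
           quality = NA_character_)
  }
}

# merge annotated rRNA genes (within `join` bp) into operon mask intervals
rrna_mask_intervals <- function(genome, join = 1000) {
  rr <- genome$genes[genome$genes$kind == "rRNA", , drop = FALSE]
  if (!nrow(rr)) {
    return(tibble(replicon_id = character(), start = integer(),
                  end = integer()))
  }
  out <- lapply(split(rr, rr$replicon_id), function(d) {
    u <- interval_union(d$start - join %/% 2, d$end + join %/% 2)
    len <- genome$replicons$length[
      match(d$replicon_id[1], genome$replicons$replicon_id)]
    u$start <- pmax(1L, as.integer(u$start))
    u$end <- pmin(len, as.integer(u$end))
    u$replicon_id <- d$replicon_id[1]
    u
  })
  dplyr::bind_rows(out)[, c("replicon_id", "start", "end")]
}

#' Recruit reads to a genome
#'
#' Best single hit per read (both strands; ties to the lowest target start,
#' then "+"). The ribosomal RNA operon is masked before alignment so that
#' its conserved sequence cannot inflate abundance; the effective genome
#' length excludes masked bases.
#'
#' @param genome A `genome_record`.
#' @param reads Tibble with `read_id`, `sequence` (QC them first with
#'   [qc_reads()]).
#' @param min_identity Identity cutoff (percent): 98 for abundance mode,
#'   70 for linear-plot mode.
#' @param min_len Minimum alignment length (nt).
#' @param mask_rrna Mask the annotated rRNA operon.
#' @param metagenome_gb Metagenome size in Gb (for RPKG).
#' @param sample_id Sample label.
#' @param k,band Aligner seeding parameters.
#' @return Object of class `recruitment_profile`: list with `genome_id`,
#'   `sample_id`, `metagenome_gb`, `masked` (tibble of masked intervals),
#'   `hits` (tibble: `read_id`, `replicon_id`, `position`, `aligned_len`,
#'   `identity_pct`, `strand`), `genome_len_effective`, `min_identity`,
#'   `min_len`.
#' @export
recruit <- function(genome, reads, min_identity = 98, min_len = 50,
                    mask_rrna = TRUE, metagenome_gb = 1,
                    sample_id = "sample", k = 13, band = 16) {
  stopifnot(inherits(genome, "genome_record"))
  reads <- tibble::as_tibble(reads)
  if (genome_length(genome) < min_len) {
    abort("recruit: genome shorter than min_len")
  }
  masked <- if (mask_rrna) rrna_mask_intervals(genome) else
    tibble(replicon_id = character(), start = integer(), end = integer())
  g <- genome
  if (nrow(masked)) {
    for (i in seq_len(nrow(masked))) {
      ri <- match(masked$replicon_id[i], g$replicons$replicon_id)
      s <- g$replicons$sequence[ri]
      substr(s, masked$start[i], masked$end[i]) <-
        strrep("N", masked$end[i] - masked$start[i] + 1)
      g$replicons$sequence[ri] <- s
    }
  }
  hits <- map_reads(reads, g, min_len = min_len, min_identity = min_identity,
                    k = k, band = band)
  hits <- tibble(read_id = hits$read_id, replicon_id = hits$replicon_id,
                 position = hits$tstart + 1L,
                 aligned_len = hits$aligned_columns,
                 identity_pct = hits$identity_pct, strand = hits$strand,
                 tend = hits$tend)
  eff <- genome_length(genome) -
    sum(if (nrow(masked)) masked$end - masked$start + 1 else 0)
  structure(list(genome_id = genome$genome_id, sample_id = sample_id,
                 metagenome_gb = metagenome_gb, masked = masked, hits = hits,
                 genome_len_effective = eff, min_identity = min_identity,
                 min_len = min_len),
            class = "recruitment_profile")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf(
    "<recruitment_profile %s / %s: %d hits, eff. length %s bp, cutoff %g%%>\n",
    x$genome_id, x$sample_id, nrow(x$hits),
    format(x$genome_len_effective, big.mark = ","), x$min_identity))
  invisible(x)
}

#' RPKG and presence call from a recruitment profile
#'
#' RPKG = hits / (effective genome length in kb x metagenome size in Gb);
#' coverage is the fraction of the effective genome under the union of hit
#' footprints. A genome is present when RPKG >= `rpkg_min` and coverage >
#' `cov_min`.
#'
#' @param profile A `recruitment_profile`.
#' @param rpkg_min RPKG threshold (default 5).
#' @param cov_min Coverage fraction threshold (default 0.70, strict >).
#' @return One-row tibble: `genome_id`, `sample_id`, `n_hits`, `rpkg`,
#'   `coverage_fraction`, `present`.
#' @export
rpkg_presence <- function(profile, rpkg_min = 5, cov_min = 0.70) {
  stopifnot(inherits(profile, "recruitment_profile"))
  if (profile$metagenome_gb <= 0) {
    abort("rpkg_presence: metagenome size must be positive")
  }
  h <- profile$hits
  rpkg <- nrow(h) / ((profile$genome_len_effective / 1000) *
                       profile$metagenome_gb)
  cov <- if (nrow(h)) {
    covered <- sum(vapply(split(h, h$replicon_id), function(d) {
      interval_union_len(d$position, d$tend)
    }, double(1)))
    covered / profile$genome_len_effective
  } else 0
  tibble(genome_id = profile$genome_id, sample_id = profile$sample_id,
         n_hits = nrow(h), rpkg = rpkg, coverage_fraction = cov,
         present = rpkg >= rpkg_min & cov > cov_min)
}

#' Read-based average nucleotide identity (ANIr)
#'
#' Mean percent identity over recruited reads; by convention computed on a
#' profile recruited at a permissive cutoff (>= 80 percent identity over
#' >= 50 nt) so that the whole intrapopulation identity distribution
#' contributes.
#'
#' @param profile A `recruitment_profile` with at least one hit.
#' @return Percent identity (scalar).
#' @export
anir <- function(profile) {
  stopifnot(inherits(profile, "recruitment_profile"))
  if (!nrow(profile$hits)) abort("anir undefined: no recruited reads")
  mean(profile$hits$identity_pct)
}

#' Identity histogram of recruited reads
#'
#' Counts per 1 percent identity bin from `bin_from` to 100; reads at
#' exactly 100 percent fall in the top bin. Relative percentages sum to
#' 100 (when there are hits).
#'
#' @param profile A `recruitment_profile`.
#' @param bin_from Lower bound of the first bin (percent).
#' @return Tibble: `bin_lo`, `bin_hi`, `count`, `rel_pct`, with attribute
#'   `species_threshold` = 95.
#' @export
identity_histogram <- function(profile, bin_from = 70) {
  stopifnot(inherits(profile, "recruitment_profile"))
  lo <- seq(bin_from, 99)
  hi <- lo + 1
  id <- profile$hits$identity_pct
  cnt <- vapply(seq_along(lo), function(i) {
    if (hi[i] >= 100) sum(id >= lo[i] & id <= 100)
    else sum(id >= lo[i] & id < hi[i])
  }, integer(1))
  out <- tibble(bin_lo = lo, bin_hi = hi, count = cnt,
                rel_pct = if (sum(cnt)) 100 * cnt / sum(cnt) else
                  rep(0, length(cnt)))
  attr(out, "species_threshold") <- 95
  out
}

#' Genomospecies-level distribution across samples
#'
#' Mean RPKG of the member genomes of each genomospecies per sample, with
#' the same presence rule applied to the mean. Genomes lacking a profile in
#' a sample count as RPKG 0 (with a warning).
#'
#' @param profiles List of `recruitment_profile` objects (one per genome x
#'   sample).
#' @param ranks Rank assignment from [cluster_ranks()] (or any tibble with
#'   `genome_id` and `genomospecies`).
#' @param rpkg_min,cov_min Presence thresholds applied to the mean RPKG and
#'   to the member-mean coverage.
#' @return Tibble: `genomospecies`, `sample_id`, `mean_rpkg`,
#'   `mean_coverage`, `n_genomes`, `present`.
#' @export
genomospecies_distribution <- function(profiles, ranks, rpkg_min = 5,
                                       cov_min = 0.70) {
  calls <- dplyr::bind_rows(lapply(profiles, rpkg_presence,
                                   rpkg_min = rpkg_min, cov_min = cov_min))
  miss <- setdiff(calls$genome_id, ranks$genome_id)
  if (length(miss)) {
    abort(paste0("genomospecies_distribution: no rank for ",
                 paste(miss, collapse = ", ")))
  }
  calls <- left_join(calls, ranks[, c("genome_id", "genomospecies")],
                     by = "genome_id")
  grid <- tidyr::expand_grid(genome_id = unique(ranks$genome_id),
                             sample_id = unique(calls$sample_id))
  full <- left_join(grid, calls, by = c("genome_id", "sample_id"))
  if (any(is.na(full$rpkg))) {
    warn("genomospecies_distribution: missing genome x sample profiles treated as RPKG 0")
    full$rpkg[is.na(full$rpkg)] <- 0
    full$coverage_fraction[is.na(full$coverage_fraction)] <- 0
  }
  full$genomospecies <- ranks$genomospecies[
    match(full$genome_id, ranks$genome_id)]
  full %>%
    group_by(.data$genomospecies, .data$sample_id) %>%
    summarise(mean_rpkg = mean(.data$rpkg),
              mean_coverage = mean(.data$coverage_fraction),
              n_genomes = n(), .groups = "drop") %>%
    mutate(present = .data$mean_rpkg >= rpkg_min &
             .data$mean_coverage > cov_min)
}
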