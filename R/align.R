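# Pairwise alignment surface shared by ANI, recruitment and clustering.
# Scoring: match +1, mismatch -1, linear gap -2; identity denominator is
# alignment columns including gaps (the common BLAST-style convention); N
# bases never count as matches. Pairs small enough for full dynamic
# programming are solved exactly; larger targets use exact k-mer seeding
# (k = 13 nucleotide) with windowed extension.

.FULL_DP_LIMIT <- 4e6

check_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort(paste0(what, " must be a single non-empty string"))
  }
  toupper(x)
}

aln_tibble <- function(hit, query_id, target_id, strand = "+") {
  tibble(
    query_id = query_id, target_id = target_id,
    qstart = hit$qstart, qend = hit$qend,
    tstart = hit$tstart, tend = hit$tend,
    strand = strand,
    matches = hit$matches, aligned_columns = hit$columns,
    identity_pct = 100 * hit$matches / hit$columns,
    score = hit$score
  )
}

empty_aln <- function() {
  tibble(query_id = character(), target_id = character(),
         qstart = integer(), qend = integer(),
         tstart = integer(), tend = integer(), strand = character(),
         matches = integer(), aligned_columns = integer(),
         identity_pct = double(), score = integer())
}

#' Best local alignment between two sequences
#'
#' Highest-scoring local alignment (match +1, mismatch -1, gap -2) between
#' two nucleotide (or amino-acid) sequences, returned only if it reaches
#' `min_len` aligned columns and `min_identity` percent identity. Spans are
#' 0-based half-open.
#'
#' @param a,b Sequences (single strings). `a` is the query.
#' @param min_len Minimum alignment length in columns (gaps included).
#' @param min_identity Minimum percent identity (matches / columns).
#' @param k Seed k-mer size used for large inputs.
#' @param band Window margin for seeded extension.
#'
#' @return A tibble with 0 rows (no qualifying alignment) or 1 row with
#'   columns `query_id`, `target_id`, `qstart`, `qend`, `tstart`, `tend`,
#'   `strand`, `matches`, `aligned_columns`, `identity_pct`, `score`.
#' @export
#' @examples
#' local_align(strrep("ACGT", 25), strrep("ACGT", 25))
local_align <- function(a, b, min_len = 1, min_identity = 0, k = 13, band = 16) {
  qid <- if (!is.null(names(a))) names(a)[1] else "query"
  tid <- if (!is.null(names(b))) names(b)[1] else "target"
  a <- check_seq(a, "a"); b <- check_seq(b, "b")
  hit <- .cpp_local_align(a, b, k, band, .FULL_DP_LIMIT)
  if (!hit$found || hit$columns < min_len ||
      100 * hit$matches / max(1L, hit$columns) < min_identity) {
    return(empty_aln())
  }
  aln_tibble(hit, qid, tid)
}

#' Map reads to a genome (best hit per read)
#'
#' Both strands are searched; each read keeps its single best hit (highest
#' score, ties broken by lowest target start, then "+" strand). With a
#' multi-replicon genome each replicon is searched and the best hit across
#' replicons is kept.
#'
#' @param reads Character vector of read sequences (optionally named), or a
#'   tibble with columns `read_id` and `sequence`.
#' @param genome A `genome_record` or a single target sequence string.
#' @param min_len Minimum alignment length (columns).
#' @param min_identity Minimum percent identity.
#' @param k,band Seeding parameters.
#'
#' @return Tibble with one row per mapped read: `read_id`, `replicon_id`,
#'   `qstart`, `qend`, `tstart`, `tend` (0-based half-open), `strand`,
#'   `matches`, `aligned_columns`, `identity_pct`, `score`.
#' @export
map_reads <- function(reads, genome, min_len = 50, min_identity = 0,
                      k = 13, band = 16) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- toupper(reads$sequence)
  } else {
    seqs <- toupper(as.character(reads))
    ids <- if (!is.null(names(reads))) names(reads) else
      paste0("read", seq_along(seqs))
  }
  if (!length(seqs)) return(empty_map())
  if (any(!nzchar(seqs) | is.na(seqs))) abort("empty read sequence")
  if (inherits(genome, "genome_record")) {
    reps <- genome$replicons
  } else {
    reps <- tibble(replicon_id = "target", sequence = toupper(genome))
  }
  best <- NULL
  for (ri in seq_len(nrow(reps))) {
    df <- .cpp_map_reads(seqs, reps$sequence[ri], k, band,
                         as.integer(min_len), min_identity, TRUE, 8L)
    df$replicon_id <- reps$replicon_id[ri]
    df$read_id <- ids
    if (is.null(best)) {
      best <- df
    } else {
      take <- df$found & (!best$found | df$score > best$score |
                            (df$score == best$score & df$tstart < best$tstart))
      take[is.na(take)] <- FALSE
      best[take, ] <- df[take, ]
    }
  }
  out <- tibble::as_tibble(best[best$found, , drop = FALSE])
  if (!nrow(out)) return(empty_map())
  out$identity_pct <- out$identity
  out$aligned_columns <- out$columns
  out[, c("read_id", "replicon_id", "qstart", "qend", "tstart", "tend",
          "strand", "matches", "aligned_columns", "identity_pct", "score")]
}

empty_map <- function() {
  tibble(read_id = character(), replicon_id = character(),
         qstart = integer(), qend = integer(), tstart = integer(),
         tend = integer(), strand = character(), matches = integer(),
         aligned_columns = integer(), identity_pct = double(),
         score = integer())
}

#' Map a single read (best hit or none)
#'
#' @inheritParams map_reads
#' @param read A single read sequence (optionally named).
#' @return Tibble with 0 or 1 rows (see [map_reads()]).
#' @export
map_read <- function(read, genome, min_len = 1, min_identity = 0,
                     k = 13, band = 16) {
  nm <- if (!is.null(names(read))) names(read)[1] else "read"
  read <- check_seq(read, "read")
  map_reads(setNames(read, nm), genome, min_len = min_len,
            min_identity = min_identity, k = k, band = band)
}

#' Percent identity between two sequences (local alignment)
#'
#' Convenience wrapper returning just `identity_pct` of the best local
#' alignment, or `NA` if none.
#' @inheritParams local_align
#' @return Numeric scalar (possibly `NA`).
#' @export
pair_identity <- function(a, b, k = 13, band = 16) {
  hit <- local_align(a, b, k = k, band = band)
  if (!nrow(hit)) return(NA_real_)
  hit$identity_pct
}
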