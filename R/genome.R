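#' Genome record container
#'
#' Bundles the assembled replicon sequences of one genome with its gene
#' annotations. Coordinates are 1-based inclusive (GFF3 convention) on the
#' forward strand of the replicon; internal alignment code converts to
#' 0-based half-open as needed.
#'
#' @param genome_id Genome identifier.
#' @param replicons Tibble with columns `replicon_id`, `sequence`
#'   (uppercase A/C/G/T/N character), `circular` (logical).
#' @param genes Tibble with columns `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand` ("+"/"-"), `kind` (CDS, tRNA, rRNA, ncRNA), `product`,
#'   and optionally `protein` (amino-acid sequence for CDS). May have zero
#'   rows.
#'
#' @return Object of class `genome_record`.
#' @export
genome_record <- function(genome_id, replicons, genes = NULL) {
  if (!is.character(genome_id) || length(genome_id) != 1 || !nzchar(genome_id)) {
    abort("genome_id must be a single non-empty string")
  }
  replicons <- tibble::as_tibble(replicons)
  need <- c("replicon_id", "sequence")
  if (!all(need %in% names(replicons))) {
    abort("replicons needs columns replicon_id and sequence")
  }
  if (!"circular" %in% names(replicons)) replicons$circular <- TRUE
  if (anyDuplicated(replicons$replicon_id)) abort("duplicate replicon ids")
  replicons$sequence <- unname(toupper(replicons$sequence))
  replicons$length <- nchar(replicons$sequence)
  if (any(replicons$length == 0)) abort("empty replicon sequence")

  if (is.null(genes)) {
    genes <- tibble(gene_id = character(), replicon_id = character(),
                    start = integer(), end = integer(), strand = character(),
                    kind = character(), product = character(),
                    protein = character())
  }
  genes <- tibble::as_tibble(genes)
  for (col in c("product", "protein")) {
    if (!col %in% names(genes)) genes[[col]] <- rep(NA_character_, nrow(genes))
  }
  if (!"kind" %in% names(genes)) genes$kind <- rep("CDS", nrow(genes))
  if (nrow(genes)) {
    need <- c("gene_id", "replicon_id", "start", "end", "strand")
    if (!all(need %in% names(genes))) {
      abort("genes needs columns gene_id, replicon_id, start, end, strand")
    }
    if (anyDuplicated(genes$gene_id)) abort("duplicate gene ids")
    if (!all(genes$replicon_id %in% replicons$replicon_id)) {
      abort("gene replicon_id not present among replicons")
    }
    if (any(genes$start < 1) || any(genes$start > genes$end)) {
      abort("gene coordinates must satisfy 1 <= start <= end")
    }
    len <- setNames(replicons$length, replicons$replicon_id)
    if (any(genes$end > len[genes$replicon_id])) {
      bad <- genes$gene_id[genes$end > len[genes$replicon_id]][1]
      abort(paste0("gene ", bad, " extends beyond its replicon"))
    }
    if (!all(genes$strand %in% c("+", "-"))) abort("strand must be + or -")
  }
  genes <- genes[, c("gene_id", "replicon_id", "start", "end", "strand",
                     "kind", "product", "protein")]
  structure(list(genome_id = genome_id, replicons = replicons, genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s: %d replicon(s), %s bp, %d gene(s)>\n",
              x$genome_id, nrow(x$replicons),
              format(sum(x$replicons$length), big.mark = ","), nrow(x$genes)))
  invisible(x)
}

#' Total genome length in bp
#' @param genome A `genome_record`.
#' @return Integer total length.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  sum(genome$replicons$length)
}

#' Extract gene nucleotide sequences (coding strand)
#'
#' @param genome A `genome_record`.
#' @param gene_ids Optional subset of gene ids.
#' @return Named character vector of coding-strand sequences.
#' @export
gene_seqs <- function(genome, gene_ids = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes
  if (!is.null(gene_ids)) {
    miss <- setdiff(gene_ids, g$gene_id)
    if (length(miss)) abort(paste0("unknown gene id(s): ", paste(miss, collapse = ", ")))
    g <- g[match(gene_ids, g$gene_id), ]
  }
  seqs <- setNames(replicon_seq(genome, g$replicon_id), NULL)
  out <- substr(seqs, g$start, g$end)
  flip <- g$strand == "-"
  if (any(flip)) out[flip] <- vapply(out[flip], .cpp_revcomp, character(1))
  setNames(out, g$gene_id)
}

replicon_seq <- function(genome, replicon_id) {
  genome$replicons$sequence[match(replicon_id, genome$replicons$replicon_id)]
}

#' Translate CDS genes of a genome
#'
#' @param genome A `genome_record`.
#' @return Named character vector of protein sequences for CDS genes.
#'   Pre-filled `protein` entries in the gene table take precedence.
#' @export
genome_proteins <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes[genome$genes$kind == "CDS", , drop = FALSE]
  if (!nrow(g)) return(setNames(character(), character()))
  have <- !is.na(g$protein)
  out <- setNames(rep(NA_character_, nrow(g)), g$gene_id)
  out[have] <- g$protein[have]
  if (any(!have)) {
    nt <- gene_seqs(genome, g$gene_id[!have])
    nt <- substr(nt, 1, (nchar(nt) %/% 3) * 3)
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                             if.fuzzy.codon = "solve"))
    out[!have] <- aa
  }
  out
}

#' Reverse complement of a nucleotide sequence
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) vapply(x, .cpp_revcomp, character(1), USE.NAMES = FALSE)
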