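# Readers and writers: FASTA + GFF3 round trip for genome records, and a
# fetch helper for NCBI reference assemblies.

#' Read a genome from FASTA + GFF3
#'
#' @param fasta Path to the replicon FASTA.
#' @param gff3 Optional path to a GFF3 annotation whose seqids match the
#'   FASTA headers.
#' @param proteins Optional protein FASTA; names must match gene ids.
#' @param genome_id Genome id (default: FASTA basename).
#' @param circular Logical, recycled over replicons.
#' @return A `genome_record`.
#' @export
read_genome <- function(fasta, gff3 = NULL, proteins = NULL,
                        genome_id = NULL, circular = TRUE) {
  if (!file.exists(fasta)) abort(paste0("no such file: ", fasta))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(fasta),
                     ignore.case = TRUE)
  }
  ss <- Biostrings::readDNAStringSet(fasta)
  reps <- tibble(replicon_id = sub("\\s.*", "", names(ss)),
                 sequence = as.character(ss), circular = circular)
  genes <- NULL
  if (!is.null(gff3)) {
    gr <- rtracklayer::import(gff3)
    keep <- as.character(gr$type) %in% c("CDS", "tRNA", "rRNA", "ncRNA")
    gr <- gr[keep]
    seqid <- as.character(GenomicRanges::seqnames(gr))
    bad <- setdiff(unique(seqid), reps$replicon_id)
    if (length(bad)) {
      abort(paste0("GFF3 seqid(s) not in FASTA: ", paste(bad, collapse = ", ")))
    }
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else
      sprintf("gene%05d", seq_along(gr))
    id[is.na(id)] <- sprintf("gene%05d", which(is.na(id)))
    genes <- tibble(
      gene_id = id, replicon_id = seqid,
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      kind = as.character(gr$type),
      product = if (!is.null(gr$product)) as.character(gr$product) else
        NA_character_,
      protein = NA_character_)
    lens <- setNames(reps$length <- nchar(reps$sequence), reps$replicon_id)
    over <- genes$end > lens[genes$replicon_id]
    if (any(over)) {
      abort(paste0("feature beyond replicon bounds: ",
                   genes$gene_id[over][1]))
    }
  }
  g <- genome_record(genome_id, reps, genes)
  if (!is.null(proteins)) {
    ps <- Biostrings::readAAStringSet(proteins)
    nm <- sub("\\s.*", "", names(ps))
    hit <- match(g$genes$gene_id, nm)
    g$genes$protein[!is.na(hit)] <- as.character(ps)[hit[!is.na(hit)]]
  }
  g
}

#' Write a genome to FASTA + GFF3 (+ optional protein FASTA)
#'
#' `read_genome(write_genome(x))` is lossless for sequences and
#' coordinates.
#'
#' @param genome A `genome_record`.
#' @param fasta,gff3,proteins Output paths (`gff3`/`proteins` optional).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta, gff3 = NULL, proteins = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  ss <- Biostrings::DNAStringSet(setNames(genome$replicons$sequence,
                                          genome$replicons$replicon_id))
  Biostrings::writeXStringSet(ss, fasta)
  out <- fasta
  if (!is.null(gff3)) {
    g <- genome$genes
    gr <- GenomicRanges::GRanges(
      seqnames = g$replicon_id,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand)
    gr$type <- g$kind
    gr$ID <- g$gene_id
    gr$product <- g$product
    gr$phase <- ifelse(g$kind == "CDS", 0L, NA_integer_)
    rtracklayer::export(gr, gff3, format = "gff3")
    out <- c(out, gff3)
  }
  if (!is.null(proteins)) {
    p <- genome_proteins(genome)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(p), proteins)
    out <- c(out, proteins)
  }
  invisible(out)
}

# known assembly directory labels for the reference genomes used in
# cross-checks
.known_assemblies <- c(
  "GCA_000005845.2" = "ASM584v2",
  "GCA_000155895.1" = "ASM15589v1",
  "GCA_002284855.1" = "ASM228485v1"
)

#' Fetch a reference assembly from NCBI (requires network)
#'
#' Downloads the genomic FASTA of a GenBank assembly from the NCBI FTP
#' layout. Intended for cross-checking published reference values (e.g. GC
#' content and genome length of E. coli K-12); offline runs will fail here
#' and should treat the result as unavailable.
#'
#' @param accession GCA accession (e.g. "GCA_000005845.2").
#' @param dest_dir Download directory.
#' @param assembly_name Assembly label (looked up for known accessions).
#' @param timeout Seconds before giving up.
#' @return Path to the downloaded FASTA (gz), or NULL if unavailable.
#' @export
fetch_reference_genome <- function(accession, dest_dir = tempdir(),
                                   assembly_name = NULL, timeout = 60) {
  if (is.null(assembly_name)) {
    assembly_name <- .known_assemblies[accession]
    if (is.na(assembly_name)) {
      abort("assembly_name required for unknown accession")
    }
  }
  part <- gsub("(...)(...)(...).*", "\\1/\\2/\\3",
               sub("^GCA_", "", accession))
  base <- sprintf("%s_%s", accession, assembly_name)
  url <- sprintf(
    "https://ftp.ncbi.nlm.nih.gov/genomes/all/GCA/%s/%s/%s_genomic.fna.gz",
    part, base, base)
  dest <- file.path(dest_dir, paste0(base, "_genomic.fna.gz"))
  old <- getOption("timeout"); on.exit(options(timeout = old))
  options(timeout = timeout)
  ok <- tryCatch({
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest)) return(NULL)
  dest
}
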