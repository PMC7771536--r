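# Composite genome reconstruction from groups of closely related SAG
# contig sets: >99% ANI groups of at least five SAGs are tiled onto the
# largest member, consensus is taken per position, and positions covered
# by fewer than two fragments are masked.

sag_contigs <- function(x, sag_id) {
  if (inherits(x, "genome_record")) {
    setNames(x$replicons$sequence, x$replicons$replicon_id)
  } else {
    nm <- names(x)
    v <- toupper(as.character(x))
    names(v) <- if (is.null(nm)) sprintf("%s_c%02d", sag_id, seq_along(v))
      else nm
    v
  }
}

#' Reconstruct a composite genome from a group of SAGs
#'
#' Enforces the three reconstruction rules: (i) all pairwise ANI of the
#' group must exceed `min_ani`; (ii) the group must have at least
#' `min_sags` members; (iii) every emitted position must be covered by at
#' least `min_cov` fragments - under-covered positions are masked to N and
#' reported. The largest SAG (total bp) is the tiling reference; remaining
#' contigs are placed by best alignment and the consensus is
#' majority-ruled with ties resolved to the reference base. A contig
#' spanning the end of one reference contig and the start of another at
#' >= `join_identity` percent identity joins them.
#'
#' @param sags Named list of SAG contig sets (named character vectors or
#'   `genome_record` objects).
#' @param ani ANI table or matrix over the SAG ids (see [ani_matrix()]).
#' @param min_ani Rule (i) threshold (percent, strict >).
#' @param min_sags Rule (ii) minimum group size.
#' @param min_cov Rule (iii) minimum per-position fragment coverage.
#' @param join_identity Identity for accepting gap-closing joins (%).
#' @param min_place_len Minimum aligned length to accept a placement (bp).
#' @param k,band Aligner seeding parameters.
#' @return Object of class `composite_genome`: list with `contigs` (tibble
#'   `contig_id`, `sequence`), `sequence` (concatenation), `coverage`
#'   (integer vector along `sequence`), `masked` (tibble of under-covered
#'   intervals), `placements` (tibble of fragment placements), `joins`,
#'   `reference_sag`, `source_map`.
#' @export
build_composite <- function(sags, ani, min_ani = 99, min_sags = 5,
                            min_cov = 2, join_identity = 99,
                            min_place_len = 100, k = 13, band = 16) {
  if (length(sags) < min_sags) {
    abort(sprintf("composite rule violation: %d SAGs supplied, at least %d required",
                  length(sags), min_sags))
  }
  ids <- names(sags)
  if (is.null(ids)) abort("build_composite: sags must be named")
  m <- ani_to_matrix(ani)
  miss <- setdiff(ids, rownames(m))
  if (length(miss)) abort(paste0("build_composite: ANI missing for ",
                                 paste(miss, collapse = ", ")))
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      v <- m[ids[i], ids[j]]
      if (is.na(v) || v <= min_ani) {
        abort(sprintf(
          "composite rule violation: ANI(%s, %s) = %.2f is not > %g",
          ids[i], ids[j], v, min_ani))
      }
    }
  }
  contig_sets <- lapply(ids, function(s) sag_contigs(sags[[s]], s))
  names(contig_sets) <- ids
  tot <- vapply(contig_sets, function(x) sum(nchar(x)), double(1))
  ref_sag <- ids[which.max(tot)]
  ref <- contig_sets[[ref_sag]]

  # votes per reference contig: 4 x L base counts
  base_i <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  votes <- lapply(ref, function(s) matrix(0L, 4, nchar(s)))
  placements <- list()
  add_votes <- function(rc, from, to, seg, sag_id, contig_id) {
    ch <- strsplit(seg, "")[[1]]
    idx <- base_i[ch]
    ok <- !is.na(idx)
    pos <- seq(from, to)
    mtx <- votes[[rc]]
    mtx[cbind(idx[ok], pos[ok])] <- mtx[cbind(idx[ok], pos[ok])] + 1L
    votes[[rc]] <<- mtx
    placements[[length(placements) + 1]] <<- tibble(
      sag_id = sag_id, contig_id = contig_id, ref_contig = rc,
      ref_start = from, ref_end = to)
  }
  # the reference's own contigs are fragments too
  for (rc in names(ref)) add_votes(rc, 1, nchar(ref[[rc]]), ref[[rc]],
                                   ref_sag, rc)
  for (s in setdiff(ids, ref_sag)) {
    for (cid in names(contig_sets[[s]])) {
      cseq <- contig_sets[[s]][[cid]]
      for (rc in names(ref)) {
        hit <- map_reads(setNames(cseq, cid), ref[[rc]],
                         min_len = min_place_len,
                         min_identity = join_identity, k = k, band = band)
        if (!nrow(hit)) next
        qlen <- hit$qend - hit$qstart
        tlen <- hit$tend - hit$tstart
        if (qlen != tlen) next # indel placements skipped (consensus is gapless)
        seg <- substr(cseq, hit$qstart + 1, hit$qend)
        if (hit$strand == "-") seg <- revcomp(seg)
        add_votes(rc, hit$tstart + 1, hit$tend, seg, s, cid)
      }
    }
  }
  # consensus per reference contig
  contigs <- list(); coverage <- list(); masked <- list()
  for (rc in names(ref)) {
    v <- votes[[rc]]
    cov <- colSums(v)
    refch <- strsplit(ref[[rc]], "")[[1]]
    win <- apply(v, 2, which.max)
    top <- v[cbind(win, seq_along(cov))]
    refv <- v[cbind(ifelse(is.na(base_i[refch]), 1L, base_i[refch]),
                    seq_along(cov))]
    cons <- ifelse(refv >= top, refch, c("A", "C", "G", "T")[win])
    low <- cov < min_cov
    cons[low] <- "N"
    if (any(low)) {
      u <- interval_union(which(low), which(low))
      u$contig_id <- rc
      masked[[length(masked) + 1]] <- u
    }
    contigs[[rc]] <- paste(cons, collapse = "")
    coverage[[rc]] <- cov
  }
  pl <- dplyr::bind_rows(placements)

  # gap-closing joins: a non-reference contig placed near the end of one
  # reference contig and near the start of another
  joins <- list()
  if (length(contigs) > 1) {
    margin <- 50
    span <- pl[pl$sag_id != ref_sag, ]
    for (key in unique(paste(span$sag_id, span$contig_id))) {
      rows <- span[paste(span$sag_id, span$contig_id) == key, ]
      if (nrow(rows) < 2) next
      for (i in seq_len(nrow(rows) - 1)) {
        for (j in seq_len(nrow(rows))[-seq_len(i)]) {
          a <- rows[i, ]; b <- rows[j, ]
          la <- nchar(contigs[[a$ref_contig]])
          if (a$ref_end >= la - margin && b$ref_start <= margin &&
              a$ref_contig != b$ref_contig) {
            joins[[length(joins) + 1]] <- tibble(
              left = a$ref_contig, right = b$ref_contig,
              via_sag = a$sag_id, via_contig = a$contig_id)
          }
        }
      }
    }
  }
  joins <- if (length(joins)) dplyr::bind_rows(joins) else
    tibble(left = character(), right = character(), via_sag = character(),
           via_contig = character())
  # order contigs applying accepted joins (left followed by right)
  order_ids <- names(contigs)
  for (r in seq_len(nrow(joins))) {
    l <- joins$left[r]; rgt <- joins$right[r]
    if (which(order_ids == rgt) == which(order_ids == l) + 1) next
    order_ids <- setdiff(order_ids, rgt)
    at <- which(order_ids == l)
    order_ids <- append(order_ids, rgt, after = at)
  }
  seq_all <- paste(unlist(contigs[order_ids]), collapse = "")
  cov_all <- unlist(coverage[order_ids], use.names = FALSE)
  offs <- cumsum(c(0, head(nchar(unlist(contigs[order_ids])), -1)))
  names(offs) <- order_ids
  masked <- if (length(masked)) {
    mm <- dplyr::bind_rows(masked)
    mm$start <- mm$start + offs[mm$contig_id]
    mm$end <- mm$end + offs[mm$contig_id]
    mm[, c("contig_id", "start", "end")]
  } else tibble(contig_id = character(), start = integer(), end = integer())
  source_map <- tibble(contig_id = order_ids,
                       start = offs[order_ids] + 1,
                       end = offs[order_ids] + nchar(unlist(contigs[order_ids])),
                       sag_id = ref_sag)
  structure(list(contigs = tibble(contig_id = order_ids,
                                  sequence = unlist(contigs[order_ids],
                                                    use.names = FALSE)),
                 sequence = seq_all, coverage = cov_all, masked = masked,
                 placements = pl, joins = joins, reference_sag = ref_sag,
                 source_map = source_map),
            class = "composite_genome")
}

#' @export
print.composite_genome <- function(x, ...) {
  cat(sprintf("<composite_genome: %d contig(s), %s bp, ref %s, %d masked interval(s)>\n",
              nrow(x$contigs), format(nchar(x$sequence), big.mark = ","),
              x$reference_sag, nrow(x$masked)))
  invisible(x)
}

#' Rotate a circular genome to start at a named gene
#'
#' The replicon is rotated so the gene's first base becomes position 1; if
#' the gene lies on the "-" strand the replicon is reverse-complemented
#' first so the gene reads forward. Annotations are re-coordinated; genes
#' that would span the new junction are dropped with a warning.
#'
#' @param genome A `genome_record` with a single circular replicon.
#' @param gene_name Gene to rotate to (matched against `gene_id` and
#'   `product`); must occur exactly once.
#' @return Rotated `genome_record` with attribute `rotation_offset`.
#' @export
rotate_to_gene <- function(genome, gene_name = "dnaA") {
  stopifnot(inherits(genome, "genome_record"))
  if (nrow(genome$replicons) != 1) {
    abort("rotate_to_gene: genome must have a single replicon")
  }
  g <- genome$genes
  hitrows <- which(g$gene_id == gene_name |
                     (!is.na(g$product) & g$product == gene_name))
  if (length(hitrows) == 0) abort(paste0("rotate_to_gene: no ", gene_name,
                                         " annotation"))
  if (length(hitrows) > 1) abort(paste0("rotate_to_gene: multiple ",
                                        gene_name, " annotations"))
  L <- genome$replicons$length[1]
  seq <- genome$replicons$sequence[1]
  tg <- g[hitrows, ]
  if (tg$strand == "-") {
    seq <- revcomp(seq)
    ns <- L - g$end + 1; ne <- L - g$start + 1
    g$start <- ns; g$end <- ne
    g$strand <- ifelse(g$strand == "+", "-", "+")
    tg <- g[hitrows, ]
  }
  off <- tg$start - 1
  if (off > 0) {
    seq <- paste0(substr(seq, off + 1, L), substr(seq, 1, off))
    ns <- ((g$start - 1 - off) %% L) + 1
    ne <- ((g$end - 1 - off) %% L) + 1
    wrap <- ne < ns
    if (any(wrap)) {
      warn(paste0("rotate_to_gene: dropping gene(s) spanning the junction: ",
                  paste(g$gene_id[wrap], collapse = ", ")))
    }
    g$start <- ns; g$end <- ne
    g <- g[!wrap, , drop = FALSE]
  }
  reps <- genome$replicons
  reps$sequence <- seq
  out <- genome_record(genome$genome_id,
                       reps[, c("replicon_id", "sequence", "circular")],
                       g[order(g$start), ])
  attr(out, "rotation_offset") <- off
  out
}
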