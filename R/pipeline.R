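# End-to-end pipeline driver: metrics -> ANI/ranks -> recruitment ->
# pangenome -> divergence/delay fit -> islands (-> composite on request).

write_tsv_prov <- function(df, path, config) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(unlist(x), collapse = ","),
                             character(1)) else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# streamclade %s; seed=%s; config=%s",
                     as.character(utils::packageVersion("streamclade")),
                     config$seed, rlang::hash(unclass(config))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative-ecogenomics pipeline
#'
#' Orchestrates the analysis stages on a set of genomes (and optionally
#' per-sample read sets): streamlining metrics; ANI and rank clustering;
#' metagenomic recruitment with RPKG presence calls and genomospecies
#' distributions; pangenome families and core/accessory counts;
#' core-sequence vs gene-content divergence with the delay-model fit; and
#' flexible-island / tRNA-hallmark detection. Results are returned as a
#' list and, when `out_dir` is given, written as TSVs carrying a
#' provenance comment (version, seed, config hash). Runs are deterministic
#' for a fixed config seed.
#'
#' @param genomes Named list of `genome_record` objects.
#' @param reads Optional named list (by sample id) of read tibbles.
#' @param metagenome_gb Named numeric: metagenome size per sample (Gb).
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for TSV reports.
#' @param min_pangenome_genomes Minimum genomes per genomospecies for the
#'   pangenome stage (forced lower for toy data).
#' @return List with elements `metrics`, `ani`, `ranks`, `recruitment`,
#'   `distribution`, `families`, `core`, `divergence_pairs`, `delay_fit`,
#'   `islands`, `hallmarks`, plus `paths` when `out_dir` is given.
#' @export
run_pipeline <- function(genomes, reads = NULL, metagenome_gb = NULL,
                         config = analysis_config(), out_dir = NULL,
                         min_pangenome_genomes = 2) {
  stopifnot(is.list(genomes), length(genomes) >= 2)
  set.seed(config$seed)
  res <- list()
  paths <- character()

  message("stage 1/6: streamlining metrics")
  res$metrics <- dplyr::bind_rows(lapply(genomes, streamline_report,
                                         config = config))

  message("stage 2/6: ANI and rank clustering")
  res$ani <- ani_matrix(genomes, fragment = config$ani_fragment,
                        min_fragment_identity = config$ani_fragment_identity,
                        min_fragment_coverage = config$ani_fragment_coverage)
  res$ranks <- cluster_ranks(res$ani, genus_thr = config$genus_ani,
                             genomospecies_thr = config$genomospecies_ani,
                             species_thr = config$species_ani)

  if (is.null(reads)) {
    warn("no reads supplied; recruitment stage skipped")
    res$recruitment <- NULL
    res$distribution <- NULL
  } else {
    message("stage 3/6: metagenomic recruitment")
    profs <- list()
    for (smp in names(reads)) {
      rd <- qc_reads(reads[[smp]], min_phred = config$qc_min_phred,
                     min_len = config$qc_min_len)
      gb <- if (!is.null(metagenome_gb)) metagenome_gb[[smp]] else 1
      for (g in names(genomes)) {
        profs[[paste(g, smp, sep = "|")]] <-
          recruit(genomes[[g]], rd,
                  min_identity = config$recruit_identity_abundance,
                  min_len = config$recruit_min_len, metagenome_gb = gb,
                  sample_id = smp)
      }
    }
    res$recruitment <- dplyr::bind_rows(
      lapply(profs, rpkg_presence, rpkg_min = config$rpkg_presence,
             cov_min = config$coverage_presence))
    res$distribution <- genomospecies_distribution(
      profs, res$ranks, rpkg_min = config$rpkg_presence,
      cov_min = config$coverage_presence)
  }

  message("stage 4/6: pangenome")
  gm <- genome_families(genomes, identity = config$ortho_identity,
                        coverage = config$ortho_coverage)
  # genomospecies pangenome units where membership allows, else genomes
  gs_sizes <- table(res$ranks$genomospecies)
  use_gs <- all(gs_sizes >= min_pangenome_genomes) && length(gs_sizes) >= 2
  if (use_gs) {
    units <- lapply(split(res$ranks$genome_id, res$ranks$genomospecies),
                    function(members) {
      prot <- dplyr::bind_rows(lapply(members, function(g) {
        p <- genome_proteins(genomes[[g]])
        tibble(genome_id = g, protein_id = names(p), sequence = unname(p))
      }))
      reps <- dereplicate_proteins(prot, identity = config$derep_identity,
                                   coverage = config$ortho_coverage,
                                   min_genomes = min_pangenome_genomes)
      setNames(reps$sequence, reps$protein_id)
    })
    res$families <- build_families(units, identity = config$ortho_identity,
                                   coverage = config$ortho_coverage)
  } else {
    res$families <- gm$families
  }
  res$core <- core_accessory(res$families)

  message("stage 5/6: divergence and delay-model fit")
  res$divergence_pairs <- NULL; res$delay_fit <- NULL
  div <- tryCatch({
    aln <- core_alignment(genomes, gene_map = gm$gene_map)
    sm <- jc_matrix(aln)
    njt <- nj_tree(sm)
    pa_genomes <- gm$families$pa
    cd <- content_distance(pa_genomes, njt$tree)
    pairs <- cd
    pairs$s <- mapply(function(a, b) sm[a, b], cd$genome_a, cd$genome_b)
    rk <- res$ranks
    cls <- function(a, b) {
      ra <- rk[rk$genome_id == a, ]; rb <- rk[rk$genome_id == b, ]
      if (ra$genomospecies == rb$genomospecies) "within-genomospecies"
      else if (ra$genus == rb$genus) "within-genus"
      else "between-genera"
    }
    pairs$class <- mapply(cls, pairs$genome_a, pairs$genome_b)
    list(pairs = pairs, fit = fit_delay_model(pairs), tree = njt$tree)
  }, error = function(e) {
    warn(paste0("divergence stage skipped: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(div)) {
    res$divergence_pairs <- div$pairs
    res$delay_fit <- div$fit
    res$core_tree <- div$tree
  }

  message("stage 6/6: islands and hallmarks")
  res$islands <- tryCatch(
    find_variable_regions(genomes, gene_map = gm$gene_map,
                          max_jaccard = config$island_max_jaccard),
    error = function(e) {
      warn(paste0("island stage skipped: ", conditionMessage(e)))
      NULL
    })
  res$hallmarks <- dplyr::bind_rows(lapply(names(genomes), function(g) {
    h <- trna_hallmarks(genomes[[g]], min_repeat = config$hallmark_min_repeat,
                        window = config$hallmark_window)
    if (nrow(h)) h$genome_id <- g
    h
  }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, nm) {
      if (is.null(df) || !nrow(df)) return(invisible(NULL))
      paths[[nm]] <<- write_tsv_prov(df, file.path(out_dir,
                                                   paste0(nm, ".tsv")), config)
    }
    wr(res$metrics %>% select(-"paralog_counts"), "metrics")
    wr(res$ani, "ani")
    wr(res$ranks, "ranks")
    wr(res$recruitment, "recruitment")
    wr(res$distribution, "distribution")
    wr(res$core, "core")
    wr(res$divergence_pairs, "divergence_pairs")
    if (!is.null(res$delay_fit)) {
      jsonlite::write_json(glance(res$delay_fit),
                           file.path(out_dir, "delay_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      paths[["delay_fit"]] <- file.path(out_dir, "delay_fit.json")
    }
    if (!is.null(res$islands)) {
      wr(res$islands %>% select(-"cargo_gene_ids", -"cargo_families"),
         "islands")
    }
    wr(res$hallmarks, "hallmarks")
    res$paths <- paths
  }
  res
}
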