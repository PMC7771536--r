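#' Central analysis configuration
#'
#' All thresholds used across the pipeline live here, so that a run can be
#' audited from a single object. Defaults are the conventional cutoffs for
#' this kind of ecogenomic survey: abundance-mode recruitment at 98 percent
#' identity over at least 50 nt, linear-plot recruitment at 70 percent,
#' presence called at RPKG >= 5 with > 70 percent genome coverage, ANIr at
#' an 80 percent identity floor, rank thresholds at 95/90/70 percent ANI
#' (species / genomospecies / genus), pangenome dereplication at 70 percent
#' identity with orthology at 30 percent identity and 75 percent coverage,
#' and composite-genome rules (> 99 percent ANI, at least five SAGs,
#' per-position fragment coverage of at least two).
#'
#' @param ... Named overrides of any default listed below.
#'
#' @return A list of class `streamclade_config`.
#' @export
#' @examples
#' cfg <- analysis_config(rpkg_presence = 10)
#' cfg$rpkg_presence
analysis_config <- function(...) {
  cfg <- list(
    recruit_identity_abundance = 98,
    recruit_identity_linear    = 70,
    recruit_min_len            = 50,
    rpkg_presence              = 5,
    coverage_presence          = 0.70,
    anir_identity              = 80,
    species_ani                = 95,
    genomospecies_ani          = 90,
    genus_ani                  = 70,
    derep_identity             = 70,
    ortho_identity             = 30,
    ortho_coverage             = 0.75,
    composite_ani              = 99,
    composite_min_sags         = 5,
    composite_min_cov          = 2,
    bootstrap_n                = 1000,
    qc_min_phred               = 30,
    qc_min_len                 = 50,
    ani_fragment               = 1020,
    ani_fragment_identity      = 30,
    ani_fragment_coverage      = 0.70,
    paralog_thresholds         = c(90, 70, 50, 30),
    paralog_coverage           = 0.75,
    operon_max_gap             = 30,
    island_max_jaccard         = 0.5,
    hallmark_min_repeat        = 15,
    hallmark_window            = 100000,
    seed                       = 1
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(ov)] <- ov
  pct <- c("recruit_identity_abundance", "recruit_identity_linear",
           "anir_identity", "species_ani", "genomospecies_ani", "genus_ani",
           "derep_identity", "ortho_identity", "composite_ani",
           "ani_fragment_identity")
  for (f in pct) {
    if (cfg[[f]] < 0 || cfg[[f]] > 100) {
      abort(paste0("config field ", f, " must be a percentage in [0, 100]"))
    }
  }
  structure(cfg, class = "streamclade_config")
}

#' @export
print.streamclade_config <- function(x, ...) {
  cat("<streamclade analysis config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
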