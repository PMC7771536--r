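# Synthetic clade simulator. Two generators are provided: a phenomenological
# one that draws (s, g) divergence pairs directly from the recombination-
# delay model, and a mechanistic one that evolves gene-resolved genomes
# along a genus/genomospecies/strain tree with substitutions, gene
# gain/loss, within-genomospecies homologous recombination, and cassette
# insertion at tRNA sites. Every stochastic event is logged and replayable.

#' Simulation parameters
#'
#' Defaults emulate a streamlined marine clade: ~100-kb toy genomes at 32.5
#' percent GC with ~97 percent coding density and few-bp median spacers,
#' ANI strata near 99+ percent within genomospecies, ~80 percent within
#' genus, and below the alignable range between genera, gene turnover at
#' 0.08 events per gene per substitution/site, and strong
#' within-genomospecies recombination.
#'
#' @param n_genera,genomospecies_per_genus,strains_per_genomospecies Clade
#'   shape (all counts >= 1).
#' @param core_genes Number of core CDS genes in the root genome.
#' @param accessory_pool Size of the accessory gene pool gains draw from.
#' @param accessory_init_frac Fraction of `core_genes` added to the root as
#'   initial accessory content.
#' @param mean_gene_len Mean CDS length (bp; rounded to codons).
#' @param target_coding_density Fraction of the genome covered by genes.
#' @param true_turnover_r Gene gain+loss events per gene per
#'   substitution/site (the linear-regime turnover/substitution ratio).
#' @param true_delay_delta Delay (substitutions/site) used by the
#'   phenomenological generator.
#' @param recombination_decay Divergence scale (substitutions/site) of the
#'   per-event recombination success probability `exp(-d/decay)`.
#' @param recomb_attempts Recombination events proposed per terminal branch.
#' @param recomb_tract_genes Genes covered by one recombination tract.
#' @param trna_count Number of tRNA genes.
#' @param gc GC fraction of simulated sequence.
#' @param skew_bias Leading-strand G-over-C bias (replichore signal).
#' @param div_strain,div_genomospecies,div_genus Target pairwise nucleotide
#'   divergence (fraction of sites) within genomospecies (before
#'   recombination), within genus, and between genera.
#' @param third_position_weight Fraction of coding substitutions directed to
#'   third codon positions (purifying-selection emulation, keeps protein
#'   identity above the orthology floor at genus-level divergence).
#' @param seed Integer seed threaded through all simulator draws.
#'
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genera = 2, genomospecies_per_genus = 2,
                       strains_per_genomospecies = 3, core_genes = 150,
                       accessory_pool = 120, accessory_init_frac = 0.2,
                       mean_gene_len = 750, target_coding_density = 0.97,
                       true_turnover_r = 0.08, true_delay_delta = 1,
                       recombination_decay = 0.25, recomb_attempts = 60,
                       recomb_tract_genes = 10, trna_count = 8, gc = 0.325,
                       skew_bias = 0.12, div_strain = 0.12,
                       div_genomospecies = 0.30, div_genus = 0.62,
                       third_position_weight = 0.8, seed = 1) {
  p <- as.list(environment())
  counts <- c("n_genera", "genomospecies_per_genus",
              "strains_per_genomospecies", "core_genes", "accessory_pool",
              "mean_gene_len", "trna_count")
  for (f in counts) {
    if (!is.numeric(p[[f]]) || p[[f]] < 1) {
      abort(paste0("sim_params: ", f, " must be a count >= 1"))
    }
  }
  if (p$true_turnover_r < 0) abort("sim_params: true_turnover_r must be >= 0")
  if (p$true_delay_delta < 0) abort("sim_params: true_delay_delta must be >= 0")
  if (p$target_coding_density > 1 || p$target_coding_density <= 0) {
    abort("sim_params: target_coding_density must be in (0, 1]")
  }
  if (p$div_genus <= p$div_genomospecies || p$div_genomospecies <= p$div_strain) {
    abort("sim_params: need div_genus > div_genomospecies > div_strain")
  }
  structure(p, class = "sim_params")
}

#' Random nucleotide sequence
#' @param length Sequence length (bp).
#' @param gc GC fraction.
#' @param seed Optional integer seed.
#' @return A single character string.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Draw divergence pairs from the recombination-delay model
#'
#' Phenomenological generator: latent true divergence m ~ Uniform(0, m_max);
#' observed core-sequence divergence s = m - delta (1 - exp(-m/delta)) and
#' gene-content divergence g = r m, each multiplied by independent lognormal
#' noise with relative standard deviation `noise_sd_rel`.
#'
#' @param r Turnover-to-substitution ratio (events per gene per subst/site).
#' @param delta Recombination delay (substitutions/site); 0 means s = m.
#' @param n Number of pairs.
#' @param noise_sd_rel Relative sd of the multiplicative lognormal noise.
#' @param m_max Upper bound of the latent divergence.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `pair_id`, `m_true`, `s`, `g`.
#' @export
#' @examples
#' simulate_pair_divergences(0.08, 1, 10, noise_sd_rel = 0, seed = 1)
simulate_pair_divergences <- function(r, delta, n, noise_sd_rel = 0.05,
                                      m_max = 5, seed = 1) {
  if (r < 0 || delta < 0 || noise_sd_rel < 0 || m_max <= 0) {
    abort("simulate_pair_divergences: parameters must be non-negative")
  }
  if (n < 1) abort("simulate_pair_divergences: n must be >= 1")
  set.seed(seed)
  m <- runif(n, 0, m_max)
  s <- delay_model_s(m, delta)
  g <- r * m
  if (noise_sd_rel > 0) {
    sdlog <- sqrt(log(1 + noise_sd_rel^2))
    s <- s * rlnorm(n, -sdlog^2 / 2, sdlog)
    g <- g * rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  tibble(pair_id = seq_len(n), m_true = m, s = s, g = g)
}

#' Expected observed divergence under the delay model
#' @param m True divergence (substitutions/site), vectorised.
#' @param delta Delay parameter (substitutions/site).
#' @return s(m) = m - delta (1 - exp(-m/delta)); s = m when delta = 0.
#' @export
delay_model_s <- function(m, delta) {
  if (delta <= 0) return(m)
  m - delta * (1 - exp(-m / delta))
}

## ---- mechanistic clade simulation -----------------------------------------

# internal gene-table state: tibble(gene_id, family, kind, strand, core,
# spacer (sequence preceding the gene), seq (coding strand))

rand_seq <- function(n, gc, gbias = 0) {
  if (n <= 0) return("")
  pg <- gc / 2 * (1 + gbias); pc <- gc / 2 * (1 - gbias)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, pc, pg, (1 - gc) / 2)), collapse = "")
}

draw_spacer_lens <- function(n, mean_gene_len, density) {
  target_mean <- mean_gene_len * (1 - density) / density
  short <- sample(0:6, n, replace = TRUE,
                  prob = c(1, 2, 3, 3, 2, 1, 1))
  mu_long <- max(1, (target_mean - 0.75 * 2.77) / 0.25)
  long <- rpois(n, mu_long)
  ifelse(runif(n) < 0.75, short, long)
}

root_state <- function(params) {
  p <- params
  n_acc0 <- max(1, round(p$core_genes * p$accessory_init_frac))
  core_len <- pmax(90, round(rnorm(p$core_genes, p$mean_gene_len,
                                   0.25 * p$mean_gene_len) / 3) * 3)
  pool_len <- pmax(90, round(rnorm(p$accessory_pool, p$mean_gene_len,
                                   0.25 * p$mean_gene_len) / 3) * 3)
  pool <- tibble(
    family = sprintf("acc%04d", seq_len(p$accessory_pool)),
    len = pool_len
  )
  pool$seq <- vapply(pool$len, rand_seq, character(1), gc = p$gc)

  genes <- tibble(
    gene_id = sprintf("core%04d", seq_len(p$core_genes)),
    family = sprintf("core%04d", seq_len(p$core_genes)),
    kind = "CDS", core = TRUE, len = core_len
  )
  acc_fam <- sample(pool$family, n_acc0)
  acc <- tibble(gene_id = paste0(acc_fam, "_r"), family = acc_fam,
                kind = "CDS", core = FALSE,
                len = pool$len[match(acc_fam, pool$family)])
  trna <- tibble(gene_id = sprintf("trna%02d", seq_len(p$trna_count)),
                 family = sprintf("trna%02d", seq_len(p$trna_count)),
                 kind = "tRNA", core = TRUE, len = 76L)
  tab <- dplyr::bind_rows(genes, acc, trna)
  tab <- tab[sample(nrow(tab)), ]
  rrna <- tibble(gene_id = c("rrna16S", "rrna23S", "rrna5S"),
                 family = c("rrna16S", "rrna23S", "rrna5S"),
                 kind = "rRNA", core = TRUE, len = c(1200L, 2500L, 111L))
  # ribosomal operon placed just after the terminus (mid-genome)
  half <- which(cumsum(tab$len) >= sum(tab$len) / 2)[1]
  tab <- dplyr::bind_rows(tab[seq_len(half), ], rrna,
                          tab[setdiff(seq_len(nrow(tab)), seq_len(half)), ])
  n <- nrow(tab)
  # operon-like strand runs
  strand <- character(n); i <- 1; cur <- "+"
  while (i <= n) {
    run <- 1 + stats::rgeom(1, 0.22)
    strand[i:min(n, i + run - 1)] <- cur
    cur <- if (cur == "+") "-" else "+"
    i <- i + run
  }
  strand[tab$kind == "rRNA"] <- "+"
  tab$strand <- strand
  sp <- draw_spacer_lens(n, p$mean_gene_len, p$target_coding_density)
  total <- sum(tab$len) + sum(sp)
  # replichore GC-skew bias: leading strand ('+' before terminus) G-rich
  pos <- cumsum(tab$len + sp) - tab$len / 2
  lead <- pos < total / 2
  gb <- ifelse(xor(lead, tab$strand == "-"), p$skew_bias, -p$skew_bias)
  tab$seq <- vapply(seq_len(n), function(i) {
    fam <- tab$family[i]
    j <- match(fam, pool$family)
    if (!is.na(j)) pool$seq[j] else rand_seq(tab$len[i], p$gc, gb[i])
  }, character(1))
  tab$spacer <- vapply(seq_len(n), function(i) rand_seq(sp[i], p$gc),
                       character(1))
  list(genes = tab[, c("gene_id", "family", "kind", "strand", "core",
                       "spacer", "seq")],
       pool = pool)
}

## event application (shared by simulation and replay)

apply_substitutions <- function(state, payload) {
  if (!nrow(payload)) return(state)
  for (gid in unique(payload$gene_id)) {
    rows <- payload[payload$gene_id == gid, ]
    idx <- match(gid, state$genes$gene_id)
    if (is.na(idx)) next
    ch <- strsplit(state$genes$seq[idx], "")[[1]]
    ch[rows$pos] <- rows$to
    state$genes$seq[idx] <- paste(ch, collapse = "")
  }
  state
}

apply_gain <- function(state, payload) {
  g <- state$genes
  at <- if (is.na(payload$after_gene_id)) 0L else
    match(payload$after_gene_id, g$gene_id)
  if (is.na(at)) at <- nrow(g)
  new <- tibble(gene_id = payload$gene_id, family = payload$family,
                kind = "CDS", strand = payload$strand, core = FALSE,
                spacer = payload$spacer, seq = payload$seq)
  state$genes <- dplyr::bind_rows(g[seq_len(at), , drop = FALSE], new,
                                  g[setdiff(seq_len(nrow(g)), seq_len(at)), ,
                                    drop = FALSE])
  state
}

apply_loss <- function(state, payload) {
  state$genes <- state$genes[state$genes$gene_id != payload$gene_id, ,
                             drop = FALSE]
  state
}

apply_recombination <- function(state, payload) {
  idx <- match(payload$gene_id, state$genes$gene_id)
  keep <- !is.na(idx)
  state$genes$seq[idx[keep]] <- payload$seq[keep]
  state
}

## branch evolution with event logging

evolve_branch <- function(state, p_branch, m_branch, branch_id, params,
                          ancestor = NULL, log_env) {
  w3 <- params$third_position_weight
  tab <- state$genes
  # substitutions, third-position weighted for CDS
  pay <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    len <- nchar(tab$seq[i])
    k <- rbinom(1, len, p_branch)
    if (k == 0) next
    if (tab$kind[i] == "CDS") {
      wt <- rep(3 * (1 - w3) / 2, len)
      wt[seq(3, len, by = 3)] <- 3 * w3
    } else wt <- rep(1, len)
    pos <- sample.int(len, k, prob = wt)
    ch <- strsplit(tab$seq[i], "")[[1]]
    from <- ch[pos]
    # replacement base drawn from the genome's stationary composition so
    # GC content does not drift toward 50% with divergence
    base_p <- setNames(c((1 - params$gc) / 2, params$gc / 2, params$gc / 2,
                         (1 - params$gc) / 2), c("A", "C", "G", "T"))
    to <- vapply(from, function(b) {
      alt <- setdiff(c("A", "C", "G", "T"), b)
      sample(alt, 1, prob = base_p[alt])
    }, character(1))
    pay[[i]] <- tibble(gene_id = tab$gene_id[i], pos = pos, from = from,
                       to = to)
  }
  pay <- dplyr::bind_rows(pay)
  if (is.null(pay) || !nrow(pay)) {
    pay <- tibble(gene_id = character(), pos = integer(),
                  from = character(), to = character())
  }
  state <- apply_substitutions(state, pay)
  log_event(log_env, branch_id, "substitution-block", pay)

  # gene gain / loss
  n_ev <- rpois(1, params$true_turnover_r * m_branch * nrow(state$genes))
  for (e in seq_len(n_ev)) {
    if (runif(1) < 0.5) {
      fam <- sample(state$pool$family, 1)
      gid <- sprintf("%s_%s_%d", fam, gsub("[^A-Za-z0-9]", "", branch_id), e)
      after <- if (nrow(state$genes)) sample(state$genes$gene_id, 1) else NA_character_
      payload <- list(gene_id = gid, family = fam,
                      seq = state$pool$seq[match(fam, state$pool$family)],
                      strand = sample(c("+", "-"), 1),
                      spacer = rand_seq(sample(0:6, 1), params$gc),
                      after_gene_id = after)
      state <- apply_gain(state, payload)
      log_event(log_env, branch_id, "gain", payload)
    } else {
      cand <- state$genes$gene_id[!state$genes$core]
      if (!length(cand)) next
      payload <- list(gene_id = sample(cand, 1))
      state <- apply_loss(state, payload)
      log_event(log_env, branch_id, "loss", payload)
    }
  }

  # within-genomospecies recombination homogenizes toward the gs ancestor
  if (!is.null(ancestor)) {
    p_ok <- exp(-m_branch / params$recombination_decay)
    for (e in seq_len(params$recomb_attempts)) {
      if (runif(1) >= p_ok) next
      n <- nrow(state$genes)
      start <- sample.int(n, 1)
      rows <- start:min(n, start + params$recomb_tract_genes - 1)
      gids <- state$genes$gene_id[rows]
      anc_idx <- match(gids, ancestor$genes$gene_id)
      keep <- !is.na(anc_idx)
      if (!any(keep)) next
      payload <- tibble(gene_id = gids[keep],
                        seq = ancestor$genes$seq[anc_idx[keep]])
      state <- apply_recombination(state, payload)
      log_event(log_env, branch_id, "recombination", payload)
    }
  }
  state
}

log_event <- function(env, branch_id, kind, payload) {
  env$events[[length(env$events) + 1]] <-
    list(branch_id = branch_id, kind = kind, payload = payload)
}

state_to_genome <- function(state, genome_id) {
  tab <- state$genes
  fwd <- ifelse(tab$strand == "-", revcomp(tab$seq), tab$seq)
  parts <- as.vector(rbind(tab$spacer, fwd))
  seq <- paste(parts, collapse = "")
  splen <- nchar(tab$spacer); glen <- nchar(tab$seq)
  end <- cumsum(splen + glen)
  start <- end - glen + 1
  genes <- tibble(gene_id = tab$gene_id, replicon_id = "chr",
                  start = as.integer(start), end = as.integer(end),
                  strand = tab$strand, kind = tab$kind, product = tab$family,
                  protein = NA_character_)
  gr <- genome_record(genome_id,
                      tibble(replicon_id = "chr", sequence = seq,
                             circular = TRUE),
                      genes)
  prots <- genome_proteins(gr)
  gr$genes$protein[match(names(prots), gr$genes$gene_id)] <- unname(prots)
  gr
}

# Per-branch substitution fractions chosen so that observed pairwise
# divergence composes exactly to the targets: a substitution round hitting
# a fraction q of sites (new base uniform among the other three) has
# Jukes-Cantor eigenvalue 1 - 4q/3, and eigenvalues multiply along a path.
branch_p <- function(params) {
  lam <- function(p) 1 - 4 * p / 3
  q <- function(l) 0.75 * (1 - l)
  lc <- sqrt(lam(params$div_strain))
  lb <- sqrt(lam(params$div_genomospecies) / lam(params$div_strain))
  la <- sqrt(lam(params$div_genus) / lam(params$div_genomospecies))
  c(genus = q(la), genomospecies = q(lb), strain = q(lc))
}

p_to_m <- function(p) -0.75 * log(1 - 4 * p / 3)

#' Simulate a clade of streamlined genomes
#'
#' Mechanistic generator: a root genome of core and accessory genes evolves
#' along a genus / genomospecies / strain hierarchy by substitutions
#' (third-position weighted in CDS), Poisson gene gain/loss at rate
#' `true_turnover_r` x branch length x gene count, and, on terminal
#' branches, homologous recombination that restores tracts to the
#' genomospecies-ancestor sequence with per-event success probability
#' `exp(-m/recombination_decay)`. Every event is logged; `replay_clade()`
#' reproduces the leaf genomes from the root byte-for-byte.
#'
#' @param params A [sim_params()] object.
#' @return List of class `clade_truth`: `tree` (tibble of branches with true
#'   lengths in substitutions/site), `genomes` (named list of
#'   `genome_record`), `truth` (genome to genus/genomospecies map),
#'   `event_log` (tibble with list payload column), `root_state`, `params`.
#' @export
simulate_clade <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  pr <- branch_p(params)
  m <- p_to_m(pr)
  log_env <- new.env(parent = emptyenv()); log_env$events <- list()
  root <- root_state(params)

  genomes <- list(); truth <- list(); tree_rows <- list()
  for (a in seq_len(params$n_genera)) {
    b1 <- sprintf("root->G%d", a)
    st_gen <- evolve_branch(root, pr["genus"], m["genus"], b1, params,
                            ancestor = NULL, log_env = log_env)
    tree_rows[[b1]] <- tibble(branch_id = b1, parent = "root",
                              child = sprintf("G%d", a), m = m[["genus"]])
    for (b in seq_len(params$genomospecies_per_genus)) {
      b2 <- sprintf("G%d->G%d.%d", a, a, b)
      st_gs <- evolve_branch(st_gen, pr["genomospecies"], m["genomospecies"],
                             b2, params, ancestor = NULL, log_env = log_env)
      tree_rows[[b2]] <- tibble(branch_id = b2, parent = sprintf("G%d", a),
                                child = sprintf("G%d.%d", a, b),
                                m = m[["genomospecies"]])
      for (s in seq_len(params$strains_per_genomospecies)) {
        gid <- sprintf("G%d.%d-%02d", a, b, s)
        b3 <- sprintf("G%d.%d->%s", a, b, gid)
        st_leaf <- evolve_branch(st_gs, pr["strain"] / 2, m[["strain"]] / 2,
                                 b3, params, ancestor = st_gs,
                                 log_env = log_env)
        tree_rows[[b3]] <- tibble(branch_id = b3,
                                  parent = sprintf("G%d.%d", a, b),
                                  child = gid, m = m[["strain"]] / 2)
        genomes[[gid]] <- state_to_genome(st_leaf, gid)
        truth[[gid]] <- tibble(genome_id = gid, genus = sprintf("G%d", a),
                               genomospecies = sprintf("G%d.%d", a, b),
                               strain = s)
      }
    }
  }
  ev <- log_env$events
  event_log <- tibble(
    branch_id = vapply(ev, `[[`, character(1), "branch_id"),
    kind = vapply(ev, `[[`, character(1), "kind"),
    payload = lapply(ev, `[[`, "payload")
  )
  structure(list(tree = dplyr::bind_rows(tree_rows),
                 genomes = genomes, truth = dplyr::bind_rows(truth),
                 event_log = event_log, root_state = root, params = params),
            class = "clade_truth")
}

#' @export
print.clade_truth <- function(x, ...) {
  cat(sprintf("<clade_truth: %d genomes, %d genomospecies, %d events>\n",
              length(x$genomes), length(unique(x$truth$genomospecies)),
              nrow(x$event_log)))
  invisible(x)
}

#' Replay a clade event log
#'
#' Deterministically re-applies the logged events from the root state along
#' the tree; the reconstructed leaves must match `clade$genomes` exactly.
#'
#' @param clade A `clade_truth` object.
#' @return Named list of `genome_record` objects.
#' @export
replay_clade <- function(clade) {
  stopifnot(inherits(clade, "clade_truth"))
  ev_by_branch <- split(seq_len(nrow(clade$event_log)),
                        clade$event_log$branch_id)
  apply_branch <- function(state, branch_id) {
    for (i in ev_by_branch[[branch_id]]) {
      kind <- clade$event_log$kind[i]
      payload <- clade$event_log$payload[[i]]
      state <- switch(kind,
        "substitution-block" = apply_substitutions(state, payload),
        "gain" = apply_gain(state, payload),
        "loss" = apply_loss(state, payload),
        "recombination" = apply_recombination(state, payload),
        abort(paste0("unknown event kind: ", kind)))
    }
    state
  }
  out <- list()
  tr <- clade$tree
  states <- list(root = clade$root_state)
  for (i in seq_len(nrow(tr))) {
    states[[tr$child[i]]] <- apply_branch(states[[tr$parent[i]]],
                                          tr$branch_id[i])
    if (tr$child[i] %in% clade$truth$genome_id) {
      out[[tr$child[i]]] <- state_to_genome(states[[tr$child[i]]],
                                            tr$child[i])
    }
  }
  out
}

#' Simulate metagenomic reads from a genome
#'
#' Uniform start positions on both strands; each base is independently
#' substituted with probability `divergence + error_rate`.
#'
#' @param genome A `genome_record` or single sequence string.
#' @param n_reads Number of reads (0 gives an empty set).
#' @param read_len Read length (bp; must not exceed the replicon length).
#' @param divergence Per-base population divergence from the reference.
#' @param error_rate Per-base sequencing error rate.
#' @param seed Integer seed.
#'
#' @return Tibble with `read_id`, `sequence`, `quality` (uniform Q40),
#'   `replicon_id`, `true_start` (1-based), `true_strand`.
#' @export
simulate_reads <- function(genome, n_reads, read_len = 150, divergence = 0,
                           error_rate = 0, seed = 1) {
  if (n_reads < 0) abort("simulate_reads: n_reads must be >= 0")
  if (inherits(genome, "genome_record")) {
    reps <- genome$replicons
  } else {
    reps <- tibble(replicon_id = "chr", sequence = toupper(genome),
                   length = nchar(genome))
  }
  if (read_len > max(reps$length)) {
    abort("simulate_reads: read_len exceeds replicon length")
  }
  empty <- tibble(read_id = character(), sequence = character(),
                  quality = character(), replicon_id = character(),
                  true_start = integer(), true_strand = character())
  if (n_reads == 0) return(empty)
  set.seed(seed)
  ok <- reps$length >= read_len
  reps <- reps[ok, , drop = FALSE]
  ri <- sample.int(nrow(reps), n_reads, replace = TRUE,
                   prob = reps$length - read_len + 1)
  start <- vapply(ri, function(i) sample.int(reps$length[i] - read_len + 1, 1),
                  integer(1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substr(reps$sequence[ri], start, start + read_len - 1)
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  p <- divergence + error_rate
  if (p > 0) {
    seqs <- vapply(seqs, function(s) {
      k <- rbinom(1, read_len, p)
      if (k == 0) return(s)
      ch <- strsplit(s, "")[[1]]
      pos <- sample.int(read_len, k)
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  tibble(read_id = sprintf("read%06d", seq_len(n_reads)), sequence = seqs,
         quality = strrep("I", read_len), replicon_id = reps$replicon_id[ri],
         true_start = as.integer(start), true_strand = strand)
}

#' Insert a gene cassette 3' of a tRNA, leaving a direct-repeat hallmark
#'
#' The cassette is inserted immediately 3' of the named tRNA on its coding
#' strand, and a copy of the tRNA's 3'-terminal `repeat_len` bases is
#' appended at the cassette's distal end - the tell-tale direct repeat of
#' site-specific integration. Downstream annotations are re-coordinated.
#'
#' @param genome A `genome_record`.
#' @param trna_id Gene id of an annotated tRNA.
#' @param cassette Cassette sequence (coding-strand orientation, may be "").
#' @param cassette_genes Optional tibble of genes on the cassette
#'   (`gene_id`, `start`, `end`, `strand` relative to the cassette).
#' @param repeat_len Length of the duplicated tRNA 3' fragment (<= tRNA
#'   length; 0 suppresses the repeat).
#'
#' @return A new `genome_record`.
#' @export
insert_cassette <- function(genome, trna_id, cassette, cassette_genes = NULL,
                            repeat_len = 20) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes
  i <- match(trna_id, g$gene_id)
  if (is.na(i)) abort(paste0("tRNA not found: ", trna_id))
  if (g$kind[i] != "tRNA") abort(paste0(trna_id, " is not annotated as tRNA"))
  tlen <- g$end[i] - g$start[i] + 1
  if (repeat_len > tlen) abort("repeat_len exceeds tRNA length")
  cassette <- toupper(cassette)
  rep_id <- g$replicon_id[i]
  seq <- replicon_seq(genome, rep_id)
  if (g$strand[i] == "+") {
    rep_seg <- if (repeat_len > 0) substr(seq, g$end[i] - repeat_len + 1,
                                          g$end[i]) else ""
    ins <- paste0(cassette, rep_seg)
    at <- g$end[i] # insert after this position
  } else {
    rep_seg <- if (repeat_len > 0) substr(seq, g$start[i],
                                          g$start[i] + repeat_len - 1) else ""
    ins <- paste0(rep_seg, revcomp(cassette))
    at <- g$start[i] - 1
  }
  if (!nzchar(ins)) return(genome)
  new_seq <- paste0(substr(seq, 1, at), ins,
                    substr(seq, at + 1, nchar(seq)))
  shift <- nchar(ins)
  g2 <- g
  on_rep <- g2$replicon_id == rep_id
  g2$start[on_rep & g2$start > at] <- g2$start[on_rep & g2$start > at] + shift
  g2$end[on_rep & g2$end > at] <- g2$end[on_rep & g2$end > at] + shift
  if (!is.null(cassette_genes) && nrow(cassette_genes)) {
    cg <- tibble::as_tibble(cassette_genes)
    clen <- nchar(cassette)
    if (g$strand[i] == "+") {
      cs <- at + cg$start; ce <- at + cg$end; cstr <- cg$strand
    } else {
      cs <- at + repeat_len + (clen - cg$end) + 1
      ce <- at + repeat_len + (clen - cg$start) + 1
      cstr <- ifelse(cg$strand == "+", "-", "+")
    }
    add <- tibble(gene_id = cg$gene_id, replicon_id = rep_id,
                  start = as.integer(cs), end = as.integer(ce), strand = cstr,
                  kind = if ("kind" %in% names(cg)) cg$kind else "CDS",
                  product = if ("product" %in% names(cg)) cg$product else
                    NA_character_,
                  protein = NA_character_)
    g2 <- dplyr::bind_rows(g2, add)
    g2 <- g2[order(g2$replicon_id, g2$start), ]
  }
  reps <- genome$replicons
  reps$sequence[reps$replicon_id == rep_id] <- new_seq
  genome_record(genome$genome_id, reps[, c("replicon_id", "sequence",
                                           "circular")], g2)
}
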