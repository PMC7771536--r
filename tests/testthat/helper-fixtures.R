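# Shared fixtures and independent oracles. Expensive simulated objects are
# built once per test run and cached.

rseq <- function(n, gc = 0.5, seed = NULL) random_genome(n, gc, seed)

# substitute exactly n_sub positions (or the given positions) of a sequence
mutate_seq <- function(s, n_sub = NULL, positions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  if (is.null(positions)) positions <- sample(length(ch), n_sub)
  ch[positions] <- vapply(ch[positions], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

# independent full-DP local alignment oracle (Biostrings; same scoring:
# match +1, mismatch -1, linear gap -2)
sw_oracle <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  cols <- nchar(ap)
  m <- sum(strsplit(ap, "")[[1]] == strsplit(as_, "")[[1]] &
             strsplit(ap, "")[[1]] != "-")
  list(score = Biostrings::score(pa), matches = m, columns = cols,
       identity = 100 * m / cols)
}

# exhaustive Fitch oracle: minimum changes over all internal 0/1 labelings
fitch_oracle <- function(states, tree) {
  nt <- length(tree$tip.label)
  nint <- tree$Nnode
  E <- tree$edge
  lab <- integer(nt + nint)
  lab[seq_len(nt)] <- as.integer(states[tree$tip.label] > 0)
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab[nt + seq_len(nint)] <- bitwAnd(bitwShiftR(mask, 0:(nint - 1)), 1L)
    best <- min(best, sum(lab[E[, 1]] != lab[E[, 2]]))
  }
  best
}

# small cached clades (shared across test files)
tiny_clade <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_clade(sim_params(
        n_genera = 1, genomospecies_per_genus = 1,
        strains_per_genomospecies = 3, core_genes = 30, accessory_pool = 15,
        trna_count = 3, seed = 101))
    }
    cache
  }
})

small_clade <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_clade(sim_params(
        core_genes = 25, accessory_pool = 15, trna_count = 2,
        strains_per_genomospecies = 2, seed = 31))
    }
    cache
  }
})

# SAG contig subsets of a known truth genome (for composite tests)
make_sag_set <- function(truth, n_sags = 6, pieces = 10, keep = 7,
                         seed = 1) {
  set.seed(seed)
  L <- nchar(truth)
  out <- list()
  for (s in seq_len(n_sags)) {
    cuts <- sort(sample(seq(200, L - 200), pieces - 1))
    bounds <- cbind(c(1, cuts + 1), c(cuts, L))
    sel <- sort(sample(pieces, keep))
    out[[sprintf("SAG%d", s)]] <- setNames(
      substring(truth, bounds[sel, 1], bounds[sel, 2]),
      sprintf("s%d_c%02d", s, sel))
  }
  out
}

full_ani_matrix <- function(ids, value = 100) {
  matrix(value, length(ids), length(ids), dimnames = list(ids, ids))
}

# partition agreement: inferred labels map one-to-one onto true labels
same_partition <- function(a, b) {
  t <- table(a, b)
  all(rowSums(t > 0) == 1) && all(colSums(t > 0) == 1)
}
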