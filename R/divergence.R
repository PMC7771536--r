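# Core-gene sequence divergence, neighbor-joining trees with bootstrap,
# gene-content distances from per-branch Fitch gain/loss events, and the
# nonlinear least-squares fit of the recombination-driven delay model:
# latent true divergence m with observed core-sequence divergence
# s(m) = m - delta (1 - exp(-m/delta)) and gene-content divergence
# g(m) = r m.

#' Jukes-Cantor distance between two aligned sequences
#'
#' Columns containing gaps or N in either sequence are excluded. The
#' distance is -(3/4) ln(1 - (4/3) p) with p the mismatch fraction;
#' p >= 0.75 is saturated and raises an error.
#'
#' @param a,b Aligned sequences of equal length.
#' @return Substitutions per site.
#' @export
#' @examples
#' jc_distance("ACGTACGTAC", "ACGTACGTAC")
jc_distance <- function(a, b) {
  a <- check_seq(a, "a"); b <- check_seq(b, "b")
  if (nchar(a) != nchar(b)) abort("jc_distance: sequences must align (equal length)")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- !(av %in% c("-", "N")) & !(bv %in% c("-", "N"))
  if (!any(ok)) abort("jc_distance: zero comparable columns")
  p <- mean(av[ok] != bv[ok])
  if (p >= 0.75) abort("jc_distance: saturated (p >= 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distance matrix
#'
#' @param alignment Named character vector of aligned sequences.
#' @return Symmetric numeric matrix (substitutions/site).
#' @export
jc_matrix <- function(alignment) {
  n <- length(alignment)
  if (is.null(names(alignment))) names(alignment) <- paste0("t", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jc_distance(alignment[[i]], alignment[[j]])
    }
  }
  m
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Standard NJ agglomeration on a symmetric distance matrix. When an
#' alignment is supplied, bootstrap pseudo-replicates resample alignment
#' columns, rebuild the JC distance matrix and the NJ tree, and internal
#' nodes are annotated with the proportion of replicates supporting each
#' bipartition.
#'
#' @param d Symmetric distance matrix (>= 3 taxa).
#' @param alignment Optional named character vector (for bootstraps).
#' @param bootstraps Number of bootstrap replicates (0 = none).
#' @param seed Integer seed for resampling.
#' @return List with `tree` (ape `phylo`) and `support` (numeric vector of
#'   per-internal-node support proportions, or NULL).
#' @export
nj_tree <- function(d, alignment = NULL, bootstraps = 0, seed = 1) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (!isSymmetric(unname(d))) abort("nj_tree: distance matrix must be symmetric")
  if (nrow(d) < 3) abort("nj_tree: need >= 3 taxa")
  tree <- ape::nj(as.dist(d))
  support <- NULL
  if (bootstraps > 0 && !is.null(alignment)) {
    set.seed(seed)
    len <- nchar(alignment[[1]])
    mats <- vector("list", bootstraps)
    chars <- lapply(alignment, function(s) strsplit(s, "")[[1]])
    reps <- list()
    for (b in seq_len(bootstraps)) {
      idx <- sample.int(len, len, replace = TRUE)
      res <- vapply(chars, function(ch) paste(ch[idx], collapse = ""),
                    character(1))
      mb <- tryCatch(jc_matrix(res), error = function(e) NULL)
      if (is.null(mb)) next
      reps[[length(reps) + 1]] <- ape::nj(as.dist(mb))
    }
    if (length(reps)) {
      counts <- ape::prop.clades(tree, reps, rooted = FALSE)
      counts[is.na(counts)] <- 0
      support <- counts / length(reps)
      tree$node.label <- format(round(support, 3))
    }
  }
  list(tree = tree, support = support)
}

#' Concatenated core-gene alignment
#'
#' Star alignment per single-copy universal family: members are placed in
#' the frame of the longest member by their best local alignment offset,
#' end-padded with gaps; columns with more than 90 percent gaps are
#' dropped; family blocks are concatenated.
#'
#' @param genomes Named list of `genome_record` objects.
#' @param gene_map Tibble (`genome_id`, `gene_id`, `family_id`) from
#'   [genome_families()]; computed if missing.
#' @param max_gap_col_frac Drop columns with more than this gap fraction.
#' @return Named character vector of aligned concatenates (one per genome),
#'   with attribute `n_families`.
#' @export
core_alignment <- function(genomes, gene_map = NULL, max_gap_col_frac = 0.9) {
  ids <- names(genomes)
  if (is.null(gene_map)) gene_map <- genome_families(genomes)$gene_map
  tab <- gene_map %>%
    group_by(.data$family_id) %>%
    mutate(n_genomes = length(unique(.data$genome_id)),
           n_copies = n()) %>%
    ungroup()
  core <- tab %>%
    filter(.data$n_genomes == length(ids),
           .data$n_copies == length(ids))
  fams <- unique(core$family_id)
  if (!length(fams)) abort("core_alignment: no single-copy universal families")
  parts <- setNames(vector("list", length(ids)), ids)
  for (f in fams) {
    rows <- core[core$family_id == f, ]
    seqs <- setNames(vapply(seq_len(nrow(rows)), function(i) {
      gene_seqs(genomes[[rows$genome_id[i]]], rows$gene_id[i])
    }, character(1)), rows$genome_id)
    ref <- seqs[[which.max(nchar(seqs))]]
    lref <- nchar(ref)
    block <- vapply(ids, function(g) {
      s <- seqs[[g]]
      if (nchar(s) == lref) return(s)
      hit <- .cpp_sw_pair(toupper(s), toupper(ref))
      if (!hit$found) return(strrep("-", lref))
      off <- hit$tstart - hit$qstart # position of s[1] in ref frame
      out <- rep("-", lref)
      sv <- strsplit(s, "")[[1]]
      idx <- seq_along(sv) + off
      keep <- idx >= 1 & idx <= lref
      out[idx[keep]] <- sv[keep]
      paste(out, collapse = "")
    }, character(1))
    # drop gap-heavy columns
    mat <- do.call(rbind, strsplit(block, ""))
    gapfrac <- colMeans(mat == "-")
    mat <- mat[, gapfrac <= max_gap_col_frac, drop = FALSE]
    for (g in ids) {
      parts[[g]] <- c(parts[[g]], paste(mat[match(g, ids), ], collapse = ""))
    }
  }
  out <- vapply(parts, paste, character(1), collapse = "")
  attr(out, "n_families") <- length(fams)
  out
}

## ---- Fitch parsimony on a guide tree --------------------------------------

# Per-family Fitch parsimony with a deterministic most-parsimonious
# reconstruction (down-pass sets; top-down pass keeps the parent state when
# allowed, preferring absence otherwise). Returns total changes and the
# change indicator per edge.
fitch_family_events <- function(states, tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  E <- post$edge
  # down-pass: bit1 = state 0 (absent), bit2 = state 1 (present)
  mask <- integer(ntip + nnode)
  mask[seq_len(ntip)] <- ifelse(states[tree$tip.label] > 0, 2L, 1L)
  children <- split(E[, 2], E[, 1])
  ord <- unique(E[, 1]) # postorder parent appearance
  for (p in ord) {
    ms <- mask[children[[as.character(p)]]]
    inter <- Reduce(bitwAnd, ms)
    mask[p] <- if (inter > 0L) inter else Reduce(bitwOr, ms)
  }
  root <- ntip + 1L
  state <- integer(ntip + nnode)
  state[root] <- if (bitwAnd(mask[root], 1L) > 0L) 0L else 1L
  pre <- E[nrow(E):1, , drop = FALSE] # preorder
  changes <- setNames(integer(nrow(tree$edge)), NULL)
  eid <- function(p, ch) which(tree$edge[, 1] == p & tree$edge[, 2] == ch)
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    pbit <- bitwShiftL(1L, state[p])
    if (bitwAnd(mask[ch], pbit) > 0L) {
      state[ch] <- state[p]
    } else {
      state[ch] <- if (bitwAnd(mask[ch], 1L) > 0L) 0L else 1L
      changes[eid(p, ch)] <- changes[eid(p, ch)] + 1L
    }
  }
  list(score = sum(changes), edge_changes = changes,
       node_states = state)
}

#' Gene-content distances from Fitch gain/loss events
#'
#' Each family's presence/absence pattern is mapped onto the guide tree by
#' Fitch parsimony with a deterministic most-parsimonious reconstruction;
#' per-branch events are summed over families, and the leaf-to-leaf
#' gene-content divergence g is the path sum of events divided by
#' `mean_genome_families` (the mean family count per unit), giving expected
#' gains+losses per gene.
#'
#' @param pa Binary matrix (family x unit) or `ortholog_families` object.
#' @param guide_tree ape `phylo` whose tip labels match the matrix columns.
#' @param mean_genome_families Normalising family count; defaults to the
#'   mean per-unit family count of `pa`.
#' @return Tibble: `genome_a`, `genome_b`, `events`, `g`.
#' @export
content_distance <- function(pa, guide_tree,
                             mean_genome_families = NULL) {
  if (inherits(pa, "ortholog_families")) pa <- pa$pa
  pa <- (pa > 0) + 0L
  if (!setequal(colnames(pa), guide_tree$tip.label)) {
    abort("content_distance: matrix units and tree tips do not match")
  }
  if (is.null(mean_genome_families)) mean_genome_families <- mean(colSums(pa))
  edge_total <- numeric(nrow(guide_tree$edge))
  for (f in seq_len(nrow(pa))) {
    res <- fitch_family_events(pa[f, ], guide_tree)
    edge_total <- edge_total + res$edge_changes
  }
  t2 <- guide_tree
  t2$edge.length <- edge_total
  dm <- cophenetic(t2)
  ids <- sort(rownames(dm))
  out <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      out[[length(out) + 1]] <- tibble(
        genome_a = ids[i], genome_b = ids[j],
        events = dm[ids[i], ids[j]],
        g = dm[ids[i], ids[j]] / mean_genome_families)
    }
  }
  dplyr::bind_rows(out)
}

## ---- recombination-delay model fit ----------------------------------------

# invert s(m) = m - delta (1 - exp(-m/delta)) for m >= 0 (monotone)
invert_delay_s <- function(s, delta, iter = 200, tol = 1e-13) {
  if (delta <= 1e-12) return(s)
  m <- s + delta * (1 - exp(-(s / delta + 1)))
  m <- pmax(m, s)
  for (i in seq_len(iter)) {
    f <- m - delta * (1 - exp(-m / delta)) - s
    fp <- pmax(1 - exp(-m / delta), 1e-14)
    step <- f / fp
    m <- pmax(m - step, s)
    if (max(abs(step)) < tol) break
  }
  m
}

delay_ss <- function(delta, s, g, objective = "log") {
  m <- invert_delay_s(s, delta)
  if (objective == "log") {
    # likelihood-consistent under multiplicative (lognormal) noise; pairs
    # with zero g or zero latent divergence carry no log information
    pos <- m > 0 & g > 0
    if (sum(pos) < 3) return(delay_ss(delta, s, g, objective = "linear"))
    lr <- mean(log(g[pos]) - log(m[pos]))
    list(ss = sum((log(g[pos]) - lr - log(m[pos]))^2), r = exp(lr))
  } else {
    den <- sum(m * m)
    r <- if (den > 0) max(0, sum(m * g) / den) else 0
    list(ss = sum((g - r * m)^2), r = r)
  }
}

#' Fit the recombination-driven delay model
#'
#' Fits (r, delta) of the model s(m) = m - delta (1 - exp(-m/delta)),
#' g(m) = r m to observed pairs of core-sequence divergence `s` and
#' gene-content divergence `g`: for each observed s the latent divergence m
#' is recovered by inverting the monotone s(m), and the residual sum of
#' squares in g is minimised. r is profiled out in closed form for each
#' delta; delta is found by a coarse grid followed by golden-section
#' refinement. Because divergence estimates carry multiplicative
#' (relative) noise, residuals are taken on the log scale by default,
#' which is the likelihood-consistent choice and removes the upward bias
#' in delta that absolute residuals show; `objective = "linear"` gives
#' plain least squares in g. Initialisation follows the linear regime:
#' the slope of the upper-quartile-s pairs gives r0 and the extrapolated
#' intercept -r0 delta0 gives delta0.
#'
#' @param pairs Tibble with columns `s` and `g` (e.g. from
#'   [simulate_pair_divergences()] or assembled from [jc_matrix()] and
#'   [content_distance()]).
#' @param objective Residual scale: "log" (default) or "linear".
#' @return Object of class `delay_fit`: list with `r`, `delta`,
#'   `residual_ss`, `n_pairs`, `breakpoint_s` (observed divergence at which
#'   the latent divergence equals the delay), `non_identifiable`, `data`.
#' @export
#' @examples
#' p <- simulate_pair_divergences(0.08, 1, 200, noise_sd_rel = 0, seed = 7)
#' fit <- fit_delay_model(p)
#' glance(fit)
fit_delay_model <- function(pairs, objective = c("log", "linear")) {
  objective <- match.arg(objective)
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("s", "g") %in% names(pairs))) {
    abort("fit_delay_model: pairs need columns s and g")
  }
  s <- pairs$s; g <- pairs$g
  if (any(!is.finite(s)) || any(!is.finite(g)) || any(s < 0) || any(g < 0)) {
    abort("fit_delay_model: s and g must be finite and non-negative")
  }
  n <- length(s)
  if (n < 10) warn("fit_delay_model: fewer than 10 pairs; fit may not span both regimes")
  if (max(s) < 1e-8) {
    fit <- structure(list(r = NA_real_, delta = NA_real_,
                          residual_ss = NA_real_, n_pairs = n,
                          breakpoint_s = NA_real_, non_identifiable = TRUE,
                          data = pairs), class = "delay_fit")
    return(fit)
  }
  # linear-regime initialisation
  hi <- s >= quantile(s, 0.75)
  r0 <- if (sum(hi) >= 2 && sd(s[hi]) > 0) {
    cf <- coef(lm(g[hi] ~ s[hi]))
    c(r = unname(cf[2]), d = unname(max(0.01, cf[1] / max(cf[2], 1e-12))))
  } else c(r = max(g) / max(s), d = 0.01)
  delta_hi <- max(5 * r0["d"], 2 * max(s), 1)
  grid <- c(1e-8, seq(delta_hi / 40, delta_hi, length.out = 40), r0["d"])
  ssv <- vapply(grid, function(d) delay_ss(d, s, g, objective)$ss,
                double(1))
  b <- which.min(ssv)
  lo <- if (b > 1) grid[b - 1] else 1e-10
  up <- if (b < length(grid)) grid[b + 1] else delta_hi * 2
  opt <- optimize(function(d) delay_ss(d, s, g, objective)$ss,
                  c(lo, up), tol = 1e-10)
  cand <- rbind(c(opt$minimum, opt$objective), c(grid[b], ssv[b]))
  best <- cand[which.min(cand[, 2]), ]
  delta <- unname(best[1])
  res <- delay_ss(delta, s, g, objective)
  structure(list(r = res$r, delta = delta, residual_ss = res$ss,
                 n_pairs = n, breakpoint_s = delay_model_s(delta, delta),
                 non_identifiable = FALSE, objective = objective,
                 data = pairs),
            class = "delay_fit")
}

#' @export
print.delay_fit <- function(x, ...) {
  cat("<delay_fit: recombination-driven delay model>\n")
  if (isTRUE(x$non_identifiable)) {
    cat("  non-identifiable (all s ~ 0)\n")
  } else {
    cat(sprintf("  r     = %.4f events/gene per subst/site\n", x$r))
    cat(sprintf("  delta = %.4f substitutions/site\n", x$delta))
    cat(sprintf("  residual SS = %.3e over %d pairs\n", x$residual_ss,
                x$n_pairs))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.delay_fit <- function(x, ...) {
  tibble(term = c("r", "delta"), estimate = c(x$r, x$delta),
         units = c("events/gene per subst/site", "substitutions/site"))
}

#' @export
glance.delay_fit <- function(x, ...) {
  tibble(r = x$r, delta = x$delta, residual_ss = x$residual_ss,
         n_pairs = x$n_pairs, breakpoint_s = x$breakpoint_s,
         non_identifiable = x$non_identifiable)
}

#' Predict gene-content divergence from observed sequence divergence
#' @param object A `delay_fit`.
#' @param s Observed core-sequence divergences.
#' @param ... Unused.
#' @return Predicted g values.
#' @export
predict.delay_fit <- function(object, s, ...) {
  if (isTRUE(object$non_identifiable)) abort("fit is non-identifiable")
  object$r * invert_delay_s(s, object$delta)
}
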