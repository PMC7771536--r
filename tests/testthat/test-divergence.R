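# Jukes-Cantor distances, NJ trees, Fitch gene-content distances, and the
# recombination-delay model fit.

test_that("jc_distance matches the closed form and flags saturation", {
  a <- rseq(1000, seed = 1)
  expect_equal(jc_distance(a, a), 0)
  b <- mutate_seq(a, positions = 1:100, seed = 2) # p = 0.1 exactly
  expect_equal(jc_distance(a, b), 0.107326, tolerance = 1e-5)
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  b75 <- mutate_seq(a, positions = 1:750, seed = 3)
  expect_error(jc_distance(a, b75), "saturated")
  # gap/N columns are excluded
  a2 <- paste0("--NN", substr(a, 5, 1000))
  b2 <- paste0("ACGT", substr(b, 5, 1000))
  expect_equal(jc_distance(a2, b2),
               jc_distance(substr(a, 5, 1000), substr(b, 5, 1000)))
  expect_error(jc_distance("----", "ACGT"), "zero comparable")
  expect_error(jc_distance(a, substr(a, 1, 10)), "equal length")
})

test_that("nj_tree reproduces the three-point formula and additive metrics", {
  d <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)$tree
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.05)
  expect_equal(bl[["B"]], 0.15)
  expect_equal(bl[["C"]], 0.25)
  # identical rows: zero-length cherry
  d2 <- matrix(c(0, 0, 0.3, 0, 0, 0.3, 0.3, 0.3, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr2 <- nj_tree(d2)$tree
  bl2 <- setNames(tr2$edge.length, tr2$tip.label[tr2$edge[, 2]])
  expect_equal(bl2[["A"]], 0, tolerance = 1e-12)
  expect_equal(bl2[["B"]], 0, tolerance = 1e-12)
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  # additive six-taxon matrices are recovered exactly
  set.seed(5)
  for (i in 1:10) {
    tt <- ape::rtree(6)
    tt$edge.length <- runif(nrow(tt$edge), 0.05, 0.5)
    dm <- cophenetic(tt)
    njt <- nj_tree(dm)$tree
    expect_equal(ape::dist.topo(ape::unroot(tt), njt), 0,
                 ignore_attr = TRUE)
    expect_equal(cophenetic(njt)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
})

test_that("bootstrap support is high for a well-separated split", {
  set.seed(9)
  base <- rseq(600)
  grpA <- c(t1 = base, t2 = mutate_seq(base, 5, seed = 1))
  far <- mutate_seq(base, 200, seed = 2)
  grpB <- c(t3 = far, t4 = mutate_seq(far, 5, seed = 3))
  aln <- c(grpA, grpB)
  res <- nj_tree(jc_matrix(aln), alignment = aln, bootstraps = 100, seed = 4)
  expect_false(is.null(res$support))
  expect_gte(max(res$support, na.rm = TRUE), 0.95)
})

test_that("Fitch per-branch events match forced cases and the exhaustive oracle", {
  fe <- streamclade:::fitch_family_events
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  # family private to one leaf: exactly one event on its pendant branch
  st <- c(A = 1, B = 0, C = 0, D = 0)
  res <- fe(st, tr)
  expect_equal(res$score, 1L)
  pend_A <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  expect_equal(unname(res$edge_changes[pend_A]), 1L)
  # identical content: zero events
  expect_equal(fe(c(A = 1, B = 1, C = 1, D = 1), tr)$score, 0L)
  # random matrices vs exhaustive enumeration (up to 6 leaves)
  set.seed(13)
  for (i in 1:150) {
    n <- sample(4:6, 1)
    tree <- ape::rtree(n)
    states <- setNames(rbinom(n, 1, 0.5), tree$tip.label)
    expect_equal(fe(states, tree)$score, fitch_oracle(states, tree))
  }
})

test_that("Fitch totals agree with phangorn as an independent cross-check", {
  skip_if_not_installed("phangorn")
  fe <- streamclade:::fitch_family_events
  set.seed(17)
  for (i in 1:20) {
    tree <- ape::rtree(7)
    states <- setNames(rbinom(7, 1, 0.5), tree$tip.label)
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(fe(states, tree)$score,
                 as.integer(phangorn::fitch(tree, pd)))
  }
})

test_that("content_distance sums per-branch events along paths", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  pa <- rbind(f1 = c(A = 1, B = 1, C = 1, D = 1),
              f2 = c(A = 1, B = 0, C = 0, D = 0),
              f3 = c(A = 1, B = 1, C = 0, D = 0))
  cd <- content_distance(pa, tr, mean_genome_families = 1)
  g_of <- function(x, y) cd$g[cd$genome_a == min(x, y) & cd$genome_b == max(x, y)]
  expect_equal(g_of("A", "B"), 1) # f2 pendant event
  expect_equal(g_of("C", "D"), 0)
  expect_equal(g_of("A", "C"), 2) # f2 + f3
  # identical contents: all zero
  pa0 <- rbind(f1 = c(A = 1, B = 1, C = 1, D = 1))
  expect_true(all(content_distance(pa0, tr, 1)$g == 0))
})

test_that("delay-model fit recovers parameters", {
  # noiseless data: exact recovery, residual at optimiser tolerance
  p <- simulate_pair_divergences(0.08, 1, 200, noise_sd_rel = 0, seed = 3)
  f <- fit_delay_model(p)
  expect_equal(f$r, 0.08, tolerance = 1e-5)
  expect_equal(f$delta, 1, tolerance = 1e-4)
  expect_lt(f$residual_ss, 1e-8)
  # no-delay limit
  p0 <- simulate_pair_divergences(0.08, 0, 200, noise_sd_rel = 0, seed = 3)
  f0 <- fit_delay_model(p0)
  expect_equal(f0$r, 0.08, tolerance = 1e-6)
  expect_lt(f0$delta, 1e-3)
  # 5% noise, 500 pairs: median recovery over a few replicates within the
  # published-scale bounds
  reps <- vapply(1:5, function(i) {
    fi <- fit_delay_model(simulate_pair_divergences(0.08, 1, 500,
                                                    noise_sd_rel = 0.05,
                                                    seed = 400 + i))
    c(fi$r, fi$delta)
  }, double(2))
  expect_gte(median(reps[1, ]), 0.072)
  expect_lte(median(reps[1, ]), 0.088)
  expect_gte(median(reps[2, ]), 0.8)
  expect_lte(median(reps[2, ]), 1.2)
  # the high-turnover regime reported for larger-genome marine bacteria
  f5 <- fit_delay_model(simulate_pair_divergences(0.5, 1, 500,
                                                  noise_sd_rel = 0.05,
                                                  seed = 5))
  expect_equal(f5$r, 0.5, tolerance = 0.05)
  # degenerate data
  dg <- tibble::tibble(s = rep(0, 20), g = runif(20))
  expect_true(fit_delay_model(dg)$non_identifiable)
  expect_warning(fit_delay_model(tibble::tibble(s = c(0.1, 1), g = c(0.1, 0.2))),
                 "fewer than 10")
})

test_that("delay_fit methods expose tidy summaries and predictions", {
  p <- simulate_pair_divergences(0.08, 1, 300, noise_sd_rel = 0.05, seed = 8)
  f <- fit_delay_model(p)
  td <- tidy(f)
  expect_equal(td$term, c("r", "delta"))
  gl <- glance(f)
  expect_equal(gl$n_pairs, 300L)
  expect_gt(gl$breakpoint_s, 0)
  # prediction passes through the origin and is monotone
  pr <- predict(f, c(0, 0.5, 1, 2))
  expect_equal(pr[1], 0)
  expect_true(all(diff(pr) > 0))
  pl <- autoplot(f)
  expect_s3_class(pl, "ggplot")
})
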