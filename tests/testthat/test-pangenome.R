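# Protein dereplication, ortholog families, core/accessory partitioning.

raa <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, TRUE),
        collapse = "")
}

mut_aa <- function(s, n_sub, seed) {
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  i <- sample(length(ch), n_sub)
  repl <- vapply(ch[i], function(x) {
    sample(setdiff(c("A", "C", "D", "E", "F", "G"), x), 1)
  }, character(1))
  ch[i] <- repl
  paste(ch, collapse = "")
}

test_that("dereplication follows the at-least-five-genomes rule", {
  base <- raa(200, 1)
  prot <- tibble::tibble(genome_id = rep(paste0("g", 1:3), each = 2),
                         protein_id = paste0("p", 1:6),
                         sequence = rep(c(base, raa(180, 2)), 3))
  expect_error(dereplicate_proteins(prot), "at least 5")
  reps <- dereplicate_proteins(prot, force = TRUE)
  expect_equal(nrow(reps), 2)
})

test_that("dereplication collapses identical proteomes and keeps disjoint ones", {
  proteome <- setNames(vapply(1:8, function(i) raa(150 + 10 * i, i),
                              character(1)), paste0("f", 1:8))
  five <- dplyr::bind_rows(lapply(1:5, function(g) {
    tibble::tibble(genome_id = paste0("g", g),
                   protein_id = paste0("g", g, "_", names(proteome)),
                   sequence = unname(proteome))
  }))
  reps <- dereplicate_proteins(five)
  expect_equal(nrow(reps), 8)
  expect_true(all(reps$n_members == 5))
  # disjoint proteomes: representative set is the union
  disj <- dplyr::bind_rows(lapply(1:5, function(g) {
    tibble::tibble(genome_id = paste0("g", g),
                   protein_id = paste0("g", g, "_p"),
                   sequence = raa(200, 100 + g))
  }))
  expect_equal(nrow(dereplicate_proteins(disj)), 5)
})

test_that("greedy clustering agrees with a brute-force oracle", {
  set.seed(4)
  # three families at ~85% internal identity + singletons
  fams <- lapply(1:3, function(f) {
    base <- raa(180, 200 + f)
    c(base, mut_aa(base, 27, f), mut_aa(base, 27, f + 50))
  })
  seqs <- c(unlist(fams), raa(180, 300), raa(180, 301))
  names(seqs) <- paste0("p", seq_along(seqs))
  prot <- tibble::tibble(genome_id = rep(paste0("g", 1:5),
                                         length.out = length(seqs)),
                         protein_id = names(seqs), sequence = unname(seqs))
  reps <- dereplicate_proteins(prot, identity = 70, force = TRUE)
  # oracle: single-linkage components from all-vs-all Hamming identity
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    id <- 100 * mean(strsplit(seqs[i], "")[[1]] == strsplit(seqs[j], "")[[1]])
    adj[i, j] <- adj[j, i] <- id >= 70
  }
  comp <- rep(0L, n); cur <- 0L
  for (i in 1:n) if (comp[i] == 0L) {
    cur <- cur + 1L; stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] == 0L) { comp[v] <- cur; stack <- c(stack, which(adj[v, ])) }
    }
  }
  expect_equal(nrow(reps), length(unique(comp)))
})

test_that("ortholog families honour identity floors and partition proteins", {
  u1 <- setNames(vapply(1:6, function(i) raa(150, i), character(1)),
                 paste0("a", 1:6))
  # identical units: every family is core
  fam <- build_families(list(u1 = u1, u2 = setNames(u1, paste0("b", 1:6))))
  expect_equal(core_accessory(fam)$n_core, 6L)
  expect_equal(core_accessory(fam)$core_fraction_of_avg_genome, 1)
  # each protein in exactly one family
  expect_equal(nrow(fam$families), 12)
  expect_equal(anyDuplicated(paste(fam$families$unit,
                                   fam$families$protein_id)), 0)
  # three units sharing exactly one family
  shared <- raa(200, 99)
  units <- lapply(1:3, function(g) {
    setNames(c(shared, raa(170, 10 * g), raa(170, 10 * g + 1)),
             paste0("u", g, "_", 1:3))
  })
  names(units) <- paste0("unit", 1:3)
  fam3 <- build_families(units)
  ca <- core_accessory(fam3)
  expect_equal(ca$n_core, 1L)
  expect_equal(ca$n_families_total, 7L)
  expect_error(build_families(list(a = u1)), ">= 2 units")
})

test_that("families match simulator gene ancestry above the identity floor", {
  cl <- small_clade()
  gm <- genome_families(cl$genomes)
  # map each gene to its true family (the simulator's product field)
  truth <- dplyr::bind_rows(lapply(cl$genomes, function(g) {
    tibble::tibble(genome_id = g$genome_id,
                   gene_id = g$genes$gene_id[g$genes$kind == "CDS"],
                   true_family = g$genes$product[g$genes$kind == "CDS"])
  }))
  j <- dplyr::left_join(gm$gene_map, truth, by = c("genome_id", "gene_id"))
  j <- j[!is.na(j$true_family), ]
  # every inferred family maps to exactly one true family (no chimeras)...
  fam2true <- vapply(split(j$true_family, j$family_id),
                     function(x) length(unique(x)), integer(1))
  expect_true(all(fam2true == 1))
  # ...true families stay together within a genus, where members sit well
  # above the 30% identity floor (deep cross-genus pairs may drop below it
  # and legitimately split)
  g1 <- cl$truth$genome_id[cl$truth$genus == "G1"]
  jg <- j[j$genome_id %in% g1, ]
  true2fam_g1 <- vapply(split(jg$family_id, jg$true_family),
                        function(x) length(unique(x)), integer(1))
  expect_gte(mean(true2fam_g1 == 1), 0.98)
  # gene pairs that align above the floor always co-cluster
  sc <- asNamespace("streamclade")
  prots <- lapply(cl$genomes, genome_proteins)
  set.seed(99)
  fams <- sample(unique(j$true_family), 10)
  for (f in fams) {
    members <- j[j$true_family == f, ]
    if (nrow(members) < 2) next
    a <- members[1, ]; b <- members[nrow(members), ]
    pid <- sc$.cpp_fit_pair(prots[[a$genome_id]][[a$gene_id]],
                            prots[[b$genome_id]][[b$gene_id]], 16L)
    if (isTRUE(pid$found) && pid$identity >= 33) {
      expect_equal(a$family_id, b$family_id)
    }
  }
})

test_that("core shrinks (weakly) as units are added and matches brute force", {
  set.seed(12)
  pa <- matrix(rbinom(300, 1, 0.7), nrow = 50,
               dimnames = list(paste0("f", 1:50), paste0("u", 1:6)))
  ca <- core_accessory(pa)
  expect_equal(ca$n_core, sum(apply(pa, 1, function(r) all(r == 1))))
  expect_equal(ca$mean_unit_families, mean(colSums(pa)))
  for (k in 2:5) {
    expect_gte(core_accessory(pa[, 1:k])$n_core,
               core_accessory(pa[, 1:(k + 1)])$n_core)
  }
  # degenerate cases
  eye <- diag(3); dimnames(eye) <- list(paste0("f", 1:3), paste0("u", 1:3))
  expect_equal(core_accessory(eye)$n_core, 0L)
  ones <- matrix(1, 10, 500 %/% 50)
  expect_equal(core_accessory(matrix(1, 500, 10))$core_fraction_of_avg_genome,
               1)
})
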