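# Flexible genomic islands from core-anchor synteny and tRNA direct-repeat
# hallmarks.

# two hand-built genomes sharing anchors with swappable cargo between them
build_island_pair <- function(cargo_b_same = FALSE) {
  anchor1 <- rseq(900, seed = 1); anchor2 <- rseq(900, seed = 2)
  anchor3 <- rseq(900, seed = 3)
  cargo_a <- rseq(1200, gc = 0.28, seed = 4)
  cargo_b <- if (cargo_b_same) cargo_a else rseq(1500, gc = 0.28, seed = 5)
  sp <- function(seed) rseq(3, seed = seed)
  mk <- function(id, cargo, cargo_name) {
    seqs <- c(anchor1, cargo, anchor2, anchor3)
    names(seqs) <- c("anc1", cargo_name, "anc2", "anc3")
    seq <- ""
    rows <- list()
    for (i in seq_along(seqs)) {
      seq <- paste0(seq, sp(10 + i))
      start <- nchar(seq) + 1
      seq <- paste0(seq, seqs[i])
      rows[[i]] <- tibble::tibble(
        gene_id = paste0(id, "_", names(seqs)[i]), replicon_id = "chr",
        start = start, end = nchar(seq), strand = "+", kind = "CDS",
        product = names(seqs)[i], protein = NA_character_)
    }
    genome_record(id, tibble::tibble(replicon_id = "chr", sequence = seq,
                                     circular = TRUE),
                  dplyr::bind_rows(rows))
  }
  ga <- mk("gA", cargo_a, "cargoA")
  gb <- mk("gB", cargo_b, if (cargo_b_same) "cargoA" else "cargoB")
  list(gA = ga, gB = gb)
}

island_gene_map <- function(genomes) {
  dplyr::bind_rows(lapply(genomes, function(g) {
    tibble::tibble(genome_id = g$genome_id, gene_id = g$genes$gene_id,
                   family_id = g$genes$product)
  }))
}

test_that("identical genomes yield no islands", {
  gs <- build_island_pair(cargo_b_same = TRUE)
  isl <- find_variable_regions(gs, gene_map = island_gene_map(gs))
  expect_equal(nrow(isl), 0)
})

test_that("a swapped cassette between shared anchors is called with its anchors", {
  gs <- build_island_pair()
  isl <- find_variable_regions(gs, gene_map = island_gene_map(gs))
  expect_equal(length(unique(isl$island_id)), 1)
  expect_equal(nrow(isl), 2) # one row per genome
  expect_setequal(unique(c(isl$left_anchor_family, isl$right_anchor_family)),
                  c("anc1", "anc2"))
  expect_equal(sort(unlist(isl$cargo_families[isl$genome_id == "gA"])),
               "cargoA")
  # low-GC cargo is reflected in the island GC
  expect_lt(mean(isl$gc_pct), 35)
  expect_error(find_variable_regions(gs["gA"]), ">= 2 genomes")
})

test_that("the Jaccard boundary 0.5 is inclusive", {
  # Cargo family sets {x} vs {x, z}: |intersection| = 1, |union| = 2, so
  # the Jaccard is exactly 0.5 and the interval must be called. Family x
  # is duplicated inside genome 1 so it cannot become an anchor.
  anchorA <- rseq(600, seed = 21); anchorB <- rseq(600, seed = 22)
  geneX <- rseq(600, seed = 23); geneZ <- rseq(600, seed = 24)
  mk <- function(id, cargo_genes) {
    parts <- c(ancA = anchorA, cargo_genes, ancB = anchorB)
    seq <- ""
    rows <- list()
    for (i in seq_along(parts)) {
      seq <- paste0(seq, "AAA")
      start <- nchar(seq) + 1
      seq <- paste0(seq, parts[i])
      rows[[i]] <- tibble::tibble(
        gene_id = paste0(id, "_", names(parts)[i], "_", i),
        replicon_id = "chr",
        start = start, end = nchar(seq), strand = "+", kind = "CDS",
        product = names(parts)[i], protein = NA_character_)
    }
    genome_record(id, tibble::tibble(replicon_id = "chr", sequence = seq,
                                     circular = TRUE),
                  dplyr::bind_rows(rows))
  }
  gs <- list(g1 = mk("g1", c(x = geneX, x = geneX)),
             g2 = mk("g2", c(x = geneX, z = geneZ)))
  isl <- find_variable_regions(gs, gene_map = island_gene_map(gs))
  expect_equal(unique(isl$min_jaccard), 0.5)
  expect_equal(length(unique(isl$island_id)), 1)
})

test_that("hallmark search is exact, strand-aware and windowed", {
  cl <- tiny_clade()
  g <- cl$genomes[[2]]
  # baseline simulated genome carries no 15-bp tRNA 3' repeats
  expect_equal(nrow(trna_hallmarks(g, min_repeat = 15)), 0)
  # min_repeat longer than the tRNA: empty result, not an error
  expect_equal(nrow(trna_hallmarks(g, min_repeat = 100)), 0)
  # insertion -> exactly one hallmark, inside the search window
  tr <- g$genes[g$genes$kind == "tRNA", ]
  g2 <- insert_cassette(g, tr$gene_id[2], rseq(2000, seed = 51),
                        repeat_len = 20)
  h <- trna_hallmarks(g2, min_repeat = 15)
  expect_equal(nrow(h), 1)
  expect_equal(h$trna_id, tr$gene_id[2])
  if (h$strand == "+") {
    expect_gt(h$repeat_start, h$trna_end3)
    expect_lte(h$repeat_start - h$trna_end3, 2100)
  } else {
    expect_lt(h$repeat_end, h$trna_end3)
  }
  # outside the window the hallmark is not reported
  h_narrow <- trna_hallmarks(g2, min_repeat = 15, window = 100)
  expect_equal(nrow(h_narrow), 0)
})

test_that("random repeat-free genomes produce no false hallmarks", {
  # expected false positives ~ L * 4^-15 per tRNA; on 200 kb effectively 0
  set.seed(61)
  for (i in 1:3) {
    seq <- rseq(200000, gc = 0.4)
    genes <- tibble::tibble(gene_id = paste0("t", 1:4), replicon_id = "chr",
                            start = c(1000, 50000, 120000, 180000),
                            end = c(1075, 50075, 120075, 180075),
                            strand = c("+", "-", "+", "-"), kind = "tRNA",
                            product = NA_character_, protein = NA_character_)
    g <- genome_record(paste0("rand", i),
                       tibble::tibble(replicon_id = "chr", sequence = seq,
                                      circular = TRUE), genes)
    expect_equal(nrow(trna_hallmarks(g, min_repeat = 15)), 0)
  }
})
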