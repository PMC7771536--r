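# Streamlining metrics: GC, coding stats, spacers, paralogs, operons,
# GC skew.

toy_genome <- function(genes, len = 1000, seed = 1) {
  genome_record("toy",
                tibble::tibble(replicon_id = "chr",
                               sequence = rseq(len, seed = seed),
                               circular = TRUE),
                genes)
}

gene_row <- function(id, start, end, strand = "+", kind = "CDS") {
  tibble::tibble(gene_id = id, replicon_id = "chr", start = start,
                 end = end, strand = strand, kind = kind,
                 product = NA_character_, protein = NA_character_)
}

test_that("gc_content follows the A/C/G/T convention and excludes N", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("GCATNNNN"), 50)
  expect_error(gc_content("NNNN"), "undefined")
})

test_that("coding stats use union coverage over strands", {
  g1 <- toy_genome(gene_row("a", 101, 400))
  cs <- coding_stats(g1)
  expect_equal(cs$coding_density_pct, 30)
  expect_equal(cs$avg_gene_size, 300)
  expect_equal(cs$n_proteins, 1L)
  # fully overlapping CDS on opposite strands do not double-count
  g2 <- toy_genome(dplyr::bind_rows(gene_row("a", 101, 400),
                                    gene_row("b", 101, 400, strand = "-")))
  expect_equal(coding_stats(g2)$coding_density_pct, 30)
  expect_equal(coding_stats(g2)$avg_gene_size, 300)
  # no CDS
  g0 <- toy_genome(NULL)
  expect_equal(coding_stats(g0)$coding_density_pct, 0)
})

test_that("simulated genomes hit the target gene density", {
  cl <- small_clade()
  cs <- coding_stats(cl$genomes[[1]])
  expect_equal(cs$gene_density_pct, 100 * cl$params$target_coding_density,
               tolerance = 0.02)
})

test_that("intergenic spacers are signed and match brute force", {
  g <- toy_genome(dplyr::bind_rows(gene_row("a", 1, 100),
                                   gene_row("b", 103, 200)))
  expect_equal(median_intergenic_spacer(g), 2)
  g2 <- toy_genome(dplyr::bind_rows(gene_row("a", 1, 100),
                                    gene_row("b", 95, 200)))
  expect_equal(median_intergenic_spacer(g2), -6)
  expect_error(median_intergenic_spacer(toy_genome(gene_row("a", 1, 50))),
               "undefined")
  # random table vs direct recomputation
  set.seed(11)
  starts <- sort(sample(seq(1, 9000, by = 10), 40))
  ends <- starts + sample(50:200, 40, replace = TRUE)
  rows <- dplyr::bind_rows(lapply(seq_along(starts), function(i) {
    gene_row(paste0("g", i), starts[i], ends[i])
  }))
  g3 <- toy_genome(rows, len = 10000)
  o <- order(starts, ends)
  expect_equal(median_intergenic_spacer(g3),
               median(starts[o][-1] - ends[o][-length(ends)] - 1))
  # median spacer of simulated streamlined genomes stays at a few bp
  expect_lte(median_intergenic_spacer(small_clade()$genomes[[1]]), 6)
})

test_that("paralog counts are correct and monotone in threshold", {
  aa <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), n,
                 TRUE), collapse = "")
  }
  mut_aa <- function(s, n_sub, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), n_sub)
    ch[i] <- sample(c("M", "N", "P", "Q", "R"), n_sub, TRUE)
    paste(ch, collapse = "")
  }
  # two identical proteins: paralogs at every threshold
  p <- c(a = aa(120, 1), b = aa(120, 1), c = aa(120, 2))
  cnt <- count_paralogs(p)
  expect_true(all(cnt$n_paralogs == 2L))
  # mutually unrelated proteins: zero at every threshold
  cnt0 <- count_paralogs(setNames(vapply(1:5, function(i) aa(150, i + 10),
                                         character(1)), paste0("p", 1:5)))
  expect_true(all(cnt0$n_paralogs == 0L))
  # constructed family at ~60% identity: found at 50/30, absent at 90
  base <- aa(200, 42)
  fam <- c(f1 = base, f2 = mut_aa(base, 80, 1), f3 = mut_aa(base, 80, 2),
           lone = aa(200, 77))
  cf <- count_paralogs(fam)
  expect_equal(cf$n_paralogs[cf$threshold == 90], 0L)
  expect_gte(cf$n_paralogs[cf$threshold == 50], 2L)
  expect_gte(cf$n_paralogs[cf$threshold == 30], 3L)
  # monotone: counts never decrease as the threshold drops
  expect_true(all(diff(cf$n_paralogs[order(-cf$threshold)]) >= 0))
})

test_that("operon heuristic groups same-strand runs", {
  rows <- dplyr::bind_rows(lapply(0:4, function(i) {
    gene_row(paste0("g", i), 1 + i * 103, 100 + i * 103)
  }))
  ops <- predict_operons(toy_genome(rows))
  expect_equal(nrow(ops$operons), 1)
  expect_equal(ops$avg_genes_per_operon, 5)
  # alternating strands: all singletons
  rows2 <- rows
  rows2$strand <- rep(c("+", "-"), length.out = 5)
  ops2 <- predict_operons(toy_genome(rows2))
  expect_equal(ops2$avg_genes_per_operon, 1)
  # random table equals brute-force run-length computation
  set.seed(5)
  starts <- seq(1, 4901, by = 100)
  ends <- starts + sample(40:95, length(starts), TRUE)
  strands <- sample(c("+", "-"), length(starts), TRUE)
  rows3 <- dplyr::bind_rows(lapply(seq_along(starts), function(i) {
    gene_row(paste0("g", i), starts[i], ends[i], strand = strands[i])
  }))
  ops3 <- predict_operons(toy_genome(rows3, len = 5000), max_gap = 30)
  gap <- starts[-1] - ends[-length(ends)] - 1
  brk <- gap > 30 | strands[-1] != strands[-length(strands)]
  expect_equal(sort(ops3$operons$n_genes),
               sort(as.integer(table(cumsum(c(TRUE, brk))))))
})

test_that("GC-skew extrema find the constructed and simulated terminus", {
  s <- paste0(strrep("G", 5000), strrep("C", 5000))
  sk <- gc_skew_extrema(s, window = 500)
  expect_equal(sk$terminus_pos, 4501) # cumulative max just before the flip
  expect_true(sk$origin_pos %in% c(1, 9501))
  # reverse complement mirrors the skew sign
  sk_rc <- gc_skew_extrema(revcomp(s), window = 500)
  expect_equal(sk_rc$profile$skew, -rev(sk$profile$skew))
  # simulated replichore-biased genome: extrema near true origin/terminus
  # near-zero divergence so substitutions do not erode the replichore bias
  cl <- simulate_clade(sim_params(
    n_genera = 1, genomospecies_per_genus = 1,
    strains_per_genomospecies = 1, core_genes = 60, accessory_pool = 20,
    trna_count = 3, skew_bias = 0.25, div_strain = 0.001,
    div_genomospecies = 0.002, div_genus = 0.003, seed = 777))
  g <- cl$genomes[[1]]
  L <- genome_length(g)
  w <- 2000
  sk2 <- gc_skew_extrema(g, window = w)
  circ_dist <- function(a, b) min(abs(a - b), L - abs(a - b))
  expect_lte(circ_dist(sk2$origin_pos, 1), 2 * w)
  expect_lte(circ_dist(sk2$terminus_pos, L / 2), 2 * w)
  expect_error(gc_skew_extrema(rseq(500), window = 1000), "2 windows")
})

test_that("streamline_report bundles the table metrics", {
  rep <- streamline_report(small_clade()$genomes[[1]])
  expect_equal(nrow(rep), 1)
  expect_true(all(c("genome_size", "gc_pct", "n_proteins",
                    "median_intergenic_spacer", "n_paralogs",
                    "avg_genes_per_operon") %in% names(rep)))
  expect_equal(rep$gc_pct, 32.5, tolerance = 0.1)
})
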