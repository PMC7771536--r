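# Read QC, recruitment, RPKG/coverage presence calls, ANIr, histograms,
# genomospecies distributions.

test_that("qc_reads enforces Phred, length and ambiguity rules", {
  reads <- tibble::tibble(
    read_id = c("ok", "short", "hasN", "lowq", "fasta"),
    sequence = c(rseq(60), rseq(49), paste0(rseq(30), "N", rseq(30)),
                 rseq(60), rseq(60)),
    quality = c(strrep("I", 60), strrep("I", 49), strrep("I", 61),
                strrep("#", 60), NA))
  kept <- qc_reads(reads, min_phred = 30, min_len = 50)
  expect_setequal(kept$read_id, c("ok", "fasta"))
  bad <- tibble::tibble(read_id = "x", sequence = rseq(60),
                        quality = strrep("I", 30))
  expect_error(qc_reads(bad), "record 1")
})

test_that("recruitment masks the rRNA operon and keeps best hits", {
  cl <- tiny_clade()
  g <- cl$genomes[[1]]
  rd <- simulate_reads(g, 300, 120, divergence = 0, seed = 1)
  prof <- recruit(g, rd, min_identity = 98, metagenome_gb = 0.001)
  rr <- g$genes[g$genes$kind == "rRNA", ]
  # reads from outside the operon recruit; none lands inside the mask
  expect_gt(nrow(prof$hits), 200)
  expect_true(all(prof$hits$position > max(rr$end) |
                    prof$hits$position + prof$hits$aligned_len <
                      min(rr$start)))
  expect_equal(prof$genome_len_effective,
               genome_length(g) - sum(prof$masked$end - prof$masked$start + 1))
  # reads sourced entirely from the masked operon give zero hits
  op <- substr(g$replicons$sequence[1], min(rr$start), max(rr$end))
  rd_op <- simulate_reads(op, 40, 100, seed = 2)
  prof_op <- recruit(g, rd_op, min_identity = 98)
  expect_equal(nrow(prof_op$hits), 0)
})

test_that("recruited fraction at 5% divergence matches the binomial oracle", {
  g <- rseq(50000, seed = 31)
  gr <- genome_record("r", tibble::tibble(replicon_id = "chr", sequence = g,
                                          circular = TRUE))
  rd <- simulate_reads(gr, 1500, 150, divergence = 0.05, seed = 32)
  prof <- recruit(gr, rd, min_identity = 98, mask_rrna = FALSE)
  frac <- nrow(prof$hits) / nrow(rd)
  # >= 98% identity over the full read allows <= 3 substitutions; local
  # end-trimming rescues a few borderline reads
  p0 <- pbinom(3, 150, 0.05)
  expect_gte(frac, p0 * 0.8)
  expect_lte(frac, p0 + 0.06)
})

test_that("RPKG, coverage and the presence rule follow the definitions", {
  prof <- structure(list(
    genome_id = "g", sample_id = "s", metagenome_gb = 2,
    masked = tibble::tibble(), genome_len_effective = 1e6,
    hits = tibble::tibble(read_id = sprintf("r%05d", 1:10000),
                          replicon_id = "chr",
                          position = rep(seq(1, 1e6 - 100, length.out = 500),
                                         20)[1:10000],
                          aligned_len = 100, identity_pct = 99,
                          strand = "+",
                          tend = rep(seq(1, 1e6 - 100, length.out = 500),
                                     20)[1:10000] + 99)),
    class = "recruitment_profile")
  call <- rpkg_presence(prof)
  expect_equal(call$rpkg, 10000 / (1000 * 2)) # = 5.0 exactly
  expect_false(call$present) # coverage far below 0.70
  # zero hits
  prof0 <- prof; prof0$hits <- prof$hits[0, ]
  call0 <- rpkg_presence(prof0)
  expect_equal(call0$rpkg, 0)
  expect_false(call0$present)
  # footprint union equals a brute-force position scan
  set.seed(9)
  L <- 5000
  pos <- sample(1:(L - 60), 300, replace = TRUE)
  prof2 <- prof
  prof2$genome_len_effective <- L
  prof2$hits <- tibble::tibble(read_id = paste0("r", seq_along(pos)),
                               replicon_id = "chr", position = pos,
                               aligned_len = 60, identity_pct = 99,
                               strand = "+", tend = pos + 59)
  covered <- logical(L)
  for (p in pos) covered[p:(p + 59)] <- TRUE
  expect_equal(rpkg_presence(prof2)$coverage_fraction, mean(covered))
})

test_that("ANIr is the mean hit identity", {
  prof <- structure(list(genome_id = "g", sample_id = "s",
                         metagenome_gb = 1, masked = tibble::tibble(),
                         genome_len_effective = 1000,
                         hits = tibble::tibble(read_id = c("a", "b", "c"),
                                               replicon_id = "chr",
                                               position = c(1, 10, 20),
                                               aligned_len = 50,
                                               identity_pct = c(96, 98, 100),
                                               strand = "+",
                                               tend = c(50, 59, 69))),
                    class = "recruitment_profile")
  expect_equal(anir(prof), 98)
  prof0 <- prof; prof0$hits <- prof$hits[0, ]
  expect_error(anir(prof0), "undefined")
})

test_that("identity histograms bin correctly and sum to 100", {
  mk <- function(ids) {
    structure(list(genome_id = "g", sample_id = "s", metagenome_gb = 1,
                   masked = tibble::tibble(), genome_len_effective = 1000,
                   hits = tibble::tibble(read_id = paste0("r", seq_along(ids)),
                                         replicon_id = "chr",
                                         position = seq_along(ids),
                                         aligned_len = 50,
                                         identity_pct = ids, strand = "+",
                                         tend = seq_along(ids) + 49)),
              class = "recruitment_profile")
  }
  h100 <- identity_histogram(mk(rep(100, 7)))
  expect_equal(h100$count[h100$bin_lo == 99], 7L)
  expect_equal(sum(h100$count > 0), 1)
  expect_equal(attr(h100, "species_threshold"), 95)
  set.seed(3)
  hu <- identity_histogram(mk(runif(5000, 90, 100)))
  expect_equal(sum(hu$rel_pct), 100)
  expect_equal(unname(hu$rel_pct[hu$bin_lo >= 90]), rep(10, 10),
               tolerance = 0.2)
  h0 <- identity_histogram(mk(numeric(0)))
  expect_equal(sum(h0$count), 0)
})

test_that("genomospecies distributions average member RPKGs", {
  mkprof <- function(g, smp, n_hits, len = 1e5, gb = 0.01) {
    pos <- if (n_hits) seq(1, len - 100, length.out = n_hits) else numeric(0)
    structure(list(genome_id = g, sample_id = smp, metagenome_gb = gb,
                   masked = tibble::tibble(), genome_len_effective = len,
                   hits = tibble::tibble(read_id = paste0("r", seq_len(n_hits)),
                                         replicon_id = "chr",
                                         position = pos, aligned_len = 100,
                                         identity_pct = 99, strand = "+",
                                         tend = pos + 99)),
              class = "recruitment_profile")
  }
  ranks <- tibble::tibble(genome_id = c("a", "b", "c"),
                          genomospecies = c("G1.1", "G1.1", "G2.1"))
  profs <- list(mkprof("a", "s1", 400), mkprof("b", "s1", 800),
                mkprof("c", "s1", 100))
  d <- genomospecies_distribution(profs, ranks)
  rp <- function(n) n / (100 * 0.01)
  expect_equal(d$mean_rpkg[d$genomospecies == "G1.1"],
               mean(c(rp(400), rp(800))))
  expect_equal(d$mean_rpkg[d$genomospecies == "G2.1"], rp(100))
  # a genome with no profile in a sample counts as zero, with a warning
  profs2 <- c(profs, list(mkprof("a", "s2", 500)))
  expect_warning(d2 <- genomospecies_distribution(profs2, ranks), "RPKG 0")
  expect_equal(d2$mean_rpkg[d2$genomospecies == "G1.1" & d2$sample_id == "s2"],
               mean(c(rp(500), 0)))
})
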