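test_that("build_census satisfies its conservation identities", {
  empty <- scan_proteome(data.frame(id = character(0),
                                    sequence = character(0)))
  cen0 <- build_census(empty)
  expect_identical(cen0$n_domains, 0L)
  expect_identical(sum(cen0$type_totals), 0L)
  expect_identical(nrow(cen0$per_protein), 0L)

  set.seed(51)
  sim <- generate_proteome(list(n_proteins = 60, n_domains = 40,
                                n_decoys = 8), seed = 7)
  m <- scan_proteome(sim$proteins, verbose = FALSE)
  cen <- build_census(m, sim$genes)
  expect_identical(sum(cen$type_totals), cen$n_domains)
  expect_identical(sum(cen$chrom_totals$n_domains), cen$n_domains)
  expect_identical(cen$n_single + cen$n_multi,
                   sum(cen$per_protein$n_complete > 0L))
  expect_identical(cen$n_multi, 5L)  # the five two-domain proteins
  expect_identical(cen$n_incomplete, 8L)
  # per-chromosome totals equal the planted design
  planted_chrom <- table(sim$genes$chromosome[
    match(sim$truth$domains$protein_id, sim$genes$protein_id)])
  got <- stats::setNames(cen$chrom_totals$n_domains,
                         cen$chrom_totals$chromosome)
  expect_identical(as.integer(got[names(planted_chrom)]),
                   as.integer(planted_chrom))
  drop <- which(sim$genes$protein_id == m$protein_id[1])
  expect_error(build_census(m, sim$genes[-drop, ]), "no gene model")
})

test_that("multi-domain proteins and unplaced chromosomes are flagged", {
  set.seed(52)
  d1 <- instantiate_consensus("RING-H2")
  d2 <- instantiate_consensus("RING-C2")
  prot <- data.frame(id = "p1",
                     sequence = paste0(strrep("A", 6), d1$sequence,
                                       strrep("A", 6), d2$sequence,
                                       strrep("A", 6)))
  m <- scan_proteome(prot, verbose = FALSE)
  cen <- build_census(m)  # no gene models: unplaced
  expect_identical(cen$n_multi, 1L)
  expect_identical(cen$per_protein$types, "RING-H2,RING-C2")
  expect_identical(cen$per_protein$chromosome, "unplaced")
  expect_true(cen$per_protein$excluded)
  genes <- data.frame(gene_id = "g1", protein_id = "p1", chromosome = "0",
                      start = 1L, end = 10000L, strand = "+",
                      exon_count = 2L)
  cen0 <- build_census(m, genes)
  expect_true(cen0$per_protein$excluded)  # chromosome 0 flagged
})

test_that("count_intronless counts single-exon genes among RING genes", {
  genes <- data.frame(gene_id = paste0("g", 1:4),
                      exon_count = c(1L, 2L, 1L, 5L))
  expect_identical(count_intronless(genes, paste0("g", 1:4)), 2L)
  expect_identical(count_intronless(genes, character(0)), 0L)
  set.seed(53)
  sim <- generate_proteome(list(n_proteins = 80, n_domains = 50,
                                n_decoys = 0, intronless_fraction = 0.25),
                           seed = 21)
  ring_genes <- sim$genes$gene_id[
    sim$genes$protein_id %in% sim$truth$domains$protein_id]
  expect_identical(
    count_intronless(sim$genes, ring_genes),
    sum(sim$genes$exon_count[sim$genes$gene_id %in% ring_genes] == 1L))
})

test_that("protein_stats computes length, mass and pI as documented", {
  g <- protein_stats("G")
  expect_equal(g$length, 1L)
  expect_equal(g$mw, 75.07, tolerance = 1e-4)
  expect_equal(protein_stats("GG")$mw, 132.12, tolerance = 1e-4)
  expect_identical(protein_stats("ACDEFG")$length, 6L)
  expect_error(protein_stats(""), "empty")
  # additivity: MW(s1 + s2) = MW(s1) + MW(s2) - one water
  set.seed(54)
  for (i in 1:10) {
    s1 <- paste(sample(ringcensus:::AA_STANDARD, 30, TRUE), collapse = "")
    s2 <- paste(sample(ringcensus:::AA_STANDARD, 45, TRUE), collapse = "")
    expect_equal(protein_stats(paste0(s1, s2))$mw,
                 protein_stats(s1)$mw + protein_stats(s2)$mw - 18.0153,
                 tolerance = 1e-9)
  }
  # non-standard letters: flagged, mass from the alphabet average
  x <- protein_stats("GXG")
  expect_identical(x$n_nonstandard, 1L)
  # pI is a zero of the net charge and orders acids below bases
  acid <- protein_stats("DDEEDDEE")
  base <- protein_stats("KKRRKKRR")
  expect_lt(acid$pi, base$pi)
  expect_lt(abs(ringcensus:::.net_charge(
    acid$pi, list(H = 0, K = 0, R = 0, C = 0, D = 4, E = 4, Y = 0))), 1e-4)
})

test_that("pairwise_identity agrees with an independent alignment DP", {
  expect_identical(pairwise_identity("PELICAN", "PELICAN"), 1)
  expect_identical(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("AAAA", "AATA"), 0.75)
  expect_error(pairwise_identity("", "AA"), "empty")
  set.seed(55)
  for (i in 1:12) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:7, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:7, 1), TRUE),
               collapse = "")
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
                 label = paste(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("find_tandem_clusters applies the proximity + identity rule", {
  seqs <- c(pA = strrep("MKLV", 25), pB = strrep("MKLV", 25),
            pC = paste(rep(c("W", "Y"), 50), collapse = ""))
  mkgenes <- function(starts, prot, chrom = "chr01") {
    data.frame(gene_id = paste0("g", seq_along(starts)),
               protein_id = prot, chromosome = chrom,
               start = starts, end = starts + 999L, strand = "+",
               stringsAsFactors = FALSE)
  }
  # two adjacent near-identical genes cluster
  g <- mkgenes(c(1000, 3000), c("pA", "pB"))
  tc <- find_tandem_clusters(g, g$gene_id, seqs)
  expect_identical(nrow(tc), 2L)
  expect_identical(unique(tc$cluster_id), 1L)
  # identical proximity but dissimilar proteins: no cluster
  g2 <- mkgenes(c(1000, 3000), c("pA", "pC"))
  expect_identical(nrow(find_tandem_clusters(g2, g2$gene_id, seqs)), 0L)
  # far apart with intervening non-RING genes: no cluster
  g3 <- rbind(mkgenes(c(1000, 2.5e6), c("pA", "pB")),
              mkgenes(seq(5e5, 2e6, length.out = 5),
                      rep("pC", 5))[,])
  g3$gene_id <- paste0("g", seq_len(nrow(g3)))
  expect_identical(nrow(find_tandem_clusters(g3, c("g1", "g2"), seqs)), 0L)

  # planted 3-copy cluster from the generator
  set.seed(56)
  sim <- generate_proteome(list(n_proteins = 25, n_domains = 10, n_decoys = 0,
                                tandem = list(n_clusters = 1L,
                                              cluster_size = 3L,
                                              substitution_rate = 0.05)),
                           seed = 3)
  ring_genes <- sim$genes$gene_id[
    sim$genes$protein_id %in% sim$truth$tandem$protein_id]
  seqv <- stats::setNames(sim$proteins$sequence, sim$proteins$id)
  tc3 <- find_tandem_clusters(sim$genes, ring_genes, seqv)
  expect_identical(nrow(tc3), 3L)
  expect_identical(unique(tc3$cluster_id), 1L)
  expect_setequal(tc3$gene_id, ring_genes)
  # invariant to input row order
  perm <- sample(nrow(sim$genes))
  tc3b <- find_tandem_clusters(sim$genes[perm, ], ring_genes, seqv)
  expect_identical(tc3, tc3b, ignore_attr = TRUE)
})
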