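test_that("instantiate_consensus inverts the grammar", {
  # fixed-gap RING-G: 8 ligands + 2+16+1+2+2+13+2 fillers = 46 residues
  set.seed(71)
  g <- instantiate_consensus("RING-G", c(2, 16, 1, 2, 2, 13, 2), filler = "A")
  expect_identical(nchar(g$sequence), 46L)
  expect_identical(g$ml_positions[1], 1L)
  expect_identical(g$ml_positions[8], 46L)

  h2 <- instantiate_consensus("RING-H2", c(2, 14, 1, 2, 2, 10, 2), filler = "A")
  expect_identical(nchar(h2$sequence), 41L)
  expect_identical(classify_octet(h2$residues, h2$gaps), "RING-H2")

  expect_error(instantiate_consensus("RING-H2", c(2, 40, 1, 2, 2, 10, 2)),
               "outside")
  expect_error(instantiate_consensus("RING-X"), "unknown")

  # S/T always places at least one serine
  for (i in 1:20) {
    st <- instantiate_consensus("RING-S/T")
    expect_true(any(st$residues[c(2, 6)] == "S"))
    expect_identical(classify_octet(st$residues, st$gaps), "RING-S/T")
  }
})

test_that("generate_proteome is byte-deterministic for a fixed seed", {
  cfg <- list(n_proteins = 10, n_domains = 10, n_two_domain_proteins = 0,
              n_decoys = 0)
  a <- generate_proteome(cfg, seed = 7)
  b <- generate_proteome(cfg, seed = 7)
  expect_identical(a, b)
  expect_identical(nrow(a$truth$domains), 10L)
  c <- generate_proteome(cfg, seed = 8)
  expect_false(identical(a$proteins, c$proteins))
})

test_that("every truth row is confirmed by re-scanning (zero false truths)", {
  set.seed(72)
  sim <- generate_proteome(list(n_proteins = 50, n_domains = 35,
                                n_decoys = 5), seed = 19)
  seqs <- stats::setNames(sim$proteins$sequence, sim$proteins$id)
  for (i in seq_len(nrow(sim$truth$domains))) {
    tr <- sim$truth$domains[i, ]
    pos <- as.integer(strsplit(tr$ml_positions, ",")[[1]])
    chars <- strsplit(seqs[[tr$protein_id]], "")[[1]]
    expect_identical(classify_octet(chars[pos], diff(pos) - 1L), tr$type,
                     label = paste("truth row", i))
  }
  for (i in seq_len(nrow(sim$truth$decoys))) {
    de <- sim$truth$decoys[i, ]
    chars <- strsplit(seqs[[de$protein_id]], "")[[1]]
    knocked <- as.integer(strsplit(de$knocked, ",")[[1]])
    pos <- as.integer(strsplit(de$ml_positions, ",")[[1]])
    expect_identical(length(knocked), de$n_knockouts)
    # the knocked ligand carries the 'A' substitution, so the damaged
    # octet no longer classifies...
    expect_true(all(chars[pos[knocked]] == "A"))
    expect_identical(classify_octet(chars[pos], diff(pos) - 1L),
                     NA_character_)
    # ...but restoring the source grammar's residues at the knocked
    # position(s) restores the match
    spec <- builtin_specs()[[de$source_type]]
    fixed <- chars[pos]
    fixed[knocked] <- vapply(spec$residues[knocked], `[`, "", 1L)
    if (length(spec$require_ser_at) &&
        !any(fixed[spec$require_ser_at] == "S"))
      fixed[max(spec$require_ser_at)] <- "S"
    expect_true(match_spec(spec, fixed, diff(pos) - 1L))
  }
})

test_that("protein lengths and flanks respect the stated world", {
  set.seed(73)
  sim <- generate_proteome(list(n_proteins = 60, n_domains = 30,
                                n_decoys = 5), seed = 4)
  len <- nchar(sim$proteins$sequence)
  expect_true(all(len >= 60 - 1))  # log-uniform draw, floor at feasibility
  expect_true(all(len <= 1888))
  expect_true(all(sim$truth$domains$start >= 6))  # >= 5 flank residues
  expect_identical(sort(unique(sim$genes$chromosome)),
                   sort(unique(sprintf("chr%02d",
                     seq_len(max(as.integer(sub("chr", "",
                       sim$genes$chromosome))))))))
  expect_identical(nrow(sim$genes), nrow(sim$proteins))
  expect_true(all(sim$genes$start <= sim$genes$end))
  expect_true(all(sim$genes$exon_count >= 1L))
})

test_that("decoys surface as incomplete iff their knockout count is one", {
  set.seed(74)
  sim1 <- generate_proteome(list(n_proteins = 20, n_domains = 10,
                                 n_two_domain_proteins = 0, n_decoys = 6,
                                 decoy_knockouts = 1L), seed = 31)
  m1 <- scan_proteome(sim1$proteins, verbose = FALSE)
  expect_identical(sum(!m1$complete), 6L)
  sim2 <- generate_proteome(list(n_proteins = 20, n_domains = 10,
                                 n_two_domain_proteins = 0, n_decoys = 6,
                                 decoy_knockouts = 2L), seed = 31)
  m2 <- scan_proteome(sim2$proteins, verbose = FALSE)
  expect_identical(sum(!m2$complete), 0L)
  # ... unless the threshold knob is raised to match
  m2b <- scan_proteome(sim2$proteins, max_violations = 2L, verbose = FALSE)
  expect_gte(sum(!m2b$complete), 6L)
})

test_that("infeasible configurations are rejected", {
  expect_error(generate_proteome(list(n_proteins = 5, n_domains = 10,
                                      n_two_domain_proteins = 0,
                                      n_decoys = 0)), "infeasible")
  expect_error(generate_proteome(list(n_domains = 4,
                                      n_two_domain_proteins = 5)),
               "infeasible")
  expect_error(generate_proteome(list(bogus_knob = 1)), "unknown config")
})

test_that("mutate_cds plants exactly the requested changes", {
  set.seed(75)
  cds <- random_cds(40)
  expect_identical(mutate_cds(cds, 0, 0)$cds, cds)

  m <- mutate_cds(strrep("AAA", 10), 1, 0)
  expect_identical(nrow(m$record), 1L)
  expect_identical(m$record$class, "synonymous")
  # the only synonymous single change of AAA is AAA -> AAG
  expect_identical(m$record$pos, 3L)
  expect_identical(m$record$to, "G")
  codons <- substring(m$cds, seq(1, 28, 3), seq(3, 30, 3))
  expect_identical(sum(codons == "AAG"), 1L)

  expect_error(mutate_cds(strrep("ATG", 5), 1, 0), "infeasible")

  # never a stop, never two changes in one codon, classes verified
  gc <- Biostrings::GENETIC_CODE
  for (i in 1:10) {
    base <- random_cds(30)
    mm <- mutate_cds(base, 3, 4)
    expect_identical(nrow(mm$record), 7L)
    expect_identical(anyDuplicated(mm$record$codon), 0L)
    split3 <- function(s) substring(s, seq(1, nchar(s) - 2, 3),
                                    seq(3, nchar(s), 3))
    expect_false(any(gc[split3(mm$cds)] == "*"))
    before <- split3(base); after <- split3(mm$cds)
    changed <- which(before != after)
    expect_setequal(changed, mm$record$codon)
    syn <- gc[before[changed]] == gc[after[changed]]
    expect_identical(sum(syn), 3L)
  }
})
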