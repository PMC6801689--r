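# Shared fixture builders (everything generated in code; no data files).

# C/H-enriched random sequence used for the oracle-equivalence property:
# cysteine-rich enough that candidate octets actually occur.
enriched_sequence <- function(n = 150L, pC = 0.20, pH = 0.12) {
  aa <- ringcensus:::AA_STANDARD
  probs <- stats::setNames(rep(0, 20L), aa)
  probs[c("C", "H", "S", "G")] <- c(pC, pH, 0.04, 0.04)
  rest <- setdiff(aa, c("C", "H", "S", "G"))
  probs[rest] <- (1 - sum(probs)) / length(rest)
  paste(sample(aa, n, replace = TRUE, prob = probs), collapse = "")
}

# A protein carrying the given instantiated domains with 'A' flanks.
flanked <- function(domain, flank = 10L)
  paste0(strrep("A", flank), domain$sequence, strrep("A", flank))

# Minimal match data.frame rows for stats tests that need only a gap
# column and the complete flag.
fake_matches <- function(gap2_values, type = "RING-H2") {
  n <- length(gap2_values)
  df <- data.frame(protein_id = sprintf("p%d", seq_len(n)),
                   type = rep(type, n), complete = rep(TRUE, n),
                   stringsAsFactors = FALSE)
  for (i in 1:7) df[[paste0("gap", i)]] <- rep(2L, n)
  df$gap2 <- as.integer(gap2_values)
  df
}
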