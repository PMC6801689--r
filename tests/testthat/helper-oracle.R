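# Independent brute-force oracles, deliberately written as flat nested
# loops / direct enumeration so they share no code path with the package
# implementations they check.

# Every octet of positions satisfying some spec, by exhaustive walk over
# the gap windows of each spec in turn.
oracle_enumerate <- function(sequence, specs = builtin_specs()) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  k <- 0L
  for (sp in specs) {
    r <- sp$residues
    g <- sp$gaps
    ok <- function(p, i) p <= n && ch[p] %in% r[[i]]
    for (p1 in seq_len(n)) {
      if (!ok(p1, 1)) next
      for (g1 in g[[1]]) { p2 <- p1 + g1 + 1L; if (!ok(p2, 2)) next
      for (g2 in g[[2]]) { p3 <- p2 + g2 + 1L; if (!ok(p3, 3)) next
      for (g3 in g[[3]]) { p4 <- p3 + g3 + 1L; if (!ok(p4, 4)) next
      for (g4 in g[[4]]) { p5 <- p4 + g4 + 1L; if (!ok(p5, 5)) next
      for (g5 in g[[5]]) { p6 <- p5 + g5 + 1L; if (!ok(p6, 6)) next
      for (g6 in g[[6]]) { p7 <- p6 + g6 + 1L; if (!ok(p7, 7)) next
      for (g7 in g[[7]]) { p8 <- p7 + g7 + 1L; if (!ok(p8, 8)) next
        pos <- c(p1, p2, p3, p4, p5, p6, p7, p8)
        if (length(sp$require_ser_at) &&
            !any(ch[pos[sp$require_ser_at]] == "S")) next
        k <- k + 1L
        rows[[k]] <- c(list(type = sp$name),
                       as.list(stats::setNames(pos, paste0("ml", 1:8))))
      }}}}}}}
    }
  }
  if (!k) {
    df <- data.frame(type = character(0))
    for (i in 1:8) df[[paste0("ml", i)]] <- integer(0)
    return(df)
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# The documented selection rule, applied literally: repeatedly take the
# best remaining candidate by (leftmost ml1, smallest span, registry
# order) and discard everything sharing a residue index with it.
oracle_select <- function(cand, type_order = ring_type_names()) {
  picked <- cand[0, , drop = FALSE]
  while (nrow(cand)) {
    o <- order(cand$ml1, cand$ml8 - cand$ml1, match(cand$type, type_order))
    cand <- cand[o, , drop = FALSE]
    top <- cand[1, , drop = FALSE]
    picked <- rbind(picked, top)
    cand <- cand[cand$ml8 < top$ml1 | cand$ml1 > top$ml8, , drop = FALSE]
  }
  rownames(picked) <- NULL
  picked
}

# Canonical match key for set comparison.
match_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(apply(df[, c("type", paste0("ml", 1:8))], 1L, paste, collapse = ":"))
}

# --- NG86 oracle ---

oracle_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (alt in nts[nts != chars[pos]]) {
    mut <- chars; mut[pos] <- alt
    aa <- gc[[paste(mut, collapse = "")]]
    if (aa != "*" && aa == gc[[codon]]) s <- s + 1 / 3
  }
  c(S = s, N = 3 - s)
}

# All permutations of a vector, own recursion (no dependency).
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

oracle_ng86 <- function(cds1, cds2) {
  gc <- Biostrings::GENETIC_CODE
  splitc <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    apply(matrix(ch, nrow = 3), 2, paste, collapse = "")
  }
  c1 <- splitc(cds1); c2 <- splitc(cds2)
  stopifnot(length(c1) == length(c2))
  sites1 <- rowSums(vapply(c1, oracle_codon_sites, numeric(2)))
  sites2 <- rowSums(vapply(c2, oracle_codon_sites, numeric(2)))
  S <- (sites1[["S"]] + sites2[["S"]]) / 2
  N <- (sites1[["N"]] + sites2[["N"]]) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    a <- strsplit(c1[i], "")[[1]]; b <- strsplit(c2[i], "")[[1]]
    pos <- which(a != b)
    if (!length(pos)) next
    evaluate <- function(allow_stop) {
      acc <- list()
      for (ord in oracle_perms(pos)) {
        cur <- a; sd <- 0; nd <- 0; dead <- FALSE
        for (p in ord) {
          nxt <- cur; nxt[p] <- b[p]
          aa1 <- gc[[paste(cur, collapse = "")]]
          aa2 <- gc[[paste(nxt, collapse = "")]]
          if (aa2 == "*" && !allow_stop) { dead <- TRUE; break }
          if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        if (!dead) acc[[length(acc) + 1L]] <- c(sd, nd)
      }
      acc
    }
    acc <- evaluate(FALSE)
    if (!length(acc)) acc <- evaluate(TRUE)
    avg <- colMeans(do.call(rbind, acc))
    Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
  }
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn))
}

# --- global alignment identity oracle (plain Needleman-Wunsch DP with
# match +1, mismatch 0, gap -1; identity over the best-scoring traceback)
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  sc <- matrix(0, n + 1, m + 1)
  sc[, 1] <- -(0:n); sc[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m)
    sc[i + 1, j + 1] <- max(sc[i, j] + (x[i] == y[j]),
                            sc[i, j + 1] - 1, sc[i + 1, j] - 1)
  # traceback
  i <- n; j <- m; ident <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    len <- len + 1L
    if (i > 0 && j > 0 && sc[i + 1, j + 1] == sc[i, j] + (x[i] == y[j])) {
      ident <- ident + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && sc[i + 1, j + 1] == sc[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  ident / len
}
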