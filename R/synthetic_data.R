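# Synthetic proteomes, gene models and CDS pairs with planted ground
# truth, emulating the population structure the census assumes: proteins
# of 60-1888 residues carrying 0-2 RING domains, near-miss decoy domains,
# genes on 12 chromosomes with exon structures, and tandem duplicate
# pairs.  All randomness comes from R's global RNG; callers seed it (or
# use the `seed` argument of generate_proteome()).

.sample1 <- function(v) v[sample.int(length(v), 1L)]

# Default filler alphabet excludes C, H, S and G so a planted domain is
# the unique grammar-satisfying octet in its neighbourhood, which makes
# recovery tests exact.
.FILLER_CLEAN <- setdiff(AA_STANDARD, c("C", "H", "S", "G"))

#' Instantiate a RING consensus into a concrete domain string
#'
#' Inverts the grammar: picks residues from each metal-ligand set (for
#' RING-S/T placing at least one serine), validates or samples the gap
#' vector inside the type's gap sets, and fills the gap regions from a
#' filler alphabet.
#'
#' @param type RING type name (see [ring_type_names()]).
#' @param gaps Integer vector of 7 gaps, or `"random"` to sample each gap
#'   uniformly from its allowed set.
#' @param filler Filler alphabet for gap regions; the default excludes
#'   C/H/S/G.
#' @param canonical_residues Use the first allowed residue at every
#'   metal-ligand (with the S/T serine forced) instead of sampling?
#' @return List with `sequence` (length `8 + sum(gaps)`), `ml_positions`
#'   (1-based within the string), `residues`, `gaps`, `type`.
#' @export
instantiate_consensus <- function(type, gaps = "random",
                                  filler = .FILLER_CLEAN,
                                  canonical_residues = FALSE) {
  spec <- builtin_specs()[[type]]
  if (is.null(spec)) stop("unknown RING type: '", type, "'")
  if (identical(gaps, "random")) {
    gaps <- vapply(spec$gaps, .sample1, 0L)
  } else {
    gaps <- as.integer(gaps)
    if (length(gaps) != 7L) stop("'gaps' must have length 7")
    bad <- which(!mapply(function(g, set) g %in% set, gaps, spec$gaps))
    if (length(bad))
      stop("gap(s) outside the ", type, " grammar at pair(s) ",
           paste(ML_PAIR_LABELS[bad], collapse = ", "))
  }
  residues <- if (canonical_residues) {
    vapply(spec$residues, `[`, "", 1L)
  } else {
    vapply(spec$residues, .sample1, "")
  }
  if (length(spec$require_ser_at) &&
      !any(residues[spec$require_ser_at] == "S"))
    residues[max(spec$require_ser_at)] <- "S"
  pieces <- character(15L)
  pieces[seq(1L, 15L, by = 2L)] <- residues
  pieces[seq(2L, 14L, by = 2L)] <- vapply(gaps, function(g) {
    paste(sample(filler, g, replace = TRUE), collapse = "")
  }, "")
  seqstr <- paste(pieces, collapse = "")
  ml_positions <- cumsum(c(1L, gaps + 1L))
  list(sequence = seqstr, ml_positions = ml_positions,
       residues = residues, gaps = gaps, type = type)
}

#' Random in-frame coding sequence
#'
#' Uniform over the 61 sense codons; never contains a stop codon.
#'
#' @param n_codons Number of codons.
#' @return A CDS string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Apply controlled synonymous/nonsynonymous point mutations to a CDS
#'
#' Introduces exactly the requested numbers of single-nucleotide changes,
#' each verified against the standard genetic code, never creating a stop
#' codon and never touching the same codon twice (which keeps NG86
#' pathway counting exact: the realised `Sd`/`Nd` equal the planted
#' counts).
#'
#' @param cds Valid in-frame CDS.
#' @param n_synonymous,n_nonsynonymous Requested change counts.
#' @return List with `cds` (mutated sequence) and `record`, a data.frame
#'   of the applied changes (`codon`, `pos`, `from`, `to`, `class`).
#' @export
mutate_cds <- function(cds, n_synonymous, n_nonsynonymous) {
  codons <- .codon_split(cds)
  gc <- Biostrings::GENETIC_CODE
  n_synonymous <- as.integer(n_synonymous)
  n_nonsynonymous <- as.integer(n_nonsynonymous)
  nmax <- 9L * length(codons)
  v_codon <- integer(nmax); v_pos <- integer(nmax)
  v_from <- character(nmax); v_to <- character(nmax); v_class <- character(nmax)
  k <- 0L
  for (ci in seq_along(codons)) {
    chars <- strsplit(codons[ci], "")[[1]]
    aa0 <- gc[[codons[ci]]]
    for (pos in 1:3) {
      for (alt in .NT[.NT != chars[pos]]) {
        mut <- chars
        mut[pos] <- alt
        aa <- gc[[paste(mut, collapse = "")]]
        if (aa == "*") next
        k <- k + 1L
        v_codon[k] <- ci; v_pos[k] <- pos
        v_from[k] <- chars[pos]; v_to[k] <- alt
        v_class[k] <- if (aa == aa0) "synonymous" else "nonsynonymous"
      }
    }
  }
  pool <- data.frame(codon = v_codon[seq_len(k)], pos = v_pos[seq_len(k)],
                     from = v_from[seq_len(k)], to = v_to[seq_len(k)],
                     class = v_class[seq_len(k)], stringsAsFactors = FALSE)
  pick <- function(pool, n, used) {
    rows <- pool[!(pool$codon %in% used), , drop = FALSE]
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    rows <- rows[!duplicated(rows$codon), , drop = FALSE]
    if (nrow(rows) < n) return(NULL)
    rows[seq_len(n), , drop = FALSE]
  }
  syn_pool <- pool[pool$class == "synonymous", , drop = FALSE]
  non_pool <- pool[pool$class == "nonsynonymous", , drop = FALSE]
  sel <- NULL
  for (try in 1:25) {
    s <- pick(syn_pool, n_synonymous, integer(0))
    if (is.null(s) && n_synonymous > 0L) break
    n <- pick(non_pool, n_nonsynonymous, s$codon)
    if (is.null(n) && n_nonsynonymous > 0L) next
    sel <- rbind(s, n)
    break
  }
  if (is.null(sel) && (n_synonymous > 0L || n_nonsynonymous > 0L))
    stop("infeasible mutation request: not enough eligible ",
         "synonymous/nonsynonymous single-site options in distinct codons")
  if (is.null(sel))
    sel <- pool[0, , drop = FALSE]
  for (r in seq_len(nrow(sel))) {
    ci <- sel$codon[r]
    chars <- strsplit(codons[ci], "")[[1]]
    stopifnot(chars[sel$pos[r]] == sel$from[r])
    chars[sel$pos[r]] <- sel$to[r]
    codons[ci] <- paste(chars, collapse = "")
    stopifnot(gc[[codons[ci]]] != "*")
  }
  rownames(sel) <- NULL
  list(cds = paste(codons, collapse = ""), record = sel)
}

.default_sim_config <- function() {
  list(
    n_proteins = 500L,
    n_domains = 300L,
    n_two_domain_proteins = NULL,  # min(5, n_domains %/% 2) when unset
    n_decoys = 50L,
    decoy_knockouts = 1L,
    type_weights = c("RING-H2" = 248, "RING-HCa" = 142, "RING-HCb" = 21,
                     "RING-v" = 40, "RING-C2" = 20, "RING-S/T" = 2,
                     "RING-G" = 1),
    ensure_all_types = TRUE,
    length_range = c(60L, 1888L),
    n_chromosomes = 12L,
    intronless_fraction = 98 / 469,
    hostile_background = FALSE,
    background_ch_freq = c(C = 0.02, H = 0.02),
    tandem = list(n_clusters = 0L, cluster_size = 2L,
                  substitution_rate = 0.05),
    flank_min = 5L
  )
}

.background_sampler <- function(cfg) {
  if (!cfg$hostile_background)
    return(function(n) paste(sample(.FILLER_CLEAN, n, replace = TRUE),
                             collapse = ""))
  freq <- stats::setNames(rep(0, 20L), AA_STANDARD)
  freq[c("C", "H")] <- cfg$background_ch_freq[c("C", "H")]
  freq[c("S", "G")] <- 0.05
  rest <- setdiff(AA_STANDARD, c("C", "H", "S", "G"))
  freq[rest] <- (1 - sum(freq)) / length(rest)
  function(n) paste(sample(AA_STANDARD, n, replace = TRUE, prob = freq),
                    collapse = "")
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Produces protein sequences, gene models and a complete truth table so
#' the whole pipeline (scan, classify, census, tandem detection) can be
#' exercised and verified without external data.  Output is byte-identical
#' for a fixed `(config, seed)` pair.
#'
#' Defaults emulate the population a plant RING census operates on:
#' 500 proteins with log-uniform lengths in 60..1888 residues, 300 planted
#' domains drawn from the seven grammars in their observed tomato
#' proportions (248/142/21/40/20/2/1), five two-domain proteins, 50
#' single-knockout decoys, 12 chromosomes, and an intronless-gene fraction
#' of 98/469.  With `ensure_all_types` (default) one domain of every type
#' is planted before sampling the remainder, so rare types are always
#' represented.  Every planted domain has at least `flank_min` background
#' residues on each side; the default (clean) background excludes C/H/S/G
#' so planted truth is exact, while `hostile_background = TRUE` re-admits
#' them to stress-test overlap resolution (check against the brute-force
#' oracle, not against planted truth).
#'
#' Tandem clusters, when requested, are appended as extra proteins beyond
#' `n_proteins`: each cluster copies a fresh single-domain protein
#' `cluster_size` times, mutates residues outside the domain at
#' `substitution_rate`, and places the copies adjacently on one
#' chromosome.
#'
#' @param config Named list overriding entries of the default
#'   configuration (see Details); unknown keys are an error.
#' @param seed Integer seed; the RNG kind is pinned for reproducibility.
#' @return List with `proteins` (data.frame `id`, `sequence`), `genes`
#'   (gene-model data.frame) and `truth` (list of `domains`, `decoys`,
#'   `tandem` data.frames plus the config snapshot and seed).
#' @export
generate_proteome <- function(config = list(), seed = 1L) {
  cfg <- .default_sim_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config entr", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  for (key in names(config)) cfg[key] <- config[key]
  if (is.null(cfg$n_two_domain_proteins))
    cfg$n_two_domain_proteins <- min(5L, cfg$n_domains %/% 2L)
  if (cfg$n_two_domain_proteins * 2L > cfg$n_domains)
    stop("infeasible config: two-domain proteins need ",
         cfg$n_two_domain_proteins * 2L, " domains but n_domains = ",
         cfg$n_domains)
  n_dom_proteins <- cfg$n_domains - cfg$n_two_domain_proteins
  if (n_dom_proteins + cfg$n_decoys > cfg$n_proteins)
    stop("infeasible config: ", n_dom_proteins, " domain proteins + ",
         cfg$n_decoys, " decoy proteins exceed n_proteins = ", cfg$n_proteins)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  bg <- .background_sampler(cfg)
  types <- names(cfg$type_weights)

  n <- cfg$n_proteins
  ids <- sprintf("SYNP%04d", seq_len(n))
  roles <- rep("none", n)
  shuffled <- sample.int(n)
  two_idx <- shuffled[seq_len(cfg$n_two_domain_proteins)]
  one_idx <- shuffled[cfg$n_two_domain_proteins +
                        seq_len(n_dom_proteins - cfg$n_two_domain_proteins)]
  decoy_idx <- shuffled[n_dom_proteins + seq_len(cfg$n_decoys)]
  roles[two_idx] <- "two"
  roles[one_idx] <- "one"
  roles[decoy_idx] <- "decoy"

  dom_types <- if (cfg$ensure_all_types && cfg$n_domains >= length(types)) {
    c(types, sample(types, cfg$n_domains - length(types), replace = TRUE,
                    prob = cfg$type_weights))
  } else {
    sample(types, cfg$n_domains, replace = TRUE, prob = cfg$type_weights)
  }
  dom_types <- sample(dom_types)

  draw_length <- function(min_needed) {
    L <- round(exp(runif(1, log(cfg$length_range[1]), log(cfg$length_range[2]))))
    max(L, min_needed)
  }
  build_protein <- function(domains) {
    k <- length(domains)
    dlen <- vapply(domains, function(d) nchar(d$sequence), 0L)
    need <- sum(dlen) + (k + 1L) * cfg$flank_min
    L <- draw_length(need)
    extra <- L - sum(dlen) - (k + 1L) * cfg$flank_min
    alloc <- as.integer(rmultinom(1L, extra, rep(1, k + 1L)))
    slots <- cfg$flank_min + alloc
    pieces <- character(2L * k + 1L)
    starts <- integer(k)
    at <- 0L
    for (j in seq_len(k + 1L)) {
      pieces[2L * j - 1L] <- bg(slots[j])
      at <- at + slots[j]
      if (j <= k) {
        starts[j] <- at + 1L
        pieces[2L * j] <- domains[[j]]$sequence
        at <- at + dlen[j]
      }
    }
    list(sequence = paste(pieces, collapse = ""), starts = starts)
  }

  proteins <- character(n)
  truth_dom <- list()
  truth_dec <- list()
  ti <- 0L
  next_type <- 0L
  for (i in seq_len(n)) {
    k <- switch(roles[i], two = 2L, one = 1L, 0L)
    if (k > 0L) {
      doms <- lapply(seq_len(k), function(j) {
        next_type <<- next_type + 1L
        instantiate_consensus(dom_types[next_type])
      })
      built <- build_protein(doms)
      proteins[i] <- built$sequence
      for (j in seq_len(k)) {
        ti <- ti + 1L
        truth_dom[[ti]] <- data.frame(
          protein_id = ids[i], start = built$starts[j],
          type = doms[[j]]$type,
          ml_positions = paste(built$starts[j] - 1L + doms[[j]]$ml_positions,
                               collapse = ","),
          gaps = paste(doms[[j]]$gaps, collapse = ","),
          stringsAsFactors = FALSE)
      }
    } else if (roles[i] == "decoy") {
      src_type <- sample(types, 1L, prob = cfg$type_weights)
      dom <- instantiate_consensus(src_type)
      knocked <- sort(sample.int(8L, cfg$decoy_knockouts))
      chars <- strsplit(dom$sequence, "")[[1]]
      chars[dom$ml_positions[knocked]] <- "A"
      dom$sequence <- paste(chars, collapse = "")
      built <- build_protein(list(dom))
      proteins[i] <- built$sequence
      truth_dec[[length(truth_dec) + 1L]] <- data.frame(
        protein_id = ids[i], start = built$starts[1],
        source_type = src_type,
        ml_positions = paste(built$starts[1] - 1L + dom$ml_positions,
                             collapse = ","),
        knocked = paste(knocked, collapse = ","),
        n_knockouts = cfg$decoy_knockouts,
        stringsAsFactors = FALSE)
    } else {
      L <- draw_length(cfg$flank_min)
      proteins[i] <- bg(L)
    }
  }

  # Tandem clusters: extra proteins appended after the base proteome.
  truth_tan <- list()
  tandem_chrom <- integer(0)
  td <- cfg$tandem
  if (td$n_clusters > 0L) {
    for (cl in seq_len(td$n_clusters)) {
      base_type <- sample(types, 1L, prob = cfg$type_weights)
      dom <- instantiate_consensus(base_type)
      built <- build_protein(list(dom))
      member_seqs <- character(td$cluster_size)
      member_seqs[1] <- built$sequence
      dom_span <- built$starts[1]:(built$starts[1] + nchar(dom$sequence) - 1L)
      for (m in 2:td$cluster_size) {
        chars <- strsplit(built$sequence, "")[[1]]
        outside <- setdiff(seq_along(chars), dom_span)
        nmut <- max(1L, round(td$substitution_rate * length(outside)))
        at <- sample(outside, min(nmut, length(outside)))
        chars[at] <- vapply(chars[at], function(old) {
          .sample1(setdiff(.FILLER_CLEAN, old))
        }, "")
        member_seqs[m] <- paste(chars, collapse = "")
      }
      mem_ids <- sprintf("SYNP%04d", length(proteins) + seq_len(td$cluster_size))
      proteins <- c(proteins, member_seqs)
      ids <- c(ids, mem_ids)
      roles <- c(roles, rep("tandem", td$cluster_size))
      chrom_pick <- sample.int(cfg$n_chromosomes, 1L)
      tandem_chrom <- c(tandem_chrom, rep(chrom_pick, td$cluster_size))
      for (m in seq_len(td$cluster_size)) {
        ti <- ti + 1L
        truth_dom[[ti]] <- data.frame(
          protein_id = mem_ids[m], start = built$starts[1],
          type = base_type,
          ml_positions = paste(built$starts[1] - 1L + dom$ml_positions,
                               collapse = ","),
          gaps = paste(dom$gaps, collapse = ","), stringsAsFactors = FALSE)
        truth_tan[[length(truth_tan) + 1L]] <- data.frame(
          cluster_id = cl, protein_id = mem_ids[m], member_order = m,
          stringsAsFactors = FALSE)
      }
    }
  }

  # Gene models: tandem members adjacent on their chromosome, everyone
  # else placed round the 12 chromosomes in random order.
  n_all <- length(ids)
  chrom <- integer(n_all)
  chrom[seq_len(n)] <- sample.int(cfg$n_chromosomes, n, replace = TRUE)
  if (n_all > n) chrom[(n + 1L):n_all] <- tandem_chrom
  exon_count <- ifelse(runif(n_all) < cfg$intronless_fraction, 1L,
                       1L + sample.int(11L, n_all, replace = TRUE))
  strand <- sample(c("+", "-"), n_all, TRUE)
  gene_rows <- vector("list", n_all)
  for (ch in seq_len(cfg$n_chromosomes)) {
    members <- which(chrom == ch)
    base <- members[members <= n]
    members <- c(base[sample.int(length(base))], members[members > n])
    cur <- sample(10000:50000, 1L)
    for (i in members) {
      cds_len <- 3L * nchar(proteins[i]) + 3L
      span <- cds_len + (exon_count[i] - 1L) * 100L
      gene_rows[[i]] <- data.frame(
        gene_id = sub("SYNP", "SYNG", ids[i]), protein_id = ids[i],
        chromosome = sprintf("chr%02d", ch), start = cur,
        end = cur + span - 1L, strand = strand[i],
        exon_count = exon_count[i], stringsAsFactors = FALSE)
      step <- if (i > n) sample(500:3000, 1L) else sample(2000:30000, 1L)
      cur <- cur + span - 1L + step
    }
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  empty_dom <- data.frame(protein_id = character(0), start = integer(0),
                          type = character(0), ml_positions = character(0),
                          gaps = character(0), stringsAsFactors = FALSE)
  empty_dec <- data.frame(protein_id = character(0), start = integer(0),
                          source_type = character(0),
                          ml_positions = character(0), knocked = character(0),
                          n_knockouts = integer(0), stringsAsFactors = FALSE)
  empty_tan <- data.frame(cluster_id = integer(0), protein_id = character(0),
                          member_order = integer(0), stringsAsFactors = FALSE)
  list(
    proteins = data.frame(id = ids, sequence = proteins,
                          stringsAsFactors = FALSE),
    genes = genes,
    truth = list(
      domains = if (ti) do.call(rbind, truth_dom) else empty_dom,
      decoys = if (length(truth_dec)) do.call(rbind, truth_dec) else empty_dec,
      tandem = if (length(truth_tan)) do.call(rbind, truth_tan) else empty_tan,
      config = cfg, seed = seed))
}
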