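# Genome-level census: per-type/per-chromosome tallies, multi-domain
# proteins, protein physico-chemical statistics, intronless genes, and
# tandem duplicate clusters.

#' Build the gene-family census
#'
#' Aggregates scanner matches and gene models into a census table:
#' per-protein domain counts and type lists, per-type totals (complete
#' domains), per-chromosome totals, single- versus multi-domain protein
#' counts, and the intronless-gene count when exon counts are available.
#'
#' Proteins whose gene model has chromosome `NA` are tallied under
#' `"unplaced"`; chromosome `"0"` (or `"chr0"`) entries are tallied but
#' flagged as excluded from downstream analyses, mirroring the common
#' practice of dropping pseudo-chromosome 0 placements.
#'
#' @param matches Match data.frame from [scan_proteome()].
#' @param genes Gene-model data.frame (see [read_gff3()]) with columns
#'   `gene_id`, `protein_id`, `chromosome`, `start`, `end`, `strand` and
#'   optionally `exon_count`.  May be `NULL`, in which case every protein
#'   is unplaced.  A match whose protein id is absent from `genes` is an
#'   input error.
#' @return A `ring_census` object.
#' @export
build_census <- function(matches, genes = NULL) {
  if (!is.data.frame(matches)) stop("'matches' must be a match data.frame")
  ids <- unique(matches$protein_id)
  if (!is.null(genes)) {
    unknown <- setdiff(ids, genes$protein_id)
    if (length(unknown))
      stop("matches reference protein id(s) with no gene model: ",
           paste(head(unknown, 5), collapse = ", "))
    gmap <- genes[match(ids, genes$protein_id), , drop = FALSE]
  } else {
    gmap <- data.frame(gene_id = rep(NA_character_, length(ids)),
                       protein_id = ids,
                       chromosome = rep(NA_character_, length(ids)),
                       stringsAsFactors = FALSE)
  }
  chrom <- as.character(gmap$chromosome)
  chrom[is.na(chrom) | !nzchar(chrom)] <- "unplaced"
  types <- ring_type_names()

  per_protein <- data.frame(protein_id = ids,
                            gene_id = as.character(gmap$gene_id),
                            chromosome = chrom,
                            stringsAsFactors = FALSE)
  comp <- matches[matches$complete, , drop = FALSE]
  inc <- matches[!matches$complete, , drop = FALSE]
  per_protein$n_complete <- as.integer(
    table(factor(comp$protein_id, levels = ids)))
  per_protein$n_incomplete <- as.integer(
    table(factor(inc$protein_id, levels = ids)))
  ord <- comp[order(match(comp$protein_id, ids), comp$ml1), , drop = FALSE]
  tl <- split(ord$type, factor(ord$protein_id, levels = ids))
  per_protein$types <- vapply(tl, paste, "", collapse = ",")
  per_protein$multi_domain <- per_protein$n_complete >= 2L
  per_protein$excluded <- per_protein$chromosome %in% c("0", "chr0", "unplaced")

  comp_chrom <- per_protein$chromosome[match(comp$protein_id, ids)]
  chrom_levels <- sort(unique(chrom))
  chrom_totals <- data.frame(
    chromosome = chrom_levels,
    n_domains = as.integer(table(factor(comp_chrom, levels = chrom_levels))),
    stringsAsFactors = FALSE)

  intronless <- NA_integer_
  if (!is.null(genes) && "exon_count" %in% names(genes)) {
    ring_genes <- unique(per_protein$gene_id[per_protein$n_complete > 0L])
    intronless <- count_intronless(genes, ring_genes)
  }

  structure(list(
    per_protein = per_protein,
    type_totals = stats::setNames(
      as.integer(table(factor(comp$type, levels = types))), types),
    chrom_totals = chrom_totals,
    n_proteins = length(ids),
    n_domains = nrow(comp),
    n_incomplete = nrow(inc),
    n_single = sum(per_protein$n_complete == 1L),
    n_multi = sum(per_protein$n_complete >= 2L),
    intronless = intronless
  ), class = "ring_census")
}

#' @export
print.ring_census <- function(x, ...) {
  cat("<ring_census> ", x$n_domains, " complete domains in ", x$n_proteins,
      " proteins (", x$n_single, " single-domain, ", x$n_multi,
      " multi-domain); ", x$n_incomplete, " incomplete\n", sep = "")
  cat("  per type: ",
      paste(names(x$type_totals), x$type_totals, sep = "=", collapse = " "),
      "\n", sep = "")
  if (!is.na(x$intronless))
    cat("  intronless RING genes: ", x$intronless, "\n", sep = "")
  invisible(x)
}

#' Count intronless genes among a set of gene ids
#'
#' @param genes Gene-model data.frame with `gene_id` and `exon_count`.
#' @param ring_gene_ids Gene ids of interest (typically RING genes).
#' @return Number of those genes with a single exon.
#' @export
count_intronless <- function(genes, ring_gene_ids) {
  if (!"exon_count" %in% names(genes)) stop("'genes' lacks an exon_count column")
  sel <- genes$gene_id %in% ring_gene_ids
  sum(genes$exon_count[sel] == 1L, na.rm = TRUE)
}

# Average (isotope-averaged) residue masses in Da, and the mass of one
# water added on chain assembly.
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

# Side-chain and termini pKa values (EMBOSS set).  Pinned here so the
# isoelectric point is reproducible; other constant sets shift pI by a
# few tenths of a unit.
.PKA <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
          H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

.net_charge <- function(ph, counts) {
  pos_groups <- c(Nterm = 1, H = counts[["H"]], K = counts[["K"]],
                  R = counts[["R"]])
  neg_groups <- c(Cterm = 1, C = counts[["C"]], D = counts[["D"]],
                  E = counts[["E"]], Y = counts[["Y"]])
  pos <- sum(pos_groups / (1 + 10^(ph - .PKA[names(pos_groups)])))
  neg <- sum(neg_groups / (1 + 10^(.PKA[names(neg_groups)] - ph)))
  pos - neg
}

#' Length, molecular weight and isoelectric point of a protein
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' non-standard letters (X, B, Z, ...) contribute the mean of the 20
#' standard residue masses and are counted in `n_nonstandard`.  The
#' isoelectric point is the unique zero of the Henderson-Hasselbalch net
#' charge (monotonically decreasing in pH), solved by bisection over pH
#' 0..14 to |charge| < 1e-4.
#'
#' @param sequence Amino-acid string.
#' @return List with `length`, `mw` (Da), `pi`, `n_nonstandard`.
#' @export
#' @examples
#' protein_stats("G")$mw   # 57.05 + 18.02
protein_stats <- function(sequence) {
  chars <- .seq_chars(sequence)
  if (!length(chars)) stop("empty sequence")
  std <- chars %in% AA_STANDARD
  mw <- sum(.AA_MASS[chars[std]]) + sum(!std) * mean(.AA_MASS) + .WATER_MASS
  counts <- vapply(c("H", "K", "R", "C", "D", "E", "Y"),
                   function(a) sum(chars == a), 0L)
  lo <- 0; hi <- 14; mid <- 7
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    ch <- .net_charge(mid, as.list(counts))
    if (abs(ch) < 1e-4) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  list(length = length(chars), mw = mw, pi = mid,
       n_nonstandard = sum(!std))
}

#' Global pairwise identity of two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, gap -1
#' (via `Biostrings::pairwiseAlignment`); identity is the number of
#' identical aligned positions divided by the alignment length.
#'
#' @param a,b Non-empty sequences (amino acid or nucleotide).
#' @return Fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  letters <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
  mat <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == sa & pa != "-") / length(pa)
}

#' Detect tandem duplicate clusters of RING genes
#'
#' Walks each chromosome left to right and groups RING genes into runs in
#' which consecutive members are separated by at most `max_intervening`
#' non-RING genes *or* at most `max_distance` bp, and every pair of
#' member proteins has global identity of at least `min_identity`.  This
#' is a documented proximity-plus-identity simplification of collinearity
#' tools such as MCScanX; all three parameters are exposed.  Clusters have
#' at least two members, and the result is invariant to input row order.
#'
#' @param genes All gene models on the genome (data.frame with `gene_id`,
#'   `protein_id`, `chromosome`, `start`, `end`).
#' @param ring_gene_ids Gene ids carrying RING domains.
#' @param sequences Named character vector of protein sequences, named by
#'   `protein_id`, covering the RING genes.
#' @param max_intervening Maximum intervening non-RING genes (default 1).
#' @param max_distance Maximum genomic separation in bp (default 1e5).
#' @param min_identity Minimum pairwise protein identity (default 0.7).
#' @return Data.frame (`cluster_id`, `chromosome`, `gene_id`,
#'   `member_order`), zero rows when no cluster is found; the rule
#'   parameters are attached as the `"params"` attribute.
#' @export
find_tandem_clusters <- function(genes, ring_gene_ids, sequences,
                                 max_intervening = 1L, max_distance = 1e5,
                                 min_identity = 0.7) {
  g <- genes[order(genes$chromosome, genes$start, genes$gene_id), , drop = FALSE]
  g$is_ring <- g$gene_id %in% ring_gene_ids
  clusters <- list()
  cid <- 0L
  for (chr in unique(g$chromosome)) {
    gc <- g[g$chromosome == chr, , drop = FALSE]
    ring_idx <- which(gc$is_ring)
    if (length(ring_idx) < 2L) next
    cur <- ring_idx[1]
    emit <- function(members) {
      if (length(members) >= 2L) {
        cid <<- cid + 1L
        clusters[[cid]] <<- data.frame(
          cluster_id = cid, chromosome = chr,
          gene_id = gc$gene_id[members],
          member_order = seq_along(members), stringsAsFactors = FALSE)
      }
    }
    for (j in ring_idx[-1]) {
      prev <- cur[length(cur)]
      intervening <- sum(!gc$is_ring[seq(prev + 1L, j - 1L)[seq_len(max(0L, j - prev - 1L))]])
      distance <- gc$start[j] - gc$end[prev]
      prox_ok <- intervening <= max_intervening || distance <= max_distance
      ident_ok <- prox_ok && all(vapply(cur, function(i) {
        pairwise_identity(sequences[[gc$protein_id[i]]],
                          sequences[[gc$protein_id[j]]]) >= min_identity
      }, TRUE))
      if (prox_ok && ident_ok) {
        cur <- c(cur, j)
      } else {
        emit(cur)
        cur <- j
      }
    }
    emit(cur)
  }
  out <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = integer(0), chromosome = character(0),
               gene_id = character(0), member_order = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "params") <- list(max_intervening = max_intervening,
                              max_distance = max_distance,
                              min_identity = min_identity)
  out
}
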