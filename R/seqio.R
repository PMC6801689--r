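# Readers/writers for FASTA, GFF3 and the pipeline's own report tables.
# Coordinates in all files and reports are 1-based inclusive (GFF3
# convention), matching the package's internal convention.

#' Read a FASTA file into a record data.frame
#'
#' Handles single-line and multi-line dialects; a trailing `*`
#' (translation stop) is stripped from each sequence; duplicate ids and
#' empty files are errors.  The record id is the first whitespace-
#' delimited token of the header.
#'
#' @param path FASTA file.
#' @param alphabet `"AA"` (default) or `"DNA"`.
#' @return Data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- if (alphabet == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("no sequence records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- sub("\\*+$", "", as.character(x))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records Data.frame with `id` and `sequence`, or a named
#'   character vector.
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.data.frame(records))
    records <- stats::setNames(records$sequence, records$id)
  set <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`/`transcript`, `exon` and `CDS` features
#' (1-based inclusive coordinates) and returns one row per mRNA with its
#' exon count.  Files without CDS features are tolerated; a non-comment
#' line with the wrong column count is an error.  Only the `ID`/`Parent`
#' attributes are interpreted.
#'
#' @param path GFF3 file.
#' @return Data.frame with columns `gene_id`, `protein_id`, `chromosome`,
#'   `start`, `end`, `strand`, `exon_count` (NA when no exon features are
#'   present for the mRNA).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 9L))
    stop("malformed GFF3: line(s) with ", paste(unique(nf[nf != 9L]),
         collapse = "/"), " column(s) instead of 9 in ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$Parent <- vapply(as.list(df$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (!nrow(mrna)) {
    # Degenerate files with bare genes: treat each gene as its own mRNA.
    mrna <- genes
    mrna$Parent <- mrna$ID
  }
  exons <- df[df$type == "exon", , drop = FALSE]
  ex_tab <- table(exons$Parent)
  gidx <- match(mrna$Parent, genes$ID)
  out <- data.frame(
    gene_id = ifelse(is.na(gidx), mrna$Parent, genes$ID[gidx]),
    protein_id = as.character(mrna$ID),
    chromosome = as.character(mrna$seqnames),
    start = as.integer(ifelse(is.na(gidx), mrna$start, genes$start[gidx])),
    end = as.integer(ifelse(is.na(gidx), mrna$end, genes$end[gidx])),
    strand = as.character(mrna$strand),
    exon_count = as.integer(ex_tab[as.character(mrna$ID)]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features per gene-model row.  Exon
#' coordinates are synthesised deterministically by splitting the gene
#' span into `exon_count` pieces separated by fixed-length introns, so a
#' write/read round trip preserves gene id, protein id, coordinates,
#' strand and exon count.
#'
#' @param genes Gene-model data.frame (see [read_gff3()] for columns).
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "ringcensus") {
  g <- genes[order(genes$chromosome, genes$start, genes$gene_id), , drop = FALSE]
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    lines <- c(lines,
      paste(r$chromosome, source, "gene", r$start, r$end, ".", r$strand, ".",
            paste0("ID=", r$gene_id), sep = "\t"),
      paste(r$chromosome, source, "mRNA", r$start, r$end, ".", r$strand, ".",
            paste0("ID=", r$protein_id, ";Parent=", r$gene_id), sep = "\t"))
    nex <- max(1L, as.integer(r$exon_count %||% 1L), na.rm = TRUE)
    span <- r$end - r$start + 1L
    intron <- if (nex > 1L) min(100L, (span - nex) %/% (nex - 1L)) else 0L
    exonic <- span - (nex - 1L) * intron
    base <- exonic %/% nex
    rem <- exonic %% nex
    at <- r$start
    for (e in seq_len(nex)) {
      len <- base + (e <= rem)
      lines <- c(lines,
        paste(r$chromosome, source, "exon", at, at + len - 1L, ".", r$strand,
              ".", paste0("ID=", r$protein_id, ".exon", e, ";Parent=",
                          r$protein_id), sep = "\t"))
      at <- at + len + intron
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  path
}

#' Write the census report tables
#'
#' Emits deterministic tab-separated tables (fixed column orders, fixed
#' row ordering, percentages to one decimal): `matches.tsv`,
#' `census_proteins.tsv`, `census_types.tsv`, `census_chromosomes.tsv`,
#' `census_summary.tsv`, plus `spacing.tsv` and `profile.tsv` when the
#' corresponding statistics are supplied.
#'
#' @param census A [build_census()] result.
#' @param matches Match data.frame.
#' @param dir Output directory (created if needed).
#' @param spacing Optional long data.frame of spacing tallies
#'   (`pair`, `gap`, `count`).
#' @param profile Optional [conservation_profile()].
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(census, matches, dir, spacing = NULL,
                          profile = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  m <- matches[order(matches$protein_id, matches$ml1), , drop = FALSE]
  files <- c(files, .write_tsv(
    m[c("protein_id", "type", "complete", "candidate_type", "violated_ml",
        paste0("ml", 1:8), paste0("gap", 1:7), "residues")],
    file.path(dir, "matches.tsv")))
  pp <- census$per_protein[order(census$per_protein$protein_id), , drop = FALSE]
  files <- c(files, .write_tsv(pp, file.path(dir, "census_proteins.tsv")))
  tt <- data.frame(type = names(census$type_totals),
                   n = as.integer(census$type_totals),
                   percent = format_percent(
                     if (census$n_domains) census$type_totals / census$n_domains
                     else rep(0, length(census$type_totals))),
                   stringsAsFactors = FALSE)
  files <- c(files, .write_tsv(tt, file.path(dir, "census_types.tsv")))
  files <- c(files, .write_tsv(census$chrom_totals,
                               file.path(dir, "census_chromosomes.tsv")))
  summ <- data.frame(
    key = c("n_proteins", "n_domains", "n_incomplete", "n_single_domain",
            "n_multi_domain", "n_intronless_ring_genes"),
    value = c(census$n_proteins, census$n_domains, census$n_incomplete,
              census$n_single, census$n_multi, census$intronless),
    stringsAsFactors = FALSE)
  files <- c(files, .write_tsv(summ, file.path(dir, "census_summary.tsv")))
  if (!is.null(spacing))
    files <- c(files, .write_tsv(spacing, file.path(dir, "spacing.tsv")))
  if (!is.null(profile))
    files <- c(files, .write_tsv(profile$freq, file.path(dir, "profile.tsv")))
  invisible(files)
}

#' Long-format spacing table over all seven ligand pairs
#'
#' Convenience wrapper around [spacing_histogram()] producing the
#' `spacing.tsv` report table.
#'
#' @param matches Match data.frame.
#' @return Data.frame with `pair`, `gap`, `count`.
#' @export
spacing_table <- function(matches) {
  rows <- lapply(1:7, function(i) {
    h <- spacing_histogram(matches, i)
    if (!length(h$counts))
      return(data.frame(pair = character(0), gap = integer(0),
                        count = integer(0), stringsAsFactors = FALSE))
    data.frame(pair = h$pair, gap = as.integer(names(h$counts)),
               count = as.integer(h$counts), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
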