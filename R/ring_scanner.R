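# Scanning protein sequences for complete and incomplete RING domains.
#
# Coordinates are 1-based throughout (R convention); gaps[i] is the number
# of residues strictly between ml_i and ml_{i+1}, i.e.
# gap[i] = pos[i+1] - pos[i] - 1.

.seq_chars <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string")
  strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
}

# Depth-first enumeration of octet positions compatible with one spec,
# allowing up to `max_violations` residue-set failures (gap constraints are
# always enforced strictly: an incomplete domain is modelled as a residue
# substitution, never a deleted position).  Returns a list of
# list(pos = int[8], viol = int[] of violated ml indices).
#
# A missing serine for a Ser-requiring spec counts as one violation,
# attributed to the last Ser-eligible position, unless one of those
# positions is already violated (then the rule is unverifiable and waived).
.enumerate_spec <- function(chars, spec, max_violations = 0L) {
  n <- length(chars)
  ok <- lapply(spec$residues, function(set) chars %in% set)
  out <- list()
  cnt <- 0L
  visit <- function(pos, viols) {
    lvl <- length(pos)
    if (lvl == 8L) {
      v <- viols
      if (length(spec$require_ser_at) &&
          !any(spec$require_ser_at %in% v) &&
          !any(chars[pos[spec$require_ser_at]] == "S")) {
        v <- c(v, max(spec$require_ser_at))
        if (length(v) > max_violations) return(invisible(NULL))
      }
      cnt <<- cnt + 1L
      out[[cnt]] <<- list(pos = pos, viol = v)
      return(invisible(NULL))
    }
    nxt <- pos[lvl] + spec$gaps[[lvl]] + 1L
    nxt <- nxt[nxt <= n]
    if (!length(nxt)) return(invisible(NULL))
    hit <- ok[[lvl + 1L]][nxt]
    for (q in nxt[hit]) visit(c(pos, q), viols)
    if (length(viols) < max_violations)
      for (q in nxt[!hit]) visit(c(pos, q), c(viols, lvl + 1L))
  }
  for (p in which(ok[[1L]])) visit(p, integer(0))
  if (max_violations > 0L)
    for (p in which(!ok[[1L]])) visit(p, 1L)
  out
}

.empty_matches <- function() {
  df <- data.frame(protein_id = character(0), type = character(0),
                   complete = logical(0), candidate_type = character(0),
                   violated_ml = character(0), residues = character(0),
                   start = integer(0), end = integer(0),
                   stringsAsFactors = FALSE)
  for (i in 1:8) df[[paste0("ml", i)]] <- integer(0)
  for (i in 1:7) df[[paste0("gap", i)]] <- integer(0)
  df[c("protein_id", "type", "complete", "candidate_type", "violated_ml",
       paste0("ml", 1:8), paste0("gap", 1:7), "start", "end", "residues")]
}

# Assemble a candidate data.frame from .enumerate_spec hits.
.hits_frame <- function(hits, chars, spec_name) {
  if (!length(hits)) return(NULL)
  posmat <- do.call(rbind, lapply(hits, `[[`, "pos"))
  viol <- vapply(hits, function(h) paste(h$viol, collapse = ","), "")
  df <- as.data.frame(posmat)
  names(df) <- paste0("ml", 1:8)
  for (i in 1:7) df[[paste0("gap", i)]] <- df[[i + 1L]] - df[[i]] - 1L
  df$candidate_type <- spec_name
  df$violated_ml <- viol
  df$n_viol <- lengths(lapply(hits, `[[`, "viol"))
  df$residues <- apply(posmat, 1L, function(p) paste(chars[p], collapse = ""))
  df$start <- df$ml1
  df$end <- df$ml8
  df$span <- df$ml8 - df$ml1
  df
}

#' Enumerate all spec-satisfying octets in a sequence
#'
#' Exhaustively lists every 8-tuple of positions whose residues and gaps
#' satisfy some built-in RING grammar, including overlapping alternatives.
#' This is the raw candidate set that [scan_protein()] resolves into a
#' non-overlapping match set.
#'
#' @param sequence Amino-acid string.
#' @param specs Spec registry (default built-ins).
#' @return A data.frame with columns `type`, `ml1`..`ml8` (1-based
#'   positions), `gap1`..`gap7`, `residues`, `start`, `end`, `span`,
#'   ordered by `ml1`, then span, then registry order.
#' @export
enumerate_octets <- function(sequence, specs = builtin_specs()) {
  chars <- .seq_chars(sequence)
  frames <- list()
  for (spec in specs) {
    df <- .hits_frame(.enumerate_spec(chars, spec, 0L), chars, spec$name)
    if (!is.null(df)) frames[[length(frames) + 1L]] <- df
  }
  if (!length(frames)) {
    out <- .empty_matches()
    out$type <- out$candidate_type
    out$span <- integer(0)
    return(out[c("type", paste0("ml", 1:8), paste0("gap", 1:7),
                 "residues", "start", "end", "span")])
  }
  df <- do.call(rbind, frames)
  df$type <- df$candidate_type
  rank <- match(df$candidate_type, vapply(specs, function(s) s$name, ""))
  df <- df[order(df$ml1, df$span, rank), , drop = FALSE]
  rownames(df) <- NULL
  df[c("type", paste0("ml", 1:8), paste0("gap", 1:7),
       "residues", "start", "end", "span")]
}

# Greedy overlap resolution: repeatedly keep the candidate with the
# leftmost ml1 (ties: smaller span, then registry order of its grammar)
# and drop every candidate sharing a residue index with it.  With rows
# pre-sorted in that order this reduces to a left-to-right sweep.
.select_nonoverlapping <- function(df, specs = builtin_specs()) {
  if (!nrow(df)) return(df)
  rank <- match(df$candidate_type, vapply(specs, function(s) s$name, ""))
  df <- df[order(df$ml1, df$ml8 - df$ml1, rank), , drop = FALSE]
  keep <- logical(nrow(df))
  max_end <- -1L
  for (i in seq_len(nrow(df))) {
    if (df$ml1[i] > max_end) {
      keep[i] <- TRUE
      max_end <- max(max_end, df$ml8[i])
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.finish_matches <- function(df, id, complete) {
  df$protein_id <- id
  df$complete <- complete
  if (complete) {
    df$type <- df$candidate_type
    df$violated_ml <- ""
  } else {
    df$type <- "incomplete"
  }
  rownames(df) <- NULL
  df[c("protein_id", "type", "complete", "candidate_type", "violated_ml",
       paste0("ml", 1:8), paste0("gap", 1:7), "start", "end", "residues")]
}

#' Scan one protein for complete RING domains
#'
#' Enumerates all spec-satisfying octets and resolves overlaps greedily by
#' (leftmost ml1, smallest span, registry order), yielding a maximal set of
#' mutually non-overlapping complete matches.  A protein may carry any
#' number of domains.
#'
#' @param sequence Amino-acid string.
#' @param id Protein identifier attached to each match.
#' @param specs Spec registry.
#' @return A match data.frame (zero rows when nothing is found) with
#'   columns `protein_id`, `type`, `complete`, `candidate_type`,
#'   `violated_ml`, `ml1`..`ml8`, `gap1`..`gap7`, `start`, `end`,
#'   `residues`.
#' @export
scan_protein <- function(sequence, id = "protein", specs = builtin_specs()) {
  chars <- .seq_chars(sequence)
  frames <- list()
  for (spec in specs) {
    df <- .hits_frame(.enumerate_spec(chars, spec, 0L), chars, spec$name)
    if (!is.null(df)) frames[[length(frames) + 1L]] <- df
  }
  if (!length(frames)) return(.empty_matches())
  sel <- .select_nonoverlapping(do.call(rbind, frames), specs)
  .finish_matches(sel, id, complete = TRUE)
}

#' Find incomplete RING domains in one protein
#'
#' Reports octet candidates that satisfy some grammar's gap constraints and
#' all but a small number of residue constraints (default: exactly one),
#' do not overlap any complete match, and are mutually non-overlapping.
#' A "lacking" metal-ligand is modelled as a residue substitution at that
#' position; gap constraints stay strict.
#'
#' @inheritParams scan_protein
#' @param complete Output of [scan_protein()] for the same sequence.
#' @param max_violations Maximum number of violated metal-ligands to
#'   report (default 1; candidates with more violations are dropped as
#'   too promiscuous to call without structural corroboration).
#' @return A match data.frame with `type = "incomplete"`, the grammar that
#'   nearly matched in `candidate_type`, and the violated metal-ligand
#'   indices (comma-separated) in `violated_ml`.
#' @export
find_incomplete <- function(sequence, id = "protein", complete = NULL,
                            max_violations = 1L, specs = builtin_specs()) {
  chars <- .seq_chars(sequence)
  max_violations <- as.integer(max_violations)
  if (max_violations < 1L) stop("'max_violations' must be >= 1")
  if (is.null(complete)) complete <- scan_protein(sequence, id, specs)
  frames <- list()
  for (spec in specs) {
    df <- .hits_frame(.enumerate_spec(chars, spec, max_violations),
                      chars, spec$name)
    if (!is.null(df)) frames[[length(frames) + 1L]] <- df
  }
  if (!length(frames)) return(.empty_matches())
  df <- do.call(rbind, frames)
  df <- df[df$n_viol >= 1L & df$n_viol <= max_violations, , drop = FALSE]
  if (!nrow(df)) return(.empty_matches())
  # The same damaged octet can nearly-match several grammars; keep one
  # report per position-octet, preferring the earliest grammar in the
  # registry.
  rank <- match(df$candidate_type, vapply(specs, function(s) s$name, ""))
  df <- df[order(df$ml1, df$ml8 - df$ml1, rank), , drop = FALSE]
  key <- apply(df[paste0("ml", 1:8)], 1L, paste, collapse = ":")
  df <- df[!duplicated(key), , drop = FALSE]
  # Never overlap a complete match.
  if (nrow(complete)) {
    clash <- vapply(seq_len(nrow(df)), function(i) {
      any(df$ml1[i] <= complete$ml8 & df$ml8[i] >= complete$ml1)
    }, TRUE)
    df <- df[!clash, , drop = FALSE]
  }
  if (!nrow(df)) return(.empty_matches())
  sel <- .select_nonoverlapping(df, specs)
  .finish_matches(sel, id, complete = FALSE)
}

#' Scan a whole proteome
#'
#' Runs [scan_protein()] (and, optionally, [find_incomplete()]) on every
#' record and concatenates the results in input order, matches ordered by
#' ml1 within each protein.
#'
#' @param proteins A data.frame with columns `id` and `sequence` (as
#'   returned by [read_fasta()] or [generate_proteome()]), or a named
#'   character vector of sequences.
#' @param include_incomplete Also report incomplete domains?
#' @param max_violations Passed to [find_incomplete()].
#' @param specs Spec registry.
#' @param verbose Log per-type tallies with `message()`?
#' @return A match data.frame over all proteins.
#' @export
scan_proteome <- function(proteins, include_incomplete = TRUE,
                          max_violations = 1L, specs = builtin_specs(),
                          verbose = FALSE) {
  if (is.character(proteins))
    proteins <- data.frame(id = names(proteins), sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  if (!is.data.frame(proteins) || !all(c("id", "sequence") %in% names(proteins)))
    stop("'proteins' must have columns 'id' and 'sequence'")
  if (anyDuplicated(proteins$id))
    stop("duplicate protein id(s): ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "))
  res <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    comp <- scan_protein(proteins$sequence[i], proteins$id[i], specs)
    if (include_incomplete) {
      inc <- find_incomplete(proteins$sequence[i], proteins$id[i], comp,
                             max_violations, specs)
      comp <- rbind(comp, inc)
    }
    res[[i]] <- comp
  }
  out <- do.call(rbind, c(res, list(.empty_matches())))
  rownames(out) <- NULL
  if (verbose) {
    tal <- table(factor(out$type,
                        levels = c(vapply(specs, function(s) s$name, ""),
                                   "incomplete")))
    message("scan_proteome: ", nrow(proteins), " proteins, ",
            sum(out$complete), " complete + ", sum(!out$complete),
            " incomplete domains [",
            paste(names(tal), tal, sep = "=", collapse = " "), "]")
  }
  out
}
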