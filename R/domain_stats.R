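# Spacing-variation statistics and positional conservation profiles.

.pair_index <- function(pair) {
  if (is.numeric(pair)) {
    i <- as.integer(pair)
    if (is.na(i) || i < 1L || i > 7L) stop("pair index must be in 1..7")
    return(i)
  }
  i <- match(pair, ML_PAIR_LABELS)
  if (is.na(i)) stop("unknown metal-ligand pair label: '", pair,
                     "' (expected one of ", paste(ML_PAIR_LABELS, collapse = ", "), ")")
  i
}

.complete_matches <- function(matches) {
  if (!is.data.frame(matches)) stop("'matches' must be a match data.frame")
  matches[matches$complete, , drop = FALSE]
}

#' Tally inter-ligand spacing over a set of domains
#'
#' @param matches Match data.frame from [scan_proteome()]; only complete
#'   matches are tallied.
#' @param pair Pair label (`"ml2-ml3"`, ...) or index 1..7.
#' @param type Optional RING type restriction (e.g. `"RING-H2"`).
#' @return A `spacing_histogram`: counts of domains per gap length.
#' @export
spacing_histogram <- function(matches, pair, type = NULL) {
  i <- .pair_index(pair)
  m <- .complete_matches(matches)
  if (!is.null(type)) m <- m[m$type == type, , drop = FALSE]
  g <- m[[paste0("gap", i)]]
  counts <- table(g)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(pair = ML_PAIR_LABELS[i], type = type %||% "all",
                 counts = counts, n = length(g)),
            class = "spacing_histogram")
}

#' @export
print.spacing_histogram <- function(x, ...) {
  cat("<spacing_histogram> ", x$pair, " (", x$type, "), n = ", x$n, "\n", sep = "")
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Modal spacing of a histogram
#'
#' Ties break toward the smaller gap, for deterministic reporting.
#'
#' @param hist A [spacing_histogram()].
#' @return Named integer vector `c(gap = , count = )`.
#' @export
modal_spacing <- function(hist) {
  if (!inherits(hist, "spacing_histogram")) stop("'hist' must be a spacing_histogram")
  if (!length(hist$counts)) stop("empty spacing histogram")
  gaps <- as.integer(names(hist$counts))
  best <- which(hist$counts == max(hist$counts))
  pick <- best[which.min(gaps[best])]
  c(gap = gaps[pick], count = hist$counts[[pick]])
}

#' Fraction of domains with spacing in a given value set
#'
#' @inheritParams spacing_histogram
#' @param values Integer set of accepted gap lengths.
#' @return Fraction in `[0, 1]` (exact ratio of counts).
#' @export
spacing_fraction <- function(matches, pair, values, type = NULL) {
  i <- .pair_index(pair)
  m <- .complete_matches(matches)
  if (!is.null(type)) m <- m[m$type == type, , drop = FALSE]
  if (!nrow(m)) stop("no complete matches to tally")
  g <- m[[paste0("gap", i)]]
  sum(g %in% as.integer(values)) / length(g)
}

#' Format a fraction as a percentage with one decimal
#' @param x Fraction in `[0, 1]`.
#' @return Character, e.g. `"97.7"`.
#' @export
format_percent <- function(x) sprintf("%.1f", 100 * x)

#' Positional conservation profile around the metal-ligands
#'
#' Computes residue frequencies at fixed signed offsets around each
#' metal-ligand, anchored per-domain on the actual ligand indices so that
#' variable gaps never misalign columns.  An offset cell is skipped for a
#' domain when it falls outside the sequence or crosses into an adjacent
#' metal-ligand position (offsets never reach past the neighbouring
#' ligand).
#'
#' @param matches Complete match data.frame.
#' @param sequences Named character vector (or data.frame with `id`,
#'   `sequence`) giving the protein sequences referenced by the matches.
#' @param window Integer offset range around each ligand, default -2..+4.
#' @param type RING type restriction or `"all"` (default).
#' @return A `conservation_profile` with a long data.frame `freq`
#'   (`ml`, `offset`, `residue`, `count`, `freq`); frequencies at each
#'   (ml, offset) cell sum to 1 over the domains covering the cell.
#' @export
conservation_profile <- function(matches, sequences, window = c(-2L, 4L),
                                 type = "all") {
  if (is.data.frame(sequences))
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  m <- .complete_matches(matches)
  if (!identical(type, "all")) m <- m[m$type == type, , drop = FALSE]
  missing <- setdiff(unique(m$protein_id), names(sequences))
  if (length(missing))
    stop("matches reference sequences not supplied: ",
         paste(head(missing, 5), collapse = ", "))
  offsets <- as.integer(window[1]):as.integer(window[2])
  recs <- list()
  k <- 0L
  for (r in seq_len(nrow(m))) {
    chars <- .seq_chars(sequences[[m$protein_id[r]]])
    pos <- as.integer(m[r, paste0("ml", 1:8)])
    for (i in 1:8) {
      lo <- if (i > 1L) pos[i - 1L] else 0L
      hi <- if (i < 8L) pos[i + 1L] else length(chars) + 1L
      for (off in offsets) {
        p <- pos[i] + off
        if (p <= lo || p >= hi) next
        k <- k + 1L
        recs[[k]] <- c(i, off, chars[p])
      }
    }
  }
  if (k) {
    df <- data.frame(ml = as.integer(vapply(recs, `[`, "", 1L)),
                     offset = as.integer(vapply(recs, `[`, "", 2L)),
                     residue = vapply(recs, `[`, "", 3L),
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            df[c("ml", "offset", "residue")], sum)
    tot <- stats::aggregate(list(total = agg$count), agg[c("ml", "offset")], sum)
    agg <- merge(agg, tot, by = c("ml", "offset"))
    agg$freq <- agg$count / agg$total
    agg$total <- NULL
    agg <- agg[order(agg$ml, agg$offset, agg$residue), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(ml = integer(0), offset = integer(0),
                      residue = character(0), count = integer(0),
                      freq = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(type = type, window = c(min(offsets), max(offsets)),
                 freq = agg, n_domains = nrow(m)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> type = ", x$type, ", ", x$n_domains,
      " domains, offsets ", x$window[1], "..", x$window[2], "\n", sep = "")
  invisible(x)
}

#' Frequency vector at one (metal-ligand, offset) cell
#'
#' @param profile A [conservation_profile()].
#' @param ml Metal-ligand index 1..8.
#' @param offset Signed offset.
#' @return Named numeric vector of residue frequencies (sums to 1), or an
#'   empty vector when no domain covers the cell.
#' @export
profile_frequency <- function(profile, ml, offset) {
  f <- profile$freq
  f <- f[f$ml == ml & f$offset == offset, , drop = FALSE]
  stats::setNames(f$freq, f$residue)
}

#' Information content of a residue frequency vector
#'
#' `log2(alphabet) - H(p)` in bits, the column height used in sequence
#' logos.
#'
#' @param freq Numeric frequency vector summing to 1.
#' @param alphabet_size Alphabet size (20 for amino acids).
#' @return Bits, in `[0, log2(alphabet_size)]`.
#' @export
information_content <- function(freq, alphabet_size = 20L) {
  if (any(freq < 0)) stop("negative frequencies")
  if (abs(sum(freq) - 1) > 1e-6) stop("frequency vector does not sum to 1")
  p <- freq[freq > 0]
  log2(alphabet_size) - (-sum(p * log2(p)))
}
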