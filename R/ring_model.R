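# Consensus grammar for RING zinc-finger domains.
#
# A RING domain is summarised by an octet of metal-ligand residues
# (ml1..ml8, the zinc-coordinating Cys/His positions) and the seven
# inter-ligand spacings.  Each RING type is a "spec": eight allowed
# residue sets plus seven allowed gap sets.

#' Construct a RING domain type specification
#'
#' A `ring_spec` encodes one row of the consensus grammar: the allowed
#' one-letter residues at each of the eight metal-ligand positions
#' (ml1..ml8) and the allowed number of intervening residues for each of
#' the seven consecutive ligand pairs (ml1-ml2 .. ml7-ml8).
#'
#' @param name Type name, e.g. `"RING-H2"`.
#' @param residues List of 8 character vectors of allowed residues.
#' @param gaps List of 7 integer vectors of allowed gap lengths
#'   (number of residues strictly between consecutive metal-ligands).
#' @param require_ser_at Optional integer vector of metal-ligand indices
#'   of which at least one must carry a serine (used by RING-S/T, whose
#'   members substitute Ser for Cys at ml2 or ml6).
#' @return An object of class `ring_spec`.
#' @export
ring_spec <- function(name, residues, gaps, require_ser_at = integer(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  if (length(residues) != 8L)
    stop("a ring_spec needs exactly 8 residue sets (got ", length(residues), ")")
  if (length(gaps) != 7L)
    stop("a ring_spec needs exactly 7 gap sets (got ", length(gaps), ")")
  residues <- lapply(residues, function(r) {
    r <- sort(unique(toupper(as.character(r))))
    if (!length(r) || !all(r %in% AA_STANDARD))
      stop("residue sets must be non-empty subsets of the 20 standard amino acids")
    r
  })
  gaps <- lapply(gaps, function(g) {
    g <- sort(unique(as.integer(g)))
    if (!length(g) || anyNA(g) || any(g < 0L))
      stop("gap sets must be non-empty sets of non-negative integers")
    g
  })
  require_ser_at <- sort(unique(as.integer(require_ser_at)))
  if (length(require_ser_at) && !all(require_ser_at %in% 1:8))
    stop("'require_ser_at' must index metal-ligand positions 1..8")
  structure(list(name = name, residues = residues, gaps = gaps,
                 require_ser_at = require_ser_at),
            class = "ring_spec")
}

#' @export
print.ring_spec <- function(x, ...) {
  res <- vapply(x$residues, paste, "", collapse = "/")
  gap <- vapply(x$gaps, .format_int_set, "")
  consensus <- paste(res[1], paste0("x", gap), c(res[-1], ""), collapse = " ")
  cat("<ring_spec> ", x$name, "\n  ", trimws(consensus), "\n", sep = "")
  if (length(x$require_ser_at))
    cat("  requires Ser at one of ml", paste(x$require_ser_at, collapse = "/ml"), "\n",
        sep = "")
  invisible(x)
}

.ring_cache <- new.env(parent = emptyenv())

#' Built-in RING type specifications
#'
#' Returns the seven RING domain grammars observed in the tomato proteome,
#' in fixed reporting order (RING-H2 first).  The order is *not* a matching
#' priority: the seven grammars are pairwise exclusive, discriminated by
#' the (ml4, ml5) residue pair -- (H,H) = H2, (H,C) = HC, (C,H) = v,
#' (C,C) = C2, (H,G) = G -- by the ml7-ml8 gap for HCa versus HCb, and by
#' the mandatory serine of RING-S/T.
#'
#' Every built-in spec fixes the ml1-ml2 and ml5-ml6 spacings at exactly
#' two residues; the ml2-ml3 and ml6-ml7 loops are the variable ones.
#'
#' The RING-D type (known from *Arabidopsis*) has no grammar here because
#' it does not occur in tomato; see [ring_d_spec()].
#'
#' @return A list of 7 [ring_spec] objects.
#' @export
#' @examples
#' length(builtin_specs())
#' builtin_specs()[["RING-G"]]
builtin_specs <- function() {
  if (is.null(.ring_cache$specs)) {
    .ring_cache$specs <- list(
      ring_spec("RING-H2",
                residues = list("C", "C", "C", "H", "H", "C", "C", "C"),
                gaps = list(2L, 11:33, 1L, 2:3, 2L, 7:64, 2L)),
      ring_spec("RING-HCa",
                residues = list("C", "C", "C", "H", "C", "C", "C", "C"),
                gaps = list(2L, 10:33, 1:3, 2:3, 2L, 6:30, 2L)),
      ring_spec("RING-HCb",
                residues = list("C", "C", "C", "H", "C", "C", "C", "C"),
                gaps = list(2L, 11:18, 1:2, 2L, 2L, 7:19, 3:4)),
      ring_spec("RING-v",
                residues = list("C", "C", "C", "C", "H", "C", "C", "C"),
                gaps = list(2L, 8:29, 1:4, c(4:7, 9L), 2L, 9:36, 2L)),
      ring_spec("RING-C2",
                residues = list("C", "C", "C", "C", "C", "C", "C", "C"),
                gaps = list(2L, 7:16, 1:3, 4L, 2L, 10:16, 2L)),
      ring_spec("RING-S/T",
                residues = list("C", c("C", "S"), "C", "H", "C", c("C", "S"),
                                "C", "C"),
                gaps = list(2L, c(11L, 14L), 1L, 2:3, 2L, c(10L, 14L), 2L),
                require_ser_at = c(2L, 6L)),
      ring_spec("RING-G",
                residues = list("C", "C", "C", "H", "G", "C", "C", "C"),
                gaps = list(2L, 16L, 1L, 2L, 2L, 13L, 2L))
    )
    names(.ring_cache$specs) <-
      vapply(.ring_cache$specs, function(s) s$name, "")
  }
  .ring_cache$specs
}

#' Names of the built-in RING types, in reporting order
#' @return Character vector of length 7.
#' @export
ring_type_names <- function() names(builtin_specs())

#' RING-D placeholder
#'
#' RING-D, present in *Arabidopsis*, is not detected in tomato and ships
#' only as this disabled stub.  Users wanting to scan for it can define a
#' custom grammar and load it with [read_ring_specs()].
#'
#' @export
ring_d_spec <- function() {
  stop("RING-D is not part of the built-in grammar set (not observed in ",
       "tomato); supply a custom spec via read_ring_specs() to scan for it.",
       call. = FALSE)
}

# Validate and normalise an octet candidate.
.as_octet <- function(residues, gaps) {
  residues <- toupper(as.character(residues))
  if (length(residues) != 8L || any(nchar(residues) != 1L))
    stop("an octet candidate has exactly 8 single-letter residues")
  gaps <- as.integer(gaps)
  if (length(gaps) != 7L || anyNA(gaps) || any(gaps < 0L))
    stop("an octet candidate has exactly 7 non-negative finite gaps")
  list(residues = residues, gaps = gaps)
}

# Fast inner matcher; assumes validated inputs.  Non-standard letters
# (X, B, Z, U, *) never satisfy a metal-ligand constraint because specs
# only contain standard residues.
.octet_matches <- function(spec, residues, gaps) {
  for (i in 1:8) if (!(residues[i] %in% spec$residues[[i]])) return(FALSE)
  for (i in 1:7) if (!(gaps[i] %in% spec$gaps[[i]])) return(FALSE)
  if (length(spec$require_ser_at) &&
      !any(residues[spec$require_ser_at] == "S")) return(FALSE)
  TRUE
}

#' Test an octet candidate against one RING type specification
#'
#' @param spec A [ring_spec].
#' @param residues 8 one-letter amino acids at ml1..ml8 (case-insensitive).
#' @param gaps 7 non-negative integers, residues between consecutive
#'   metal-ligands.
#' @return `TRUE` iff every residue lies in its allowed set, every gap in
#'   its allowed set, and any serine requirement is met.
#' @export
#' @examples
#' sp <- builtin_specs()[["RING-H2"]]
#' match_spec(sp, c("C","C","C","H","H","C","C","C"), c(2,14,1,2,2,10,2))
match_spec <- function(spec, residues, gaps) {
  if (!inherits(spec, "ring_spec")) stop("'spec' must be a ring_spec")
  oct <- .as_octet(residues, gaps)
  .octet_matches(spec, oct$residues, oct$gaps)
}

#' Classify an octet candidate into a RING type
#'
#' Returns the unique built-in type matched by the candidate, or
#' `NA_character_` when none matches.  The built-in grammars are pairwise
#' exclusive, so at most one can match; more than one match signals a
#' corrupted spec registry and raises an error.
#'
#' @inheritParams match_spec
#' @param specs Spec registry to classify against (default: the built-ins).
#' @return A type name or `NA_character_`.
#' @export
#' @examples
#' classify_octet(c("C","C","C","H","G","C","C","C"), c(2,16,1,2,2,13,2))
classify_octet <- function(residues, gaps, specs = builtin_specs()) {
  oct <- .as_octet(residues, gaps)
  hit <- NA_character_
  for (spec in specs) {
    if (.octet_matches(spec, oct$residues, oct$gaps)) {
      if (!is.na(hit))
        stop("spec registry conflict: octet matches both '", hit, "' and '",
             spec$name, "'")
      hit <- spec$name
    }
  }
  hit
}

# ---- plain-text (de)serialisation of spec profiles ----

# "2", "11-33", "2,3", "4-7,9"
.format_int_set <- function(v) {
  v <- sort(unique(as.integer(v)))
  runs <- split(v, cumsum(c(1L, diff(v) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) > 2L) paste0(r[1], "-", r[length(r)]) else paste(r, collapse = ",")
  }, ""), collapse = ",")
}

.parse_int_set <- function(s) {
  parts <- strsplit(trimws(s), ",", fixed = TRUE)[[1]]
  out <- unlist(lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (length(ab) != 2L || anyNA(ab)) stop("malformed integer range: '", p, "'")
      ab[1]:ab[2]
    } else {
      x <- as.integer(p)
      if (is.na(x)) stop("malformed integer: '", p, "'")
      x
    }
  }))
  sort(unique(out))
}

#' Write RING specs to a plain-text profile file
#'
#' The format is a simple INI-style key-value profile so users can add
#' custom domain grammars:
#' ```
#' [RING-H2]
#' ml = C | C | C | H | H | C | C | C
#' gaps = 2 | 11-33 | 1 | 2,3 | 2 | 7-64 | 2
#' ```
#' Residue alternatives are separated by `/` (e.g. `C/S`); gap sets use
#' ranges (`11-33`) and comma lists (`2,3`).  An optional
#' `require_ser_at = 2,6` line encodes a mandatory serine.
#'
#' @param specs List of [ring_spec] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ring_specs <- function(specs, path) {
  lines <- c("# ringcensus RING domain grammar profile")
  for (spec in specs) {
    stopifnot(inherits(spec, "ring_spec"))
    lines <- c(lines, "",
               paste0("[", spec$name, "]"),
               paste("ml =", paste(vapply(spec$residues, paste, "",
                                          collapse = "/"), collapse = " | ")),
               paste("gaps =", paste(vapply(spec$gaps, .format_int_set, ""),
                                     collapse = " | ")))
    if (length(spec$require_ser_at))
      lines <- c(lines, paste("require_ser_at =",
                              paste(spec$require_ser_at, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read RING specs from a plain-text profile file
#'
#' @param path Profile file written by [write_ring_specs()] (or by hand,
#'   in the same format).
#' @return Named list of [ring_spec] objects.
#' @export
read_ring_specs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  specs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$ml) || is.null(cur$gaps))
      stop("spec '", cur$name, "' is missing an 'ml' or 'gaps' line")
    ring_spec(cur$name,
              residues = lapply(strsplit(cur$ml, "|", fixed = TRUE)[[1]],
                                function(s) strsplit(trimws(s), "/", fixed = TRUE)[[1]]),
              gaps = lapply(strsplit(cur$gaps, "|", fixed = TRUE)[[1]],
                            .parse_int_set),
              require_ser_at = if (is.null(cur$require_ser_at)) integer(0)
                               else .parse_int_set(cur$require_ser_at))
  }
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      sp <- flush(cur)
      if (!is.null(sp)) specs[[sp$name]] <- sp
      cur <- list(name = sub("^\\[(.*)\\]$", "\\1", ln))
    } else {
      if (is.null(cur)) stop("key-value line outside a [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed line: ", ln)
      cur[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  sp <- flush(cur)
  if (!is.null(sp)) specs[[sp$name]] <- sp
  if (!length(specs)) stop("no specs found in ", path)
  specs
}
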