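# Nei-Gojobori (1986) synonymous/nonsynonymous rate estimation with
# Jukes-Cantor multiple-hit correction.

.NT <- c("A", "C", "G", "T")

.codon_split <- function(cds, what = "CDS") {
  cds <- toupper(as.character(cds))
  if (length(cds) != 1L || !nzchar(cds)) stop("empty ", what)
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  if (length(chars) %% 3L != 0L)
    stop(what, " length (", length(chars), ") is not divisible by 3")
  if (!all(chars %in% .NT))
    stop(what, " contains non-ACGT characters")
  codons <- apply(matrix(chars, nrow = 3L), 2L, paste, collapse = "")
  aa <- Biostrings::GENETIC_CODE[codons]
  if (any(aa == "*"))
    stop(what, " contains stop codon(s) at codon position(s) ",
         paste(which(aa == "*"), collapse = ", "),
         "; strip terminal stops before calling")
  codons
}

.ng_cache <- new.env(parent = emptyenv())

# Fractional synonymous/nonsynonymous site counts for every sense codon:
# each of the three positions contributes (synonymous single-nucleotide
# changes)/3 to S; changes to stop codons count as nonsynonymous.
.codon_site_table <- function() {
  if (is.null(.ng_cache$sites)) {
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    tab <- matrix(0, nrow = length(sense), ncol = 2L,
                  dimnames = list(sense, c("S", "N")))
    for (codon in sense) {
      chars <- strsplit(codon, "")[[1]]
      s <- 0
      for (pos in 1:3) {
        for (alt in setdiff(.NT, chars[pos])) {
          mut <- chars
          mut[pos] <- alt
          mutc <- paste(mut, collapse = "")
          if (gc[[mutc]] != "*" && gc[[mutc]] == gc[[codon]]) s <- s + 1 / 3
        }
      }
      tab[codon, ] <- c(s, 3 - s)
    }
    .ng_cache$sites <- tab
  }
  .ng_cache$sites
}

#' NG86 synonymous and nonsynonymous site counts of one CDS
#'
#' @param cds In-frame coding sequence (ACGT, length divisible by 3, no
#'   stop codons).
#' @return Named numeric vector `c(S = , N = )`; `S + N` equals the
#'   nucleotide length.
#' @export
#' @examples
#' ng86_sites("ATG")  # Met: S = 0, N = 3
ng86_sites <- function(cds) {
  codons <- .codon_split(cds)
  tab <- .codon_site_table()
  c(S = sum(tab[codons, "S"]), N = sum(tab[codons, "N"]))
}

.PERMS <- list(matrix(1L), rbind(c(1L, 2L), c(2L, 1L)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Average synonymous/nonsynonymous difference counts between two codons
# over all mutational pathways (orderings of the differing positions).
# Pathways passing through a stop codon are excluded; when every pathway
# is blocked (possible only for 2-3 differences between codons adjacent
# to stops), all pathways are used as a documented fallback.
.codon_path_diffs <- function(a, b) {
  if (a == b) return(c(0, 0))
  gc <- Biostrings::GENETIC_CODE
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  perms <- .PERMS[[length(pos)]]
  walk <- function(order, allow_stop) {
    cur <- ca
    sd <- 0; nd <- 0
    for (p in pos[order]) {
      nxt <- cur
      nxt[p] <- cb[p]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && !allow_stop) return(NULL)
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- lapply(seq_len(nrow(perms)),
                  function(i) walk(perms[i, ], allow_stop = FALSE))
  paths <- paths[!vapply(paths, is.null, TRUE)]
  if (!length(paths))
    paths <- lapply(seq_len(nrow(perms)),
                    function(i) walk(perms[i, ], allow_stop = TRUE))
  colMeans(do.call(rbind, paths))
}

#' NG86 Ka/Ks for a pre-aligned pair of coding sequences
#'
#' Site counts are averaged over the two sequences; per-codon differences
#' are partitioned into synonymous and nonsynonymous by averaging over all
#' orderings of multi-site codon differences (pathways through stop codons
#' excluded).  Proportions are Jukes-Cantor corrected,
#' `K = -3/4 * log(1 - 4p/3)`; a proportion at or beyond the 3/4
#' saturation bound leaves the corrected rate `NA` and sets the
#' `saturated` flag.  The Ka/Ks ratio is defined only when `Ks > 0`.
#'
#' @param cds1,cds2 Equal-length in-frame coding sequences (aligned;
#'   aligning unequal pairs is the caller's job).
#' @return A `kaks_result` list: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `Ka`,
#'   `Ks`, `ratio`, `saturated`.
#' @export
ng86_kaks <- function(cds1, cds2) {
  co1 <- .codon_split(cds1, "cds1")
  co2 <- .codon_split(cds2, "cds2")
  if (length(co1) != length(co2))
    stop("coding sequences differ in length (", 3 * length(co1), " vs ",
         3 * length(co2), " nt); align them first")
  tab <- .codon_site_table()
  S <- (sum(tab[co1, "S"]) + sum(tab[co2, "S"])) / 2
  N <- (sum(tab[co1, "N"]) + sum(tab[co2, "N"])) / 2
  d <- vapply(seq_along(co1),
              function(i) .codon_path_diffs(co1[i], co2[i]), numeric(2))
  Sd <- sum(d[1, ])
  Nd <- sum(d[2, ])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(ps)
  Ka <- jc(pn)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ka = Ka, Ks = Ks, ratio = ratio,
                 saturated = ps >= 3 / 4 || pn >= 3 / 4),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ka=%s Ks=%s ratio=%s%s\n",
              x$S, x$N, x$Sd, x$Nd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Selection regime implied by a Ka/Ks ratio
#'
#' @param result A [ng86_kaks()] result.
#' @return `"purifying"` (ratio < 1), `"neutral"` (= 1), `"positive"`
#'   (> 1), or `"undefined"` when the ratio is undefined.
#' @export
classify_selection <- function(result) {
  r <- result$ratio
  if (is.null(r) || is.na(r)) return("undefined")
  if (r < 1) "purifying" else if (r > 1) "positive" else "neutral"
}
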