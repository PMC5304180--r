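# Modification-mass bookkeeping and enzyme-specific in-silico digestion.

# IUPAC monoisotopic atomic masses (Da), >= 6 decimals so rounded peptide and
# modification masses are bit-stable across platforms.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

# Elemental composition of each amino-acid residue (peptide-bond residue, i.e.
# the free amino acid minus one water).
.RESIDUE_COMPOSITION <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  D = c(C = 4, H = 5, N = 1, O = 3),
  E = c(C = 5, H = 7, N = 1, O = 3),
  F = c(C = 9, H = 9, N = 1, O = 1),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  R = c(C = 6, H = 12, N = 4, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2)
)

.AA_LETTERS <- sort(names(.RESIDUE_COMPOSITION))

#' Parse an elemental composition string
#'
#' Converts a Hill-style composition string such as `"C3H4OS"` into a named
#' integer vector of element counts. An element symbol without a trailing
#' number counts once.
#'
#' @param x Composition string, e.g. `"C15H23N3O3S3"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_composition("C3H4OS")
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x), length(x) <= 1L)
  if (length(x) == 0L || !nzchar(x)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse composition string: '", x, "'")
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(sub("^[A-Z][a-z]?", "", paste0(parts, "")))
  n[is.na(n)] <- 1L
  out <- tapply(n, el, sum)
  structure(as.integer(out), names = names(out))
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums element counts times monoisotopic atomic masses. Accepts either a
#' named count vector (`c(C = 3, H = 4, O = 1, S = 1)`) or a composition
#' string (`"C3H4OS"`).
#'
#' @param composition Named numeric vector of element counts, or a single
#'   composition string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C3H4OS")      # thioacyl lysine label, 87.998 Da
#' monoisotopic_mass(c(H = 2, O = 1)) # water
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_composition(composition)
  if (length(composition) == 0L) return(0)
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named element -> count vector")
  }
  unknown <- setdiff(names(composition), names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(composition < 0)) stop("element counts must be non-negative")
  sum(.ATOMIC_MASS[names(composition)] * composition)
}

#' Table of lysine/cysteine modifications left by cleavable surface biotinylation
#'
#' Modifications produced by sulfo-NHS-SS-biotin labeling followed by
#' reductive or alkylative processing, with elemental compositions and masses
#' recomputed from monoisotopic atomic masses. The `note` column records
#' literature-rounding discrepancies (Thio(NEM) is commonly quoted as
#' 213.045 Da; its composition sums to 213.046 Da).
#'
#' The same table ships as a user-extensible TSV under
#' `system.file("extdata", "modifications.tsv", package = "topolabel")`.
#'
#' @return `data.frame` with columns `name`, `target` (`K`, `protein-N-term`
#'   or `C`), `composition`, `monoisotopic_mass` (Da) and `note`.
#' @export
modification_table <- function() {
  path <- system.file("extdata", "modifications.tsv", package = "topolabel")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$monoisotopic_mass <- vapply(tab$composition, monoisotopic_mass, numeric(1))
  tab
}

.get_modification <- function(name) {
  tab <- modification_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown modification: '", name, "'")
  tab[i, , drop = FALSE]
}

#' Monoisotopic mass of a peptide with optional modifications
#'
#' Residue masses are summed from elemental compositions, one water is added
#' for the termini, and modification masses are added on top. Modifications
#' are checked for target compatibility: a `K`-targeted modification must sit
#' on a lysine, `protein-N-term` on offset 1, `C` on a cysteine.
#'
#' @param sequence Peptide string over the 20 one-letter codes.
#' @param modifications Optional list of `list(offset =, name =)` entries,
#'   `name` being a row of [modification_table()].
#' @return Monoisotopic peptide mass in Da.
#' @examples
#' peptide_mass("G") # 75.032
#' @export
peptide_mass <- function(sequence, modifications = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, .AA_LETTERS)
  if (length(bad)) stop("illegal residue(s) in peptide: ", paste(unique(bad), collapse = ", "))
  mass <- sum(vapply(aa, function(a) monoisotopic_mass(.RESIDUE_COMPOSITION[[a]]), numeric(1)))
  mass <- mass + monoisotopic_mass(c(H = 2, O = 1))
  for (mod in modifications) {
    def <- .get_modification(mod$name)
    off <- mod$offset
    if (off < 1L || off > length(aa)) stop("modification offset out of range: ", off)
    ok <- switch(def$target,
      "K" = aa[off] == "K",
      "protein-N-term" = off == 1L,
      "C" = aa[off] == "C",
      stop("unknown modification target: ", def$target)
    )
    if (!ok) {
      stop("modification '", mod$name, "' (target ", def$target,
           ") incompatible with residue ", aa[off], " at offset ", off)
    }
    mass <- mass + def$monoisotopic_mass
  }
  mass
}

.ENZYME_RULES <- list(
  trypsin      = list(residues = c("K", "R"), side = "C", no_before_P = TRUE),
  chymotrypsin = list(residues = c("F", "W", "Y", "L"), side = "C", no_before_P = TRUE),
  thermolysin  = list(residues = c("A", "F", "I", "L", "M", "V"), side = "N", no_before_P = FALSE)
)

#' Construct a protease digestion rule
#'
#' @param enzyme One of `"trypsin"` (cleaves C-terminal to K/R, not before P),
#'   `"chymotrypsin"` (C-terminal to F/W/Y/L, not before P) or
#'   `"thermolysin"` (N-terminal to A/F/I/L/M/V).
#' @param max_missed Maximum number of missed cleavage sites per peptide.
#' @param specificity `"full"` for fully specific peptides, `"semi"` to
#'   additionally enumerate peptides with one ragged (non-enzymatic) end.
#' @return A `digest_rule` object.
#' @export
digest_rule <- function(enzyme = c("trypsin", "chymotrypsin", "thermolysin"),
                        max_missed = 0L, specificity = c("full", "semi")) {
  enzyme <- match.arg(enzyme)
  specificity <- match.arg(specificity)
  max_missed <- as.integer(max_missed)
  if (max_missed < 0L) stop("max_missed must be >= 0")
  structure(list(enzyme = enzyme, max_missed = max_missed,
                 specificity = specificity),
            class = "digest_rule")
}

# 0-based cut points: a cut after sequence position i (between i and i+1)
.cleavage_sites <- function(aa, enzyme) {
  rule <- .ENZYME_RULES[[enzyme]]
  L <- length(aa)
  if (L < 2L) return(integer(0))
  if (rule$side == "C") {
    cut <- which(aa[-L] %in% rule$residues)
    if (rule$no_before_P) cut <- cut[aa[cut + 1L] != "P"]
  } else {
    # N-side cleavage: cut before a matching residue
    cut <- which(aa[-1L] %in% rule$residues)
  }
  cut
}

#' Enzyme-specific in-silico digestion
#'
#' Enumerates the peptides a protease produces from a protein sequence, for
#' 0..`max_missed` missed cleavage sites; in semi-specific mode additionally
#' every peptide with exactly one ragged (non-enzymatic) end. Coordinates are
#' 1-based inclusive.
#'
#' @param sequence Protein sequence string.
#' @param rule A [digest_rule()].
#' @return `data.frame` with columns `peptide`, `start`, `end`, `missed`
#'   (internal missed cleavages) and `specific` (`"full"` or `"semi"`),
#'   sorted by `start` then `end`, duplicates removed.
#' @examples
#' digest("AKRGK", digest_rule("trypsin"))
#' @export
digest <- function(sequence, rule) {
  stopifnot(inherits(rule, "digest_rule"))
  if (!nzchar(sequence)) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0),
                      specific = character(0), stringsAsFactors = FALSE))
  }
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  sites <- .cleavage_sites(aa, rule$enzyme)
  bounds <- c(0L, sites, L)           # peptide boundaries as 0-based cuts
  nb <- length(bounds)
  starts <- integer(0); ends <- integer(0); missed <- integer(0); spec <- character(0)
  # fully specific: boundary pair with <= max_missed internal sites
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + rule$max_missed)
    for (j in (i + 1L):jmax) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
      missed <- c(missed, j - i - 1L)
      spec <- c(spec, "full")
    }
  }
  if (rule$specificity == "semi") {
    n_internal <- function(s, e) sum(sites > s - 1L & sites < e)
    # ragged right end: start at a boundary, end anywhere
    for (i in seq_len(nb - 1L)) {
      s <- bounds[i] + 1L
      for (e in s:L) {
        if (e %in% bounds) next
        if (n_internal(s, e) > rule$max_missed) break
        starts <- c(starts, s); ends <- c(ends, e)
        missed <- c(missed, n_internal(s, e)); spec <- c(spec, "semi")
      }
    }
    # ragged left end: end at a boundary, start anywhere
    for (j in 2L:nb) {
      e <- bounds[j]
      for (s in e:1L) {
        if ((s - 1L) %in% bounds) next
        if (n_internal(s, e) > rule$max_missed) break
        starts <- c(starts, s); ends <- c(ends, e)
        missed <- c(missed, n_internal(s, e)); spec <- c(spec, "semi")
      }
    }
  }
  out <- data.frame(
    peptide = substring(sequence, starts, ends),
    start = starts, end = ends, missed = missed, specific = spec,
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
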