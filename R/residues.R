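#' Canonical residue identifiers
#'
#' Residues are identified throughout the package by the string
#' `"<chain>:<author number><insertion code>"`, e.g. `"A:70"` or `"A:52B"`.
#' Author numbering from the source file is kept verbatim; no renumbering is
#' ever performed.
#'
#' @param chain chain label(s).
#' @param number author residue sequence number(s), integer.
#' @param insert insertion code(s); `""` or `NA` when absent.
#' @return character vector of canonical residue ids.
#' @examples
#' residue_id("A", 70)            # "A:70"
#' residue_id("R", 52, "B")       # "R:52B"
#' @export
residue_id <- function(chain, number, insert = "") {
  insert <- ifelse(is.na(insert), "", insert)
  paste0(chain, ":", as.integer(number), insert)
}

#' Split canonical residue ids into chain / number / insertion code
#'
#' @param ids character vector of ids as produced by [residue_id()].
#' @return data.frame with columns `id`, `chain`, `number`, `insert`.
#' @export
parse_residue_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):(-?[0-9]+)([A-Za-z]?)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed residue id(s): ", paste(ids[bad], collapse = ", "))
  data.frame(
    id     = ids,
    chain  = vapply(m, `[`, "", 2L),
    number = as.integer(vapply(m, `[`, "", 3L)),
    insert = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# "32-227,267-342" (or a list of c(lo, hi)) -> list of inclusive ranges
parse_residue_ranges <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    stopifnot(all(vapply(x, length, 1L) == 2L))
    return(lapply(x, function(r) as.integer(sort(r))))
  }
  if (is.numeric(x) && length(x) == 2L) return(list(as.integer(sort(x))))
  parts <- strsplit(as.character(x), ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    lohi <- as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]])
    if (length(lohi) == 1L) lohi <- c(lohi, lohi)
    if (length(lohi) != 2L || anyNA(lohi)) stop("bad residue range: ", p)
    sort(lohi)
  })
}

in_ranges <- function(number, ranges) {
  if (is.null(ranges)) return(rep(TRUE, length(number)))
  hit <- rep(FALSE, length(number))
  for (r in ranges) hit <- hit | (number >= r[1] & number <= r[2])
  hit
}

# one- to three-letter amino-acid codes (for anchor presets)
AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
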