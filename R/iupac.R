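# IUPAC nucleotide algebra: the 15 ambiguity symbols, degeneracy, expansion,
# set -> code lookup and reverse complement.  These primitives underlie the
# degenerate consensus and everything downstream of it.

# Code table taken from Biostrings; base letters put in canonical ACGT order
# so that set keys are stable.
.iupac_init <- function() {
    map <- Biostrings::IUPAC_CODE_MAP
    canon <- vapply(strsplit(map, ""), function(b)
        paste(c("A", "C", "G", "T")[c("A", "C", "G", "T") %in% b],
              collapse = ""), character(1))
    names(canon) <- names(map)
    canon
}

.iupac <- new.env(parent = emptyenv())

.iupac_map <- function() {
    if (is.null(.iupac$map)) {
        .iupac$map <- .iupac_init()
        .iupac$rev <- structure(names(.iupac$map), names = .iupac$map)
        .iupac$size <- nchar(.iupac$map)
    }
    .iupac$map
}

#' IUPAC symbols and their base sets
#'
#' @return Named character vector mapping each of the 15 IUPAC nucleotide
#'   symbols to its set of plain bases (e.g. `R` -> `"AG"`).
#' @examples
#' iupac_codes()[["R"]]
#' @export
iupac_codes <- function() .iupac_map()

.check_iupac <- function(chars, context = "sequence") {
    bad <- setdiff(unique(chars), names(.iupac_map()))
    if (length(bad) > 0L)
        stop(sprintf("invalid character(s) in %s: %s", context,
                     paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    invisible(TRUE)
}

#' Degeneracy of an IUPAC string
#'
#' The degeneracy of a degenerate oligonucleotide is the number of distinct
#' plain-ACGT sequences it represents: the product over positions of the
#' size of each position's IUPAC base set.
#'
#' @param seq A gap-free IUPAC string (single character scalar or vector).
#' @return Numeric vector of degeneracies (exact integers; doubles are used
#'   so that long windows do not overflow).
#' @examples
#' degeneracy_of("ACGT")  # 1
#' degeneracy_of("ARN")   # 8
#' @export
degeneracy_of <- function(seq) {
    stopifnot(is.character(seq))
    map <- .iupac_map()
    vapply(seq, function(s) {
        if (!nzchar(s)) stop("empty sequence", call. = FALSE)
        chars <- strsplit(s, "")[[1]]
        .check_iupac(chars)
        prod(.iupac$size[match(chars, names(map))])
    }, numeric(1), USE.NAMES = FALSE)
}

#' Expand a degenerate IUPAC string to its plain-ACGT sequences
#'
#' @param seq A gap-free IUPAC string.
#' @param cap Safety cap on the number of expansions; expansion refuses to
#'   enumerate more (default 2000, matching the default maximum degeneracy).
#' @return Character vector of all distinct ACGT expansions, sorted; its
#'   length equals `degeneracy_of(seq)`.
#' @examples
#' iupac_expand("AR")  # "AA" "AG"
#' @export
iupac_expand <- function(seq, cap = 2000) {
    stopifnot(is.character(seq), length(seq) == 1L)
    d <- degeneracy_of(seq)
    if (d > cap)
        stop(sprintf("degeneracy %.0f exceeds expansion cap %.0f", d, cap),
             call. = FALSE)
    map <- .iupac_map()
    sets <- strsplit(unname(map[strsplit(seq, "")[[1]]]), "")
    out <- ""
    for (s in sets) out <- as.vector(t(outer(out, s, paste0)))
    sort(out)
}

#' IUPAC code for a set of bases
#'
#' @param bases Character vector: a nonempty subset of A, C, G, T
#'   (duplicates allowed and ignored).
#' @return The single IUPAC symbol whose base set equals `bases`.
#' @examples
#' code_for_set(c("A", "G"))  # "R"
#' @export
code_for_set <- function(bases) {
    .iupac_map()
    bases <- unique(bases)
    if (length(bases) == 0L) stop("empty base set", call. = FALSE)
    if (!all(bases %in% c("A", "C", "G", "T")))
        stop("bases must be a subset of {A, C, G, T}", call. = FALSE)
    key <- paste(c("A", "C", "G", "T")[c("A", "C", "G", "T") %in% bases],
                 collapse = "")
    unname(.iupac$rev[key])
}

.comp_from <- "ACGTRYKMBDHVSWN-"
.comp_to   <- "TGCAYRMKVHDBSWN-"

#' Reverse complement of an IUPAC string
#'
#' Ambiguity codes are complemented set-wise (R <-> Y, K <-> M, B <-> V,
#' D <-> H; S, W and N are self-complementary).  A gap character `-` is
#' passed through, so gapped alignment rows can also be flipped.
#'
#' @param seq IUPAC string (scalar or vector).
#' @return Reverse-complemented string(s).
#' @examples
#' reverse_complement("GATTACA")  # "TGTAATC"
#' @export
reverse_complement <- function(seq) {
    stopifnot(is.character(seq))
    for (s in seq) .check_iupac(setdiff(strsplit(s, "")[[1]], "-"))
    comp <- chartr(.comp_from, .comp_to, seq)
    vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""),
           character(1), USE.NAMES = FALSE)
}
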