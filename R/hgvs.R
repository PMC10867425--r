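# HGVS protein-level (p.) notation: parsing and loss-of-function classification.

AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Glu = "E",
  Gln = "Q", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*", Xaa = "X"
)

.aa_token_to_1 <- function(tok) {
  if (tok %in% AA3_TO_1) return(tok)                    # already one-letter
  key <- paste0(toupper(substr(tok, 1, 1)), tolower(substr(tok, 2, 3)))
  if (key %in% names(AA3_TO_1)) return(unname(AA3_TO_1[key]))
  NA_character_
}

# one- or three-letter amino-acid token (three-letter case-insensitive)
.AA_RX <- "([ARNDCEQGHILKMFPSTWYVX]|[A-Za-z]{3})"

#' Parse an HGVS protein-consequence string
#'
#' Accepts the common protein-level dialect used in population-database
#' exports: stop-gain (\code{"Q1012*"}), frameshift with novel-tail length
#' (\code{"L7Qfs*21"}), start-loss (\code{"M1?"}), missense
#' (\code{"V5M"}) and synonymous (\code{"K7="}). One- and three-letter
#' amino-acid codes are both accepted, as are optional \code{"p."} and
#' parenthesis wrappers (\code{"p.(Q1012*)"}).
#'
#' For truncating classes the derived lengths follow the HGVS semantics:
#' a stop at residue k retains k-1 wild-type residues and adds no novel
#' tail; a frameshift \code{"fs*N"} starting at residue k retains k-1
#' wild-type residues and appends N-1 novel residues before the new stop,
#' for a truncated total of k-1+N-1 residues.
#'
#' @param notation single non-empty character string.
#' @return an object of class \code{protein_consequence}: a list with
#'   \code{class} (one of \code{stop_gain, frameshift, start_loss,
#'   missense, synonymous, other}), \code{first_affected_residue},
#'   \code{retained_wt_length}, \code{novel_tail_length},
#'   \code{truncated_total_length} (\code{NA} for non-truncating classes),
#'   \code{ref_aa}, \code{alt_aa} and the normalized \code{notation}.
#' @examples
#' parse_hgvs_p("Q1012*")$truncated_total_length   # 1011
#' parse_hgvs_p("L7Qfs*21")$truncated_total_length # 26
#' parse_hgvs_p("Met1?")$class                     # start_loss
#' @export
parse_hgvs_p <- function(notation) {
  if (length(notation) != 1L || is.na(notation) || !nzchar(notation))
    stop("parse_hgvs_p: notation must be a single non-empty string")
  raw <- notation
  s <- gsub("∗|✱", "*", notation)       # typographic asterisks
  s <- sub("^p\\.", "", trimws(s))
  s <- gsub("^\\(|\\)$", "", s)
  if (!nzchar(s)) stop("parse_hgvs_p: empty notation after removing wrappers")

  mk <- function(class, pos, ref = NA_character_, alt = NA_character_,
                 retained = NA_integer_, tail = NA_integer_, total = NA_integer_) {
    structure(list(class = class, first_affected_residue = pos,
                   retained_wt_length = retained, novel_tail_length = tail,
                   truncated_total_length = total,
                   ref_aa = ref, alt_aa = alt, notation = raw),
              class = "protein_consequence")
  }
  chk_pos <- function(pos) {
    if (is.na(pos) || pos < 1L)
      stop("parse_hgvs_p: residue position must be >= 1 in '", raw, "'")
    pos
  }

  # start-loss: M1? / Met1?
  if (grepl("^(M|Met)1\\?$", s))
    return(mk("start_loss", 1L, ref = "M"))

  # frameshift: <aa><pos><aa>fs*<N>  (the new-frame aa is optional)
  m <- regmatches(s, regexec(paste0("^", .AA_RX, "([0-9]+)", .AA_RX,
                                    "?fs\\*([0-9]+)$"), s))[[1]]
  if (length(m)) {
    ref <- .aa_token_to_1(m[2])
    alt <- if (nzchar(m[4])) .aa_token_to_1(m[4]) else NA_character_
    if (is.na(ref)) stop("parse_hgvs_p: unknown amino-acid token '", m[2],
                         "' in '", raw, "'")
    pos <- chk_pos(as.integer(m[3])); n <- as.integer(m[5])
    if (n < 1L) stop("parse_hgvs_p: fs*N needs N >= 1 in '", raw, "'")
    return(mk("frameshift", pos, ref, alt,
              retained = pos - 1L, tail = n - 1L, total = pos - 1L + n - 1L))
  }

  # stop-gain: <aa><pos>(*|Ter|X)
  m <- regmatches(s, regexec(paste0("^", .AA_RX, "([0-9]+)(\\*|Ter|X)$"), s))[[1]]
  if (length(m)) {
    ref <- .aa_token_to_1(m[2])
    if (is.na(ref)) stop("parse_hgvs_p: unknown amino-acid token '", m[2],
                         "' in '", raw, "'")
    pos <- chk_pos(as.integer(m[3]))
    return(mk("stop_gain", pos, ref, alt = "*",
              retained = pos - 1L, tail = 0L, total = pos - 1L))
  }

  # synonymous: <aa><pos>=
  m <- regmatches(s, regexec(paste0("^", .AA_RX, "([0-9]+)=$"), s))[[1]]
  if (length(m)) {
    ref <- .aa_token_to_1(m[2])
    if (is.na(ref)) stop("parse_hgvs_p: unknown amino-acid token '", m[2],
                         "' in '", raw, "'")
    pos <- chk_pos(as.integer(m[3]))
    return(mk("synonymous", pos, ref, alt = ref))
  }

  # missense: <aa><pos><aa>; unknown trailing tokens (del, dup, ...) fall
  # through to the "other" class below
  m <- regmatches(s, regexec(paste0("^", .AA_RX, "([0-9]+)", .AA_RX, "$"), s))[[1]]
  if (length(m) && !is.na(.aa_token_to_1(m[2])) && !is.na(.aa_token_to_1(m[4]))) {
    ref <- .aa_token_to_1(m[2]); alt <- .aa_token_to_1(m[4])
    pos <- chk_pos(as.integer(m[3]))
    if (identical(ref, alt)) return(mk("synonymous", pos, ref, alt))
    return(mk("missense", pos, ref, alt))
  }

  # recognizable residue+position but unsupported trailing syntax -> "other"
  m <- regmatches(s, regexec(paste0("^", .AA_RX, "([0-9]+)"), s))[[1]]
  if (length(m) && !is.na(.aa_token_to_1(m[2]))) {
    pos <- chk_pos(as.integer(m[3]))
    warning("parse_hgvs_p: unsupported variant syntax '", raw,
            "', classified as 'other'")
    return(mk("other", pos, ref = .aa_token_to_1(m[2])))
  }

  stop("parse_hgvs_p: cannot parse '", raw, "' (offending token: '", s, "')")
}

#' Format a protein consequence back to canonical one-letter HGVS p. notation
#'
#' @param x a \code{protein_consequence} from \code{\link{parse_hgvs_p}}.
#' @return canonical string, e.g. \code{"Q1012*"}, \code{"L7Qfs*21"}.
#' @export
format_hgvs_p <- function(x) {
  stopifnot(inherits(x, "protein_consequence"))
  pos <- x$first_affected_residue
  switch(x$class,
    stop_gain  = paste0(x$ref_aa, pos, "*"),
    frameshift = paste0(x$ref_aa, pos,
                        if (!is.na(x$alt_aa)) x$alt_aa else "",
                        "fs*", x$novel_tail_length + 1L),
    start_loss = "M1?",
    missense   = paste0(x$ref_aa, pos, x$alt_aa),
    synonymous = paste0(x$ref_aa, pos, "="),
    other      = x$notation
  )
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence> ", format_hgvs_p(x), " [", x$class, "]\n", sep = "")
  if (x$class %in% c("stop_gain", "frameshift"))
    cat("  retained WT: ", x$retained_wt_length,
        "  novel tail: ", x$novel_tail_length,
        "  truncated total: ", x$truncated_total_length, "\n", sep = "")
  invisible(x)
}

#' Classify a protein consequence as loss-of-function
#'
#' Premature-stop consequences (stop-gain and frameshift) are truncating;
#' loss of the initiator methionine is its own class; everything else is
#' treated as non-LoF at the protein-annotation level.
#'
#' @param x a \code{protein_consequence}.
#' @return one of \code{"truncating"}, \code{"start_loss"}, \code{"non_lof"}.
#' @export
classify_lof <- function(x) {
  stopifnot(inherits(x, "protein_consequence"))
  switch(x$class,
    stop_gain = , frameshift = "truncating",
    start_loss = "start_loss",
    "non_lof"
  )
}
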