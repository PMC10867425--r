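# Truncated-isoform prediction: Kozak-consensus alternative-start scanning,
# retained/removed feature reporting and predicted fusion-protein masses.

#' Kozak context around an ATG within a coding sequence
#'
#' Returns the 10-character context covering positions -6..+4 relative to
#' the A of the ATG (A = +1). Positions falling outside the sequence are
#' reported as \code{"-"} and count as mismatches when scoring.
#'
#' @param cds coding sequence (A/C/G/T string).
#' @param nt_position 1-based position of the A of the ATG.
#' @return list with \code{context} (10 chars), \code{strength}
#'   (\code{strong}: purine at -3 and G at +4; \code{adequate}: exactly one
#'   of the two; \code{weak}: neither) and \code{score}, the number of
#'   matches (0..7) to the gccRccATGG consensus over the informative
#'   non-ATG positions.
#' @export
kozak_context <- function(cds, nt_position) {
  n <- nchar(cds)
  at <- function(i) if (i >= 1 && i <= n) substr(cds, i, i) else "-"
  idx <- (nt_position - 6):(nt_position + 3)   # -6..-1, +1..+4
  chars <- vapply(idx, at, character(1))
  context <- paste(chars, collapse = "")
  minus3 <- chars[4]
  plus4 <- chars[10]
  purine3 <- minus3 %in% c("A", "G")
  g4 <- plus4 == "G"
  strength <- if (purine3 && g4) "strong" else if (xor(purine3, g4)) "adequate" else "weak"
  # consensus gccRcc ATGG: informative positions -6,-5,-4,-2,-1 (g,c,c,c,c),
  # -3 (purine), +4 (G)
  score <- sum(chars[c(1, 2, 3, 5, 6)] == c("G", "C", "C", "C", "C")) +
    purine3 + g4
  list(context = context, strength = strength, score = as.integer(score))
}

#' Scan a CDS for in-frame downstream translation-initiation sites
#'
#' Finds every in-frame ATG at or after \code{min_codon} whose Kozak
#' context meets the requested stringency. Only in-frame starts are
#' reported because an out-of-frame initiation cannot produce an
#' N-terminally truncated isoform of the annotated protein. Stringency is
#' nested: \code{"strong"} requires a purine at -3 and G at +4,
#' \code{"adequate"} accepts one of the two, \code{"weak"} accepts all
#' in-frame ATGs.
#'
#' @param cds coding sequence, A/C/G/T, normally starting with ATG and a
#'   multiple of 3 long (warnings otherwise).
#' @param min_codon smallest codon index reported (>= 2); for a frameshift
#'   at residue k one scans from codon k+1 onward.
#' @param stringency \code{"strong"} (default), \code{"adequate"} or
#'   \code{"weak"}.
#' @return data.frame with one row per site: \code{nt_position} (1-based,
#'   A of ATG), \code{codon_index}, \code{strength}, \code{context},
#'   \code{score}, \code{in_frame} (always \code{TRUE}); ordered by
#'   position.
#' @examples
#' kozak_scan("ATGAAAGCCACCATGGGCAAA", min_codon = 2)
#' @export
kozak_scan <- function(cds, min_codon = 2L,
                       stringency = c("strong", "adequate", "weak")) {
  stringency <- match.arg(stringency)
  cds <- toupper(cds)
  if (nchar(cds) < 3) stop("kozak_scan: cds shorter than one codon")
  bad <- regexpr("[^ACGT]", cds)
  if (bad > 0)
    stop("kozak_scan: non-ACGT character '", substr(cds, bad, bad),
         "' at position ", bad)
  if (min_codon < 2) stop("kozak_scan: min_codon must be >= 2")
  if (substr(cds, 1, 3) != "ATG")
    warning("kozak_scan: cds does not begin with ATG")
  if (nchar(cds) %% 3 != 0)
    warning("kozak_scan: cds length is not a multiple of 3")

  empty <- data.frame(nt_position = integer(), codon_index = integer(),
                      strength = character(), context = character(),
                      score = integer(), in_frame = logical(),
                      stringsAsFactors = FALSE)
  starts <- gregexpr("ATG", cds, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(empty)
  starts <- starts[starts %% 3 == 1]                 # in frame
  codons <- (starts - 1L) %/% 3L + 1L
  keep <- codons >= min_codon
  starts <- starts[keep]; codons <- codons[keep]
  if (!length(starts)) return(empty)
  ctx <- lapply(starts, function(p) kozak_context(cds, p))
  out <- data.frame(
    nt_position = as.integer(starts),
    codon_index = as.integer(codons),
    strength = vapply(ctx, `[[`, character(1), "strength"),
    context = vapply(ctx, `[[`, character(1), "context"),
    score = vapply(ctx, `[[`, integer(1), "score"),
    in_frame = TRUE, stringsAsFactors = FALSE)
  allowed <- switch(stringency,
                    strong = "strong",
                    adequate = c("strong", "adequate"),
                    weak = c("strong", "adequate", "weak"))
  out <- out[out$strength %in% allowed, , drop = FALSE]
  out <- out[order(out$nt_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition protein features into retained and removed after truncation
#'
#' A truncating variant retains wild-type residues 1..k (k =
#' \code{retained_wt_length}); any feature whose interval extends beyond
#' residue k is lost (a partially lost feature counts as removed, since
#' epitopes and domains generally do not survive partial deletion).
#'
#' @param consequence a truncating \code{protein_consequence}.
#' @param features data.frame \code{name, start, end} (1-based residue
#'   intervals within the wild-type protein).
#' @param protein_length wild-type protein length.
#' @return list of class \code{truncation_report}: \code{variant},
#'   \code{retained_range} (c(1, k)), \code{retained_features},
#'   \code{removed_features}.
#' @export
truncation_report <- function(consequence, features, protein_length) {
  stopifnot(inherits(consequence, "protein_consequence"))
  if (!consequence$class %in% c("stop_gain", "frameshift"))
    stop("truncation_report: consequence is not truncating (",
         consequence$class, ")")
  stopifnot(is.data.frame(features),
            all(c("name", "start", "end") %in% names(features)))
  if (nrow(features) && (any(features$start < 1) ||
                         any(features$end > protein_length) ||
                         any(features$start > features$end)))
    stop("truncation_report: feature intervals must lie within [1, ",
         protein_length, "]")
  if (consequence$first_affected_residue > protein_length)
    stop("truncation_report: variant position beyond protein length")
  k <- consequence$retained_wt_length
  removed <- features$end > k
  structure(list(variant = consequence,
                 retained_range = c(1L, k),
                 retained_features = features[!removed, , drop = FALSE],
                 removed_features = features[removed, , drop = FALSE]),
            class = "truncation_report")
}

# Average residue masses (Da), standard values used for gel-scale estimates
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' Predicted average mass of a (fusion) protein in kDa
#'
#' Sums average residue masses over the protein and any fusion partners,
#' adding one water per chain and removing one water per fusion junction —
#' i.e. the whole fusion is a single chain, so the total carries exactly
#' one water. Average (not monoisotopic) masses are used because the
#' quantity is compared against gel migration.
#'
#' @param protein amino-acid string (standard 20-letter alphabet).
#' @param fusion_partners optional character vector of partner sequences
#'   fused in frame (e.g. a YFP tag).
#' @return predicted mass in kDa.
#' @examples
#' predicted_mass("G")    # 0.07507 kDa
#' @export
predicted_mass <- function(protein, fusion_partners = character()) {
  chains <- c(protein, fusion_partners)
  res_mass <- vapply(chains, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    unknown <- setdiff(aa, names(AA_AVG_MASS))
    if (length(unknown))
      stop("predicted_mass: unknown amino-acid letter(s): ",
           paste(unknown, collapse = ", "))
    sum(AA_AVG_MASS[aa])
  }, numeric(1))
  (sum(res_mass) + WATER_MASS) / 1000
}
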