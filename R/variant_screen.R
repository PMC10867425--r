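# CIVa screen: variant-table ingestion, cross-database merging, the
# prevalence filter, allele frequencies and lollipop / database exports.
#
# Variant records are held in long form, one row per (gene, variant, source):
#   gene, hgvs_p, source, het, hom [, uniprot]
# This mirrors the per-database carrier counts reported by population
# databases and keeps cohorts separate so counts are never pooled silently.

.validate_records <- function(records) {
  need <- c("gene", "hgvs_p", "source", "het", "hom")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("variant table is missing columns: ", paste(miss, collapse = ", "))
  if (any(records$het < 0) || any(records$hom < 0))
    stop("het and hom counts must be non-negative")
  invisible(records)
}

#' Read a variant table from TSV/CSV
#'
#' Expects a header with columns \code{gene,hgvs_p,source,het,hom}
#' (an optional \code{uniprot} column is kept if present). The delimiter
#' is inferred from the file extension (.csv is comma, anything else tab).
#'
#' @param path file path.
#' @return data.frame in long record form.
#' @export
read_variant_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  .validate_records(df)
}

#' Normalize an HGVS.p string to the canonical one-letter form
#' @param hgvs_p character vector of notations.
#' @return character vector of canonical notations.
#' @export
normalize_hgvs_p <- function(hgvs_p) {
  vapply(hgvs_p, function(s) format_hgvs_p(parse_hgvs_p(s)), character(1),
         USE.NAMES = FALSE)
}

.consequence_class <- function(hgvs_p) {
  vapply(hgvs_p, function(s) parse_hgvs_p(s)$class, character(1),
         USE.NAMES = FALSE)
}

.residue_pos <- function(hgvs_p) {
  vapply(hgvs_p, function(s) parse_hgvs_p(s)$first_affected_residue,
         integer(1), USE.NAMES = FALSE)
}

#' Merge variant tables from several source databases
#'
#' Records are unified by (gene symbol, normalized HGVS.p). Each source's
#' heterozygous/homozygous carrier counts are kept as separate rows; counts
#' are never summed across sources because cohorts may overlap. A variant
#' whose consequence class differs between sources is an error.
#'
#' @param tables either a named list of record data.frames (names are the
#'   source database names, overriding any \code{source} column), or a
#'   single long-form data.frame that already carries a \code{source} column.
#' @return long-form data.frame with one row per (gene, hgvs_p, source),
#'   \code{hgvs_p} normalized, sorted by gene, residue position and source.
#' @export
merge_databases <- function(tables) {
  if (is.data.frame(tables)) {
    df <- .validate_records(tables)
  } else {
    stopifnot(is.list(tables), length(tables) > 0)
    parts <- lapply(seq_along(tables), function(i) {
      t <- tables[[i]]
      if (!is.null(names(tables)) && nzchar(names(tables)[i]))
        t$source <- names(tables)[i]
      .validate_records(t)
    })
    common <- Reduce(intersect, lapply(parts, names))
    df <- do.call(rbind, lapply(parts, function(t) t[common]))
  }
  if (nrow(df) == 0) return(df)
  df$hgvs_p <- normalize_hgvs_p(df$hgvs_p)
  key <- paste(df$gene, df$hgvs_p, sep = "|")

  dup <- duplicated(paste(key, df$source, sep = "|"))
  if (any(dup))
    stop("duplicate (gene, variant, source) rows: ",
         paste(unique(paste(df$gene, df$hgvs_p, df$source)[dup]), collapse = "; "))

  cls <- .consequence_class(df$hgvs_p)
  bad <- tapply(cls, key, function(v) length(unique(v)) > 1)
  if (any(bad))
    stop("conflicting consequence classes across sources for: ",
         paste(names(bad)[bad], collapse = "; "))

  ord <- order(df$gene, .residue_pos(df$hgvs_p), df$source)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-variant carrier counts across sources
#'
#' @param records long-form record data.frame.
#' @param sum_sources if \code{FALSE} (default) the number of individuals
#'   carrying a variant is the maximum single-source carrier count, a
#'   conservative choice when cohorts may overlap; if \code{TRUE} carriers
#'   are summed across sources.
#' @return data.frame with one row per (gene, hgvs_p):
#'   \code{n_individuals}, \code{hom_total}, \code{n_sources}.
#' @keywords internal
.carrier_counts <- function(records, sum_sources = FALSE) {
  key <- paste(records$gene, records$hgvs_p, sep = "|")
  carriers <- records$het + records$hom
  agg <- if (sum_sources) tapply(carriers, key, sum) else tapply(carriers, key, max)
  hom <- tapply(records$hom, key, sum)
  ns <- tapply(key, key, length)
  first <- !duplicated(key)
  data.frame(gene = records$gene[first], hgvs_p = records$hgvs_p[first],
             n_individuals = as.integer(agg[key[first]]),
             hom_total = as.integer(hom[key[first]]),
             n_sources = as.integer(ns[key[first]]),
             stringsAsFactors = FALSE)
}

#' CIVa prevalence filter
#'
#' Selects candidate chromosomal-instability-aiding variants: truncating
#' (premature-stop or frameshift) variants carried by at least
#' \code{min_individuals} individuals.
#'
#' @param records long-form record data.frame (any number of sources).
#' @param min_individuals minimum number of carrier individuals (default 2).
#' @param sum_sources see \code{\link{.carrier_counts}}; default \code{FALSE}.
#' @return data.frame of candidates sorted by (gene, residue position):
#'   \code{gene, hgvs_p, class, residue, n_individuals,
#'   homozygous_observed}.
#' @examples
#' tab <- data.frame(gene = "SKA3", hgvs_p = "Q70Kfs*7", source = "DB",
#'                   het = 1906, hom = 2)
#' civa_filter(tab)
#' @export
civa_filter <- function(records, min_individuals = 2L, sum_sources = FALSE) {
  stopifnot(min_individuals >= 1)
  .validate_records(records)
  empty <- data.frame(gene = character(), hgvs_p = character(),
                      class = character(), residue = integer(),
                      n_individuals = integer(),
                      homozygous_observed = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  records$hgvs_p <- normalize_hgvs_p(records$hgvs_p)
  cc <- .carrier_counts(records, sum_sources = sum_sources)
  cons <- lapply(cc$hgvs_p, parse_hgvs_p)
  lof <- vapply(cons, classify_lof, character(1))
  keep <- lof == "truncating" & cc$n_individuals >= min_individuals
  if (!any(keep)) return(empty)
  out <- data.frame(
    gene = cc$gene[keep],
    hgvs_p = cc$hgvs_p[keep],
    class = vapply(cons[keep], `[[`, character(1), "class"),
    residue = vapply(cons[keep], `[[`, integer(1), "first_affected_residue"),
    n_individuals = cc$n_individuals[keep],
    homozygous_observed = cc$hom_total[keep] >= 1L,
    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$residue, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diploid allele frequency from carrier counts
#'
#' @param het,hom numbers of heterozygous and homozygous individuals.
#' @param n_individuals cohort size (diploid individuals).
#' @return allele frequency \code{(het + 2*hom) / (2*n_individuals)}.
#' @export
allele_frequency <- function(het, hom, n_individuals) {
  if (any(n_individuals <= 0)) stop("n_individuals must be positive")
  if (any(het < 0) || any(hom < 0)) stop("counts must be non-negative")
  if (any(het + hom > n_individuals))
    stop("het + hom cannot exceed n_individuals")
  (het + 2 * hom) / (2 * n_individuals)
}

#' Tabulate variants of one gene for a lollipop plot
#'
#' One row per (residue position, category); the categories follow the
#' usual lollipop colour scheme: truncating, missense, and other
#' (start-loss, synonymous and unclassified variants).
#'
#' @param gene gene symbol; all records must belong to it.
#' @param records long-form record data.frame.
#' @return data.frame \code{position, category, n_occurrences,
#'   n_homozygous} ordered by position (carriers summed across sources).
#' @export
lollipop_export <- function(gene, records) {
  .validate_records(records)
  if (nrow(records) == 0)
    return(data.frame(position = integer(), category = character(),
                      n_occurrences = integer(), n_homozygous = integer(),
                      stringsAsFactors = FALSE))
  if (any(records$gene != gene))
    stop("lollipop_export: records from a different gene: ",
         paste(unique(setdiff(records$gene, gene)), collapse = ", "))
  cons <- lapply(records$hgvs_p, parse_hgvs_p)
  cls <- vapply(cons, `[[`, character(1), "class")
  category <- ifelse(cls %in% c("stop_gain", "frameshift"), "truncating",
                     ifelse(cls == "missense", "missense", "other"))
  pos <- vapply(cons, `[[`, integer(1), "first_affected_residue")
  key <- paste(pos, category, sep = "|")
  occ <- tapply(records$het + records$hom, key, sum)
  hom <- tapply(records$hom, key, sum)
  first <- !duplicated(key)
  out <- data.frame(position = pos[first], category = category[first],
                    n_occurrences = as.integer(occ[key[first]]),
                    n_homozygous = as.integer(hom[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a queryable CIVa database document
#'
#' Builds the JSON document backing a gene-variant lookup: a top-level
#' \code{genes} map keyed by gene symbol, each entry holding the symbol,
#' UniProt ID and the variant list with per-source counts, plus a
#' \code{uniprot_index} so entries resolve by either key.
#'
#' @param genes data.frame with columns \code{gene}, \code{uniprot} plus
#'   long-form record columns (\code{hgvs_p, source, het, hom}).
#' @param path optional file path; when given the JSON is written there.
#' @return the document as a nested list (invisibly when \code{path} given).
#' @export
civa_db_export <- function(genes, path = NULL) {
  .validate_records(genes)
  if (!"uniprot" %in% names(genes)) genes$uniprot <- NA_character_
  sym <- unique(genes$gene)
  upg <- vapply(sym, function(g) {
    u <- unique(genes$uniprot[genes$gene == g])
    u <- u[!is.na(u)]
    if (length(u) > 1) stop("gene ", g, " maps to multiple UniProt IDs")
    if (length(u)) u else NA_character_
  }, character(1))
  if (anyDuplicated(upg[!is.na(upg)]))
    stop("duplicate UniProt IDs across genes")
  entries <- lapply(sym, function(g) {
    rec <- genes[genes$gene == g, , drop = FALSE]
    rec$hgvs_p <- normalize_hgvs_p(rec$hgvs_p)
    vs <- lapply(unique(rec$hgvs_p), function(v) {
      r <- rec[rec$hgvs_p == v, , drop = FALSE]
      src <- lapply(seq_len(nrow(r)), function(i)
        list(het = as.integer(r$het[i]), hom = as.integer(r$hom[i])))
      names(src) <- r$source
      list(hgvs_p = v, class = parse_hgvs_p(v)$class, sources = src)
    })
    list(symbol = g, uniprot = upg[[g]], variants = vs)
  })
  names(entries) <- sym
  uni <- upg[!is.na(upg)]
  doc <- list(genes = entries,
              uniprot_index = as.list(stats::setNames(names(uni), uni)))
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    return(invisible(doc))
  }
  doc
}

#' Import a CIVa database document
#' @param path JSON file written by \code{\link{civa_db_export}}.
#' @return the document as a nested list.
#' @export
civa_db_import <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Query a CIVa database document by gene symbol or UniProt ID
#' @param db document from \code{\link{civa_db_export}} / import.
#' @param key gene symbol or UniProt ID.
#' @return the gene entry, or \code{NULL} if absent.
#' @export
civa_db_query <- function(db, key) {
  if (key %in% names(db$genes)) return(db$genes[[key]])
  if (key %in% names(db$uniprot_index))
    return(db$genes[[db$uniprot_index[[key]]]])
  NULL
}
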