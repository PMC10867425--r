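# Shared test helpers: brute-force oracles and truth-matching utilities.

# precision/recall of detected centroids against truth positions
match_detections <- function(truth, detected, tol_px = 2) {
  if (nrow(detected) == 0) return(c(recall = 0, precision = 0))
  d <- sqrt(outer(truth$y_px, detected$y_px, "-")^2 +
            outer(truth$x_px, detected$x_px, "-")^2)
  c(recall = mean(apply(d, 1, min) <= tol_px),
    precision = mean(apply(d, 2, min) <= tol_px))
}

# brute-force CIVa filter: record-by-record application of the two
# predicates (truncating class, >= min carriers), independent of the
# vectorized implementation
brute_civa <- function(records, min_individuals = 2, sum_sources = FALSE) {
  key <- paste(records$gene, normalize_hgvs_p(records$hgvs_p), sep = "|")
  out <- character()
  for (k in unique(key)) {
    rows <- records[key == k, , drop = FALSE]
    cons <- parse_hgvs_p(rows$hgvs_p[1])
    carriers <- rows$het + rows$hom
    n <- if (sum_sources) sum(carriers) else max(carriers)
    if (classify_lof(cons) == "truncating" && n >= min_individuals)
      out <- c(out, k)
  }
  sort(out)
}

# brute-force Kozak scan: test every position for in-frame ATG, codon
# index and context strength directly on substrings
brute_kozak <- function(cds, min_codon, stringency = "strong") {
  n <- nchar(cds)
  hits <- integer()
  for (p in seq_len(n - 2)) {
    if (substr(cds, p, p + 2) != "ATG") next
    if (p %% 3 != 1) next
    codon <- (p - 1) %/% 3 + 1
    if (codon < min_codon) next
    m3 <- if (p - 3 >= 1) substr(cds, p - 3, p - 3) else "-"
    p4 <- if (p + 3 <= n) substr(cds, p + 3, p + 3) else "-"
    strong <- m3 %in% c("A", "G") && p4 == "G"
    adequate <- xor(m3 %in% c("A", "G"), p4 == "G")
    ok <- switch(stringency,
                 strong = strong,
                 adequate = strong || adequate,
                 weak = TRUE)
    if (ok) hits <- c(hits, p)
  }
  hits
}

# random A/C/G/T sequence beginning with ATG, length a multiple of 3
random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(c("A", "C", "G", "T"),
                             3 * (n_codons - 1), replace = TRUE),
                      collapse = ""))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
brute_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = p)
}

# random long-form variant table for filter oracle checks
random_variant_table <- function(n, seed) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "Q", "G", "L", "K", "S", "V")
  cls <- sample(c("stop", "fs", "mis", "syn"), n, replace = TRUE)
  pos <- sample(2:900, n, replace = TRUE)
  ref <- sample(aa, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(aa, r), 1), character(1))
  hgvs <- mapply(function(cl, p, r, al) switch(cl,
      stop = paste0(r, p, "*"),
      fs = paste0(r, p, al, "fs*", sample(2:20, 1)),
      mis = paste0(r, p, al),
      syn = paste0(r, p, "=")),
    cls, pos, ref, alt)
  data.frame(gene = sample(sprintf("G%02d", 1:12), n, replace = TRUE),
             hgvs_p = unname(hgvs),
             source = sample(c("DB1", "DB2"), n, replace = TRUE),
             het = rpois(n, 2), hom = rbinom(n, 2, 0.1),
             stringsAsFactors = FALSE)
}
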