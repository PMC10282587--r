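AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Expasy average residue masses (Da); whole-protein mass adds one water
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Amino-acid composition of proteins
#'
#' Frequencies over the 20 standard residues; non-standard letters (X, B,
#' Z, U, O, gaps) are excluded from both numerator and denominator, and a
#' trailing stop symbol (`*`) is stripped.
#'
#' @param proteins A [sequence_set()] or character vector of amino-acid
#'   sequences (named).
#' @return Matrix, one row per protein, 20 columns (standard residues),
#'   rows summing to 1; attribute `length` holds the counted residue
#'   totals. A protein with no standard residue is an error.
#' @export
aa_composition <- function(proteins) {
  s <- toupper(as.character(proteins))
  s <- sub("\\*$", "", s)
  ids <- names(proteins)
  if (is.null(ids)) ids <- paste0("p", seq_along(s))
  counts <- matrix(0L, nrow = length(s), ncol = 20,
                   dimnames = list(ids, AA20))
  for (i in seq_along(s)) {
    tab <- table(strsplit(s[i], "")[[1]])
    tab <- tab[names(tab) %in% AA20]
    counts[i, names(tab)] <- as.integer(tab)
  }
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("no standard residues in protein: ", ids[tot == 0][1])
  freq <- counts / tot
  attr(freq, "length") <- tot
  freq
}

#' Per-residue frequency percentiles of a reference proteome
#'
#' For each standard amino acid, the empirical q-th percentile
#' (nearest-rank, i.e. inverse ECDF / `quantile` type 1) of its
#' per-protein frequency across reference proteins of at least `min_len`
#' residues. Screening a proteome against the SwissProt-derived table
#' reproduces the classic compositional-bias screen.
#'
#' @param reference A [sequence_set()] of reference proteins.
#' @param q Percentile (default 99).
#' @param min_len Minimum counted residues for a reference protein to
#'   qualify (default 50).
#' @return Object of class `percentile_table`: `values` (named numeric,
#'   one per residue), `q`, `min_len`, `reference_size`.
#' @export
reference_percentiles <- function(reference, q = 99, min_len = 50) {
  freq <- aa_composition(reference)
  freq <- freq[attr(freq, "length") >= min_len, , drop = FALSE]
  if (nrow(freq) < 100)
    stop("reference too small: ", nrow(freq),
         " qualifying proteins (need >= 100)")
  values <- apply(freq, 2, stats::quantile, probs = q / 100, type = 1,
                  names = FALSE)
  structure(list(values = values, q = q, min_len = min_len,
                 reference_size = nrow(freq)),
            class = "percentile_table")
}

#' @export
print.percentile_table <- function(x, ...) {
  cat("percentile_table: P", x$q, " over ", x$reference_size,
      " reference proteins (min_len ", x$min_len, ")\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Flag compositionally biased proteins
#'
#' A protein is flagged when it has at least `min_len` counted residues
#' and the frequency of at least one amino acid reaches its reference
#' percentile.
#'
#' @param proteome A [sequence_set()] of proteins to screen.
#' @param table A [reference_percentiles()] result (built with the same
#'   `min_len`).
#' @param min_len Minimum protein length to screen (default 50).
#' @return Object of class `bias_report`: data.frame `report` (`protein`,
#'   `length`, `flagged`, `biased_aas` comma-joined) plus the frequency
#'   matrix `freq` and the `table` used.
#' @export
flag_biased_proteins <- function(proteome, table, min_len = 50) {
  stopifnot(inherits(table, "percentile_table"))
  freq <- aa_composition(proteome)
  lens <- attr(freq, "length")
  hits <- sweep(freq, 2, table$values, ">=")
  hits[lens < min_len, ] <- FALSE
  biased <- apply(hits, 1, function(z) paste(AA20[z], collapse = ","))
  report <- data.frame(protein = rownames(freq), length = as.integer(lens),
                       flagged = unname(rowSums(hits) > 0),
                       biased_aas = unname(biased))
  structure(list(report = report, freq = freq, table = table),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("bias_report:", sum(x$report$flagged), "of", nrow(x$report),
      "proteins flagged for compositional bias\n")
  invisible(x)
}

#' Narrow biased proteins to biomineralization candidates
#'
#' Keeps proteins whose bias involves the biomineralization-associated
#' residue set (DEHPST by default) and whose differential expression is
#' significant in the required direction, the classic osculum-tip
#' upregulation filter.
#'
#' @param report A [flag_biased_proteins()] result.
#' @param expr Expression table (`gene`, `log2fc`, `padj`), e.g. from
#'   [read_expression_table()].
#' @param allowed Residues that count as biomineralization-type bias.
#' @param padj_max Adjusted p-value threshold (default 1e-4).
#' @param direction `"up"` (log2fc > 0) or `"down"`.
#' @return data.frame of class `candidate_list`: `protein`, `biased_aas`
#'   (intersection with `allowed`, comma-joined), `log2fc`, `padj`,
#'   sorted by `padj`. Flagged proteins absent from `expr` are dropped
#'   with a warning.
#' @export
select_candidates <- function(report, expr,
                              allowed = c("D", "E", "H", "P", "S", "T"),
                              padj_max = 1e-4, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(report, "bias_report"))
  df <- report$report[report$report$flagged, , drop = FALSE]
  aas <- strsplit(df$biased_aas, ",", fixed = TRUE)
  shared <- lapply(aas, intersect, allowed)
  df <- df[lengths(shared) > 0, , drop = FALSE]
  shared <- shared[lengths(shared) > 0]
  m <- match(df$protein, expr$gene)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " flagged protein(s) without expression ",
            "record; excluded (first: ", df$protein[is.na(m)][1], ")")
    shared <- shared[!is.na(m)]
    df <- df[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  out <- data.frame(protein = df$protein,
                    biased_aas = vapply(shared, paste, "", collapse = ","),
                    log2fc = expr$log2fc[m], padj = expr$padj[m])
  keep <- !is.na(out$padj) & out$padj <= padj_max &
    if (direction == "up") out$log2fc > 0 else out$log2fc < 0
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$padj, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' Scan a protein for cathepsin-L style cleavage sites
#'
#' Matches the `[V/L]G'G` motif: every Val-or-Leu followed by two
#' glycines, with the cut between the glycines. Overlapping matches are
#' all reported. Fragments are returned with their predicted average
#' masses.
#'
#' @param protein A single amino-acid sequence (character scalar).
#' @param id Optional protein id for the report.
#' @return Object of class `cleavage_result`: `sites` (0-based cut
#'   positions: a fragment boundary after `site` residues), `fragments`
#'   (data.frame `sequence`, `mass_kda`), `n_sites`.
#' @export
scan_cleavage_sites <- function(protein, id = NULL) {
  s <- toupper(sub("\\*$", "", as.character(protein)[1]))
  m <- gregexpr("(?=[VL]GG)", s, perl = TRUE)[[1]]
  sites <- if (m[1] == -1) integer(0) else as.integer(m) + 1L
  # cut after [VL]G, i.e. `sites` residues from the start
  bounds <- c(0L, sites, nchar(s))
  frags <- substring(s, bounds[-length(bounds)] + 1L, bounds[-1])
  frags <- frags[nzchar(frags)]
  structure(list(id = id, sites = sites, n_sites = length(sites),
                 fragments = data.frame(
                   sequence = frags,
                   mass_kda = vapply(frags, predict_mass, 0,
                                     USE.NAMES = FALSE))),
            class = "cleavage_result")
}

#' @export
print.cleavage_result <- function(x, ...) {
  cat("cleavage_result:", x$n_sites, "cleavage site(s),",
      nrow(x$fragments), "fragment(s);",
      paste(sprintf("%.1f", x$fragments$mass_kda), collapse = " + "),
      "kDa\n")
  invisible(x)
}

#' Predicted average protein mass
#'
#' Sum of Expasy average residue masses plus one water, in kDa; the scale
#' of an SDS-PAGE band estimate.
#'
#' @param fragment Amino-acid sequence (standard residues only).
#' @return Mass in kDa.
#' @export
predict_mass <- function(fragment) {
  s <- toupper(sub("\\*$", "", as.character(fragment)[1]))
  if (!nchar(s)) stop("empty sequence")
  ch <- strsplit(s, "")[[1]]
  bad <- which(!(ch %in% AA20))
  if (length(bad))
    stop("non-standard residue '", ch[bad[1]], "' at position ", bad[1])
  (sum(AA_AVG_MASS[ch]) + WATER_MASS) / 1000
}
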