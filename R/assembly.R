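# round half away from zero (base round() is half-to-even)
.round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Filter contigs by length
#'
#' @param lengths Positive integer contig lengths (bp).
#' @param min_length Threshold in bp.
#' @param strict If `TRUE` (default), keep lengths strictly greater than
#'   the threshold — the ">2 kbp" convention used when screening
#'   single-cell assemblies for annotation; if `FALSE`, keep `>=`.
#' @return Retained lengths, input order preserved; the number retained
#'   is in attribute `n_retained`.
#' @examples
#' filter_contigs(c(1500, 2000, 2001, 9000), 2000)  # 2001, 9000
#' @export
filter_contigs <- function(lengths, min_length = 2000, strict = TRUE) {
  stopifnot(all(lengths > 0))
  keep <- if (strict) lengths > min_length else lengths >= min_length
  out <- lengths[keep]
  attr(out, "n_retained") <- length(out)
  out
}

#' Assembly N50
#'
#' The smallest contig length L such that contigs of length >= L together
#' contain at least half the assembly's total bases (descending
#' cumulative-sum convention).
#'
#' @param lengths Positive contig lengths (bp), non-empty.
#' @return N50 in bp.
#' @examples
#' n50(c(1, 2, 3, 4, 10))  # 10
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' GC content of sequences
#'
#' Percent `100 * (G + C) / (A + C + G + T)` over all sequences pooled;
#' ambiguous bases (N) are excluded from the denominator.
#'
#' @param sequences A `Biostrings::DNAStringSet`, a character vector of
#'   sequences (alphabet ACGTN, case-insensitive), or a path to a FASTA
#'   file.
#' @return GC percent.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (is.character(sequences)) {
    bad <- grepl("[^ACGTNacgtn]", sequences)
    if (any(bad)) stop("sequences contain letters outside A/C/G/T/N")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (length(sequences) == 0L) stop("no sequences")
  freq <- colSums(Biostrings::alphabetFrequency(sequences,
                                                baseOnly = TRUE))
  counted <- sum(freq[c("A", "C", "G", "T")])
  if (counted == 0) stop("no unambiguous bases to count")
  100 * sum(freq[c("G", "C")]) / counted
}

#' Extrapolate complete genome size from a partial assembly
#'
#' Scales an assembly size by its estimated completeness:
#' `assembly_size / (completeness / 100)`. Units (bp or Mbp) pass
#' through unchanged. Vectorized.
#'
#' @param assembly_size Assembly size(s).
#' @param completeness Percent completeness, strictly positive.
#' @return Estimated complete genome size(s), same units as input.
#' @examples
#' estimate_complete_size(1.26, 69.5)  # ~1.81 Mbp
#' @export
estimate_complete_size <- function(assembly_size, completeness) {
  if (any(completeness <= 0)) stop("completeness must be > 0")
  assembly_size / (completeness / 100)
}

#' Count-based percentage
#'
#' `100 * count / total`; with `round = TRUE` the report convention is
#' applied (nearest integer, halves away from zero), e.g. 28 of 66
#' genomes reports as 42%.
#'
#' @param count,total Non-negative integers, `count <= total`,
#'   `total > 0`.
#' @param round Round to the nearest integer percent for reporting.
#' @return Percent.
#' @examples
#' proportion(28, 66, round = TRUE)  # 42
#' @export
proportion <- function(count, total, round = FALSE) {
  if (total <= 0) stop("total must be positive")
  if (count < 0 || count > total) stop("count must lie in [0, total]")
  pct <- 100 * count / total
  if (round) .round_half_away(pct) else pct
}

#' Reference genome characteristics of the Hydrothermarchaeota SAGs/MAGs
#'
#' The published general characteristics of the five single-amplified
#' genomes (SAGs) and three metagenome-assembled genomes (MAGs) of
#' *Candidatus* Hydrothermarchaeota from Juan de Fuca Ridge flank crustal
#' fluids: assembly size, GC content, contig statistics, gene counts, and
#' CheckM-style completeness/contamination estimates. These values are
#' inputs (assembly and completeness estimation are upstream of this
#' package); they drive the complete-genome-size extrapolation.
#'
#' @return Data frame, one row per genome.
#' @export
table1_genomes <- function() {
  data.frame(
    genome_id = c("AC-334-K11", "AC-708-L17", "AC-335-L21", "AC-335-G21",
                  "AC-708-N22", "JdFR-16", "JdFR-17", "JdFR-18"),
    genome_type = c(rep("SAG", 5), rep("MAG", 3)),
    isolation_source = c("U1362B", "U1362A", "U1362B", "U1362B", "U1362A",
                         "U1362B", "U1362A", "U1362A"),
    assembly_size_mbp = c(0.92, 1.26, 0.73, 0.63, 0.47, 1.35, 2.18, 2.06),
    gc_pct = c(50.9, 50.7, 51.0, 50.5, 50.3, 49.7, 49.6, 39.1),
    n_contigs = c(33, 39, 23, 24, 23, 24, 1334, 22),
    max_contig_kbp = c(179, 191, 125, 129, 70.6, 45.2, 39.6, 364),
    n50_bases = c(59108, 70385, 64756, 68317, 34461, 6267, 7687, 149032),
    gene_count = c(1129, 1499, 877, 763, 543, 1715, 2771, 2320),
    completeness_pct = c(43.2, 69.5, 48.8, 39.2, 22.9, 31.1, 53.9, 96.8),
    contamination_pct = c(0.0, 1.6, 0.8, 0.0, 0.0, 7.3, 25.2, 2.4),
    stringsAsFactors = FALSE)
}

#' Complete-genome-size extrapolation across a genome table
#'
#' Applies [estimate_complete_size()] to every genome in a
#' characteristics table and aggregates. With the shipped reference table
#' restricted to SAGs this reproduces the ~1.8 Mbp complete-genome
#' estimate for the lineage.
#'
#' @param table Data frame with columns `genome_id`,
#'   `assembly_size_mbp`, `completeness_pct` (and optionally
#'   `genome_type`); defaults to [table1_genomes()].
#' @param type Optional filter on `genome_type` (e.g. `"SAG"`).
#' @return List with `per_genome` (data frame adding
#'   `estimated_size_mbp`), `mean_mbp`, `median_mbp`, and `mean_2sf`
#'   (mean rounded to two significant figures, the reporting convention
#'   for the extrapolation).
#' @examples
#' extrapolate_genome_size(type = "SAG")$mean_2sf  # 1.8
#' @export
extrapolate_genome_size <- function(table = table1_genomes(), type = NULL) {
  if (!is.null(type) && "genome_type" %in% names(table)) {
    table <- table[table$genome_type %in% type, , drop = FALSE]
  }
  if (nrow(table) == 0L) stop("no genomes to extrapolate")
  est <- estimate_complete_size(table$assembly_size_mbp,
                                table$completeness_pct)
  per_genome <- data.frame(
    genome_id = table$genome_id,
    assembly_size_mbp = table$assembly_size_mbp,
    completeness_pct = table$completeness_pct,
    estimated_size_mbp = est, stringsAsFactors = FALSE)
  list(per_genome = per_genome,
       mean_mbp = mean(est), median_mbp = median(est),
       mean_2sf = signif(mean(est), 2))
}
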