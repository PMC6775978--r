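#' Metabolic marker-set definitions
#'
#' Loads the named pathway marker sets used to score genomes, one row per
#' (set, member). The built-in file encodes the pathway inventory reported
#' for the Hydrothermarchaeota lineage: Wood-Ljungdahl
#' (fwdA-G, ftr, mch, mtd, mer, mtrA, hdrBCD), dissimilatory sulfate
#' reduction (sat, aprAB, dsrAB), nitrate reduction (nap/nar subunits),
#' mono-functional CO oxidation (cooS, cooC), the CODH/ACS complex
#' (cdhA-E), Ni-Fe hydrogenase maturation (hypA-F),
#' glycolysis/gluconeogenesis (9 enzymes including pyruvate kinase),
#' RuBisCO, and a negative-expectation methanogenesis set (mcrA, asserted
#' absent in this lineage). Grouped subunit names are already expanded to
#' individual members so pathway-completeness fractions have per-subunit
#' resolution.
#'
#' @param file Optional TSV with columns `set_name`, `member`, `ko_id`,
#'   `rule` (`any`, `all`, or `fraction`), `theta` (required for
#'   `fraction`), `expectation` (`present` or `absent`).
#' @return Data frame of class `marker_sets`.
#' @export
marker_sets <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "marker_sets.tsv",
                        package = "crustalbio", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  required <- c("set_name", "member", "ko_id", "rule", "theta", "expectation")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("marker-set table missing columns: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab[c("set_name", "member")])) {
    stop("duplicate (set, member) rows in marker sets")
  }
  if (!all(tab$rule %in% c("any", "all", "fraction"))) {
    stop("rule must be one of any/all/fraction")
  }
  if (!all(tab$expectation %in% c("present", "absent"))) {
    stop("expectation must be 'present' or 'absent'")
  }
  frac <- tab$rule == "fraction"
  if (any(frac & (is.na(tab$theta) | tab$theta <= 0 | tab$theta > 1))) {
    stop("theta must lie in (0, 1] for fractional rules")
  }
  per_set <- unique(tab[c("set_name", "rule", "theta")])
  if (anyDuplicated(per_set$set_name)) {
    stop("duplicate marker-set names with conflicting rules")
  }
  class(tab) <- c("marker_sets", "data.frame")
  tab
}

# Does each annotation row match a given marker (symbol first, KO second)?
.matches_marker <- function(annotations, member, ko_id) {
  sym <- !is.na(annotations$symbol) &
    tolower(annotations$symbol) == tolower(member)
  if (!is.na(ko_id)) {
    sym <- sym | (!is.na(annotations$ko_id) & annotations$ko_id == ko_id)
  }
  sym
}

#' Score genomes against marker sets
#'
#' Builds the genomes-by-markers presence matrix: a marker is present in a
#' genome if at least one of its annotations matches the marker's gene
#' symbol (case-insensitive) or its KO identifier (exact). Pathway
#' completeness per (genome, set) is the fraction of the set's
#' positive-expectation members present; negative (expected-absent)
#' markers are excluded from completeness and sets with only negative
#' members get `NA` completeness.
#'
#' @param annotations Data frame of gene annotations with columns
#'   `genome_id`, `gene_id`, and at least one of `symbol`, `ko_id`
#'   (see [read_annotations()]).
#' @param sets A [marker_sets()] data frame.
#' @param genomes Optional character vector fixing the genome rows (and
#'   permitting all-absent rows for genomes with no annotations);
#'   defaults to the genomes in `annotations`, input order.
#' @return Object of class `presence_matrix`: list with `genomes`,
#'   `markers` (per-member data frame), `presence` (logical genome x
#'   member matrix), `sets` (per-set rules), and `completeness` (numeric
#'   genome x set matrix).
#' @export
evaluate_presence <- function(annotations, sets = marker_sets(),
                              genomes = NULL) {
  required <- c("set_name", "member", "ko_id", "rule", "theta", "expectation")
  if (!all(required %in% names(sets))) {
    stop("marker sets must carry columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(sets[c("set_name", "member")])) {
    stop("duplicate marker-set entries")
  }
  if (is.null(genomes)) genomes <- unique(annotations$genome_id)
  if (length(genomes) == 0L) stop("no genomes to score")
  members <- sets$member
  presence <- matrix(FALSE, nrow = length(genomes), ncol = nrow(sets),
                     dimnames = list(genomes, members))
  for (g in genomes) {
    ann_g <- annotations[annotations$genome_id == g, , drop = FALSE]
    if (nrow(ann_g) == 0L) next
    presence[g, ] <- vapply(seq_len(nrow(sets)), function(j) {
      any(.matches_marker(ann_g, sets$member[j], sets$ko_id[j]))
    }, logical(1))
  }
  set_names <- unique(sets$set_name)
  completeness <- matrix(NA_real_, nrow = length(genomes),
                         ncol = length(set_names),
                         dimnames = list(genomes, set_names))
  for (sn in set_names) {
    pos <- sets$set_name == sn & sets$expectation == "present"
    if (!any(pos)) next  # purely negative set: completeness undefined
    completeness[, sn] <- rowMeans(presence[, pos, drop = FALSE])
  }
  per_set <- unique(sets[c("set_name", "rule", "theta")])
  rownames(per_set) <- per_set$set_name
  structure(
    list(genomes = genomes,
         markers = as.data.frame(sets[c("set_name", "member", "ko_id",
                                        "expectation")]),
         presence = presence, sets = per_set,
         completeness = completeness),
    class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d genomes x %d markers (%d sets)\n",
              length(x$genomes), ncol(x$presence), nrow(x$sets)))
  print(round(x$completeness, 3))
  invisible(x)
}

#' Collective (lineage-level) marker summary
#'
#' Unions presence over all genomes: a marker counts as present in the
#' lineage if found in at least one genome, the convention used when a set
#' of partial single-cell and metagenome-assembled genomes is interpreted
#' collectively. Negative-expectation sets are additionally checked: their
#' expectation is met when no genome carries any member.
#'
#' @param matrix A `presence_matrix`.
#' @return List with `marker_present` (named logical, union over genomes),
#'   `n_present` (count of present markers), and `negative_sets` (data
#'   frame `set_name`, `expectation_met`).
#' @export
lineage_summary <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (length(matrix$genomes) == 0L) stop("empty presence matrix")
  union_present <- apply(matrix$presence, 2, any)
  neg <- unique(matrix$markers$set_name[matrix$markers$expectation == "absent"])
  neg_df <- data.frame(
    set_name = neg,
    expectation_met = vapply(neg, function(sn) {
      idx <- which(matrix$markers$set_name == sn &
                     matrix$markers$expectation == "absent")
      !any(union_present[idx])
    }, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(marker_present = union_present,
       n_present = sum(union_present),
       negative_sets = neg_df)
}

#' Per-genome pathway report
#'
#' One row per genome and marker set, with the completeness fraction and
#' whether the set's rule is satisfied. Rules: `any` needs one
#' positive-expectation member present, `all` needs all of them,
#' `fraction` needs completeness `>= theta`; in every case all
#' negative-expectation members must be absent.
#'
#' @param matrix A `presence_matrix`.
#' @return Data frame `genome_id`, `pathway`, `completeness`,
#'   `rule_satisfied`.
#' @export
pathway_report <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  sets <- matrix$sets
  rows <- lapply(matrix$genomes, function(g) {
    lapply(sets$set_name, function(sn) {
      idx <- which(matrix$markers$set_name == sn)
      pres <- matrix$presence[g, idx]
      pos <- matrix$markers$expectation[idx] == "present"
      comp <- matrix$completeness[g, sn]
      rule <- sets[sn, "rule"]
      pos_ok <- if (!any(pos)) TRUE else switch(
        rule,
        any = any(pres[pos]),
        all = all(pres[pos]),
        fraction = comp >= sets[sn, "theta"])
      neg_ok <- !any(pres[!pos])
      data.frame(genome_id = g, pathway = sn, completeness = comp,
                 rule_satisfied = pos_ok && neg_ok,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}
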