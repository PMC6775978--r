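#' Per-sample COG category profile
#'
#' A genome or metagenome summarized as counts of genes per COG functional
#' category letter. `total_annotated` counts genes carrying at least one
#' category letter; genes with multi-letter category strings (e.g. `"NT"`)
#' increment each listed category but count once in the total, so the sum
#' of category counts may exceed the total.
#'
#' @param sample_id Character identifier.
#' @param sample_type `"genome"` or `"metagenome"`.
#' @param environment One of `"sediment"`, `"hydrothermal_vent"`,
#'   `"crustal_aquifer"`, `"water_column"`.
#' @param counts Named integer vector, COG category letter -> gene count.
#' @param total_annotated Number of genes with >= 1 COG category.
#' @param completeness Percent in `[0, 100]`; required for genomes,
#'   ignored (NA) for metagenomes.
#' @return Object of class `genome_profile`.
#' @export
genome_profile <- function(sample_id, sample_type, environment, counts,
                           total_annotated, completeness = NA_real_) {
  sample_type <- match.arg(sample_type, c("genome", "metagenome"))
  environment <- match.arg(environment, .ENVIRONMENTS)
  if (sample_type == "genome" &&
      (is.na(completeness) || completeness < 0 || completeness > 100)) {
    stop("genomes require completeness in [0, 100]")
  }
  stopifnot(is.numeric(total_annotated), total_annotated >= 0)
  if (length(counts) && (is.null(names(counts)) || any(counts < 0))) {
    stop("counts must be a named non-negative vector")
  }
  structure(
    list(sample_id = sample_id, sample_type = sample_type,
         environment = environment, counts = counts,
         total_annotated = as.numeric(total_annotated),
         completeness = completeness),
    class = "genome_profile")
}

#' Build a COG category profile from an annotation table
#'
#' Tallies COG category letters for one sample from a gene-annotation
#' table (IMG/M-style export; see [read_annotations()]). Multi-letter
#' category strings increment every listed category; the denominator
#' `total_annotated` is the number of genes with at least one category.
#'
#' @param annotations Annotation data frame; rows are subset to
#'   `genome_id == metadata$sample_id` when that column is present.
#' @param metadata List or one-row data frame with `sample_id`,
#'   `sample_type`, `environment`, and (for genomes) `completeness`.
#' @return A [genome_profile()].
#' @export
profile_from_annotations <- function(annotations, metadata) {
  md <- as.list(metadata)
  for (field in c("sample_id", "sample_type", "environment")) {
    if (is.null(md[[field]]) || is.na(md[[field]])) {
      stop("metadata is missing field '", field, "'")
    }
  }
  if ("genome_id" %in% names(annotations)) {
    annotations <- annotations[annotations$genome_id == md$sample_id, ,
                               drop = FALSE]
  }
  cats <- annotations$cog_category
  cats <- cats[!is.na(cats) & nzchar(cats)]
  letters_list <- strsplit(cats, "", fixed = TRUE)
  tallied <- table(unlist(letters_list))
  counts <- stats::setNames(as.integer(tallied), names(tallied))
  genome_profile(md$sample_id, md$sample_type, md$environment,
                 counts = counts, total_annotated = length(cats),
                 completeness = md$completeness %||% NA_real_)
}

#' Relative abundance of motility genes
#'
#' Fraction of COG-annotated genes assigned to category N (cell motility):
#' `counts["N"] / total_annotated`, 0 when the category is absent.
#'
#' @param profile A [genome_profile()].
#' @return Fraction in `[0, 1]`.
#' @export
motility_relative_abundance <- function(profile) {
  stopifnot(inherits(profile, "genome_profile"))
  if (profile$total_annotated == 0) {
    stop("no annotated genes in sample '", profile$sample_id, "'")
  }
  n <- profile$counts["N"]
  if (is.na(n)) n <- 0
  unname(n / profile$total_annotated)
}

#' Filter genomes by estimated completeness
#'
#' Retains genomes whose completeness meets the threshold (inclusive, so
#' "at least 10% complete" keeps a 10.0% genome); metagenomes are always
#' retained. Input order is preserved.
#'
#' @param profiles List of [genome_profile()] objects.
#' @param min_completeness Percent in `[0, 100]`.
#' @return Filtered list.
#' @export
filter_by_completeness <- function(profiles, min_completeness = 10) {
  stopifnot(min_completeness >= 0, min_completeness <= 100)
  keep <- vapply(profiles, function(p) {
    p$sample_type == "metagenome" || p$completeness >= min_completeness
  }, logical(1))
  profiles[keep]
}

#' Per-sample motility abundance table
#'
#' Tabulates the motility-gene relative abundance of each profile, with a
#' completeness-normalized column (`rel_abundance / (completeness/100)`,
#' genomes only) offered as an experimental alternative normalization.
#'
#' @param profiles List of [genome_profile()] objects.
#' @return Data frame `sample_id`, `sample_type`, `environment`,
#'   `completeness`, `rel_abundance`, `rel_abundance_per_completeness`.
#' @export
motility_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    ra <- motility_relative_abundance(p)
    data.frame(
      sample_id = p$sample_id, sample_type = p$sample_type,
      environment = p$environment, completeness = p$completeness,
      rel_abundance = ra,
      rel_abundance_per_completeness =
        if (p$sample_type == "genome") ra / (p$completeness / 100)
        else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quartile summary of motility abundance by environment
#'
#' Groups samples by environment and summarizes the motility-gene
#' relative abundance with Tukey's five-number summary (minimum, lower
#' hinge, median, upper hinge, maximum; the inclusive-median quartile
#' convention), the statistic behind box-and-whisker comparisons across
#' environments.
#'
#' @param profiles List of [genome_profile()] objects.
#' @return Data frame `environment`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, sorted by environment; zero rows for empty input.
#' @export
group_quartiles <- function(profiles) {
  if (length(profiles) == 0L) {
    return(data.frame(environment = character(), n = integer(),
                      min = numeric(), q1 = numeric(), median = numeric(),
                      q3 = numeric(), max = numeric()))
  }
  env <- vapply(profiles, `[[`, "", "environment")
  ra <- vapply(profiles, motility_relative_abundance, numeric(1))
  groups <- sort(unique(env))
  rows <- lapply(groups, function(e) {
    v <- fivenum(ra[env == e])
    data.frame(environment = e, n = sum(env == e),
               min = v[1], q1 = v[2], median = v[3], q3 = v[4], max = v[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
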