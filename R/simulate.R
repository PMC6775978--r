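# Stable per-genome sub-seed: hash the genome id so that adding or
# removing other genomes never perturbs a genome's own stream.
.sub_seed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 131 + code) %% 1999999973
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# Background COG categories assigned to non-motility genes
.BG_CATEGORIES <- c("C", "E", "F", "G", "H", "I", "J", "K", "L", "M",
                    "O", "P", "Q", "T", "U", "V")

#' Specification for synthetic annotation tables
#'
#' Describes a cohort of synthetic genomes: how many genomes per
#' environment, how many COG-annotated genes each carries, the
#' per-environment probability that a gene belongs to COG category N
#' (motility), which marker sets to plant into which genomes, and the
#' completeness range drawn per environment. Defaults describe a
#' crustal-aquifer versus sediment contrast (motility fractions 0.03 vs
#' 0.005) of the kind observed between crustal-fluid and sedimentary
#' genomes.
#'
#' @param seed Integer root seed; generation is a pure function of
#'   (spec, seed).
#' @param n_genomes Named integer vector, environment -> genome count.
#' @param genes_per_genome Number of COG-annotated background genes per
#'   genome.
#' @param motility_fraction Named numeric vector, environment ->
#'   probability in `[0, 1]`.
#' @param marker_inventory Named list, genome id -> character vector of
#'   marker-set names whose members are planted (each exactly once).
#'   Genome ids are `<environment>_g<k>`.
#' @param completeness_range Named list or single numeric length-2 range,
#'   percent, drawn uniformly per genome.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1,
                     n_genomes = c(crustal_aquifer = 30, sediment = 30),
                     genes_per_genome = 1000,
                     motility_fraction = c(crustal_aquifer = 0.03,
                                           sediment = 0.005,
                                           hydrothermal_vent = 0.02,
                                           water_column = 0.02),
                     marker_inventory = list(),
                     completeness_range = c(20, 95)) {
  stopifnot(length(n_genomes) >= 1, !is.null(names(n_genomes)))
  if (!all(names(n_genomes) %in% .ENVIRONMENTS)) {
    stop("unknown environment in n_genomes")
  }
  if (any(motility_fraction < 0 | motility_fraction > 1)) {
    stop("motility fractions must lie in [0, 1]")
  }
  missing_p <- setdiff(names(n_genomes), names(motility_fraction))
  if (length(missing_p)) {
    stop("no motility fraction for environment(s): ",
         paste(missing_p, collapse = ", "))
  }
  stopifnot(genes_per_genome >= 1)
  structure(
    list(seed = as.integer(seed), n_genomes = n_genomes,
         genes_per_genome = as.integer(genes_per_genome),
         motility_fraction = motility_fraction,
         marker_inventory = marker_inventory,
         completeness_range = completeness_range),
    class = "sim_spec")
}

#' Generate synthetic gene-annotation tables with known truth
#'
#' Emulates IMG/M-style per-genome annotation exports. For each genome:
#' plants every member of each marker set listed in the spec's inventory
#' exactly once (symbol and KO carried, no COG category, so planted
#' markers do not enter the COG-annotated denominator); assigns COG
#' category N to a Binomial(`genes_per_genome`, p) subset of background
#' genes; gives the remaining background genes random single-letter
#' categories. Returns the table together with sample metadata and a
#' machine-readable truth object; truth is a first-class output, never
#' re-derived from the generated data.
#'
#' @param spec A [sim_spec()].
#' @param sets A [marker_sets()] table the inventory is validated
#'   against.
#' @return List with `annotations` (data frame: `genome_id`, `gene_id`,
#'   `cog_id`, `cog_category`, `ko_id`, `symbol`), `metadata` (data
#'   frame: `sample_id`, `sample_type`, `environment`, `completeness`),
#'   and `truth` (list: per-genome environment, motility fraction,
#'   realized motility count, planted sets, completeness; plus the seed).
#' @export
gen_annotations <- function(spec, sets = marker_sets()) {
  stopifnot(inherits(spec, "sim_spec"))
  known_sets <- unique(sets$set_name)
  bad <- setdiff(unique(unlist(spec$marker_inventory)), known_sets)
  if (length(bad)) {
    stop("marker set(s) not in shipped sets: ", paste(bad, collapse = ", "))
  }
  ann <- list()
  meta <- list()
  truth <- list()
  for (env in names(spec$n_genomes)) {
    p <- spec$motility_fraction[[env]]
    crange <- if (is.list(spec$completeness_range)) {
      spec$completeness_range[[env]]
    } else {
      spec$completeness_range
    }
    for (k in seq_len(spec$n_genomes[[env]])) {
      gid <- sprintf("%s_g%02d", env, k)
      set.seed(.sub_seed(spec$seed, gid))
      n <- spec$genes_per_genome
      is_motile <- runif(n) < p
      cat_letters <- character(n)
      cat_letters[is_motile] <- "N"
      n_bg <- sum(!is_motile)
      cat_letters[!is_motile] <- sample(.BG_CATEGORIES, n_bg,
                                        replace = TRUE)
      rows <- data.frame(
        genome_id = gid,
        gene_id = sprintf("%s_%05d", gid, seq_len(n)),
        cog_id = sprintf("COG%04d", sample.int(5000, n, replace = TRUE)),
        cog_category = cat_letters,
        ko_id = NA_character_,
        symbol = NA_character_,
        stringsAsFactors = FALSE)
      planted <- spec$marker_inventory[[gid]]
      if (length(planted)) {
        mem <- sets[sets$set_name %in% planted &
                      sets$expectation == "present", ]
        marker_rows <- data.frame(
          genome_id = gid,
          gene_id = sprintf("%s_m%04d", gid, seq_len(nrow(mem))),
          cog_id = NA_character_,
          cog_category = NA_character_,
          ko_id = mem$ko_id,
          symbol = mem$member,
          stringsAsFactors = FALSE)
        rows <- rbind(rows, marker_rows)
      }
      completeness <- runif(1, crange[1], crange[2])
      ann[[gid]] <- rows
      meta[[gid]] <- data.frame(
        sample_id = gid, sample_type = "genome", environment = env,
        completeness = completeness, stringsAsFactors = FALSE)
      truth[[gid]] <- list(environment = env, p_motility = p,
                           n_motility = sum(is_motile),
                           n_annotated = n,
                           planted_sets = as.character(planted %||% character()),
                           completeness = completeness)
    }
  }
  list(annotations = do.call(rbind, c(ann, list(make.row.names = FALSE))),
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       truth = list(seed = spec$seed, genomes = truth))
}

#' Generate synthetic contigs as FASTA-ready sequences
#'
#' Contig lengths follow a log-normal law (truncated below at
#' `min_length`) and bases are drawn i.i.d. with G+C probability set by
#' `gc_target`, so that for total lengths of 1e5 bp or more the realized
#' GC content concentrates within about 1 percentage point of the
#' target. Record names carry the true length.
#'
#' @param seed Integer seed.
#' @param n Number of contigs (> 0).
#' @param meanlog,sdlog Log-normal length-law parameters (defaults give
#'   a median length of ~5 kbp, typical of single-cell assemblies).
#' @param gc_target Target GC percent.
#' @param min_length Minimum contig length, bp.
#' @param fixed_lengths Optional explicit lengths overriding the length
#'   law.
#' @return A `Biostrings::DNAStringSet` with names
#'   `contig_<k> length=<bp>`.
#' @export
gen_contigs <- function(seed, n, meanlog = 8.5, sdlog = 1.0,
                        gc_target = 50, min_length = 200,
                        fixed_lengths = NULL) {
  if (n <= 0) stop("n must be positive")
  set.seed(as.integer(seed))
  lengths <- if (!is.null(fixed_lengths)) {
    stopifnot(length(fixed_lengths) == n, all(fixed_lengths > 0))
    as.integer(fixed_lengths)
  } else {
    pmax(as.integer(min_length), as.integer(round(rlnorm(n, meanlog, sdlog))))
  }
  p_gc <- gc_target / 100
  probs <- c(G = p_gc / 2, C = p_gc / 2,
             A = (1 - p_gc) / 2, T = (1 - p_gc) / 2)
  seqs <- vapply(lengths, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("contig_%05d length=%d", seq_len(n), lengths)
  out
}
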