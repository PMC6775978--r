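#' Parse an elemental formula string
#'
#' Formulas are written as element symbols each followed by an integer
#' count, e.g. `"C1H1O3"` for bicarbonate or `"H2O1"` for water. A missing
#' count means 1.
#'
#' @param formula Character scalar formula.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C2H3O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("malformed formula: ", formula)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(counts == "", 1L, as.integer(counts))
  if (any(counts < 0) || length(elements) == 0L) {
    stop("formula must contain at least one element with a non-negative count")
  }
  tapply(counts, elements, sum)[unique(elements)]
}

#' Chemical species formation-property table
#'
#' Loads the table of chemical species used in the catabolic reactions:
#' name, elemental formula, charge, phase, and standard Gibbs energy and
#' enthalpy of formation at 298.15 K (kJ/mol, aqueous standard states for
#' solutes; liquid standard state for water). The built-in table covers the
#' participants of the four shipped sulfate-reduction reactions, with
#' values transcribed from the standard aqueous-geochemistry compilations
#' recorded in its `source` column. Supply `file` to use a custom table
#' with the same columns.
#'
#' @param file Optional path to a TSV with columns `name`, `formula`,
#'   `charge`, `phase`, `dGf0_kJ_mol`, `dHf0_kJ_mol`, `source`.
#' @return A data frame of class `species_table`, one row per species,
#'   row names set to species names.
#' @examples
#' sp <- species_table()
#' sp["SO4-2", "charge"]
#' @export
species_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "species_formation.tsv",
                        package = "crustalbio", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = c(charge = "integer"))
  required <- c("name", "formula", "charge", "phase",
                "dGf0_kJ_mol", "dHf0_kJ_mol")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("species table missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$name)) stop("duplicate species names in table")
  if (!all(tab$phase %in% c("aqueous", "liquid-water"))) {
    stop("phase must be 'aqueous' or 'liquid-water'")
  }
  # liquid-water is reserved for the solvent
  solvent <- tab$phase == "liquid-water"
  if (any(solvent & tab$formula != "H2O1")) {
    stop("liquid-water phase is permitted only for the solvent H2O")
  }
  for (f in tab$formula) parse_formula(f)  # validates
  rownames(tab) <- tab$name
  class(tab) <- c("species_table", "data.frame")
  tab
}

# Element-count matrix for a set of species (elements x species)
.element_matrix <- function(species_tab, names) {
  counts <- lapply(names, function(nm) parse_formula(species_tab[nm, "formula"]))
  elements <- unique(unlist(lapply(counts, names)))
  mat <- matrix(0L, nrow = length(elements), ncol = length(names),
                dimnames = list(elements, names))
  for (j in seq_along(names)) {
    mat[names(counts[[j]]), j] <- counts[[j]]
  }
  mat
}
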