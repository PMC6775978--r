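#' Construct a catabolic reaction
#'
#' A reaction is a signed stoichiometry over named species (negative
#' coefficients for reactants, positive for products) together with the
#' number of electrons transferred per formula unit as written, and the
#' designated electron donor and terminal acceptor.
#'
#' @param id Character reaction identifier.
#' @param stoichiometry Named numeric vector of signed coefficients.
#' @param n_electrons Positive number of moles of electrons transferred.
#' @param donor,acceptor Species names; both must appear as reactants.
#' @return Object of class `reaction`.
#' @examples
#' reaction("toy", c(A = -1, B = 1), n_electrons = 2,
#'          donor = "A", acceptor = "A")
#' @export
reaction <- function(id, stoichiometry, n_electrons, donor, acceptor) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometry must be a named numeric vector")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("duplicate species in stoichiometry")
  }
  if (!is.numeric(n_electrons) || length(n_electrons) != 1L ||
      n_electrons <= 0) {
    stop("n_electrons must be positive")
  }
  for (role in c(donor, acceptor)) {
    if (!role %in% names(stoichiometry)) {
      stop("donor/acceptor '", role, "' not in stoichiometry")
    }
    if (stoichiometry[[role]] >= 0) {
      stop("donor/acceptor '", role, "' must appear as a reactant ",
           "(negative coefficient)")
    }
  }
  structure(
    list(id = id, stoichiometry = stoichiometry,
         n_electrons = as.numeric(n_electrons),
         donor = donor, acceptor = acceptor),
    class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  s <- x$stoichiometry
  side <- function(sel) paste(
    sprintf("%s %s", format(abs(s[sel])), names(s)[sel]), collapse = " + ")
  cat(sprintf("<reaction %s> %s -> %s  (%g e-; donor %s, acceptor %s)\n",
              x$id, side(s < 0), side(s > 0), x$n_electrons,
              x$donor, x$acceptor))
  invisible(x)
}

#' Shipped sulfate-reduction reactions
#'
#' Reads the built-in reaction definitions: sulfate reduction coupled to
#' oxidation of carbon monoxide, hydrogen, methane, or acetate, each
#' written per mole of sulfate (8 electrons), with bicarbonate as the
#' carbon product and water as solvent.
#'
#' @param file Optional YAML file with one document entry per reaction
#'   (`id`, `stoichiometry`, `n_electrons`, `donor`, `acceptor`).
#' @return Named list of `reaction` objects.
#' @export
shipped_reactions <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "reactions.yaml",
                        package = "crustalbio", mustWork = TRUE)
  }
  docs <- yaml::read_yaml(file)
  out <- lapply(docs, function(d) {
    reaction(d$id, unlist(d$stoichiometry), d$n_electrons,
             d$donor, d$acceptor)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Validate reaction mass and charge balance
#'
#' Checks a reaction's stoichiometry against a species table: every
#' element must balance (sum of coefficient times element count is zero)
#' and so must charge. Returns a data frame of violations; zero rows means
#' the reaction is valid.
#'
#' @param reaction A `reaction` object.
#' @param species_tab A [species_table()].
#' @return Data frame with columns `type` (`"element"`, `"charge"`, or
#'   `"empty"`), `what`, and `imbalance`.
#' @examples
#' sp <- species_table()
#' rx <- shipped_reactions()
#' nrow(validate_reaction(rx$co_sulfate, sp))  # 0: balanced
#' @export
validate_reaction <- function(reaction, species_tab) {
  stopifnot(inherits(reaction, "reaction"))
  empty_df <- data.frame(type = character(), what = character(),
                         imbalance = numeric(), stringsAsFactors = FALSE)
  s <- reaction$stoichiometry
  if (length(s) == 0L) {
    return(rbind(empty_df, data.frame(type = "empty", what = "no species",
                                      imbalance = NA_real_)))
  }
  unknown <- setdiff(names(s), rownames(species_tab))
  if (length(unknown)) {
    stop("unknown species in reaction '", reaction$id, "': ",
         paste(unknown, collapse = ", "))
  }
  violations <- empty_df
  elem <- .element_matrix(species_tab, names(s))
  balance <- drop(elem %*% s)
  for (el in names(balance)[abs(balance) > 1e-9]) {
    violations <- rbind(violations, data.frame(
      type = "element", what = el, imbalance = balance[[el]]))
  }
  qbal <- sum(s * species_tab[names(s), "charge"])
  if (abs(qbal) > 1e-9) {
    violations <- rbind(violations, data.frame(
      type = "charge", what = "net charge", imbalance = qbal))
  }
  violations
}
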